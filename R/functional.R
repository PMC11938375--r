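#' Cluster neurons into functional clusters (FCs) for one state
#'
#' Hierarchically clusters the trial-averaged within-state t-auROC response
#' profiles (correlation distance, average linkage) and cuts at two clusters.
#' The cluster with the higher mean epoch response is labeled `Act-FC`, the
#' other `Inh-FC`.
#'
#' @param responses a `carma_responses` object.
#' @param state state label to cluster within.
#' @param k number of clusters (fixed at 2 by default; deeper cuts are
#'   exploratory).
#' @return tibble (class `carma_fc`): neuron, fc (`"Act-FC"`/`"Inh-FC"`; or
#'   `"FC1.."` for k > 2); attributes `state` and `mean_traces` (fc x bin).
#' @export
cluster_functional <- function(responses, state, k = 2) {
  prof <- state_profiles(responses)
  if (!state %in% dimnames(prof)[[3]]) abort("state not found in responses")
  m <- prof[, , state]
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  if (nrow(m) < 4) abort("need >= 4 neurons for functional clustering")
  if (all(apply(m, 2, function(col) length(unique(col)) == 1))) {
    abort("degenerate clustering: all response traces identical",
          class = "carma_degenerate")
  }
  hc <- stats::hclust(correlation_dist(m), method = "average")
  cl <- stats::cutree(hc, k = k)
  mean_by <- vapply(seq_len(k), function(g) mean(m[cl == g, , drop = FALSE]),
                    numeric(1))
  if (k == 2) {
    lab <- ifelse(cl == which.max(mean_by), "Act-FC", "Inh-FC")
  } else {
    ord <- order(mean_by, decreasing = TRUE)
    lab <- paste0("FC", match(cl, ord))
  }
  mean_traces <- do.call(rbind, lapply(split(seq_len(nrow(m)), lab),
                                       function(ix) colMeans(m[ix, , drop = FALSE])))
  out <- tibble::tibble(neuron = rownames(m), fc = lab)
  structure(out, class = c("carma_fc", class(tibble::tibble())),
            state = state, mean_traces = mean_traces, hclust = hc)
}

#' Differential gene expression between functional clusters
#'
#' For each gene, a two-sided Wilcoxon rank-sum test of expression between the
#' activated and inhibited FC, plus the Act/Inh mean expression ratio
#' (epsilon-guarded). Genes are returned ranked by `-log10(p)`.
#'
#' @param fc a `carma_fc` tibble (two FCs, both non-empty).
#' @param expression expression tibble.
#' @param eps denominator guard for the ratio (default 1e-9).
#' @return tibble: gene, p_value, neg_log10_p, ratio, direction (FC with the
#'   higher mean), ranked by increasing p.
#' @export
fc_gene_enrichment <- function(fc, expression, eps = 1e-9) {
  stopifnot(inherits(fc, "carma_fc"))
  if (length(unique(fc$fc)) != 2) abort("need exactly 2 non-empty FCs")
  m <- expr_to_matrix(expression)
  m <- m[fc$neuron, , drop = FALSE]
  act <- fc$fc == "Act-FC"
  res <- purrr::map_dfr(colnames(m), function(g) {
    xa <- m[act, g]; xi <- m[!act, g]
    p <- suppressWarnings(wilcox.test(xa, xi)$p.value)
    if (is.nan(p)) p <- 1  # both groups constant and equal
    ratio <- mean(xa) / max(mean(xi), eps)
    tibble::tibble(gene = g, p_value = p,
                   neg_log10_p = -log10(max(p, .Machine$double.xmin)),
                   ratio = ratio,
                   direction = ifelse(mean(xa) >= mean(xi), "Act-FC", "Inh-FC"))
  })
  dplyr::arrange(res, .data$p_value)
}

#' Cell-type enrichment within functional clusters
#'
#' For each molecular cluster, a two-sided Fisher exact test on the 2x2 table
#' (member of type x member of Act-FC), with the odds ratio.
#'
#' @param fc a `carma_fc` tibble.
#' @param clusters a `carma_clusters` tibble.
#' @return tibble: cluster, label, n_act, n_inh, odds_ratio, p_value.
#' @export
fc_celltype_enrichment <- function(fc, clusters) {
  stopifnot(inherits(fc, "carma_fc"))
  cl <- clusters[match(fc$neuron, clusters$cell), ]
  act <- fc$fc == "Act-FC"
  labels <- attr(clusters, "labels")
  purrr::map_dfr(sort(unique(cl$cluster)), function(t) {
    in_t <- cl$cluster == t
    tab <- matrix(c(sum(in_t & act), sum(in_t & !act),
                    sum(!in_t & act), sum(!in_t & !act)), 2, byrow = TRUE)
    ft <- fisher.test(tab)
    tibble::tibble(cluster = t,
                   label = if (!is.null(labels)) unname(labels[as.character(t)])
                           else sprintf("MC%d", t),
                   n_act = sum(in_t & act), n_inh = sum(in_t & !act),
                   odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
}
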