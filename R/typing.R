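#' Normalize expression to a bounded [0, 1] scale
#'
#' Applies `log1p` to each gene then divides by the gene's own maximum, so
#' every gene spans `[0, 1]` with zeros preserved. All-zero genes map to
#' all-zero columns (no division error). This is the normalization used for
#' molecular clustering and cluster naming.
#'
#' @param expression tibble with a `cell` column plus numeric gene columns.
#' @return tibble of the same shape with normalized values.
#' @export
#' @examples
#' ex <- tibble::tibble(cell = c("a", "b", "c", "d"), g1 = c(0, 1, 3, 7))
#' normalize_expression(ex)
normalize_expression <- function(expression) {
  m <- expr_to_matrix(expression)
  if (nrow(m) < 1 || ncol(m) < 1) abort("need >= 1 cell and >= 1 gene")
  lg <- log1p(m)
  mx <- apply(lg, 2, max)
  mx[mx == 0] <- 1  # all-zero gene stays all-zero
  matrix_to_expr(sweep(lg, 2, mx, "/"))
}

# correlation distance across profiles in rows of `m`; constant profiles get
# distance 1 to everything and 0 among themselves
correlation_dist <- function(m) {
  cc <- suppressWarnings(cor(t(m)))
  const <- apply(m, 1, sd) == 0
  d <- 1 - cc
  if (any(const)) {
    d[const, ] <- 1
    d[, const] <- 1
    d[const, const] <- 0
  }
  diag(d) <- 0
  stats::as.dist(d)
}

#' Cluster cells into molecularly defined clusters (MCs)
#'
#' Agglomerative hierarchical clustering of normalized expression profiles,
#' by default with correlation distance and average linkage. The dendrogram is
#' stored so the tree can be re-cut at any cluster count or height without
#' re-clustering (used by the cluster-count sweep analyses).
#'
#' @param norm normalized expression tibble (see [normalize_expression()]).
#' @param n_clusters number of clusters to cut (<= number of cells), or `NULL`
#'   if `h` is given.
#' @param h merge-height threshold to cut at (alternative to `n_clusters`).
#' @param gene_subset optional character vector restricting clustering to a
#'   subset of genes (e.g. the first nine markers).
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage linkage method for [stats::hclust()] (default `"average"`).
#' @return tibble (class `carma_clusters`) with columns `cell`, `cluster`;
#'   attributes `hclust` (the linkage tree) and `params`.
#' @export
cluster_cells <- function(norm, n_clusters = NULL, h = NULL,
                          gene_subset = NULL,
                          distance = c("correlation", "euclidean"),
                          linkage = "average") {
  distance <- match.arg(distance)
  m <- expr_to_matrix(norm)
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, colnames(m))
    if (length(missing)) abort(paste0("genes not in matrix: ",
                                      paste(missing, collapse = ", ")))
    m <- m[, gene_subset, drop = FALSE]
  }
  if (is.null(n_clusters) && is.null(h)) {
    abort("supply n_clusters or h")
  }
  if (!is.null(n_clusters) && n_clusters > nrow(m)) {
    abort(sprintf("n_clusters (%d) exceeds number of cells (%d)",
                  n_clusters, nrow(m)))
  }
  d <- if (distance == "correlation") correlation_dist(m) else stats::dist(m)
  hc <- stats::hclust(d, method = linkage)
  cl <- if (!is.null(n_clusters)) stats::cutree(hc, k = n_clusters)
        else stats::cutree(hc, h = h)
  out <- tibble::tibble(cell = rownames(m), cluster = unname(cl))
  structure(out, class = c("carma_clusters", class(out)),
            hclust = hc,
            params = list(distance = distance, linkage = linkage,
                          gene_subset = gene_subset))
}

#' Re-cut a stored molecular-clustering tree
#'
#' @param clusters a `carma_clusters` result.
#' @param n_clusters new cluster count.
#' @param h alternative merge-height threshold.
#' @return a new `carma_clusters` tibble sharing the same tree.
#' @export
cut_clusters <- function(clusters, n_clusters = NULL, h = NULL) {
  hc <- attr(clusters, "hclust")
  if (is.null(hc)) abort("no stored linkage; run cluster_cells() first")
  cl <- if (!is.null(n_clusters)) stats::cutree(hc, k = n_clusters)
        else stats::cutree(hc, h = h)
  out <- tibble::tibble(cell = clusters$cell, cluster = unname(cl))
  structure(out, class = class(clusters), hclust = hc,
            params = attr(clusters, "params"))
}

#' Name molecular clusters by their dominant marker gene
#'
#' Each cluster is labeled `MC{i}-{gene}` where `gene` has the highest
#' cluster-mean normalized expression, or `MC{i}-Low` when that mean falls
#' below `floor`. Ties go to the lower gene (column) index and are reported
#' with a message.
#'
#' @param clusters a `carma_clusters` tibble.
#' @param norm the normalized expression used for clustering.
#' @param floor minimum cluster-mean normalized expression for a gene label
#'   (default 0.1).
#' @return `clusters` with an added `label` column and a `labels` attribute
#'   (named character vector, cluster id -> label).
#' @export
name_clusters <- function(clusters, norm, floor = 0.1) {
  m <- expr_to_matrix(norm)
  m <- m[clusters$cell, , drop = FALSE]
  ids <- sort(unique(clusters$cluster))
  labels <- vapply(ids, function(i) {
    mu <- colMeans(m[clusters$cluster == i, , drop = FALSE])
    top <- which(mu == max(mu))
    if (length(top) > 1) {
      rlang::inform(sprintf(
        "cluster %d: tie between genes %s; using %s",
        i, paste(colnames(m)[top], collapse = ", "), colnames(m)[top[1]]))
    }
    if (max(mu) < floor) sprintf("MC%d-Low", i)
    else sprintf("MC%d-%s", i, colnames(m)[top[1]])
  }, character(1))
  names(labels) <- ids
  out <- dplyr::mutate(tibble::as_tibble(clusters),
                       label = unname(labels[as.character(.data$cluster)]))
  structure(out, class = c("carma_clusters", class(tibble::tibble())),
            hclust = attr(clusters, "hclust"),
            params = attr(clusters, "params"), labels = labels)
}

#' Per-cell coexpression counts and pairwise coexpression fractions
#'
#' A gene is "expressed" in a cell when its value exceeds
#' `detection_threshold`. Returns the per-cell expressed-gene counts (the
#' coexpression histogram) and the conditional pairwise fractions
#' `P(g1 expressed | g2 expressed)`.
#'
#' @param expression expression tibble.
#' @param detection_threshold expression cutoff (default 0: any signal).
#' @return list with `counts` (tibble: cell, n_expressed), `pairwise` (tibble:
#'   gene, given, fraction), `mode_n_expressed`, and `frac_multigene` (the
#'   fraction of cells expressing more than two genes).
#' @export
coexpression_summary <- function(expression, detection_threshold = 0) {
  check_scalar_number(detection_threshold, "detection_threshold", min = 0)
  m <- expr_to_matrix(expression)
  on <- m > detection_threshold
  counts <- tibble::tibble(cell = rownames(m),
                           n_expressed = unname(rowSums(on)))
  genes <- colnames(m)
  pw <- tidyr::expand_grid(gene = genes, given = genes) |>
    dplyr::filter(.data$gene != .data$given)
  pw$fraction <- purrr::map2_dbl(pw$gene, pw$given, function(g1, g2) {
    denom <- sum(on[, g2])
    if (denom == 0) NA_real_ else sum(on[, g1] & on[, g2]) / denom
  })
  tab <- table(counts$n_expressed)
  list(
    counts = counts,
    pairwise = pw,
    mode_n_expressed = as.integer(names(tab)[which.max(tab)]),
    frac_multigene = mean(counts$n_expressed > 2)
  )
}
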