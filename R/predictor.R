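#' Build normalized per-gene feature triplets
#'
#' Each gene contributes three features per neuron: `lin` = max-scaled linear
#' expression, `log` = max-scaled `log1p` expression, `det` = detection
#' indicator (expression > 0). All features are z-scored across neurons;
#' zero-variance features (e.g. from all-zero genes) are dropped with a
#' message. Genes always enter and leave downstream selection as a full
#' feature block.
#'
#' @param expression expression tibble (>= 2 neurons).
#' @return A `carma_features` object: list with `x` (neuron x feature matrix),
#'   `gene_of` (gene of each column), `genes` (genes with >= 1 retained
#'   feature), `neurons`.
#' @export
build_gene_features <- function(expression) {
  m <- expr_to_matrix(expression)
  if (nrow(m) < 2) abort("need >= 2 neurons")
  feats <- list()
  gene_of <- character()
  for (g in colnames(m)) {
    x <- m[, g]
    trio <- cbind(lin = if (max(x) > 0) x / max(x) else x,
                  log = if (max(x) > 0) log1p(x) / max(log1p(x)) else x,
                  det = as.numeric(x > 0))
    colnames(trio) <- paste0(g, "_", colnames(trio))
    keep <- apply(trio, 2, sd) > 0
    if (!all(keep)) {
      rlang::inform(sprintf("dropping zero-variance feature(s): %s",
                            paste(colnames(trio)[!keep], collapse = ", ")))
    }
    trio <- trio[, keep, drop = FALSE]
    if (ncol(trio)) {
      feats[[g]] <- scale(trio)
      gene_of <- c(gene_of, rep(g, ncol(trio)))
    }
  }
  x <- do.call(cbind, feats)
  rownames(x) <- rownames(m)
  structure(list(x = x, gene_of = gene_of, genes = unique(gene_of),
                 neurons = rownames(m)),
            class = "carma_features")
}

feature_block <- function(features, genes) {
  features$x[, features$gene_of %in% genes, drop = FALSE]
}

align_fc_labels <- function(features, labels) {
  if (inherits(labels, "carma_fc") ||
      (is.data.frame(labels) && all(c("neuron", "fc") %in% names(labels)))) {
    labels <- setNames(labels$fc, labels$neuron)[features$neurons]
  }
  y <- factor(labels)
  if (nlevels(y) < 2) abort("labels contain a single class")
  if (nlevels(y) > 2) abort("FC prediction expects binary labels")
  if (anyNA(y)) abort("labels missing for some neurons")
  y
}

# binary ridge logistic CV on a fixed fold assignment; returns mean fold
# accuracy and pooled out-of-fold scores for the second factor level
binary_cv <- function(x, y, fold, lambda) {
  x <- pad_x(x)
  n_folds <- max(fold)
  scores <- numeric(length(y))
  pred <- character(length(y))
  coefs <- numeric(ncol(x) + 1)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = lambda * c(100, 10, 1),
                          standardize = FALSE)
    scores[!tr] <- as.numeric(predict(fit, x[!tr, , drop = FALSE],
                                      type = "response", s = lambda))
    pred[!tr] <- as.character(predict(fit, x[!tr, , drop = FALSE],
                                      type = "class", s = lambda))
    coefs <- coefs + as.numeric(coef(fit, s = lambda)) / n_folds
  }
  acc <- vapply(seq_len(n_folds),
                function(f) mean(pred[fold == f] == as.character(y)[fold == f]),
                numeric(1))
  names(coefs) <- c("(Intercept)", colnames(x))
  list(accuracy = mean(acc), fold_accuracy = acc, scores = scores,
       pred = pred, coefficients = coefs[names(coefs) != ".pad"])
}

#' Predict functional-cluster membership from gene features
#'
#' L2-regularized (ridge) logistic regression with stratified k-fold
#' cross-validation. Accuracy is the mean fold accuracy; the auROC is computed
#' from the pooled out-of-fold scores by exact pair counting; coefficients are
#' averaged over folds.
#'
#' @param features a `carma_features` object (or plain numeric matrix).
#' @param labels binary FC labels: a `carma_fc` tibble or a vector aligned
#'   with the feature rows.
#' @param folds CV folds (default 10; reduced with a warning when a class is
#'   smaller).
#' @param seed integer seed (fold assignment).
#' @param lambda ridge penalty (default `1/n`).
#' @param genes optional gene subset (feature blocks).
#' @return A `carma_fc_fit` object: list with `accuracy`, `fold_accuracy`,
#'   `auroc`, `coefficients`, `predictions` tibble, `classes`.
#' @export
predict_fc <- function(features, labels, folds = 10, seed = 1L, lambda = NULL,
                       genes = NULL) {
  if (is.matrix(features)) {
    features <- list(x = features,
                     gene_of = colnames(features) %||%
                       as.character(seq_len(ncol(features))),
                     genes = colnames(features), neurons = rownames(features))
    class(features) <- "carma_features"
  }
  y <- align_fc_labels(features, labels)
  x <- if (is.null(genes)) features$x else feature_block(features, genes)
  lambda <- lambda %||% (1 / nrow(x))
  fold <- stratified_folds(y, safe_folds(y, folds, "neurons"), seed)
  fit <- binary_cv(x, y, fold, lambda)
  pos <- levels(y)[2]  # glmnet scores model P(second level)
  t_roc <- t_auroc(fit$scores[y == pos], fit$scores[y != pos])
  structure(list(accuracy = fit$accuracy, fold_accuracy = fit$fold_accuracy,
                 auroc = t_roc / 2 + 0.5,
                 coefficients = fit$coefficients,
                 predictions = tibble::tibble(
                   neuron = features$neurons %||% seq_along(y),
                   label = as.character(y), score = fit$scores,
                   predicted = fit$pred),
                 classes = levels(y), lambda = lambda, folds = fold),
            class = "carma_fc_fit")
}

#' Sequential forward feature selection over gene blocks (one round)
#'
#' Starts from the single most predictive gene (by stratified-CV accuracy on a
#' fold split fixed once for the whole search) and greedily adds the gene that
#' most improves accuracy, stopping when the best improvement is `<= tol`.
#' Ties go to the lower gene index and are reported. Genes contribute their
#' full feature triplet as an indivisible block.
#'
#' @inheritParams predict_fc
#' @param tol minimum accuracy improvement to continue (default 0.001).
#' @param pool candidate genes (default: all genes in `features`).
#' @return An `sffs_report`: list with `steps` tibble (step, gene, accuracy),
#'   `selected`, `accuracy`, `auroc`, `coefficients`, `pool`, `removed`.
#' @export
sffs <- function(features, labels, folds = 10, seed = 1L, lambda = NULL,
                 tol = 0.001, pool = NULL) {
  stopifnot(inherits(features, "carma_features"))
  pool <- pool %||% features$genes
  if (length(pool) < 1) abort("empty candidate gene pool")
  y <- align_fc_labels(features, labels)
  lambda <- lambda %||% (1 / nrow(features$x))
  fold <- stratified_folds(y, safe_folds(y, folds, "neurons"), seed)
  acc_of <- function(genes) {
    binary_cv(feature_block(features, genes), y, fold, lambda)$accuracy
  }
  selected <- character()
  path <- numeric()
  current <- -Inf
  remaining <- pool
  repeat {
    accs <- vapply(remaining, function(g) acc_of(c(selected, g)), numeric(1))
    best <- which(accs == max(accs))
    if (length(best) > 1) {
      rlang::inform(sprintf("SFFS tie between %s; using %s",
                            paste(remaining[best], collapse = ", "),
                            remaining[best[1]]))
    }
    best <- best[1]  # lower gene index wins
    if (length(selected) > 0 && accs[best] <= current + tol) break
    selected <- c(selected, remaining[best])
    path <- c(path, accs[best])
    current <- accs[best]
    remaining <- setdiff(remaining, selected)
    if (length(remaining) == 0) break
  }
  final <- predict_fc(features, labels, folds = folds, seed = seed,
                      lambda = lambda, genes = selected)
  structure(list(steps = tibble::tibble(step = seq_along(selected),
                                        gene = selected, accuracy = path),
                 selected = selected, accuracy = current,
                 auroc = final$auroc, coefficients = final$coefficients,
                 pool = pool, removed = setdiff(features$genes, pool)),
            class = "sffs_report")
}

#' Multi-round SFFS (mSFFS)
#'
#' Runs [sffs()] repeatedly; each new round removes the first-selected gene of
#' every previous round from the candidate pool, exposing genes that can
#' compensate for the removal of the most predictive gene. Stops early when
#' the pool is exhausted or a round's accuracy falls below `significance`
#' (e.g. a shuffle-null 95th percentile).
#'
#' @inheritParams sffs
#' @param n_rounds maximum number of rounds (>= 1).
#' @param significance optional accuracy floor; the first round at or below it
#'   is flagged `below_significance` and stops the recursion.
#' @return list of `sffs_report`s (class `msffs_report`), one per executed
#'   round, each with an added `round` field.
#' @export
msffs <- function(features, labels, n_rounds = 3, folds = 10, seed = 1L,
                  lambda = NULL, tol = 0.001, significance = NULL) {
  stopifnot(n_rounds >= 1)
  pool <- features$genes
  rounds <- list()
  for (r in seq_len(n_rounds)) {
    if (length(pool) == 0) {
      rlang::inform("mSFFS: candidate pool exhausted; stopping")
      break
    }
    rep_r <- sffs(features, labels, folds = folds, seed = seed,
                  lambda = lambda, tol = tol, pool = pool)
    rep_r$round <- r
    rep_r$below_significance <- !is.null(significance) &&
      rep_r$accuracy <= significance
    rounds[[r]] <- rep_r
    if (rep_r$below_significance) break
    pool <- setdiff(pool, rep_r$selected[1])
  }
  structure(rounds, class = "msffs_report")
}

#' Shuffle-null distribution of prediction accuracy
#'
#' Permutes the neuron-to-label mapping `n_shuffles` times, refits the
#' cross-validated classifier on the full feature set each time, and reports
#' the 95th percentile of shuffled accuracies plus the empirical p-value of
#' the real accuracy.
#'
#' @inheritParams predict_fc
#' @param n_shuffles number of permutations (>= 100).
#' @return list: `real_accuracy`, `null95`, `p_value` (empirical, with the +1
#'   correction), `null_accuracies`.
#' @export
shuffle_null <- function(features, labels, n_shuffles = 1000, seed = 1L,
                         folds = 10, lambda = NULL) {
  if (n_shuffles < 100) abort("n_shuffles must be >= 100")
  y <- align_fc_labels(features, labels)
  real <- suppressWarnings(
    predict_fc(features, y, folds = folds, seed = seed, lambda = lambda))
  nulls <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      ys <- y[sample.int(length(y))]
      suppressWarnings(
        predict_fc(features, ys, folds = folds, seed = seed,
                   lambda = lambda)$accuracy)
    }, numeric(1))
  })
  list(real_accuracy = real$accuracy,
       null95 = quantile(nulls, 0.95, names = FALSE),
       p_value = (sum(nulls >= real$accuracy) + 1) / (n_shuffles + 1),
       null_accuracies = nulls)
}

#' Optimal expression cutpoint by Youden's J
#'
#' Sweeps candidate thresholds (midpoints between consecutive observed
#' expression values) for classifying the positive class as
#' "expression above threshold", and returns the cutpoint maximizing
#' `J = sensitivity + specificity - 1` (ties -> lower threshold). Also
#' compares the precision -- and, when responses are supplied, the response
#' purity -- of the any-expression group (> 0) against the above-optimal
#' group.
#'
#' @param x numeric expression values of one gene.
#' @param labels binary class labels aligned with `x`.
#' @param positive label of the class expected at high expression (default:
#'   the class with the higher mean expression).
#' @param responses optional per-neuron signed response values for the purity
#'   comparison.
#' @return A `carma_youden` list: `cutpoint`, `j`, `sensitivity`,
#'   `specificity`, `positive`, `precision_any`, `precision_optimal`, and
#'   (with responses) `purity_any`, `purity_optimal`.
#' @export
youden_threshold <- function(x, labels, positive = NULL, responses = NULL) {
  y <- factor(labels)
  if (nlevels(y) < 2) abort("both classes must be present")
  if (length(unique(x)) < 2) abort("no ROC: constant expression")
  if (is.null(positive)) {
    mu <- tapply(x, y, mean)
    positive <- names(mu)[which.max(mu)]
  }
  is_pos <- y == positive
  u <- sort(unique(x))
  cuts <- (u[-length(u)] + u[-1]) / 2
  j_of <- function(cut) {
    sens <- mean(x[is_pos] > cut)
    spec <- mean(x[!is_pos] <= cut)
    sens + spec - 1
  }
  js <- vapply(cuts, j_of, numeric(1))
  best <- which(js == max(js))[1]  # ties -> lower threshold
  cut <- cuts[best]
  out <- list(
    cutpoint = cut, j = js[best],
    sensitivity = mean(x[is_pos] > cut),
    specificity = mean(x[!is_pos] <= cut),
    positive = positive,
    precision_any = if (any(x > 0)) mean(is_pos[x > 0]) else NA_real_,
    precision_optimal = mean(is_pos[x > cut])
  )
  if (!is.null(responses)) {
    out$purity_any <- if (any(x > 0)) purity(responses[x > 0]) else NA_real_
    out$purity_optimal <- purity(responses[x > cut])
  }
  structure(out, class = "carma_youden")
}

#' Concatenated per-timestamp response series
#'
#' Flattens a `carma_responses` array into a neuron x timestamp matrix by
#' concatenating all epochs in schedule order, with per-column metadata.
#'
#' @param responses a `carma_responses` object.
#' @return list: `values` (neuron x timestamp matrix), `info` tibble (column,
#'   state, trial, time_s from epoch onset).
#' @export
response_series <- function(responses) {
  ep <- responses$epochs
  cols <- purrr::map(seq_len(nrow(ep)), function(j) {
    responses$values[, seq_len(ep$n_bins[j]), j, drop = FALSE][, , 1]
  })
  values <- do.call(cbind, cols)
  info <- purrr::map_dfr(seq_len(nrow(ep)), function(j) {
    tibble::tibble(state = ep$state[j], trial = ep$trial[j],
                   time_s = responses$bin_times[seq_len(ep$n_bins[j])])
  })
  info$column <- seq_len(nrow(info))
  list(values = values, info = dplyr::relocate(info, "column"))
}

# multi-response out-of-fold least-squares predictions. X: n x p, Y: n x T.
# Returns list(pred, null_pred): out-of-fold model predictions and
# intercept-only (train-mean) predictions.
oof_linear <- function(X, Y, fold) {
  pred <- matrix(NA_real_, nrow(Y), ncol(Y))
  null_pred <- pred
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    Xtr <- cbind(1, X[tr, , drop = FALSE])
    fit <- tryCatch(qr.solve(Xtr, Y[tr, , drop = FALSE]),
                    error = function(e) {
                      qr.coef(qr(Xtr), Y[tr, , drop = FALSE])
                    })
    fit[is.na(fit)] <- 0
    pred[!tr, ] <- cbind(1, X[!tr, , drop = FALSE]) %*% fit
    null_pred[!tr, ] <- matrix(colMeans(Y[tr, , drop = FALSE]),
                               sum(!tr), ncol(Y), byrow = TRUE)
  }
  list(pred = pred, null_pred = null_pred)
}

fde_of <- function(y, pred, null_pred) {
  1 - sum((y - pred)^2) / sum((y - null_pred)^2)
}

#' Per-timestamp fraction of deviance explained (FDE)
#'
#' At every timestamp, regresses the per-neuron response value on gene
#' features (Gaussian deviance) and reports `FDE = 1 - residual deviance /
#' null deviance`, evaluated out-of-fold by default (the null model is the
#' fold-training-set mean). Computed for each supplied gene set (typically
#' all genes, the mSFFS-optimal set, and the top-2 genes), with an optional
#' per-timestamp shuffle significance level (95th percentile of FDE after
#' permuting the gene-expression-to-neuron mapping, under the first model).
#'
#' @param features a `carma_features` object (>= 10 neurons).
#' @param series a [response_series()] list, or a neuron x timestamp matrix.
#' @param gene_sets named list of gene subsets (default: `all` genes).
#' @param folds CV folds over neurons (default 10).
#' @param seed integer seed.
#' @param n_shuffles shuffle count for the significance level (0 disables).
#' @param out_of_fold evaluate out-of-fold (default) or in-fold (then FDE of
#'   an exact linear response is 1).
#' @return A `carma_temporal_fde` object: list with `fde` tibble (timestamp,
#'   model, fde), `null95` (per-timestamp significance level or NULL),
#'   `pred`/`null_pred` per model, `series`, `fold`, `info`.
#' @export
temporal_fde <- function(features, series, gene_sets = NULL, folds = 10,
                         seed = 1L, n_shuffles = 0, out_of_fold = TRUE) {
  Y <- if (is.list(series) && !is.data.frame(series)) series$values else series
  info <- if (is.list(series) && !is.null(series$info)) series$info else
    tibble::tibble(column = seq_len(ncol(Y)))
  if (nrow(Y) < 10) abort("need >= 10 neurons for temporal FDE models")
  gene_sets <- gene_sets %||% list(all = features$genes)
  fold <- if (out_of_fold) {
    with_seed(seed, rep_len(seq_len(folds), nrow(Y))[sample.int(nrow(Y))])
  } else {
    rep(1L, nrow(Y))  # in-fold: single "fold" trained and evaluated on all
  }
  run_model <- function(X) {
    if (out_of_fold) {
      oof_linear(X, Y, fold)
    } else {
      Xi <- cbind(1, X)
      fit <- qr.coef(qr(Xi), Y)
      fit[is.na(fit)] <- 0
      list(pred = Xi %*% fit,
           null_pred = matrix(colMeans(Y), nrow(Y), ncol(Y), byrow = TRUE))
    }
  }
  fits <- lapply(gene_sets, function(gs) run_model(feature_block(features, gs)))
  fde_tab <- purrr::imap_dfr(fits, function(ft, nm) {
    tibble::tibble(
      timestamp = seq_len(ncol(Y)), model = nm,
      fde = vapply(seq_len(ncol(Y)), function(j) {
        fde_of(Y[, j], ft$pred[, j], ft$null_pred[, j])
      }, numeric(1)))
  })
  null95 <- NULL
  if (n_shuffles > 0) {
    X1 <- feature_block(features, gene_sets[[1]])
    null_fde <- with_seed(seed + 1L, {
      vapply(seq_len(n_shuffles), function(s) {
        Xs <- X1[sample.int(nrow(X1)), , drop = FALSE]
        ft <- run_model(Xs)
        vapply(seq_len(ncol(Y)), function(j) {
          fde_of(Y[, j], ft$pred[, j], ft$null_pred[, j])
        }, numeric(1))
      }, numeric(ncol(Y)))
    })
    null_fde <- matrix(null_fde, nrow = ncol(Y))
    null95 <- apply(null_fde, 1, quantile, probs = 0.95, names = FALSE)
  }
  structure(list(fde = fde_tab, null95 = null95, fits = fits, Y = Y,
                 fold = fold, info = info, gene_sets = gene_sets,
                 features = features, out_of_fold = out_of_fold),
            class = "carma_temporal_fde")
}

#' Rank neurons by predictability of their full temporal response
#'
#' For each neuron, computes the FDE of the model's (out-of-fold) predicted
#' versus observed response over the concatenated time series, tests
#' significance against a per-neuron shuffle of the gene-to-neuron mapping,
#' and assigns predictability quartiles (quartile 1 = most predictable).
#'
#' @param tf a `carma_temporal_fde` result.
#' @param model which stored gene-set model to use (default the first).
#' @param n_shuffles permutations for per-neuron significance (default 200).
#' @param seed integer seed.
#' @param alpha significance level (default 0.05).
#' @return tibble: neuron, fde, null95, significant, rank, quartile.
#' @export
neuron_fde_ranking <- function(tf, model = NULL, n_shuffles = 200, seed = 1L,
                               alpha = 0.05) {
  stopifnot(inherits(tf, "carma_temporal_fde"))
  model <- model %||% names(tf$fits)[1]
  ft <- tf$fits[[model]]
  Y <- tf$Y
  fde_n <- vapply(seq_len(nrow(Y)), function(i) {
    fde_of(Y[i, ], ft$pred[i, ], ft$null_pred[i, ])
  }, numeric(1))
  X <- feature_block(tf$features, tf$gene_sets[[model]])
  null_mat <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      Xs <- X[sample.int(nrow(X)), , drop = FALSE]
      fs <- if (tf$out_of_fold) oof_linear(Xs, Y, tf$fold) else {
        Xi <- cbind(1, Xs)
        cf <- qr.coef(qr(Xi), Y); cf[is.na(cf)] <- 0
        list(pred = Xi %*% cf, null_pred = ft$null_pred)
      }
      vapply(seq_len(nrow(Y)), function(i) {
        fde_of(Y[i, ], fs$pred[i, ], fs$null_pred[i, ])
      }, numeric(1))
    }, numeric(nrow(Y)))
  })
  null_mat <- matrix(null_mat, nrow = nrow(Y))
  crit <- apply(null_mat, 1, quantile, probs = 1 - alpha, names = FALSE)
  rk <- rank(-fde_n, ties.method = "first")
  tibble::tibble(
    neuron = rownames(Y) %||% as.character(seq_len(nrow(Y))),
    fde = fde_n, null95 = crit, significant = fde_n > crit,
    rank = rk,
    quartile = as.integer(cut(rk, breaks = 4, labels = FALSE))
  )
}

#' Enrichment tests for the most predictable neuron quartile
#'
#' Compares the top predictability quartile against the rest: per-gene
#' Wilcoxon rank-sum tests on expression levels, and per-molecular-cluster
#' Fisher exact tests on membership.
#'
#' @param ranking output of [neuron_fde_ranking()].
#' @param expression optional expression tibble.
#' @param clusters optional `carma_clusters` tibble.
#' @return list with `genes` and/or `clusters` tibbles.
#' @export
fde_quartile_tests <- function(ranking, expression = NULL, clusters = NULL) {
  top <- ranking$neuron[ranking$quartile == 1]
  out <- list()
  if (!is.null(expression)) {
    m <- expr_to_matrix(expression)[ranking$neuron, , drop = FALSE]
    is_top <- rownames(m) %in% top
    out$genes <- purrr::map_dfr(colnames(m), function(g) {
      p <- suppressWarnings(wilcox.test(m[is_top, g], m[!is_top, g],
                                        alternative = "greater")$p.value)
      tibble::tibble(gene = g, p_value = if (is.nan(p)) 1 else p,
                     mean_top = mean(m[is_top, g]),
                     mean_rest = mean(m[!is_top, g]))
    })
  }
  if (!is.null(clusters)) {
    cl <- clusters[match(ranking$neuron, clusters$cell), ]
    is_top <- ranking$quartile == 1
    out$clusters <- purrr::map_dfr(sort(unique(cl$cluster)), function(t) {
      in_t <- cl$cluster == t
      ft <- fisher.test(matrix(c(sum(in_t & is_top), sum(in_t & !is_top),
                                 sum(!in_t & is_top), sum(!in_t & !is_top)),
                               2, byrow = TRUE), alternative = "greater")
      tibble::tibble(cluster = t, n_top = sum(in_t & is_top),
                     n = sum(in_t), odds_ratio = unname(ft$estimate),
                     p_value = ft$p.value)
    })
  }
  out
}
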