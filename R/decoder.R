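#' Build per-trial decoding feature vectors
#'
#' For every labeled epoch (trial), each neuron contributes `n_bins`
#' mean-binned t-auROC values over the first `window_s` seconds of the epoch.
#' Trials are the cross-validation unit downstream (no timebin leakage).
#'
#' @param responses a `carma_responses` object.
#' @param window_s feature window from epoch onset in seconds (default 20);
#'   must not exceed the shortest epoch.
#' @param n_bins number of mean bins (default 10).
#' @return A `carma_samples` object: list with `features` (array neuron x bin
#'   x trial-sample), `labels` (state per sample), `trials`, `neurons`,
#'   `n_bins`.
#' @export
build_samples <- function(responses, window_s = 20, n_bins = 10) {
  ep <- responses$epochs
  trials_per_state <- table(ep$state)
  if (any(trials_per_state < 2)) {
    abort(paste0("every state needs >= 2 trials for cross-validation; short: ",
                 paste(names(trials_per_state)[trials_per_state < 2],
                       collapse = ", ")))
  }
  shortest <- min(ep$end_s - ep$start_s)
  if (window_s > shortest + 1e-9) {
    abort(sprintf("window_s (%g) exceeds shortest epoch (%g s)",
                  window_s, shortest))
  }
  dt <- responses$sampling_interval
  n_use <- max(1L, floor(window_s / dt + 1e-9))
  bin_of <- ceiling(seq_len(n_use) / (n_use / n_bins))
  feats <- array(NA_real_, c(length(responses$neurons), n_bins, nrow(ep)),
                 dimnames = list(responses$neurons, NULL, NULL))
  for (j in seq_len(nrow(ep))) {
    v <- responses$values[, seq_len(n_use), j, drop = FALSE][, , 1]
    if (is.null(dim(v))) v <- matrix(v, nrow = 1)
    for (b in seq_len(n_bins)) {
      feats[, b, j] <- rowMeans(v[, bin_of == b, drop = FALSE])
    }
  }
  structure(list(features = feats, labels = ep$state, trials = ep$trial,
                 neurons = responses$neurons, n_bins = n_bins),
            class = "carma_samples")
}

# ridge multinomial logistic regression with stratified CV.
# "Unit" L2 strength = penalty 1 on the summed log-likelihood, i.e. glmnet
# lambda = 1/n. Returns overall/per-state accuracy, row-normalized confusion,
# and fold-averaged per-class coefficients.
decode_core <- function(x, y, folds = 10, seed = 1L, lambda = NULL) {
  y <- factor(y)
  if (nlevels(y) < 2) abort("need >= 2 states to decode")
  x <- pad_x(as.matrix(x))
  lambda <- lambda %||% (1 / nrow(x))
  fold <- stratified_folds(y, safe_folds(y, folds, "trials"), seed)
  n_folds <- max(fold)
  classes <- levels(y)
  pred <- character(length(y))
  coefs <- matrix(0, length(classes), ncol(x),
                  dimnames = list(classes, colnames(x)))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    # short decreasing path ending at the target lambda: single-value fits
    # trip a dimnames bug in glmnet's multinomial coefficient extraction
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                          family = "multinomial", alpha = 0,
                          lambda = lambda * c(100, 10, 1),
                          standardize = FALSE)
    pred[!tr] <- as.character(predict(fit, x[!tr, , drop = FALSE],
                                      type = "class", s = lambda))
    cf <- coef(fit, s = lambda)
    for (k in seq_along(classes)) {
      coefs[k, ] <- coefs[k, ] + as.numeric(cf[[classes[k]]])[-1] / n_folds
    }
  }
  conf <- table(factor(y, classes), factor(pred, classes))
  conf <- sweep(unclass(conf), 1, pmax(rowSums(conf), 1), "/")
  acc_fold <- vapply(seq_len(n_folds),
                     function(f) mean(pred[fold == f] == y[fold == f]),
                     numeric(1))
  list(accuracy = mean(pred == y),
       fold_accuracy = acc_fold,
       per_state = diag(conf),
       confusion = conf,
       coefficients = coefs,
       correct = sum(pred == y), total = length(y),
       folds = fold)
}

#' Decode behavioral state from single neurons, grouped by cell type
#'
#' Fits one ridge multinomial logistic regression per neuron on its binned
#' t-auROC trial features with stratified cross-validation, then summarizes
#' decoding accuracy per cell type (mean over member neurons) and for the
#' `"All"` pseudo-type (every neuron regardless of type).
#'
#' @param samples a `carma_samples` object from [build_samples()].
#' @param clusters optional `carma_clusters` tibble mapping neurons to types.
#' @param folds cross-validation folds (default 10; reduced with a warning if
#'   any state has fewer trials).
#' @param seed integer seed (fold assignment).
#' @param lambda ridge penalty (default `1/n_samples`).
#' @return A `carma_decoding` object: list with `per_neuron` tibble (neuron,
#'   cluster, label, accuracy, correct, total), `summary` tibble per type
#'   (including `"All"`), and `confusion` (list of per-type mean confusion
#'   matrices, rows = true state summing to 1).
#' @export
decode_single_type <- function(samples, clusters = NULL, folds = 10,
                               seed = 1L, lambda = NULL) {
  stopifnot(inherits(samples, "carma_samples"))
  neurons <- samples$neurons
  y <- samples$labels
  res <- purrr::map(seq_along(neurons), function(i) {
    x <- t(samples$features[i, , ])
    suppressWarnings(decode_core(x, y, folds, seed, lambda))
  })
  per_neuron <- tibble::tibble(
    neuron = neurons,
    accuracy = vapply(res, `[[`, numeric(1), "accuracy"),
    correct = vapply(res, `[[`, numeric(1), "correct"),
    total = vapply(res, `[[`, numeric(1), "total")
  )
  if (!is.null(clusters)) {
    per_neuron$cluster <- clusters$cluster[match(neurons, clusters$cell)]
    labels <- attr(clusters, "labels")
    if (!is.null(labels)) {
      per_neuron$label <- unname(labels[as.character(per_neuron$cluster)])
    } else {
      per_neuron$label <- sprintf("MC%d", per_neuron$cluster)
    }
  } else {
    per_neuron$cluster <- 1L
    per_neuron$label <- "All"
  }
  summary <- per_neuron |>
    dplyr::group_by(.data$cluster, .data$label) |>
    dplyr::summarise(n_neurons = dplyr::n(),
                     accuracy = mean(.data$accuracy),
                     correct = sum(.data$correct),
                     total = sum(.data$total), .groups = "drop")
  if (!is.null(clusters)) {
    summary <- dplyr::bind_rows(summary, tibble::tibble(
      cluster = NA_integer_, label = "All", n_neurons = nrow(per_neuron),
      accuracy = mean(per_neuron$accuracy),
      correct = sum(per_neuron$correct), total = sum(per_neuron$total)))
  }
  confusion <- lapply(split(seq_along(neurons), per_neuron$cluster),
                      function(ix) {
                        Reduce(`+`, lapply(res[ix], `[[`, "confusion")) /
                          length(ix)
                      })
  structure(list(per_neuron = per_neuron, summary = summary,
                 confusion = confusion, states = sort(unique(y))),
            class = "carma_decoding")
}

#' Decode behavioral state from grouped cell-type ensembles
#'
#' Repeatedly draws one neuron per cell type (with replacement across
#' resamples), concatenates their binned t-auROC trial features into a
#' type-ensemble feature vector, and fits a cross-validated ridge multinomial
#' logistic regression per resample. Reports the resample accuracy
#' distribution, the element-wise mean confusion matrix, and per-(type, state)
#' decoding weights (mean over resamples of the summed absolute coefficients
#' of a state's class over the type's feature block, normalized to sum 1 over
#' types).
#'
#' @param samples a `carma_samples` object.
#' @param clusters `carma_clusters` tibble; every cluster must have >= 1
#'   member among the sampled neurons.
#' @param n_resamples number of ensemble draws (default 100).
#' @param folds CV folds (default 10, reduced as needed).
#' @param seed integer seed; fixed seed gives identical resamples and folds.
#' @param lambda ridge penalty (default `1/n_samples`).
#' @return A `carma_grouped` object: list with `accuracy` (vector over
#'   resamples), `confusion` (mean, rows sum to 1), `weights` (type x state
#'   matrix, columns sum to 1), `draws` (resample x type neuron ids),
#'   `types`, `labels`, `states`.
#' @export
decode_grouped <- function(samples, clusters, n_resamples = 100, folds = 10,
                           seed = 1L, lambda = NULL) {
  stopifnot(inherits(samples, "carma_samples"))
  neurons <- samples$neurons
  cl <- clusters[match(neurons, clusters$cell), ]
  types <- sort(unique(cl$cluster))
  members <- lapply(types, function(t) which(cl$cluster == t))
  if (any(lengths(members) == 0)) abort("every type needs >= 1 member neuron")
  y <- samples$labels
  states <- sort(unique(y))
  n_bins <- samples$n_bins
  draws <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(r) {
      vapply(members, function(ix) ix[sample.int(length(ix), 1)], integer(1))
    }, integer(length(types)))
  })
  draws <- matrix(draws, nrow = length(types))
  acc <- numeric(n_resamples)
  conf_sum <- NULL
  w_sum <- matrix(0, length(types), length(states),
                  dimnames = list(types, states))
  for (r in seq_len(n_resamples)) {
    x <- do.call(cbind, lapply(draws[, r], function(i) t(samples$features[i, , ])))
    colnames(x) <- paste0("t", rep(types, each = n_bins), "_b",
                          rep(seq_len(n_bins), length(types)))
    fit <- suppressWarnings(decode_core(x, y, folds, seed = seed + r, lambda))
    acc[r] <- fit$accuracy
    conf_sum <- if (is.null(conf_sum)) fit$confusion else conf_sum + fit$confusion
    blk <- rep(types, each = n_bins)
    for (s in states) {
      w_sum[, s] <- w_sum[, s] +
        vapply(types, function(t) sum(abs(fit$coefficients[s, blk == t])),
               numeric(1))
    }
  }
  w <- sweep(w_sum, 2, pmax(colSums(w_sum), 1e-12), "/")
  labels <- attr(clusters, "labels")
  structure(list(accuracy = acc, confusion = conf_sum / n_resamples,
                 weights = w, draws = draws, types = types,
                 labels = if (!is.null(labels)) unname(labels[as.character(types)])
                          else sprintf("MC%d", types),
                 states = states),
            class = "carma_grouped")
}

#' Scramble neuron-to-type assignment into dummy types
#'
#' Permutes the neuron -> cluster map, preserving the cluster size spectrum
#' exactly; the null control for grouped-ensemble decoding.
#'
#' @param clusters a `carma_clusters` tibble.
#' @param seed integer seed.
#' @return a `carma_clusters` tibble with permuted assignments.
#' @export
dummy_types <- function(clusters, seed = 1L) {
  perm <- with_seed(seed, sample.int(nrow(clusters)))
  out <- tibble::tibble(cell = clusters$cell,
                        cluster = clusters$cluster[perm])
  structure(out, class = c("carma_clusters", class(tibble::tibble())),
            labels = attr(clusters, "labels"))
}

#' Compare per-type decoding accuracies
#'
#' Overall chi-squared test on correct/incorrect counts per type, followed by
#' the Marascuillo procedure: the pair (i, j) is flagged when
#' `|p_i - p_j| > sqrt(qchisq(1 - alpha, k - 1)) *
#' sqrt(p_i(1-p_i)/n_i + p_j(1-p_j)/n_j)`.
#'
#' @param summary tibble with columns `label`, `correct`, `total` (e.g. the
#'   `summary` element of [decode_single_type()]).
#' @param alpha significance level (default 0.05).
#' @return list: `chisq` (tibble statistic, df, p_value) and `pairwise`
#'   (tibble a, b, diff, critical_range, significant).
#' @export
compare_type_accuracies <- function(summary, alpha = 0.05) {
  stopifnot(all(c("label", "correct", "total") %in% names(summary)),
            nrow(summary) >= 2)
  p <- summary$correct / summary$total
  k <- nrow(summary)
  chi <- suppressWarnings(
    chisq.test(cbind(summary$correct, summary$total - summary$correct)))
  crit <- sqrt(stats::qchisq(1 - alpha, k - 1))
  pairs <- combn(k, 2)
  pairwise <- tibble::tibble(
    a = summary$label[pairs[1, ]], b = summary$label[pairs[2, ]],
    diff = abs(p[pairs[1, ]] - p[pairs[2, ]]),
    critical_range = crit * sqrt(
      p[pairs[1, ]] * (1 - p[pairs[1, ]]) / summary$total[pairs[1, ]] +
      p[pairs[2, ]] * (1 - p[pairs[2, ]]) / summary$total[pairs[2, ]])
  )
  pairwise$significant <- pairwise$diff > pairwise$critical_range
  list(chisq = tibble::tibble(statistic = unname(chi$statistic),
                              df = unname(chi$parameter),
                              p_value = chi$p.value),
       pairwise = pairwise)
}

#' One-way repeated-measures ANOVA on per-state response amplitudes
#'
#' Neurons are the subjects, states the within-subject factor. The F statistic
#' uses the subject-removed error term; pairwise state comparisons use the
#' Tukey-Kramer studentized range on the same error term.
#'
#' @param amplitudes neuron x state numeric matrix (every neuron measured in
#'   every state).
#' @param alpha significance level for flagged pairs (default 0.05).
#' @return list: `anova` (tibble F, df1, df2, p_value) and `pairwise` (tibble
#'   a, b, diff, p_value, significant).
#' @export
amplitude_anova <- function(amplitudes, alpha = 0.05) {
  m <- as.matrix(amplitudes)
  n <- nrow(m); k <- ncol(m)
  if (k < 2) abort("need >= 2 states")
  if (any(is.na(m))) abort("every neuron must be measured in every state")
  grand <- mean(m)
  ss_state <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- max(ss_tot - ss_state - ss_subj, 0)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_err <- ss_err / df2
  if (ms_err < 1e-12 * max(ss_tot, 1)) ms_err <- 0  # degenerate: no residual
  f <- if (ss_state == 0) 0 else (ss_state / df1) / ms_err
  p <- if (ss_state == 0) 1 else pf(f, df1, df2, lower.tail = FALSE)
  mu <- colMeans(m)
  pairs <- combn(k, 2)
  dmu <- abs(mu[pairs[1, ]] - mu[pairs[2, ]])
  pq <- if (ms_err == 0) {
    ifelse(dmu > 0, 0, 1)  # no residual error: any difference is exact
  } else {
    stats::ptukey(dmu / sqrt(ms_err / n), k, df2, lower.tail = FALSE)
  }
  states <- colnames(m) %||% as.character(seq_len(k))
  list(
    anova = tibble::tibble(statistic = f, df1 = df1, df2 = df2, p_value = p),
    pairwise = tibble::tibble(a = states[pairs[1, ]], b = states[pairs[2, ]],
                              diff = unname(mu[pairs[1, ]] - mu[pairs[2, ]]),
                              p_value = unname(pq),
                              significant = unname(pq < alpha))
  )
}

#' Response-decoding diagram table
#'
#' Pairs each (type, state) consistent-response temporal maximum with the
#' type's grouped-ensemble decoding weight for that state.
#'
#' @param grouped a `carma_grouped` result.
#' @param crm a `carma_cr_map` tibble.
#' @return tibble: cluster, label, state, max_cr, weight.
#' @export
decoding_diagram <- function(grouped, crm) {
  w <- tibble::as_tibble(as.data.frame.table(grouped$weights,
                                             responseName = "weight"))
  names(w)[1:2] <- c("cluster", "state")
  w$cluster <- as.integer(as.character(w$cluster))
  w$state <- as.character(w$state)
  dplyr::inner_join(
    dplyr::select(tibble::as_tibble(crm), "cluster", "label", "state",
                  "max_cr"),
    w, by = c("cluster", "state"))
}
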