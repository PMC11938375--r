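#' Classify per-state responsiveness against a circular-shift null
#'
#' For every neuron and state, the observed whole-epoch t-auROC (pooled over
#' trials, see [state_response()]) is compared with a null distribution
#' obtained by circularly time-shifting the neuron's trace (which preserves
#' its autocorrelation) and recomputing the statistic. A neuron is
#' `activated` in a state if the observed value exceeds the null's
#' `1 - alpha/2` quantile, `inhibited` below the `alpha/2` quantile, otherwise
#' `none`.
#'
#' @param traces neuron x time dF/F matrix.
#' @param schedule a [carma_schedule()].
#' @param baseline_s baseline window in seconds (default 10).
#' @param n_shifts number of circular shifts (default 1000).
#' @param alpha two-sided significance level (default 0.05).
#' @param seed integer seed for the shift draws.
#' @return A `carma_responsiveness` object: list with `category` (neuron x
#'   state character matrix), `t_auroc` (observed values), `lower`/`upper`
#'   null quantiles, and `alpha`.
#' @export
classify_responsiveness <- function(traces, schedule, baseline_s = 10,
                                    n_shifts = 1000, alpha = 0.05, seed = 1L) {
  n_t <- ncol(traces)
  idx <- state_window_indices(schedule, n_t, baseline_s)
  states <- names(idx)
  shifts <- with_seed(seed, sample.int(n_t - 1L, n_shifts, replace = TRUE))
  obs <- matrix(NA_real_, nrow(traces), length(states),
                dimnames = list(rownames(traces), states))
  lo <- hi <- obs
  tauroc_fast <- function(tr, w) {
    nr <- length(w$response)
    r <- rank(tr[c(w$response, w$baseline)])
    2 * ((sum(r[seq_len(nr)]) - nr * (nr + 1) / 2) /
           (nr * length(w$baseline)) - 0.5)
  }
  for (i in seq_len(nrow(traces))) {
    tr <- traces[i, ]
    obs[i, ] <- vapply(idx, function(w) tauroc_fast(tr, w), numeric(1))
    null <- vapply(shifts, function(s) {
      shifted <- tr[((seq_len(n_t) + s - 1L) %% n_t) + 1L]
      vapply(idx, function(w) tauroc_fast(shifted, w), numeric(1))
    }, numeric(length(states)))
    null <- matrix(null, nrow = length(states))
    lo[i, ] <- apply(null, 1, quantile, probs = alpha / 2, names = FALSE)
    hi[i, ] <- apply(null, 1, quantile, probs = 1 - alpha / 2, names = FALSE)
  }
  category <- matrix("none", nrow(traces), length(states),
                     dimnames = dimnames(obs))
  category[obs > hi] <- "activated"
  category[obs < lo] <- "inhibited"
  structure(list(category = category, t_auroc = obs, lower = lo, upper = hi,
                 alpha = alpha),
            class = "carma_responsiveness")
}

as_category_matrix <- function(R) {
  if (inherits(R, "carma_responsiveness")) R$category
  else if (is.matrix(R)) R
  else abort("R must be a carma_responsiveness object or a category matrix")
}

#' Find labeled-line neurons within a subset of states
#'
#' A neuron is a labeled-line for state `s` within `subset` if it is
#' responsive (activated or inhibited) in `s` and `none` in every other state
#' of the subset. Activated and inhibited sets are reported separately.
#'
#' @param R a `carma_responsiveness` object or a neuron x state character
#'   matrix with entries `"activated"`, `"inhibited"`, `"none"`.
#' @param subset character vector of >= 2 state names.
#' @return tibble: state, neuron, category (only responsive labeled-line
#'   rows).
#' @export
find_labeled_lines <- function(R, subset) {
  cat_m <- as_category_matrix(R)
  if (length(subset) < 2) abort("subset must contain >= 2 states")
  missing <- setdiff(subset, colnames(cat_m))
  if (length(missing)) abort(paste0("states not in responsiveness matrix: ",
                                    paste(missing, collapse = ", ")))
  m <- cat_m[, subset, drop = FALSE]
  responsive <- m != "none"
  n_resp <- rowSums(responsive)
  purrr::map_dfr(subset, function(s) {
    sel <- which(responsive[, s] & n_resp == 1L)
    tibble::tibble(state = s,
                   neuron = rownames(m)[sel] %||% as.character(sel),
                   category = m[sel, s])
  })
}

#' Screen all k-subsets of states for labeled-line neurons
#'
#' Enumerates every size-`k` combination of states, counts labeled-line
#' neurons per state within each subset, and selects the best subset. The
#' default objective maximizes the minimum per-state count (a subset fails as
#' soon as any of its states has no dedicated neuron); `"max_total"`
#' maximizes the summed count instead.
#'
#' @param R responsiveness matrix or object (see [find_labeled_lines()]).
#' @param k subset sizes to screen (default `2:n_states`).
#' @param objective `"max_min"` (default) or `"max_total"`.
#' @return tibble (class `carma_ll_screen`): k, best_subset (list-column of
#'   state names), min_count, total_count; per-subset count tables in the
#'   `details` attribute (one tibble per k: subset id, state, count).
#' @export
screen_all_subsets <- function(R, k = NULL,
                               objective = c("max_min", "max_total")) {
  objective <- match.arg(objective)
  cat_m <- as_category_matrix(R)
  states <- colnames(cat_m)
  if (is.null(k)) k <- 2:length(states)
  stopifnot(all(k >= 2), all(k <= length(states)))
  responsive <- cat_m != "none"
  details <- list()
  rows <- purrr::map_dfr(k, function(kk) {
    combos <- combn(states, kk, simplify = FALSE)
    counts <- purrr::map(combos, function(sub) {
      r <- responsive[, sub, drop = FALSE]
      one <- rowSums(r) == 1L
      vapply(sub, function(s) sum(r[, s] & one), integer(1))
    })
    score <- vapply(counts, if (objective == "max_min") min else sum,
                    numeric(1))
    best <- which.max(score)  # ties -> first combination in lexicographic order
    details[[as.character(kk)]] <<- purrr::imap_dfr(counts, function(ct, ix) {
      tibble::tibble(subset_id = ix, state = names(ct), count = unname(ct))
    })
    tibble::tibble(k = kk, best_subset = list(combos[[best]]),
                   min_count = min(counts[[best]]),
                   total_count = sum(counts[[best]]))
  })
  structure(rows, class = c("carma_ll_screen", class(tibble::tibble())),
            details = details, objective = objective)
}

#' Fisher exact test for per-state labeled-line selectivity
#'
#' For each state in `subset`, builds a 2x2 contingency table with rows
#' (labeled-line for the state, responsive in the state but not labeled-line)
#' and columns (observed matrix, null expectation). The null expectation is
#' the average labeled-line count over matrices in which each state's
#' responsiveness column is independently permuted across neurons (breaking
#' cross-state dependence while preserving per-state rates), rounded to
#' integers. One-sided Fisher exact p (observed more selective than the
#' null).
#'
#' @param R responsiveness matrix or object.
#' @param subset state names to screen over (default: all states).
#' @param n_perm number of column permutations (default 1000).
#' @param seed integer seed.
#' @return tibble: state, observed, responsive, null_expected, p_value.
#' @export
selectivity_test <- function(R, subset = NULL, n_perm = 1000, seed = 1L) {
  cat_m <- as_category_matrix(R)
  if (is.null(subset)) subset <- colnames(cat_m)
  m <- cat_m[, subset, drop = FALSE]
  responsive <- m != "none"
  count_selective <- function(resp) {
    one <- rowSums(resp) == 1L
    vapply(subset, function(s) sum(resp[, s] & one), integer(1))
  }
  obs_sel <- count_selective(responsive)
  n_resp <- colSums(responsive)
  null_sel <- with_seed(seed, {
    acc <- numeric(length(subset))
    for (p in seq_len(n_perm)) {
      perm <- apply(responsive, 2, function(col) col[sample.int(length(col))])
      acc <- acc + count_selective(perm)
    }
    acc / n_perm
  })
  null_int <- round(null_sel)
  pvals <- vapply(seq_along(subset), function(j) {
    if (n_resp[j] == 0) {
      warn(sprintf("no responsive neurons in state '%s'; p = 1", subset[j]))
      return(1)
    }
    tab <- matrix(c(obs_sel[j], n_resp[j] - obs_sel[j],
                    null_int[j], n_resp[j] - null_int[j]),
                  nrow = 2, byrow = TRUE)
    fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
  tibble::tibble(state = subset, observed = unname(obs_sel),
                 responsive = unname(n_resp),
                 null_expected = unname(null_sel), p_value = pvals)
}

#' Group states into state classes by ensemble response similarity
#'
#' Hierarchically clusters the per-state ensemble mean-response vectors (one
#' entry per neuron: its trial-averaged mean t-auROC in the state) with
#' correlation distance and average linkage, cuts the dendrogram at
#' `threshold`, and optionally reruns the labeled-line screen with state
#' classes as pseudo-states. A neuron's class-level category is `activated`
#' (or `inhibited`) when it has at least one state of that category and none
#' of the opposite sign within the class, otherwise `none`.
#'
#' @param responses a `carma_responses` object.
#' @param threshold dendrogram cut height; must lie within `[0, max merge
#'   height]`.
#' @param R optional responsiveness matrix/object; when given, the screen is
#'   rerun on the collapsed class matrix.
#' @return list: `map` (tibble state, class), `class_matrix` (neuron x class
#'   categories, when `R` given), `screen` (see [screen_all_subsets()], when
#'   `R` given and >= 2 classes).
#' @export
state_class_grouping <- function(responses, threshold, R = NULL) {
  prof <- state_profiles(responses)
  states <- dimnames(prof)[[3]]
  if (length(states) < 2) abort("need >= 2 states")
  sv <- t(vapply(states, function(s) {
    rowMeans(prof[, , s, drop = FALSE][, , 1], na.rm = TRUE)
  }, numeric(dim(prof)[1])))
  hc <- stats::hclust(correlation_dist(sv), method = "average")
  if (threshold < 0 || threshold > max(hc$height)) {
    abort(sprintf("threshold %.3g outside dendrogram range [0, %.3g]",
                  threshold, max(hc$height)))
  }
  cl <- stats::cutree(hc, h = threshold)
  map <- tibble::tibble(state = states, class = unname(cl))
  out <- list(map = map, hclust = hc)
  if (!is.null(R)) {
    cat_m <- as_category_matrix(R)[, states, drop = FALSE]
    classes <- sort(unique(cl))
    cm <- matrix("none", nrow(cat_m), length(classes),
                 dimnames = list(rownames(cat_m), paste0("class", classes)))
    for (g in classes) {
      sub <- cat_m[, states[cl == g], drop = FALSE]
      act <- rowSums(sub == "activated") > 0
      inh <- rowSums(sub == "inhibited") > 0
      cm[act & !inh, paste0("class", g)] <- "activated"
      cm[inh & !act, paste0("class", g)] <- "inhibited"
    }
    out$class_matrix <- cm
    if (length(classes) >= 2) out$screen <- screen_all_subsets(cm)
  }
  out
}
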