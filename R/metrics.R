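#' Transformed auROC (t-auROC) of a response window against baseline
#'
#' The auROC is the probability that a response sample exceeds a baseline
#' sample, counting ties as half: `P(r > b) + 0.5 P(r = b)` over all pairs
#' (computed exactly via midranks). The transform `2 * (auROC - 0.5)` maps it
#' to `[-1, 1]`, with sign encoding activation (+) versus inhibition (-).
#'
#' @param response numeric vector of response-window dF/F samples.
#' @param baseline numeric vector of baseline-window dF/F samples.
#' @return scalar in `[-1, 1]`.
#' @export
#' @examples
#' t_auroc(c(1, 2, 3), c(0, 1, 2))  # 6 wins + 2 ties over 9 pairs
t_auroc <- function(response, baseline) {
  if (length(response) == 0 || length(baseline) == 0) {
    abort("both response and baseline windows must be non-empty")
  }
  nr <- length(response)
  nb <- length(baseline)
  r <- rank(c(response, baseline))
  u <- sum(r[seq_len(nr)]) - nr * (nr + 1) / 2
  2 * (u / (nr * nb) - 0.5)
}

# exceedance score of each sample in y against baseline b:
# P(y_i > b) + 0.5 P(y_i = b), vectorized over y
exceedance_scores <- function(y, b) {
  bs <- sort(b)
  n_lt <- findInterval(y, bs, left.open = TRUE)  # count of b <  y_i
  n_le <- findInterval(y, bs)                    # count of b <= y_i
  (n_lt + 0.5 * (n_le - n_lt)) / length(b)
}

# truncated causal rolling mean over a window of `w` samples
rolling_mean <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - w, 0)
  (cs - c(0, cs)[lo + 1]) / (i - lo)
}

#' Per-timebin t-auROC response traces
#'
#' Converts raw dF/F traces into baseline-referenced t-auROC responses: for
#' every labeled epoch, each timebin's value is the t-auROC of a causal
#' `window_s`-second dF/F window (truncated at epoch start) against the
#' `baseline_s` seconds of trace immediately preceding the epoch.
#'
#' @param traces neuron x time dF/F matrix with a `sampling_interval`
#'   attribute.
#' @param schedule a [carma_schedule()].
#' @param baseline_s pre-stimulus baseline length in seconds (default 10).
#' @param window_s causal response window in seconds (default 2).
#' @return A `carma_responses` object: list with `values` (array neuron x bin
#'   x epoch, NA-padded when epochs differ in length), `epochs` tibble
#'   (state, trial, start_s, end_s, n_bins), `bin_times` (seconds from epoch
#'   onset), `sampling_interval`, and `neurons`.
#' @export
response_traces <- function(traces, schedule, baseline_s = 10, window_s = 2) {
  stopifnot(inherits(schedule, "carma_schedule"))
  dt <- attr(traces, "sampling_interval") %||% schedule$sampling_interval
  n_t <- ncol(traces)
  ep <- schedule$epochs
  w <- max(1L, round(window_s / dt))
  idx_of <- function(from, to) {  # samples with time in [from, to)
    lo <- max(0L, ceiling(from / dt - 1e-9))
    hi <- min(n_t - 1L, floor((to - 1e-9) / dt))
    if (hi < lo) integer() else (lo:hi) + 1L
  }
  resp_idx <- purrr::map2(ep$start_s, ep$end_s, idx_of)
  base_idx <- purrr::map(ep$start_s, function(s) idx_of(s - baseline_s, s))
  if (any(lengths(base_idx) == 0)) {
    abort("empty baseline window before an epoch; reduce baseline_s",
          class = "carma_format_error")
  }
  n_bins <- lengths(resp_idx)
  vals <- array(NA_real_, c(nrow(traces), max(n_bins), nrow(ep)),
                dimnames = list(rownames(traces), NULL, NULL))
  for (j in seq_len(nrow(ep))) {
    b_ix <- base_idx[[j]]
    r_ix <- resp_idx[[j]]
    for (i in seq_len(nrow(traces))) {
      s <- exceedance_scores(traces[i, r_ix], traces[i, b_ix])
      vals[i, seq_along(r_ix), j] <- 2 * (rolling_mean(s, w) - 0.5)
    }
  }
  # guard against |value| = 1 + epsilon from the rolling-mean arithmetic
  vals <- pmin(pmax(vals, -1), 1)
  structure(list(
    values = vals,
    epochs = dplyr::mutate(ep, n_bins = n_bins),
    bin_times = (seq_len(max(n_bins)) - 1) * dt,
    sampling_interval = dt,
    neurons = rownames(traces)
  ), class = "carma_responses")
}

#' @export
print.carma_responses <- function(x, ...) {
  cat(sprintf("<carma_responses> %d neurons x %d bins x %d epochs (%d states)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              length(unique(x$epochs$state))))
  invisible(x)
}

#' @export
#' @rdname response_traces
#' @param x a `carma_responses` object.
#' @param ... unused.
tidy.carma_responses <- function(x, ...) {
  ep <- x$epochs
  purrr::map_dfr(seq_len(nrow(ep)), function(j) {
    nb <- ep$n_bins[j]
    tidyr::expand_grid(neuron = x$neurons, bin = seq_len(nb)) |>
      dplyr::mutate(state = ep$state[j], trial = ep$trial[j],
                    time_s = x$bin_times[.data$bin],
                    t_auroc = as.vector(x$values[, seq_len(nb), j]))
  })
}

#' Trial-averaged per-state response profiles
#'
#' Averages per-timebin t-auROC values across an epoch's trials, yielding one
#' response profile per neuron per state.
#'
#' @param responses a `carma_responses` object.
#' @return array neuron x bin x state (dimnames on neuron and state).
#' @export
state_profiles <- function(responses) {
  states <- unique(responses$epochs$state)
  nb <- dim(responses$values)[2]
  out <- array(NA_real_, c(length(responses$neurons), nb, length(states)),
               dimnames = list(responses$neurons, NULL, states))
  for (s in states) {
    j <- which(responses$epochs$state == s)
    out[, , s] <- apply(responses$values[, , j, drop = FALSE], c(1, 2),
                        mean, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Whole-epoch state responses
#'
#' Pools all of a state's epoch samples (and their pre-epoch baselines) and
#' computes one t-auROC per neuron per state.
#'
#' @param traces neuron x time dF/F matrix.
#' @param schedule a [carma_schedule()].
#' @param baseline_s baseline length in seconds (default 10).
#' @return neuron x state matrix of t-auROC values.
#' @export
state_response <- function(traces, schedule, baseline_s = 10) {
  idx <- state_window_indices(schedule, ncol(traces), baseline_s)
  vapply(idx, function(w) {
    apply(traces, 1, function(tr) t_auroc(tr[w$response], tr[w$baseline]))
  }, numeric(nrow(traces)))
}

# pooled response/baseline sample indices per state
state_window_indices <- function(schedule, n_t, baseline_s = 10) {
  dt <- schedule$sampling_interval
  idx_of <- function(from, to) {
    lo <- max(0L, ceiling(from / dt - 1e-9))
    hi <- min(n_t - 1L, floor((to - 1e-9) / dt))
    if (hi < lo) integer() else (lo:hi) + 1L
  }
  states <- unique(schedule$epochs$state)
  out <- lapply(states, function(s) {
    ep <- schedule$epochs[schedule$epochs$state == s, ]
    list(
      response = unlist(purrr::map2(ep$start_s, ep$end_s, idx_of)),
      baseline = unlist(purrr::map(ep$start_s,
                                   function(st) idx_of(st - baseline_s, st)))
    )
  })
  setNames(out, states)
}

#' Linear purity of a set of signed responses
#'
#' `purity = |sum(r)| / sum(|r|)`: 1 when all members respond with the same
#' sign in proportion, 0 for perfectly balanced opposite responses. Defined as
#' 0 when `sum(|r|)` falls below `eps` (silent timebin). The `"sign"`
#' alternative is the fraction-based `|n+ - n-| / n`.
#'
#' @param r numeric vector of one cluster's signed responses at one timebin.
#' @param method `"linear"` (default) or `"sign"`.
#' @param eps denominator floor (default 1e-9).
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' purity(c(0.8, 0.4, -0.2))  # 1.0 / 1.4
purity <- function(r, method = c("linear", "sign"), eps = 1e-9) {
  method <- match.arg(method)
  if (length(r) == 0) abort("purity of an empty cluster is undefined")
  if (method == "linear") {
    denom <- sum(abs(r))
    if (denom < eps) 0 else abs(sum(r)) / denom
  } else {
    if (all(r == 0)) 0 else abs(sum(r > 0) - sum(r < 0)) / length(r)
  }
}

#' Consistent-response: purity-weighted mean response
#'
#' `CR = purity(r) * mean(r)`; satisfies `|CR| <= |mean(r)|`, attenuating the
#' cluster mean when members disagree.
#'
#' @inheritParams purity
#' @return scalar with `|CR| <= |mean(r)|`.
#' @export
consistent_response <- function(r, method = c("linear", "sign"), eps = 1e-9) {
  purity(r, method, eps) * mean(r)
}

#' Cluster-by-state consistent-response map
#'
#' For every (cluster, state) pair, scans the trial-averaged response profile
#' and reports the temporal maximum of `|CR(t)|` with its sign retained,
#' together with the purity and mean response at that timebin and the time of
#' the maximum (seconds from state onset). Clusters smaller than `min_size`
#' are excluded.
#'
#' @param responses a `carma_responses` object.
#' @param clusters a `carma_clusters` tibble (cell ids must match trace
#'   neuron ids).
#' @param min_size minimum cluster size retained (default 3).
#' @param method purity flavor passed to [purity()].
#' @return tibble (class `carma_cr_map`): cluster, label, state, max_cr,
#'   response_at_max, purity_at_max, time_of_max, n_neurons.
#' @export
cr_map <- function(responses, clusters, min_size = 3,
                   method = c("linear", "sign")) {
  method <- match.arg(method)
  prof <- state_profiles(responses)
  keep <- intersect(clusters$cell, responses$neurons)
  cl <- clusters[match(keep, clusters$cell), ]
  sizes <- table(cl$cluster)
  ids <- as.integer(names(sizes)[sizes >= min_size])
  if (length(ids) == 0) abort("no cluster meets min_size")
  labels <- attr(clusters, "labels")
  states <- dimnames(prof)[[3]]
  out <- tidyr::expand_grid(cluster = ids, state = states)
  res <- purrr::pmap_dfr(out, function(cluster, state) {
    members <- cl$cell[cl$cluster == cluster]
    p <- prof[members, , state, drop = FALSE]
    nb <- sum(colSums(!is.na(p[, , 1, drop = FALSE])) > 0)
    crs <- vapply(seq_len(nb), function(b) {
      r <- p[, b, 1]
      r <- r[!is.na(r)]
      c(consistent_response(r, method), purity(r, method), mean(r))
    }, numeric(3))
    b_max <- which.max(abs(crs[1, ]))
    tibble::tibble(
      max_cr = crs[1, b_max], response_at_max = crs[3, b_max],
      purity_at_max = crs[2, b_max],
      time_of_max = responses$bin_times[b_max],
      n_neurons = length(members)
    )
  })
  out <- dplyr::bind_cols(out, res)
  out$label <- if (!is.null(labels)) unname(labels[as.character(out$cluster)])
               else sprintf("MC%d", out$cluster)
  out <- dplyr::relocate(out, "label", .after = "cluster")
  structure(out, class = c("carma_cr_map", class(tibble::tibble())))
}

#' Compare temporal response profiles of two clusters via response slopes
#'
#' Each neuron's instantaneous response slope is the least-squares slope of
#' its trial-averaged t-auROC profile against time within `window` during
#' `state`; the two clusters' slope sets are compared with a two-sample
#' Kolmogorov-Smirnov test (distinguishes slow-ramping from fast-responding
#' types with similar consistent-responses).
#'
#' @param responses a `carma_responses` object.
#' @param clusters a `carma_clusters` tibble.
#' @param cluster_a,cluster_b cluster ids to compare (each >= 3 members).
#' @param state state label.
#' @param window numeric length-2: seconds from state onset (default: whole
#'   epoch). Must span at least 2 timebins.
#' @return tibble: statistic (KS D), p_value, n_a, n_b; slopes in the
#'   `slopes` attribute.
#' @export
slope_comparison <- function(responses, clusters, cluster_a, cluster_b, state,
                             window = NULL) {
  prof <- state_profiles(responses)
  if (!state %in% dimnames(prof)[[3]]) abort("state not found in responses")
  tt <- responses$bin_times
  if (is.null(window)) window <- range(tt)
  sel <- which(tt >= window[1] & tt <= window[2])
  if (length(sel) < 2) abort("degenerate window: fewer than 2 timebins")
  slope_of <- function(cells) {
    vapply(cells, function(cc) {
      y <- prof[cc, sel, state]
      ok <- !is.na(y)
      if (sum(ok) < 2) return(NA_real_)
      unname(coef(lm(y[ok] ~ tt[sel][ok]))[2])
    }, numeric(1))
  }
  mem <- function(id) clusters$cell[clusters$cluster == id]
  a <- mem(cluster_a); b <- mem(cluster_b)
  if (length(a) < 3 || length(b) < 3) abort("both clusters need >= 3 members")
  sa <- slope_of(a); sb <- slope_of(b)
  ks <- suppressWarnings(ks.test(sa, sb))
  structure(tibble::tibble(statistic = unname(ks$statistic),
                           p_value = ks$p.value,
                           n_a = length(sa), n_b = length(sb)),
            slopes = list(a = sa, b = sb))
}
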