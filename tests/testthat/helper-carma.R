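# Shared fixtures and independent oracles, all built in code.

mini_config <- function(...) {
  args <- list(n_types = 4, n_genes = 6, n_states = 4, n_cells = 48,
               n_trials = 3)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

mini_dataset <- function(seed = 1, ...) {
  generate_dataset(mini_config(...), seed = seed)
}

# brute-force t-auROC: exhaustive pair counting
brute_tauroc <- function(response, baseline) {
  wins <- 0
  for (r in response) for (b in baseline) {
    wins <- wins + (r > b) + 0.5 * (r == b)
  }
  2 * (wins / (length(response) * length(baseline)) - 0.5)
}

# brute-force labeled-line sets by direct definition
brute_labeled_lines <- function(cat_m, subset) {
  out <- list()
  for (s in subset) {
    hits <- character()
    for (i in seq_len(nrow(cat_m))) {
      if (cat_m[i, s] != "none" &&
          all(cat_m[i, setdiff(subset, s)] == "none")) {
        hits <- c(hits, rownames(cat_m)[i])
      }
    }
    out[[s]] <- hits
  }
  out
}

# brute-force best subset (max-min objective) over all size-k subsets
brute_screen <- function(cat_m, k) {
  combos <- combn(colnames(cat_m), k, simplify = FALSE)
  scores <- vapply(combos, function(sub) {
    ll <- brute_labeled_lines(cat_m, sub)
    min(lengths(ll))
  }, numeric(1))
  list(best = combos[[which.max(scores)]], min_count = max(scores))
}

# random responsiveness matrix
random_category_matrix <- function(n_neurons, n_states, seed,
                                   p = c(0.25, 0.15, 0.6)) {
  withr::with_seed(seed, {
    matrix(sample(c("activated", "inhibited", "none"),
                  n_neurons * n_states, replace = TRUE, prob = p),
           n_neurons, n_states,
           dimnames = list(paste0("n", seq_len(n_neurons)),
                           paste0("s", seq_len(n_states))))
  })
}

# hand-rolled carma_responses object with given per-neuron state profiles:
# profiles is a list state -> neuron x bin matrix (one trial per state unless
# n_trials > 1, in which case trials are identical)
fake_responses <- function(profiles, dt = 0.4, n_trials = 2) {
  states <- names(profiles)
  nb <- ncol(profiles[[1]])
  neurons <- rownames(profiles[[1]]) %||% paste0("n", seq_len(nrow(profiles[[1]])))
  n_ep <- length(states) * n_trials
  vals <- array(NA_real_, c(length(neurons), nb, n_ep),
                dimnames = list(neurons, NULL, NULL))
  ep_state <- rep(states, n_trials)
  for (j in seq_len(n_ep)) vals[, , j] <- profiles[[ep_state[j]]]
  epochs <- tibble::tibble(
    state = ep_state,
    start_s = 10 + (seq_len(n_ep) - 1) * (nb * dt + 10),
    end_s = 10 + (seq_len(n_ep) - 1) * (nb * dt + 10) + nb * dt,
    trial = rep(seq_len(n_trials), each = length(states)),
    n_bins = nb
  )
  structure(list(values = vals, epochs = epochs,
                 bin_times = (seq_len(nb) - 1) * dt,
                 sampling_interval = dt, neurons = neurons),
            class = "carma_responses")
}

# synthetic gene-feature/label problems for selection tests: expression for
# `informative` genes shifts by `effect` in class "B"
planted_expression <- function(n, genes, informative, effect = 2,
                               seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(c("A", "B"), length.out = n)[sample.int(n)]
    m <- matrix(exp(rnorm(n * length(genes), 1, 0.6)), n,
                dimnames = list(sprintf("c%03d", seq_len(n)), genes))
    for (g in informative) {
      m[lab == "B", g] <- m[lab == "B", g] * effect
    }
    list(expression = tibble::as_tibble(m) |>
           dplyr::mutate(cell = rownames(m), .before = 1),
         labels = lab)
  })
}

# exhaustive best-subset search sharing the implementation's CV accuracy
# evaluation; ties resolved toward smaller subsets then earlier gene order
best_subset_oracle <- function(features, labels, folds = 10, seed = 1) {
  genes <- features$genes
  subsets <- unlist(lapply(seq_along(genes), function(k) {
    combn(genes, k, simplify = FALSE)
  }), recursive = FALSE)
  accs <- vapply(subsets, function(gs) {
    suppressWarnings(
      predict_fc(features, labels, folds = folds, seed = seed,
                 genes = gs)$accuracy)
  }, numeric(1))
  best <- max(accs)
  cand <- subsets[accs >= best - 1e-12]
  cand[[which.min(lengths(cand))]]
}

make_decodable <- function(n_states = 3, n_trials = 6, n_neurons = 4,
                           sep = 1, noise = 0.05, seed = 1) {
  withr::with_seed(seed, {
    states <- paste0("s", seq_len(n_states))
    nb <- 10
    profs <- lapply(states, function(s) {
      base <- sep * (match(s, states) - 1) / n_states
      matrix(base, n_neurons, nb,
             dimnames = list(paste0("n", seq_len(n_neurons)), NULL))
    })
    names(profs) <- states
    resp <- fake_responses(profs, n_trials = n_trials)
    resp$values <- resp$values + rnorm(length(resp$values), sd = noise)
    resp
  })
}


make_split_responses <- function(n = 12, nb = 20, amp = 0.8, noise = 0,
                                 seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * nb, sd = noise), n, nb,
                dimnames = list(paste0("n", seq_len(n)), NULL))
    half <- seq_len(n / 2)
    shape <- 1 - exp(-(seq_len(nb) * 0.4) / 2)
    m[half, ] <- m[half, ] + amp * matrix(shape, n / 2, nb, byrow = TRUE)
    m[-half, ] <- m[-half, ] - amp * matrix(shape, n / 2, nb, byrow = TRUE)
    fake_responses(list(stim = m))
  })
}

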