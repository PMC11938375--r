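# craft samples with a linear ramp to check bin means in closed form
test_that("feature binning averages the ramp exactly", {
  nb <- 50
  ramp <- matrix(seq_len(nb), 1, dimnames = list("n1", NULL))
  resp <- fake_responses(list(a = ramp, b = ramp), n_trials = 2)
  s <- build_samples(resp, window_s = nb * 0.4, n_bins = 10)
  # bin b averages samples 5b-4 .. 5b of the ramp
  expected <- vapply(1:10, function(b) mean((5 * b - 4):(5 * b)), numeric(1))
  expect_equal(unname(s$features[1, , 1]), expected)
  s1 <- build_samples(resp, window_s = nb * 0.4, n_bins = 1)
  expect_equal(unname(s1$features[1, 1, 1]), mean(seq_len(nb)))
  flat <- fake_responses(list(a = matrix(2, 1, nb,
                                         dimnames = list("n1", NULL)),
                              b = matrix(2, 1, nb,
                                         dimnames = list("n1", NULL))))
  sf <- build_samples(flat, window_s = nb * 0.4, n_bins = 5)
  expect_true(all(sf$features == 2))
  expect_error(build_samples(resp, window_s = 1000), "exceeds")
  one_trial <- fake_responses(list(a = ramp), n_trials = 1)
  expect_error(build_samples(one_trial, window_s = 4), ">= 2 trials")
})

test_that("separable features decode perfectly, shuffled labels at chance", {
  resp <- make_decodable(sep = 3, noise = 0.02)
  s <- build_samples(resp, window_s = 4, n_bins = 5)
  fit <- suppressWarnings(decode_single_type(s, folds = 6, seed = 1))
  expect_equal(mean(fit$per_neuron$accuracy), 1)
  expect_true(all(vapply(fit$confusion,
                         function(cm) all(abs(rowSums(cm) - 1) < 1e-9),
                         logical(1))))
  # destroy the label-feature relationship: accuracy within 3 binomial sd
  s_sh <- s
  s_sh$labels <- withr::with_seed(9, sample(s$labels))
  fit_sh <- suppressWarnings(decode_single_type(s_sh, folds = 6, seed = 1))
  chance <- 1 / 3
  n <- length(s$labels)
  expect_lt(abs(mean(fit_sh$per_neuron$accuracy) - chance),
            3 * sqrt(chance * (1 - chance) / n) + 1e-9)
})

test_that("grouped decoding is seed-deterministic and reduces for one type", {
  resp <- make_decodable(n_neurons = 6, sep = 2, noise = 0.3, seed = 2)
  s <- build_samples(resp, window_s = 4, n_bins = 5)
  cl <- tibble::tibble(cell = paste0("n", 1:6), cluster = rep(1:2, each = 3))
  g1 <- suppressWarnings(decode_grouped(s, cl, n_resamples = 8, seed = 5))
  g2 <- suppressWarnings(decode_grouped(s, cl, n_resamples = 8, seed = 5))
  expect_identical(g1$accuracy, g2$accuracy)
  expect_true(all(abs(rowSums(g1$confusion) - 1) < 1e-9))
  expect_true(all(abs(colSums(g1$weights) - 1) < 1e-9))
  # single type with a single neuron equals that neuron's own decoding
  cl1 <- tibble::tibble(cell = "n1", cluster = 1L)
  s1 <- s; s1$features <- s$features[1, , , drop = FALSE]; s1$neurons <- "n1"
  g_one <- suppressWarnings(decode_grouped(s1, cl1, n_resamples = 2, seed = 1))
  d_one <- suppressWarnings(decode_single_type(s1, seed = 1))
  expect_equal(unique(g_one$accuracy), d_one$per_neuron$accuracy[1],
               tolerance = 1e-9)
})

test_that("perfectly separable grouped ensembles decode every resample", {
  resp <- make_decodable(n_states = 6, n_trials = 4, n_neurons = 4, sep = 4,
                         noise = 0.01, seed = 3)
  s <- build_samples(resp, window_s = 4, n_bins = 5)
  cl <- tibble::tibble(cell = paste0("n", 1:4), cluster = rep(1:2, each = 2))
  g <- suppressWarnings(decode_grouped(s, cl, n_resamples = 5, seed = 2))
  expect_true(all(g$accuracy == 1))
})

test_that("dummy types preserve the size spectrum", {
  cl <- tibble::tibble(cell = paste0("n", 1:6),
                       cluster = c(1L, 1L, 1L, 2L, 2L, 3L))
  dm <- dummy_types(cl, seed = 3)
  expect_equal(sort(as.integer(table(dm$cluster))), c(1, 2, 3))
  expect_equal(dm$cell, cl$cell)
  one <- tibble::tibble(cell = c("a", "b"), cluster = c(1L, 1L))
  expect_equal(dummy_types(one, seed = 1)$cluster, one$cluster)
})

test_that("Marascuillo procedure flags clearly different proportions", {
  tab <- tibble::tibble(label = c("A", "B"),
                        correct = c(90, 50), total = c(100, 100))
  out <- compare_type_accuracies(tab)
  expect_equal(nrow(out$pairwise), 1)
  crit <- sqrt(stats::qchisq(0.95, 1)) * sqrt(0.9 * 0.1 / 100 + 0.5 * 0.5 / 100)
  expect_equal(out$pairwise$critical_range, crit, tolerance = 1e-12)
  expect_true(out$pairwise$significant)
  same <- tibble::tibble(label = c("A", "B", "C"),
                         correct = c(50, 50, 50), total = rep(100, 3))
  out2 <- compare_type_accuracies(same)
  expect_gt(out2$chisq$p_value, 0.99)
  expect_false(any(out2$pairwise$significant))
})

test_that("repeated-measures ANOVA matches the aov stratum oracle", {
  m <- matrix(c(1, 2, 3,
                2, 4, 5), ncol = 2,
              dimnames = list(paste0("n", 1:3), c("s1", "s2")))
  out <- amplitude_anova(m)
  df <- data.frame(y = as.vector(m),
                   state = factor(rep(colnames(m), each = 3)),
                   neuron = factor(rep(rownames(m), 2)))
  oracle <- summary(aov(y ~ state + Error(neuron), data = df))
  o <- oracle[["Error: Within"]][[1]]
  expect_equal(out$anova$statistic, o[["F value"]][1], tolerance = 1e-10)
  expect_equal(out$anova$p_value, o[["Pr(>F)"]][1], tolerance = 1e-10)
  flat <- matrix(rep(c(1, 5, 2), 3), ncol = 3)
  out_flat <- amplitude_anova(flat)
  expect_equal(out_flat$anova$statistic, 0)
  expect_error(amplitude_anova(m[, 1, drop = FALSE]), ">= 2 states")
})

test_that("planted amplitude differences are detected", {
  hits <- vapply(1:20, function(s) {
    m <- withr::with_seed(s, {
      base <- matrix(rnorm(12 * 3, sd = 0.3), 12, 3)
      base[, 2] <- base[, 2] + 1
      base
    })
    amplitude_anova(m)$anova$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("decoding weights concentrate on the informative type", {
  withr::with_seed(4, {
    nb <- 5
    states <- paste0("s", 1:3)
    profs <- lapply(states, function(s) {
      m <- matrix(0, 4, nb, dimnames = list(paste0("n", 1:4), NULL))
      m[1:2, ] <- 2 * (match(s, states) - 2)  # informative pair
      m
    })
    names(profs) <- states
    resp <- fake_responses(profs, n_trials = 5)
    resp$values <- resp$values + rnorm(length(resp$values), sd = 0.2)
    s <- build_samples(resp, window_s = 2, n_bins = nb)
    cl <- tibble::tibble(cell = paste0("n", 1:4), cluster = rep(1:2, each = 2))
    g <- suppressWarnings(decode_grouped(s, cl, n_resamples = 10, seed = 1))
    expect_true(all(g$weights["1", ] > g$weights["2", ]))
    crm_stub <- structure(
      tidyr::expand_grid(cluster = 1:2, state = states) |>
        dplyr::mutate(label = sprintf("MC%d", .data$cluster), max_cr = 0.5),
      class = c("carma_cr_map", class(tibble::tibble())))
    dg <- decoding_diagram(g, crm_stub)
    expect_equal(nrow(dg), 6)
    expect_true(all(c("max_cr", "weight") %in% names(dg)))
  })
})
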