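test_that("t-auROC matches hand-counted pairs and edge cases", {
  expect_equal(t_auroc(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(t_auroc(c(1, 2), c(1, 2)), 0)
  # baseline {0,1,2}, response {1,2,3}: 6 wins + 2 ties over 9 pairs
  expect_equal(t_auroc(c(1, 2, 3), c(0, 1, 2)), 2 * (7 / 9 - 0.5))
  expect_error(t_auroc(numeric(), 1:3), "non-empty")
})

test_that("t-auROC equals brute-force pair counting on 200 random windows", {
  withr::with_seed(42, {
    for (i in 1:200) {
      r <- sample(0:6, sample(2:9, 1), replace = TRUE) / 2
      b <- sample(0:6, sample(2:9, 1), replace = TRUE) / 2
      expect_equal(t_auroc(r, b), brute_tauroc(r, b), tolerance = 1e-12)
    }
  })
})

test_that("purity and consistent-response match hand formulas", {
  expect_equal(purity(c(0.5, 0.5, 0.5)), 1)
  expect_equal(purity(c(0.5, -0.5)), 0)
  expect_equal(purity(c(0.8, 0.4, -0.2)), 1.0 / 1.4)
  expect_equal(purity(rep(0, 5)), 0)  # eps floor, no 0/0
  expect_equal(consistent_response(c(0.6, 0.6, 0.6)), 0.6)
  expect_equal(consistent_response(c(0.3, -0.3)), 0)
  expect_equal(consistent_response(c(0.8, 0.4, -0.2)),
               (1.0 / 1.4) * (1.0 / 3), tolerance = 1e-12)
  expect_error(purity(numeric()), "empty")
})

test_that("purity is bounded, scale-invariant and sign-symmetric", {
  withr::with_seed(7, {
    for (i in 1:50) {
      r <- rnorm(sample(2:12, 1))
      p <- purity(r)
      expect_gte(p, 0); expect_lte(p, 1)
      expect_equal(purity(3.7 * r), p)
      expect_equal(purity(-r), p)
      expect_lte(abs(consistent_response(r)), mean(abs(r)) + 1e-12)
      expect_equal(purity(r, method = "sign"),
                   abs(sum(r > 0) - sum(r < 0)) / length(r))
    }
  })
})

test_that("per-timebin response traces agree with the t-auROC oracle", {
  ds <- mini_dataset(seed = 8)
  resp <- response_traces(ds$traces, ds$schedule, baseline_s = 10,
                          window_s = 2)
  dt <- 0.4
  ep <- resp$epochs[3, ]
  i0 <- round(ep$start_s / dt)
  base <- ds$traces[2, (i0 - 25 + 1):i0]
  for (b in c(1, 5, 17, 50)) {
    win <- ds$traces[2, (i0 + max(0, b - 5) + 1):(i0 + b)]
    expect_equal(unname(resp$values[2, b, 3]), brute_tauroc(win, base),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(resp$values) <= 1, na.rm = TRUE))
})

test_that("cr_map reduces to the member response for singleton clusters", {
  prof <- list(up = matrix(c(0.1, 0.4, 0.8, 0.6), 1,
                           dimnames = list("n1", NULL)))
  resp <- fake_responses(prof)
  cl <- tibble::tibble(cell = "n1", cluster = 1L)
  crm <- cr_map(resp, cl, min_size = 1)
  expect_equal(crm$purity_at_max, 1)
  expect_equal(crm$max_cr, 0.8)
  expect_equal(crm$response_at_max, 0.8)
  expect_equal(crm$time_of_max, 2 * 0.4)
})

test_that("coherent noise-free planted types reach purity one", {
  cfg <- mini_config(noise_sd = 0, coherence = 1,
                     incoherent_types = integer(), conductor_types = 1:2)
  ds <- generate_dataset(cfg, seed = 2)
  resp <- response_traces(ds$traces, ds$schedule)
  cl <- structure(ds$ground_truth$types |>
                    dplyr::rename(cluster = "type"),
                  class = c("carma_clusters", class(tibble::tibble())))
  # non-conductor types: no expression-coupled sign flips
  crm <- cr_map(resp, cl)
  non_cond <- setdiff(seq_len(cfg$n_types), cfg$conductor_types)
  sub <- crm[crm$cluster %in% non_cond & abs(crm$response_at_max) > 0.2, ]
  expect_true(all(sub$purity_at_max > 0.999))
})

test_that("incoherent planted types have low purity", {
  cfg <- mini_config(n_cells = 80, coherence = 0,
                     incoherent_types = 1:4)
  ds <- generate_dataset(cfg, seed = 9)
  resp <- response_traces(ds$traces, ds$schedule)
  cl <- structure(ds$ground_truth$types |> dplyr::rename(cluster = "type"),
                  class = c("carma_clusters", class(tibble::tibble())))
  crm <- cr_map(resp, cl)
  expect_lt(median(crm$purity_at_max), 0.5)
})

test_that("slope comparison distinguishes planted ramp kinetics", {
  tt <- (0:19) * 0.4
  slow <- t(vapply(c(1, 2, 3), function(s) s * tt, numeric(20)))
  fast <- t(vapply(c(4, 5, 6), function(s) s * tt, numeric(20)))
  prof <- list(stim = rbind(slow, fast))
  rownames(prof$stim) <- paste0("n", 1:6)
  resp <- fake_responses(prof)
  cl <- tibble::tibble(cell = paste0("n", 1:6), cluster = rep(1:2, each = 3))
  out <- slope_comparison(resp, cl, 1, 2, "stim")
  expect_equal(out$statistic, 1)
  expect_equal(out$p_value, 0.1)  # exact two-sample KS p for D=1, n=m=3
  slopes <- attr(out, "slopes")
  expect_equal(unname(slopes$a), c(1, 2, 3), tolerance = 1e-9)
  same <- slope_comparison(resp, cl, 1, 1, "stim")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(slope_comparison(resp, cl, 1, 2, "stim", window = c(0, 0.1)),
               "degenerate")
})
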