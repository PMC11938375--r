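test_that("labeled-line definition on toy matrices", {
  m <- matrix("none", 3, 2, dimnames = list(paste0("n", 1:3), c("s1", "s2")))
  m["n1", "s1"] <- "activated"
  m["n2", "s1"] <- "inhibited"; m["n2", "s2"] <- "activated"
  ll <- find_labeled_lines(m, c("s1", "s2"))
  expect_equal(ll$neuron[ll$state == "s1"], "n1")
  expect_equal(ll$category[ll$state == "s1"], "activated")
  expect_false("n2" %in% ll$neuron)  # responsive in both subset states
  expect_error(find_labeled_lines(m, "s1"), ">= 2 states")
})

test_that("subset screen on degenerate matrices", {
  all_resp <- matrix("activated", 5, 4,
                     dimnames = list(paste0("n", 1:5), paste0("s", 1:4)))
  sc <- screen_all_subsets(all_resp)
  expect_true(all(sc$min_count == 0))
  diag_m <- matrix("none", 4, 4,
                   dimnames = list(paste0("n", 1:4), paste0("s", 1:4)))
  diag(diag_m) <- "activated"
  sc2 <- screen_all_subsets(diag_m, k = 4)
  expect_equal(sc2$min_count, 1)
})

test_that("screen and labeled-line sets match brute-force enumeration", {
  for (seed in 1:12) {
    n_states <- sample(3:5, 1)
    cat_m <- random_category_matrix(sample(4:8, 1), n_states, seed = seed)
    for (k in 2:n_states) {
      sc <- screen_all_subsets(cat_m, k = k)
      brute <- brute_screen(cat_m, k)
      expect_equal(sc$min_count, brute$min_count,
                   info = sprintf("seed %d k %d", seed, k))
    }
    sub <- colnames(cat_m)[1:3]
    ll <- find_labeled_lines(cat_m, sub)
    brute_ll <- brute_labeled_lines(cat_m, sub)
    for (s in sub) {
      expect_setequal(ll$neuron[ll$state == s], brute_ll[[s]])
    }
  }
})

test_that("labeled-line status is monotone under subset shrinkage", {
  withr::with_seed(3, {
    for (i in 1:10) {
      cat_m <- random_category_matrix(10, 5, seed = i)
      big <- colnames(cat_m)[1:4]
      small <- big[1:3]
      ll_big <- find_labeled_lines(cat_m, big)
      ll_small <- find_labeled_lines(cat_m, small)
      keep <- ll_big[ll_big$state %in% small, ]
      joined <- dplyr::anti_join(keep, ll_small, by = c("state", "neuron"))
      expect_equal(nrow(joined), 0)
    }
  })
})

test_that("responsiveness classification recovers planted responses", {
  # sparse tuning: each type responds (+0.8 dF/F) only in its signature state
  cfg <- synth_config(n_types = 5, n_genes = 6, n_states = 5, n_cells = 40,
                      n_trials = 3, noise_sd = 0.05, coherence = 1,
                      incoherent_types = integer(),
                      conductor_states = character(0),
                      amp_range = c(0.8, 1.0),
                      p_sign = c(pos = 0, neg = 0, zero = 1))
  ds <- generate_dataset(cfg, seed = 4)
  R <- classify_responsiveness(ds$traces, ds$schedule, n_shifts = 199,
                               seed = 1)
  type <- ds$ground_truth$types$type[match(rownames(ds$traces),
                                           ds$ground_truth$types$cell)]
  sig_state <- cfg$states[type]
  hit <- vapply(seq_len(nrow(ds$traces)),
                function(i) R$category[i, sig_state[i]] == "activated",
                logical(1))
  expect_gte(mean(hit), 0.95)
  flat <- matrix(0, 1, ncol(ds$traces), dimnames = list("z", NULL))
  attr(flat, "sampling_interval") <- 0.4
  Rf <- classify_responsiveness(flat, ds$schedule, n_shifts = 99, seed = 1)
  expect_true(all(Rf$category == "none"))
})

test_that("selectivity test is calm under independence, alarmed by plants", {
  # independent columns: observed counts match the permutation null
  cat_m <- random_category_matrix(200, 4, seed = 10)
  sel <- selectivity_test(cat_m, n_perm = 300, seed = 1)
  expect_true(all(sel$p_value > 0.05))
  # planted: many neurons selective for s1 only
  m <- random_category_matrix(100, 4, seed = 11, p = c(0.4, 0.2, 0.4))
  m[1:30, ] <- "none"
  m[1:30, "s1"] <- "activated"
  sel2 <- selectivity_test(m, n_perm = 300, seed = 1)
  expect_lt(sel2$p_value[sel2$state == "s1"], 0.05)
  # no responsive neurons: p = 1 with a warning
  none <- matrix("none", 5, 2, dimnames = list(paste0("n", 1:5), c("a", "b")))
  w <- testthat::capture_warnings(
    sel3 <- selectivity_test(none, n_perm = 100, seed = 1))
  expect_match(w, "no responsive", all = TRUE)
  expect_length(w, 2)
  expect_true(all(sel3$p_value == 1))
})

test_that("state-class grouping merges identical states and reruns screen", {
  pa <- withr::with_seed(5, matrix(rnorm(6 * 10), 6,
                                   dimnames = list(paste0("n", 1:6), NULL)))
  pa2 <- pa + withr::with_seed(6, matrix(rnorm(6 * 10, sd = 0.02), 6))
  prof <- list(A1 = pa, A2 = pa2, B = -pa)
  resp <- fake_responses(prof)
  g <- state_class_grouping(resp, threshold = 0.1)
  classes <- setNames(g$map$class, g$map$state)
  expect_equal(classes[["A1"]], classes[["A2"]])
  expect_false(classes[["A1"]] == classes[["B"]])
  # threshold below all merges: classes = states
  g0 <- state_class_grouping(resp, threshold = 0)
  expect_length(unique(g0$map$class), 3)
  expect_error(state_class_grouping(resp, threshold = 99), "outside")
  # collapsed screen runs on class pseudo-states
  cat_m <- random_category_matrix(8, 3, seed = 2)
  colnames(cat_m) <- c("A1", "A2", "B")
  g2 <- state_class_grouping(resp, threshold = 0.1, R = cat_m)
  expect_equal(ncol(g2$class_matrix), 2)
  expect_s3_class(g2$screen, "carma_ll_screen")
})
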