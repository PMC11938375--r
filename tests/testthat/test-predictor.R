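test_that("gene feature triplets are scaled as documented", {
  ex <- tibble::tibble(cell = c("a", "b", "c", "d"),
                       g1 = c(0, 1, 3, 7),
                       g2 = c(0, 0, 0, 0),
                       g3 = c(0, 5, 0, 5))
  ft <- suppressMessages(build_gene_features(ex))
  expect_false("g2" %in% ft$genes)  # all-zero gene dropped entirely
  f1 <- ft$x[, "g1_lin"]
  expect_equal(unname(f1), as.numeric(scale(c(0, 1 / 7, 3 / 7, 1))))
  f2 <- ft$x[, "g1_log"]
  expect_equal(unname(f2),
               as.numeric(scale(log1p(c(0, 1, 3, 7)) / log1p(7))))
  # binary gene: detection carries the signal and lin is proportional to det
  expect_equal(unname(ft$x[, "g3_lin"]), unname(ft$x[, "g3_det"]))
})

test_that("FC prediction is perfect on separable data, chance on noise", {
  withr::with_seed(1, {
    n <- 80
    lab <- rep(c("Act-FC", "Inh-FC"), each = n / 2)
    x <- matrix(rnorm(n * 2, sd = 0.2), n,
                dimnames = list(sprintf("c%02d", 1:n), c("sig", "noise")))
    x[lab == "Act-FC", "sig"] <- x[lab == "Act-FC", "sig"] + 5
  })
  fit <- suppressWarnings(predict_fc(x, lab, seed = 1))
  expect_equal(fit$accuracy, 1)
  expect_equal(fit$auroc, 1)
  noise_fit <- suppressWarnings(
    predict_fc(x[, "noise", drop = FALSE], lab, seed = 1))
  expect_lt(abs(noise_fit$accuracy - 0.5), 3 * sqrt(0.25 / n))
  expect_error(predict_fc(x, rep("A", n)), "single class")
})

test_that("planted logistic coefficients recover their signs", {
  withr::with_seed(2, {
    n <- 300
    x <- matrix(rnorm(n * 3), n,
                dimnames = list(sprintf("c%03d", 1:n), c("up", "down", "nil")))
    eta <- 2 * x[, "up"] - 2 * x[, "down"]
    lab <- ifelse(runif(n) < plogis(eta), "B", "A")
  })
  fit <- suppressWarnings(predict_fc(x, lab, seed = 3))
  co <- fit$coefficients
  expect_gt(co[["up"]], 0)     # positive for the second level "B"
  expect_lt(co[["down"]], 0)
  expect_lt(abs(co[["nil"]]), min(abs(co[["up"]]), abs(co[["down"]])))
})

test_that("SFFS selects the planted gene first and stops on noise", {
  pl <- planted_expression(120, sprintf("g%d", 1:5), informative = "g3",
                           effect = 6, seed = 4)
  ft <- suppressMessages(build_gene_features(pl$expression))
  rep1 <- suppressWarnings(suppressMessages(sffs(ft, pl$labels, seed = 1)))
  expect_equal(rep1$selected[1], "g3")
  expect_lte(length(rep1$selected), 2)
  # pure noise: stops at one gene near chance
  pl0 <- planted_expression(80, sprintf("g%d", 1:4), informative = character(),
                            seed = 5)
  ft0 <- suppressMessages(build_gene_features(pl0$expression))
  rep0 <- suppressWarnings(suppressMessages(sffs(ft0, pl0$labels, seed = 1)))
  expect_equal(length(rep0$selected), 1)
  expect_lt(rep0$accuracy, 0.68)
})

test_that("SFFS agrees with the exhaustive best-subset oracle", {
  for (seed in 1:8) {
    pl <- planted_expression(90, sprintf("g%d", 1:4),
                             informative = c("g1", "g4"), effect = 5,
                             seed = seed)
    ft <- suppressMessages(build_gene_features(pl$expression))
    greedy <- suppressWarnings(suppressMessages(
      sffs(ft, pl$labels, seed = 1, tol = 0.001)))
    oracle <- suppressWarnings(best_subset_oracle(ft, pl$labels, seed = 1))
    expect_true(all(c("g1", "g4") %in% greedy$selected),
                info = paste("seed", seed))
    expect_true(all(oracle %in% greedy$selected),
                info = paste("seed", seed))
  }
})

test_that("mSFFS reveals redundant partners and reduces to SFFS", {
  withr::with_seed(6, {
    n <- 150
    lab <- rep(c("A", "B"), length.out = n)
    base <- exp(rnorm(n, 1, 0.5)) * ifelse(lab == "B", 4, 1)
    expr <- tibble::tibble(
      cell = sprintf("c%03d", 1:n),
      g1 = base * exp(rnorm(n, 0, 0.2)),           # informative
      g2 = base * exp(rnorm(n, 0, 0.2)),           # redundant twin
      g3 = exp(rnorm(n, 1, 0.5)),
      g4 = exp(rnorm(n, 1, 0.5))
    )
  })
  ft <- suppressMessages(build_gene_features(expr))
  ms <- suppressWarnings(suppressMessages(msffs(ft, lab, n_rounds = 2,
                                                seed = 1)))
  twins <- c("g1", "g2")
  expect_true(ms[[1]]$selected[1] %in% twins)
  expect_equal(ms[[2]]$selected[1], setdiff(twins, ms[[1]]$selected[1]))
  expect_gt(ms[[2]]$accuracy, ms[[1]]$accuracy - 0.1)
  one <- suppressWarnings(suppressMessages(msffs(ft, lab, n_rounds = 1,
                                                 seed = 1)))
  ref <- suppressWarnings(suppressMessages(sffs(ft, lab, seed = 1)))
  expect_identical(one[[1]]$selected, ref$selected)
  expect_identical(one[[1]]$steps, ref$steps)
})

test_that("shuffle null matches the binomial closed form and is seeded", {
  withr::with_seed(7, {
    n <- 200
    lab <- rep(c("A", "B"), each = n / 2)
    x <- matrix(rnorm(n * 2), n,
                dimnames = list(sprintf("c%03d", 1:n), c("f1", "f2")))
    ft <- list(x = scale(x), gene_of = c("f1", "f2"),
               genes = c("f1", "f2"), neurons = rownames(x))
    class(ft) <- "carma_features"
  })
  sn <- suppressWarnings(shuffle_null(ft, lab, n_shuffles = 150, seed = 2))
  # balanced-label CV accuracy under the null is ~Binomial(n, 1/2)/n
  expect_lt(abs(sn$null95 - (0.5 + 1.645 * sqrt(0.25 / n))), 0.03)
  expect_gt(sn$p_value, 0.05)
  sn2 <- suppressWarnings(shuffle_null(ft, lab, n_shuffles = 150, seed = 2))
  expect_identical(sn$null_accuracies, sn2$null_accuracies)
  expect_error(shuffle_null(ft, lab, n_shuffles = 50), ">= 100")
})

test_that("Youden cutpoint matches enumeration and the midpoint rule", {
  yt <- youden_threshold(c(1, 2, 3, 7, 8, 9),
                         c("lo", "lo", "lo", "hi", "hi", "hi"))
  expect_equal(yt$cutpoint, 5)
  expect_equal(yt$j, 1)
  expect_equal(yt$positive, "hi")
  same <- youden_threshold(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$j, 0)
  expect_error(youden_threshold(rep(2, 6), rep(c("a", "b"), 3)), "no ROC")
  expect_error(youden_threshold(1:6, rep("a", 6)), "both classes")
  # brute force over all candidate cuts on random data
  withr::with_seed(8, {
    for (i in 1:20) {
      x <- round(rexp(40, 0.3), 1)
      lab <- sample(c("a", "b"), 40, replace = TRUE)
      if (length(unique(x)) < 2 || length(unique(lab)) < 2) next
      yt <- youden_threshold(x, lab, positive = "b")
      u <- sort(unique(x))
      cuts <- (u[-length(u)] + u[-1]) / 2
      js <- vapply(cuts, function(cc) {
        mean(x[lab == "b"] > cc) + mean(x[lab == "a"] <= cc) - 1
      }, numeric(1))
      expect_equal(yt$j, max(js), tolerance = 1e-12)
      expect_equal(yt$cutpoint, cuts[which.max(js)])
    }
  })
})

test_that("planted expression thresholds are recovered within 10 percent", {
  withr::with_seed(9, {
    n <- 300
    x <- exp(rnorm(n, 2, 0.8))
    thr <- exp(2)
    lab <- ifelse(x >= thr, "Act-FC", "Inh-FC")
    flip <- runif(n) < 0.05  # small labeling noise
    lab[flip] <- ifelse(lab[flip] == "Act-FC", "Inh-FC", "Act-FC")
  })
  yt <- youden_threshold(x, lab, positive = "Act-FC")
  expect_lt(abs(yt$cutpoint - thr) / thr, 0.10)
  expect_gte(yt$precision_optimal, yt$precision_any)
})

test_that("in-fold Gaussian FDE equals the least-squares R2 oracle", {
  withr::with_seed(10, {
    n <- 40
    X <- matrix(rnorm(n * 3), n,
                dimnames = list(sprintf("c%02d", 1:n), c("a", "b", "c")))
    ft <- list(x = X, gene_of = colnames(X), genes = colnames(X),
               neurons = rownames(X))
    class(ft) <- "carma_features"
    Y <- cbind(X %*% c(1, -2, 0.5) + rnorm(n, sd = 0.3),
               rnorm(n))
  })
  tf <- temporal_fde(ft, Y, out_of_fold = FALSE)
  for (j in 1:2) {
    r2 <- summary(lm(Y[, j] ~ X))$r.squared
    expect_equal(tf$fde$fde[tf$fde$timestamp == j], r2, tolerance = 1e-10)
  }
  # exact linear response, in-fold: FDE = 1
  Y_exact <- cbind(X %*% c(2, 1, -1))
  tf2 <- temporal_fde(ft, Y_exact, out_of_fold = FALSE)
  expect_equal(tf2$fde$fde, 1, tolerance = 1e-10)
  # FDE is invariant to affine feature rescaling
  ft_scaled <- ft
  ft_scaled$x <- sweep(ft$x, 2, c(10, 0.1, 3), "*") + 7
  tf3 <- temporal_fde(ft_scaled, Y, out_of_fold = FALSE)
  expect_equal(tf3$fde$fde, tf$fde$fde, tolerance = 1e-8)
})

test_that("out-of-fold FDE of an uninformative model is near or below zero", {
  withr::with_seed(11, {
    n <- 60
    X <- matrix(rnorm(n * 3), n,
                dimnames = list(sprintf("c%02d", 1:n), c("a", "b", "c")))
    ft <- list(x = X, gene_of = colnames(X), genes = colnames(X),
               neurons = rownames(X))
    class(ft) <- "carma_features"
    Y <- matrix(rnorm(n * 5), n)
  })
  tf <- temporal_fde(ft, Y, folds = 5, seed = 1)
  expect_lt(mean(tf$fde$fde), 0.05)
  expect_true(all(tf$fde$fde <= 1))
})

test_that("neuron FDE ranking rewards predictable neurons", {
  withr::with_seed(12, {
    n <- 40; p <- 3; nt <- 30
    X <- matrix(rnorm(n * p), n,
                dimnames = list(sprintf("c%02d", 1:n), c("a", "b", "c")))
    ft <- list(x = X, gene_of = colnames(X), genes = colnames(X),
               neurons = rownames(X))
    class(ft) <- "carma_features"
    B <- matrix(rnorm(p * nt, sd = 1), p, nt)
    Y <- X %*% B + rnorm(n * nt, sd = 0.1)   # predictable
    Y[n, ] <- rnorm(nt, sd = 1)              # except the last neuron
  })
  tf <- temporal_fde(ft, Y, folds = 5, seed = 1)
  rk <- neuron_fde_ranking(tf, n_shuffles = 100, seed = 2)
  expect_gte(mean(rk$significant[-n]), 0.9)
  expect_false(rk$significant[n])
  expect_equal(sort(unique(rk$quartile)), 1:4)
  expect_gt(min(rk$fde[rk$quartile == 1]), max(rk$fde[rk$quartile == 4]))
})
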