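test_that("generator is deterministic for a fixed config and seed", {
  cfg <- mini_config()
  t1 <- build_templates(cfg, seed = 1)
  t2 <- build_templates(cfg, seed = 1)
  expect_identical(t1, t2)
  d1 <- generate_dataset(cfg, seed = 3)
  d2 <- generate_dataset(cfg, seed = 3)
  expect_identical(d1$expression, d2$expression)
  expect_identical(unclass(d1$traces)[, ], unclass(d2$traces)[, ])
})

test_that("degenerate generator configs are rejected", {
  expect_error(synth_config(n_types = 1), class = "carma_config_error")
  expect_error(synth_config(n_genes = 1), class = "carma_config_error")
  expect_error(synth_config(n_states = 1), class = "carma_config_error")
  expect_error(synth_config(nonsense = 1), class = "carma_config_error")
})

test_that("conductor gene spans several templates at high detection", {
  tpl <- build_templates(synth_config(), seed = 1)
  cond <- synth_config()$genes[synth_config()$conductor_gene]
  hits <- vapply(tpl, function(tp) tp$detect_prob[[cond]] >= 0.9, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("default templates are each dominated by one high-mean gene", {
  tpl <- build_templates(synth_config(), seed = 1)
  expect_length(tpl, 10)
  dominants <- vapply(tpl, function(tp) names(which.max(tp$gene_means)),
                      character(1))
  expect_length(unique(dominants), 10)
  for (tp in tpl) {
    expect_gt(max(tp$gene_means), sort(tp$gene_means, decreasing = TRUE)[2])
  }
})

test_that("zero detection probability silences a gene", {
  tpl <- build_templates(mini_config(), seed = 1)
  for (i in seq_along(tpl)) tpl[[i]]$detect_prob[["g03"]] <- 0
  xp <- sample_expression(tpl, 100, seed = 2)
  expect_true(all(xp$expression$g03 == 0))
  expect_true(all(as.matrix(xp$expression[-1]) >= 0))
})

test_that("nonzero expression is strongly right-skewed", {
  tpl <- build_templates(synth_config(n_cells = 5000), seed = 1)
  xp <- sample_expression(tpl, 5000, seed = 1)
  m <- as.matrix(xp$expression[-1])
  skew <- apply(m, 2, function(x) {
    x <- x[x > 0]
    mean((x - mean(x))^3) / sd(x)^3
  })
  expect_true(all(skew > 0.5))
})

test_that("every cell gets exactly one true type", {
  ds <- mini_dataset(seed = 4)
  expect_setequal(ds$ground_truth$types$cell, ds$expression$cell)
  expect_false(anyDuplicated(ds$ground_truth$types$cell) > 0)
})

test_that("silent kernels and zero noise give all-zero traces", {
  cfg <- mini_config(noise_sd = 0)
  tpl <- build_templates(cfg, seed = 1)
  for (i in seq_along(tpl)) {
    tpl[[i]]$response_kernels$amplitude <- 0
    tpl[[i]]$coherence <- 1
  }
  xp <- sample_expression(tpl, 10, seed = 1)
  tr <- sample_traces(tpl, xp$ground_truth, build_schedule(cfg), seed = 1)
  expect_true(all(tr == 0))
})

test_that("coherent same-type neurons at zero noise differ only by gain", {
  cfg <- mini_config(noise_sd = 0, coherence = 1,
                     incoherent_types = integer(), conductor_types = 1:2)
  ds <- generate_dataset(cfg, seed = 2)
  # a non-conductor type avoids the expression-coupled sign flips
  non_cond <- setdiff(seq_len(cfg$n_types), cfg$conductor_types)[1]
  cells <- ds$ground_truth$types$cell[ds$ground_truth$types$type == non_cond]
  a <- ds$traces[cells[1], ]
  b <- ds$traces[cells[2], ]
  nz <- abs(a) > 1e-12
  expect_gt(sum(nz), 100)
  ratio <- b[nz] / a[nz]
  expect_lt(diff(range(ratio)), 1e-8)
})

test_that("within-type trace correlation exceeds between-type correlation", {
  ds <- mini_dataset(seed = 6)
  cc <- cor(t(ds$traces))
  type <- ds$ground_truth$types$type[match(rownames(ds$traces),
                                           ds$ground_truth$types$cell)]
  same <- outer(type, type, "==")
  diag(same) <- NA
  expect_gt(mean(cc[same & !is.na(same)]), mean(cc[!same & !is.na(same)]))
})

test_that("default schedule covers 11 states and 319 neurons", {
  cfg <- synth_config()
  sched <- build_schedule(cfg)
  expect_length(unique(sched$epochs$state), 11)
  expect_true(all(diff(sched$epochs$start_s) > 0))
  expect_true(all(sched$epochs$start_s[-1] >=
                    sched$epochs$end_s[-nrow(sched$epochs)]))
  tpl <- build_templates(cfg, seed = 1)
  xp <- sample_expression(tpl, cfg$n_cells, seed = 2)
  tr <- sample_traces(tpl, xp$ground_truth, sched, seed = 3)
  expect_equal(nrow(tr), 319)
  expect_equal(ncol(tr), floor(sched$duration_s / cfg$sampling_interval))
})

test_that("expressed-gene histogram has its mode at three genes", {
  tpl <- build_templates(synth_config(), seed = 1)
  xp <- sample_expression(tpl, 2000, seed = 5)
  cx <- coexpression_summary(xp$expression)
  expect_equal(cx$mode_n_expressed, 3L)
  expect_gt(cx$frac_multigene, 0.6)
})

test_that("schedule constructor enforces epoch and event invariants", {
  ep <- tibble::tibble(state = c("a", "b"), start_s = c(0, 15),
                       end_s = c(10, 25))
  s <- carma_schedule(ep, events = tibble::tibble(label = "a", time_s = 2))
  expect_s3_class(s, "carma_schedule")
  expect_error(carma_schedule(ep, events = tibble::tibble(label = "a",
                                                          time_s = 12)),
               class = "carma_format_error")
  expect_error(
    carma_schedule(tibble::tibble(state = c("a", "b"), start_s = c(0, 5),
                                  end_s = c(10, 15))),
    class = "carma_format_error")
})

test_that("templates needing a state absent from the schedule error", {
  cfg <- mini_config()
  tpl <- build_templates(cfg, seed = 1)
  xp <- sample_expression(tpl, 8, seed = 1)
  short <- carma_schedule(tibble::tibble(state = cfg$states[1],
                                         start_s = 30, end_s = 50),
                          sampling_interval = 0.4, duration_s = 60)
  expect_error(sample_traces(tpl, xp$ground_truth, short, seed = 1),
               class = "carma_schedule_mismatch")
})
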