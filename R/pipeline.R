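#' Run configuration for the end-to-end pipeline
#'
#' Assembles stage toggles and numeric parameters for [carma_report()].
#' Unknown keys are rejected; every stochastic stage draws its seed from the
#' single run seed.
#'
#' @param ... named overrides of the defaults below.
#' @details Defaults: `n_clusters` 10 molecular clusters; `min_cluster_size` 3
#'   (smaller clusters are excluded from cluster statistics);
#'   `baseline_s` 10 and `window_s` 2 for t-auROC; `decode_window_s` 20 and
#'   `n_bins` 10 decoding features; `folds` 10 (auto-reduced to the trial
#'   count); `n_resamples` 50 grouped-ensemble draws; `n_shifts` 100
#'   circular shifts for responsiveness; `n_perm` 100 permutations for the
#'   selectivity null; `n_shuffles` 100 label shuffles for FC-prediction
#'   significance; `time_stride` 10 (temporal FDE evaluated every 10th
#'   timestamp, i.e. every 4 s at 0.4-s sampling); `msffs_rounds` 2;
#'   `stages` toggles for typing, metrics, labeled_line, decode, functional,
#'   predict_fc, predict_time.
#' @return named list of class `carma_run_config`.
#' @export
carma_run_config <- function(...) {
  defaults <- list(
    n_clusters = 10L, min_cluster_size = 3L,
    baseline_s = 10, window_s = 2,
    decode_window_s = 20, n_bins = 10L, folds = 10L,
    n_resamples = 50L, n_shifts = 100L, n_perm = 100L, n_shuffles = 100L,
    time_stride = 10L, msffs_rounds = 2L,
    stages = list(typing = TRUE, metrics = TRUE, labeled_line = TRUE,
                  decode = TRUE, functional = TRUE, predict_fc = TRUE,
                  predict_time = TRUE)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown run parameter(s): ", paste(unknown, collapse = ", ")),
          class = "carma_config_error")
  }
  if (!is.null(overrides$stages)) {
    defaults$stages[names(overrides$stages)] <- overrides$stages
    overrides$stages <- NULL
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "carma_run_config")
}

#' Simulate a dataset to disk
#'
#' Generates a synthetic dataset and writes all components plus a
#' machine-readable summary (`simulate_summary.json` with the seed, the
#' generator config hash, and md5 hashes of every written file). Byte-identical
#' across runs with the same config and seed.
#'
#' @param out_dir output directory.
#' @param config a [synth_config()] list.
#' @param seed integer master seed.
#' @return the `carma_dataset`, invisibly.
#' @export
carma_simulate <- function(out_dir, config = synth_config(), seed = 1L) {
  ds <- generate_dataset(config, seed, out_dir = out_dir)
  files <- sort(setdiff(list.files(out_dir, full.names = TRUE),
                        file.path(out_dir, "simulate_summary.json")))
  cfg_file <- file.path(tempdir(), "carma-config-hash.yaml")
  write_config(config, cfg_file)
  jsonlite::write_json(
    list(seed = seed,
         config_hash = unname(tools::md5sum(cfg_file)),
         files = as.list(setNames(unname(tools::md5sum(files)),
                                  basename(files)))),
    file.path(out_dir, "simulate_summary.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(ds)
}

#' Run the analysis pipeline and write a report
#'
#' Reads a dataset directory written by [carma_simulate()] (or hand-assembled
#' in the same formats), runs the enabled stages -- molecular typing, response
#' metrics, the labeled-line screen, single-type and grouped-ensemble
#' decoding with a paired dummy-type control, functional clustering with
#' enrichment, FC prediction from gene features (SFFS + shuffle null), and
#' per-timestamp FDE prediction with neuron ranking -- writing one
#' tab-delimited table per result and an aggregate `report.json`.
#'
#' @param data_dir dataset directory.
#' @param out_dir output directory (default `data_dir`).
#' @param config a [carma_run_config()].
#' @param seed integer seed for all stochastic stages.
#' @return list of stage results (class `carma_report`), invisibly; the
#'   aggregate summary is in `$summary`.
#' @export
carma_report <- function(data_dir, out_dir = data_dir,
                         config = carma_run_config(), seed = 1L) {
  seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- read_dataset(data_dir)
  al <- align_span(ds$traces, ds$schedule)
  traces <- al$traces; schedule <- al$schedule
  expression <- ds$expression
  st <- config$stages
  res <- list()
  summary <- list(seed = seed)

  norm <- normalize_expression(expression)
  if (isTRUE(st$typing)) {
    k <- min(config$n_clusters, nrow(expression))
    clusters <- cluster_cells(norm, n_clusters = k)
    clusters <- name_clusters(clusters, norm)
    coex <- coexpression_summary(expression)
    res$clusters <- clusters
    res$coexpression <- coex
    write_tsv_plain(clusters, file.path(out_dir, "mc_assignments.tsv"))
    write_tsv_plain(coex$counts, file.path(out_dir, "coexpression_counts.tsv"))
    summary$n_clusters <- k
    summary$coexpression_mode <- coex$mode_n_expressed
    summary$frac_multigene <- coex$frac_multigene
    if (!is.null(ds$ground_truth) && "type" %in% names(ds$ground_truth)) {
      truth <- ds$ground_truth$type[match(clusters$cell,
                                          ds$ground_truth$cell)]
      summary$typing_ari <- mclust::adjustedRandIndex(clusters$cluster, truth)
    }
  } else {
    clusters <- NULL
  }

  responses <- NULL
  if (isTRUE(st$metrics) || isTRUE(st$decode) || isTRUE(st$functional) ||
      isTRUE(st$predict_time)) {
    responses <- response_traces(traces, schedule,
                                 baseline_s = config$baseline_s,
                                 window_s = config$window_s)
  }
  if (isTRUE(st$metrics) && !is.null(clusters)) {
    crm <- cr_map(responses, clusters, min_size = config$min_cluster_size)
    res$cr_map <- crm
    write_tsv_plain(crm, file.path(out_dir, "cr_map.tsv"))
    summary$max_consistent_response <- max(abs(crm$max_cr))
  }

  if (isTRUE(st$labeled_line)) {
    R <- classify_responsiveness(traces, schedule,
                                 baseline_s = config$baseline_s,
                                 n_shifts = config$n_shifts, seed = seed)
    screen <- screen_all_subsets(R)
    sel <- selectivity_test(R, n_perm = config$n_perm, seed = seed + 1L)
    res$responsiveness <- R
    res$ll_screen <- screen
    res$selectivity <- sel
    write_tsv_plain(dplyr::mutate(tibble::as_tibble(screen),
                                  best_subset = purrr::map_chr(
                                    .data$best_subset, paste, collapse = ",")),
                    file.path(out_dir, "labeled_line_screen.tsv"))
    write_tsv_plain(sel, file.path(out_dir, "labeled_line_selectivity.tsv"))
    nz <- screen$k[screen$min_count > 0]
    summary$labeled_line_max_k <- if (length(nz)) max(nz) else 0L
  }

  if (isTRUE(st$decode) && !is.null(clusters)) {
    samples <- build_samples(responses, window_s = config$decode_window_s,
                             n_bins = config$n_bins)
    single <- decode_single_type(samples, clusters, folds = config$folds,
                                 seed = seed)
    grouped <- decode_grouped(samples, clusters,
                              n_resamples = config$n_resamples,
                              folds = config$folds, seed = seed)
    dummy <- decode_grouped(samples, dummy_types(clusters, seed = seed),
                            n_resamples = config$n_resamples,
                            folds = config$folds, seed = seed)
    wt <- suppressWarnings(wilcox.test(grouped$accuracy, dummy$accuracy,
                                       alternative = "greater"))
    cmp <- compare_type_accuracies(
      dplyr::filter(single$summary, !is.na(.data$cluster)))
    res$decode_single <- single
    res$decode_grouped <- grouped
    res$decode_dummy <- dummy
    res$type_comparison <- cmp
    write_tsv_plain(single$summary, file.path(out_dir, "decode_single.tsv"))
    write_tsv_plain(tibble::tibble(resample = seq_along(grouped$accuracy),
                                   grouped = grouped$accuracy,
                                   dummy = dummy$accuracy),
                    file.path(out_dir, "decode_grouped.tsv"))
    if (!is.null(res$cr_map)) {
      res$diagram <- decoding_diagram(grouped, res$cr_map)
      write_tsv_plain(res$diagram, file.path(out_dir, "decoding_diagram.tsv"))
    }
    summary$grouped_accuracy <- mean(grouped$accuracy)
    summary$dummy_accuracy <- mean(dummy$accuracy)
    summary$grouped_vs_dummy_p <- wt$p.value
  }

  states <- unique(schedule$epochs$state)
  if (isTRUE(st$functional)) {
    fcs <- lapply(states, function(s) cluster_functional(responses, s))
    names(fcs) <- states
    enr <- purrr::imap_dfr(fcs, function(fc, s) {
      dplyr::mutate(fc_gene_enrichment(fc, expression), state = s, .before = 1)
    })
    res$fcs <- fcs
    res$fc_gene_enrichment <- enr
    write_tsv_plain(enr, file.path(out_dir, "fc_gene_enrichment.tsv"))
    if (!is.null(clusters)) {
      tenr <- purrr::imap_dfr(fcs, function(fc, s) {
        dplyr::mutate(fc_celltype_enrichment(fc, clusters), state = s,
                      .before = 1)
      })
      res$fc_celltype_enrichment <- tenr
      write_tsv_plain(tenr, file.path(out_dir, "fc_celltype_enrichment.tsv"))
    }
  }

  features <- NULL
  if (isTRUE(st$predict_fc) || isTRUE(st$predict_time)) {
    features <- suppressMessages(build_gene_features(expression))
  }
  if (isTRUE(st$predict_fc) && isTRUE(st$functional)) {
    pf <- purrr::imap_dfr(res$fcs, function(fc, s) {
      fit <- suppressWarnings(predict_fc(features, fc, folds = config$folds,
                                         seed = seed))
      sn <- suppressWarnings(shuffle_null(features, fc,
                                          n_shuffles = max(config$n_shuffles,
                                                           100L),
                                          seed = seed, folds = config$folds))
      sf <- suppressWarnings(suppressMessages(
        sffs(features, fc, folds = config$folds, seed = seed)))
      tibble::tibble(state = s, accuracy = fit$accuracy, auroc = fit$auroc,
                     null95 = sn$null95, p_value = sn$p_value,
                     sffs_accuracy = sf$accuracy,
                     sffs_genes = paste(sf$selected, collapse = ","))
    })
    res$fc_prediction <- pf
    write_tsv_plain(pf, file.path(out_dir, "fc_prediction.tsv"))
    summary$fc_prediction_best <- max(pf$accuracy)
    summary$fc_prediction_worst <- min(pf$accuracy)
    summary$fc_sffs_best <- max(pf$sffs_accuracy)
  }

  if (isTRUE(st$predict_time) && isTRUE(st$functional)) {
    ser <- response_series(responses)
    keep <- seq(1, ncol(ser$values), by = config$time_stride)
    ser$values <- ser$values[, keep, drop = FALSE]
    ser$info <- ser$info[keep, ]
    ms <- suppressWarnings(suppressMessages(
      msffs(features, res$fcs[[1]], n_rounds = max(config$msffs_rounds, 2L),
            folds = config$folds, seed = seed)))
    top2 <- vapply(ms[seq_len(min(2, length(ms)))],
                   function(r) r$selected[1], character(1))
    gene_sets <- list(all = features$genes, optimal = ms[[1]]$selected,
                      top2 = top2)
    tf <- temporal_fde(features, ser, gene_sets = gene_sets,
                       folds = config$folds, seed = seed,
                       n_shuffles = max(config$n_shuffles, 100L))
    ranking <- neuron_fde_ranking(tf, model = "all",
                                  n_shuffles = max(config$n_shuffles, 100L),
                                  seed = seed)
    qt <- fde_quartile_tests(ranking, expression = expression,
                             clusters = clusters)
    res$temporal_fde <- tf
    res$fde_ranking <- ranking
    res$fde_quartiles <- qt
    fde_wide <- tidyr::pivot_wider(tf$fde, names_from = "model",
                                   values_from = "fde")
    fde_wide$null95 <- tf$null95
    write_tsv_plain(dplyr::bind_cols(ser$info, fde_wide[-1]),
                    file.path(out_dir, "fde_timeseries.tsv"))
    write_tsv_plain(ranking, file.path(out_dir, "neuron_fde.tsv"))
    if (!is.null(qt$genes)) {
      write_tsv_plain(qt$genes, file.path(out_dir, "fde_quartile_genes.tsv"))
    }
    summary$fde_significant_fraction <- mean(ranking$significant)
    summary$fde_median <- median(ranking$fde)
  }

  summary$states <- length(states)
  summary$neurons <- nrow(traces)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$summary <- summary
  invisible(structure(res, class = "carma_report"))
}
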