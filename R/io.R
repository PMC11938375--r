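#' @name carma-io
#' @title Readers and writers for CaRMA on-disk formats
#' @description All tables are tab-delimited text with `#` comment lines for
#'   metadata; times are seconds (float), intervals half-open `[start, end)`.
#'   Calcium traces can additionally be stored in a binary array container
#'   (Apache Arrow feather, via the optional `arrow` package).
NULL

write_tsv_plain <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  cols <- vapply(df, function(x) {
    if (is.numeric(x)) sprintf("%.10g", x) else as.character(x)
  }, character(nrow(df))) |> matrix(nrow = nrow(df))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) writeLines(apply(cols, 1, paste, collapse = "\t"), con)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

read_tsv_meta <- function(path) {
  lines <- readLines(path, n = 20)
  meta <- grep("^#", lines, value = TRUE)
  out <- list()
  for (m in meta) {
    kv <- strsplit(sub("^#\\s*", "", m), "[=:]\\s*")[[1]]
    if (length(kv) == 2) out[[kv[1]]] <- kv[2]
  }
  out
}

#' Read a cell-by-gene expression table
#'
#' Expects a tab-delimited table with a header row of gene names and a first
#' column of cell ids. Values must be finite and non-negative; gene names must
#' be unique.
#'
#' @param path file path.
#' @return tibble with a `cell` column plus one numeric column per gene, in
#'   file order.
#' @export
read_expression <- function(path) {
  df <- read_tsv_plain(path)
  if (ncol(df) < 2) abort("expression table needs cell ids plus >= 1 gene",
                          class = "carma_format_error")
  names(df)[1] <- "cell"
  genes <- names(df)[-1]
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene names: ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")),
          class = "carma_format_error")
  }
  for (g in genes) {
    v <- suppressWarnings(as.numeric(df[[g]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      abort(sprintf("invalid expression value at row %d (cell '%s'), gene '%s': %s",
                    bad[1], df$cell[bad[1]], g, df[[g]][bad[1]]),
            class = "carma_format_error")
    }
    df[[g]] <- v
  }
  tibble::as_tibble(df)
}

#' Write an expression table
#' @param expression tibble with `cell` column plus gene columns.
#' @param path output path.
#' @export
write_expression <- function(expression, path) {
  write_tsv_plain(expression, path)
}

#' Read calcium traces
#'
#' Tab-delimited traces have a first column of neuron ids and one column per
#' timepoint, with the sampling interval in a `# sampling_interval_s = ...`
#' comment line. Feather files (`.feather`) are read via the `arrow` package,
#' in which case `sampling_interval` must be supplied (or the 0.4-s default is
#' used).
#'
#' @param path file path (`.tsv` or `.feather`).
#' @param sampling_interval sampling step in seconds; overrides file metadata.
#' @return neuron x time matrix with `sampling_interval` and `times`
#'   attributes.
#' @export
read_traces <- function(path, sampling_interval = NULL) {
  if (grepl("\\.feather$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("reading feather traces requires the 'arrow' package")
    }
    df <- as.data.frame(arrow::read_feather(path))
    dt <- sampling_interval %||% 0.4
  } else {
    df <- read_tsv_plain(path)
    meta <- read_tsv_meta(path)
    dt <- sampling_interval %||%
      (if (!is.null(meta$sampling_interval_s)) as.numeric(meta$sampling_interval_s)
       else abort("sampling interval not in file metadata or arguments",
                  class = "carma_format_error"))
  }
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort("non-finite trace values",
                                class = "carma_format_error")
  rownames(m) <- as.character(df[[1]])
  attr(m, "sampling_interval") <- dt
  attr(m, "times") <- (seq_len(ncol(m)) - 1) * dt
  m
}

#' Write calcium traces
#'
#' `.feather` paths use the Arrow binary container (if the `arrow` package is
#' installed); any other extension writes the tab-delimited fallback with the
#' sampling interval as a comment line.
#'
#' @param traces neuron x time matrix with a `sampling_interval` attribute.
#' @param path output path.
#' @export
write_traces <- function(traces, path) {
  dt <- attr(traces, "sampling_interval") %||% 0.4
  df <- tibble::as_tibble(traces, .name_repair = "minimal")
  names(df) <- sprintf("t%d", seq_len(ncol(df)) - 1L)
  df <- dplyr::bind_cols(tibble::tibble(neuron = rownames(traces)), df)
  if (grepl("\\.feather$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("writing feather traces requires the 'arrow' package")
    }
    arrow::write_feather(df, path)
  } else {
    write_tsv_plain(df, path,
                    comments = sprintf("sampling_interval_s = %.10g", dt))
  }
  invisible(path)
}

#' Read a behavioral-state schedule
#'
#' Tab-delimited interval table with columns `state`, `start_s`, `end_s` (and
#' optionally `trial`); stimulus events may live in a second table with
#' columns `label`, `time_s`. Overlapping or non-monotone epochs and empty
#' tables are format errors.
#'
#' @param path epochs file path.
#' @param events_path optional events file path.
#' @param sampling_interval seconds; overrides file metadata (default 0.4).
#' @return A [carma_schedule()].
#' @export
read_schedule <- function(path, events_path = NULL, sampling_interval = NULL) {
  df <- read_tsv_plain(path)
  if (nrow(df) == 0) abort("no epochs", class = "carma_format_error")
  meta <- read_tsv_meta(path)
  dt <- sampling_interval %||%
    (if (!is.null(meta$sampling_interval_s)) as.numeric(meta$sampling_interval_s)
     else 0.4)
  dur <- if (!is.null(meta$duration_s)) as.numeric(meta$duration_s) else NULL
  events <- if (!is.null(events_path)) read_tsv_plain(events_path) else NULL
  carma_schedule(df, events, sampling_interval = dt, duration_s = dur)
}

#' Write a behavioral-state schedule
#' @param schedule a [carma_schedule()].
#' @param path epochs output path.
#' @param events_path optional events output path.
#' @export
write_schedule <- function(schedule, path, events_path = NULL) {
  write_tsv_plain(schedule$epochs, path,
                  comments = c(sprintf("sampling_interval_s = %.10g",
                                       schedule$sampling_interval),
                               sprintf("duration_s = %.10g",
                                       schedule$duration_s)))
  if (!is.null(events_path)) write_tsv_plain(schedule$events, events_path)
  invisible(path)
}

#' Reconcile trace and schedule time spans
#'
#' If the traces and the schedule cover different time spans, warns and
#' truncates both to the intersection: trailing trace samples are dropped and
#' epochs beyond the trace span are removed.
#'
#' @param traces neuron x time matrix from [read_traces()].
#' @param schedule a [carma_schedule()].
#' @return list with elements `traces` and `schedule`.
#' @export
align_span <- function(traces, schedule) {
  dt <- attr(traces, "sampling_interval")
  trace_end <- ncol(traces) * dt
  sched_end <- schedule$duration_s
  if (abs(trace_end - sched_end) > dt / 2) {
    warn(sprintf("traces span %.1f s but schedule spans %.1f s; truncating to %.1f s",
                 trace_end, sched_end, min(trace_end, sched_end)))
    end <- min(trace_end, sched_end)
    keep_t <- seq_len(floor(end / dt + 1e-9))
    traces2 <- traces[, keep_t, drop = FALSE]
    attr(traces2, "sampling_interval") <- dt
    attr(traces2, "times") <- (keep_t - 1) * dt
    attr(traces2, "coherent") <- attr(traces, "coherent")
    ep <- schedule$epochs[schedule$epochs$end_s <= end + 1e-9, , drop = FALSE]
    ev <- schedule$events[schedule$events$time_s < end, , drop = FALSE]
    schedule <- carma_schedule(ep, ev, dt, duration_s = end)
    traces <- traces2
  }
  list(traces = traces, schedule = schedule)
}

#' Read/write a YAML run configuration
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
    x
  } else {
    unname(unclass(c(x)))
  }
}

#' Write a full synthetic dataset to disk
#'
#' Writes `expression.tsv`, `traces.tsv`, `schedule.tsv`, `events.tsv`,
#' `ground_truth_types.tsv`, `ground_truth.json` (informative genes and
#' planted thresholds), `templates.yaml` and `config.yaml` into `dir`.
#'
#' @param dataset a `carma_dataset` from [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "carma_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  write_traces(dataset$traces, file.path(dir, "traces.tsv"))
  write_schedule(dataset$schedule, file.path(dir, "schedule.tsv"),
                 file.path(dir, "events.tsv"))
  gt <- dataset$ground_truth
  write_tsv_plain(dplyr::mutate(
    gt$types, coherent = unname(gt$coherent[gt$types$cell])),
    file.path(dir, "ground_truth_types.tsv"))
  jsonlite::write_json(
    list(informative_genes = gt$informative_genes,
         conductor_gene = gt$conductor_gene,
         planted_thresholds = as.list(gt$planted_thresholds)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  tpl <- lapply(dataset$templates, function(tp) {
    tp$response_kernels <- as.list(as.data.frame(tp$response_kernels))
    unclass_deep(tp)
  })
  yaml::write_yaml(tpl, file.path(dir, "templates.yaml"))
  write_config(dataset$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `expression`, `traces`, `schedule` and `ground_truth`
#'   (types/coherence tibble only).
#' @export
read_dataset <- function(dir) {
  traces <- read_traces(file.path(dir, "traces.tsv"))
  gt <- read_tsv_plain(file.path(dir, "ground_truth_types.tsv"))
  list(
    expression = read_expression(file.path(dir, "expression.tsv")),
    traces = traces,
    schedule = read_schedule(file.path(dir, "schedule.tsv"),
                             file.path(dir, "events.tsv")),
    ground_truth = tibble::as_tibble(gt)
  )
}
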