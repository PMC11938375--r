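#' Generator configuration for synthetic CaRMA datasets
#'
#' Builds the parameter list consumed by [build_templates()] and
#' [generate_dataset()]. Defaults emulate a posterior-PVH-style recording:
#' 319 neurons from 10 molecularly defined types probed with 12 marker genes
#' across 11 behavioral states. Expression is zero-inflated log-normal
#' (continuous, strongly right-skewed, high variance); each type is dominated
#' by one high-mean marker gene, and a "conductor" receptor-like gene spans
#' several types with its expression level coupled to response amplitude.
#'
#' @param ... named overrides of any default listed below. Unknown names are
#'   rejected.
#'
#' @details Defaults:
#' \describe{
#'   \item{n_types, genes, states, n_cells}{10 types; 12 genes `g01..g12`;
#'     11 state labels; 319 cells.}
#'   \item{mu_hi, mu_lo, mu_conductor, mu_class, dispersion}{log-scale
#'     location of the dominant gene (3.0), off-type background (-1.0), the
#'     conductor gene (1.8) and class-level markers (2.0); common log-scale
#'     dispersion 0.8. Genes that are dominant in no type and are not the
#'     conductor act as class markers spanning contiguous blocks of types
#'     (the hierarchical marker organization of real panels).}
#'   \item{detect_hi, detect_bg, detect_conductor, detect_class}{probability
#'     of nonzero expression: 0.99 dominant, 0.12 background, 0.90 conductor
#'     in member types, 0.85 class markers. Background 0.12 puts the per-cell
#'     expressed-gene mode at 3 with ~80% of cells coexpressing more than
#'     two genes.}
#'   \item{conductor_gene, conductor_types, conductor_states,
#'     conductor_coupling}{index of the conductor gene (last gene), the types
#'     it spans (1..6), the states in which it organizes responses (first 3),
#'     and the exponent coupling expression level to response gain (0.8).}
#'   \item{coherence, incoherent_types}{fraction of member neurons following
#'     the type kernel (0.95); the last type is fully incoherent (coherence
#'     0), emulating a low-purity type.}
#'   \item{amp_range, p_sign, onset_range, ramp_fast, ramp_slow,
#'     decay_range}{each type responds strongly (amp_range[2] = 1.6 dF/F) in
#'     its signature state and weakly (0.4-1.0 dF/F) in a sparse set of other
#'     states with sign probabilities (+, -, 0) = (0.20, 0.15, 0.65), so each
#'     state is carried primarily by one driver type; onset latency
#'     0.4-1.2 s, ramp time constants 0.8 s (fast types) or 6 s (slow types),
#'     decay 2-8 s.}
#'   \item{noise_sd, ar_coef, gain_sdlog}{stationary AR(1) noise sd 0.3 dF/F
#'     with coefficient 0.8 at 0.4-s steps; per-neuron log-normal gain
#'     (sdlog 0.15).}
#'   \item{n_trials, stim_s, iti_s, sampling_interval}{3 trials per state,
#'     20-s stimulus epochs, 24-s inter-trial intervals, 0.4-s sampling.}
#' }
#'
#' @return A named list of class `carma_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_cells = 60, n_trials = 2)
#' cfg$n_types
synth_config <- function(...) {
  defaults <- list(
    n_types = 10L,
    genes = sprintf("g%02d", 1:12),
    states = c("Eat-Hng", "Eat-Aft", "Drink-Thirst", "Drink-Aft", "Eat-Hed",
               "Fear", "Ghrelin", "Leptin", "Saline", "Groom", "Rest"),
    n_cells = 319L,
    mu_hi = 3.0, mu_lo = -1.0, mu_conductor = 1.8, mu_class = 2.0,
    dispersion = 0.8,
    detect_hi = 0.99, detect_bg = 0.12, detect_conductor = 0.90,
    detect_class = 0.85,
    conductor_gene = NA_integer_,   # resolved to the last gene below
    conductor_types = NULL,         # resolved to 1..min(6, n_types) below
    conductor_states = NULL,        # resolved to the first 3 states below
    conductor_coupling = 0.8,
    coherence = 0.95,
    incoherent_types = NA_integer_, # resolved to the last type below
    amp_range = c(0.4, 1.6),
    p_sign = c(pos = 0.20, neg = 0.15, zero = 0.65),
    onset_range = c(0.4, 1.2),
    ramp_fast = 0.8, ramp_slow = 6,
    decay_range = c(2, 8),
    noise_sd = 0.3, ar_coef = 0.8, gain_sdlog = 0.15,
    n_trials = 3L, stim_s = 20, iti_s = 24, sampling_interval = 0.4
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("all generator overrides must be named", class = "carma_config_error")
    }
    unknown <- setdiff(names(overrides), c(names(defaults), "n_genes", "n_states"))
    if (length(unknown)) {
      abort(paste0("unknown generator parameter(s): ",
                   paste(unknown, collapse = ", ")),
            class = "carma_config_error")
    }
    if (!is.null(overrides$n_genes)) {
      overrides$genes <- sprintf("g%02d", seq_len(overrides$n_genes))
      overrides$n_genes <- NULL
    }
    if (!is.null(overrides$n_states)) {
      n <- overrides$n_states
      overrides$states <- if (n <= length(defaults$states)) {
        defaults$states[seq_len(n)]
      } else {
        c(defaults$states, sprintf("State%02d", seq_len(n - length(defaults$states))))
      }
      overrides$n_states <- NULL
    }
    defaults[names(overrides)] <- overrides
  }
  cfg <- defaults
  cfg$n_types <- as.integer(cfg$n_types)
  if (is.na(cfg$conductor_gene)) cfg$conductor_gene <- length(cfg$genes)
  if (is.null(cfg$conductor_types)) cfg$conductor_types <- seq_len(min(6L, cfg$n_types))
  if (is.null(cfg$conductor_states)) {
    cfg$conductor_states <- cfg$states[seq_len(min(3L, length(cfg$states)))]
  }
  if (length(cfg$incoherent_types) == 1 && is.na(cfg$incoherent_types)) {
    cfg$incoherent_types <- cfg$n_types
  }
  validate_synth_config(cfg)
  structure(cfg, class = "carma_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_types < 2L) {
    abort("generator needs at least 2 cell types", class = "carma_config_error")
  }
  if (length(cfg$genes) < 2L) {
    abort("generator needs at least 2 genes", class = "carma_config_error")
  }
  if (length(cfg$states) < 2L) {
    abort("generator needs at least 2 behavioral states", class = "carma_config_error")
  }
  if (anyDuplicated(cfg$genes)) abort("gene names must be unique", class = "carma_config_error")
  if (anyDuplicated(cfg$states)) abort("state labels must be unique", class = "carma_config_error")
  stopifnot(cfg$sampling_interval > 0, cfg$stim_s > 0, cfg$iti_s > 0,
            cfg$n_trials >= 1, cfg$dispersion > 0,
            all(cfg$detect_bg >= 0 & cfg$detect_bg <= 1),
            cfg$coherence >= 0, cfg$coherence <= 1)
  invisible(cfg)
}

#' Build per-type generative templates
#'
#' Deterministically (for a fixed seed) constructs one template per cell type:
#' per-gene log-scale means, dispersions and detection probabilities, per-state
#' response kernels (sign, amplitude, onset latency, ramp and decay time
#' constants), and the coherence fraction. Type `t` is dominated by gene `t`
#' (high mean, high detection) and responds strongly in its signature state;
#' conductor-spanned types additionally share the conductor gene at high
#' detection, with conductor-state kernel amplitude increasing with the type's
#' conductor expression level.
#'
#' @param config a [synth_config()] list.
#' @param seed integer seed; identical `(config, seed)` gives identical
#'   templates.
#' @return A list of type templates (class `carma_templates`), each a list
#'   with `type_id`, `gene_means`, `gene_dispersions`, `detect_prob`,
#'   `response_kernels` (tibble: state, sign, amplitude, onset_s, ramp_s,
#'   decay_s) and `coherence`. Serializable with `as.list()`/[yaml::as.yaml()].
#' @export
build_templates <- function(config, seed = 1L) {
  validate_synth_config(config)
  genes <- config$genes
  states <- config$states
  n_types <- config$n_types
  n_genes <- length(genes)
  n_states <- length(states)
  cond_g <- config$conductor_gene
  # conductor types ordered by increasing conductor mean so that kernel
  # amplitude in conductor states tracks expression level across types
  cond_types <- intersect(config$conductor_types, seq_len(n_types))
  mu_c <- setNames(rep(NA_real_, n_types), NULL)
  if (length(cond_types)) {
    offs <- if (length(cond_types) > 1) {
      seq(-0.4, 0.4, length.out = length(cond_types))
    } else 0
    mu_c[cond_types] <- config$mu_conductor + offs
  }

  # spare genes (dominant in no type, not the conductor) act as class-level
  # markers, each spanning a contiguous block of types -- the hierarchical
  # marker organization in which broad classes subdivide into types
  dominants <- vapply(seq_len(n_types),
                      function(t) ((t - 1L) %% n_genes) + 1L, integer(1))
  spare <- setdiff(seq_len(n_genes), c(dominants, cond_g))
  class_of_type <- if (length(spare)) {
    sort(rep_len(seq_along(spare), n_types))
  } else rep(NA_integer_, n_types)

  with_seed(seed, {
    lapply(seq_len(n_types), function(t) {
      dom <- dominants[t]
      means <- rep(config$mu_lo, n_genes)
      detect <- rep(config$detect_bg, n_genes)
      means[dom] <- config$mu_hi
      detect[dom] <- config$detect_hi
      if (!is.na(class_of_type[t])) {
        cg <- spare[class_of_type[t]]
        means[cg] <- config$mu_class
        detect[cg] <- config$detect_class
      }
      is_cond_type <- t %in% cond_types
      if (is_cond_type && cond_g != dom) {
        means[cond_g] <- mu_c[t]
        detect[cond_g] <- config$detect_conductor
      }
      names(means) <- names(detect) <- genes
      disps <- setNames(rep(config$dispersion, n_genes), genes)

      # secondary (off-signature) responses are weak and shared within
      # consecutive state pairs (state classes): paired states are
      # distinguished primarily by their dedicated driver types, so state
      # identity genuinely requires cell-type coverage
      n_blocks <- ceiling(n_states / 2)
      block_of <- rep(seq_len(n_blocks), each = 2)[seq_len(n_states)]
      sign_draw <- sample(c(1, -1, 0), n_blocks, replace = TRUE,
                          prob = config$p_sign)[block_of]
      amp <- runif(n_blocks, config$amp_range[1],
                   mean(config$amp_range))[block_of]
      onset <- runif(n_blocks, config$onset_range[1],
                     config$onset_range[2])[block_of]
      ramp <- rep(if (t %% 2 == 0) config$ramp_fast else config$ramp_slow, n_states)
      decay <- runif(n_blocks, config$decay_range[1],
                     config$decay_range[2])[block_of]
      if (is_cond_type) {
        cs <- match(config$conductor_states, states)
        sign_draw[cs] <- 1
        amp[cs] <- 0.8 * exp(mu_c[t] - config$mu_conductor)
      }
      # signature state: a strong response guaranteeing identifiability and
      # making this type the primary driver of that state (applied last so
      # every state keeps a dedicated driver)
      sig <- ((t - 1L) %% n_states) + 1L
      sign_draw[sig] <- 1
      amp[sig] <- config$amp_range[2]
      kernels <- tibble::tibble(
        state = states, sign = sign_draw, amplitude = amp,
        onset_s = onset, ramp_s = ramp, decay_s = decay
      )
      coh <- if (t %in% config$incoherent_types) 0 else config$coherence
      list(type_id = t, gene_means = means, gene_dispersions = disps,
           detect_prob = detect, response_kernels = kernels, coherence = coh)
    }) |>
      structure(class = "carma_templates", config = config)
  })
}

#' Sample a zero-inflated log-normal expression matrix
#'
#' Each cell is assigned one true type (balanced assignment, shuffled), and
#' each gene value is nonzero with the template's detection probability, with
#' nonzero values `exp(Normal(gene_mean, gene_dispersion))` -- continuous,
#' strictly positive and right-skewed.
#'
#' @param templates output of [build_templates()].
#' @param n_cells number of cells to draw (>= 1).
#' @param seed integer seed.
#' @return A list with `expression` (tibble: `cell` + one column per gene) and
#'   `ground_truth` (class `carma_ground_truth`): tibble `types` (cell, type),
#'   `informative_genes` (per-state character list), `conductor_gene`,
#'   `planted_thresholds` (named numeric; the conductor expression cutoff
#'   separating response classes).
#' @export
sample_expression <- function(templates, n_cells, seed = 1L) {
  stopifnot(inherits(templates, "carma_templates"))
  check_scalar_number(n_cells, "n_cells", min = 1)
  config <- attr(templates, "config")
  genes <- config$genes
  n_types <- length(templates)

  with_seed(seed, {
    type_of <- rep_len(seq_len(n_types), n_cells)[sample.int(n_cells)]
    mu <- do.call(rbind, lapply(templates, `[[`, "gene_means"))[type_of, , drop = FALSE]
    dsp <- do.call(rbind, lapply(templates, `[[`, "gene_dispersions"))[type_of, , drop = FALSE]
    det <- do.call(rbind, lapply(templates, `[[`, "detect_prob"))[type_of, , drop = FALSE]
    n <- n_cells * length(genes)
    on_mask <- matrix(runif(n) < det, n_cells)
    vals <- matrix(exp(rnorm(n, mean = mu, sd = dsp)), n_cells) * on_mask
    colnames(vals) <- genes
    rownames(vals) <- sprintf("cell%04d", seq_len(n_cells))

    informative <- lapply(config$states, function(s) {
      resp <- vapply(templates, function(tp) {
        k <- tp$response_kernels
        k$sign[k$state == s] != 0
      }, logical(1))
      dom <- vapply(which(resp), function(t) {
        genes[((t - 1L) %% length(genes)) + 1L]
      }, character(1))
      if (s %in% config$conductor_states) {
        dom <- union(dom, genes[config$conductor_gene])
      }
      unique(dom)
    })
    names(informative) <- config$states

    thr <- setNames(exp(config$mu_conductor), genes[config$conductor_gene])
    gt <- structure(
      list(
        types = tibble::tibble(cell = rownames(vals), type = type_of),
        informative_genes = informative,
        conductor_gene = genes[config$conductor_gene],
        planted_thresholds = thr
      ),
      class = "carma_ground_truth"
    )
    list(expression = matrix_to_expr(vals), ground_truth = gt)
  })
}

#' Build a trial-block behavioral-state schedule
#'
#' Sweeps through all states in order, `n_trials` times, each trial an
#' `iti_s`-second unlabeled inter-trial interval followed by a `stim_s`-second
#' labeled state epoch. Stimulus-onset events are placed at each epoch start.
#'
#' @param config a [synth_config()] list.
#' @return A `carma_schedule` (see [carma_schedule()]).
#' @export
build_schedule <- function(config) {
  validate_synth_config(config)
  states <- rep(config$states, times = config$n_trials)
  trial <- rep(seq_len(config$n_trials), each = length(config$states))
  cycle <- config$iti_s + config$stim_s
  start <- config$iti_s + (seq_along(states) - 1) * cycle
  epochs <- tibble::tibble(
    state = states, start_s = start, end_s = start + config$stim_s,
    trial = trial
  )
  events <- tibble::tibble(label = states, time_s = start)
  carma_schedule(epochs, events, config$sampling_interval,
                 duration_s = max(epochs$end_s) + config$iti_s)
}

#' Behavioral-state schedule container
#'
#' Validates and wraps a table of labeled state epochs (half-open intervals
#' `[start_s, end_s)`, in seconds), optional stimulus events, and the trace
#' sampling interval.
#'
#' @param epochs data frame with columns `state`, `start_s`, `end_s` (and
#'   optionally `trial`). Must be sorted, strictly increasing, non-overlapping.
#' @param events optional data frame with columns `label`, `time_s`; every
#'   event must fall inside an epoch.
#' @param sampling_interval trace sampling step in seconds (default 0.4).
#' @param duration_s total session length in seconds (default: last epoch end).
#' @return A list of class `carma_schedule`.
#' @export
carma_schedule <- function(epochs, events = NULL, sampling_interval = 0.4,
                           duration_s = NULL) {
  epochs <- tibble::as_tibble(epochs)
  need <- c("state", "start_s", "end_s")
  if (!all(need %in% names(epochs))) {
    abort("epochs need columns state, start_s, end_s", class = "carma_format_error")
  }
  if (nrow(epochs) == 0) abort("no epochs", class = "carma_format_error")
  if (!"trial" %in% names(epochs)) {
    epochs$trial <- stats::ave(seq_len(nrow(epochs)), epochs$state,
                               FUN = seq_along)
  }
  if (any(!is.finite(epochs$start_s)) || any(!is.finite(epochs$end_s))) {
    abort("non-finite epoch times", class = "carma_format_error")
  }
  if (any(epochs$end_s <= epochs$start_s)) {
    abort("epoch end must exceed start", class = "carma_format_error")
  }
  if (is.unsorted(epochs$start_s, strictly = TRUE)) {
    abort("epochs must be sorted with strictly increasing start times",
          class = "carma_format_error")
  }
  if (nrow(epochs) > 1 &&
      any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)])) {
    abort("overlapping epochs", class = "carma_format_error")
  }
  check_scalar_number(sampling_interval, "sampling_interval", min = 1e-9)
  if (is.null(duration_s)) duration_s <- max(epochs$end_s)
  if (!is.null(events) && nrow(events) > 0) {
    events <- tibble::as_tibble(events)
    inside <- vapply(events$time_s, function(tt) {
      any(tt >= epochs$start_s & tt < epochs$end_s)
    }, logical(1))
    if (!all(inside)) {
      abort("every event time must fall inside an epoch",
            class = "carma_format_error")
    }
  } else {
    events <- tibble::tibble(label = character(), time_s = numeric())
  }
  structure(list(epochs = epochs, events = events,
                 sampling_interval = sampling_interval,
                 duration_s = duration_s),
            class = "carma_schedule")
}

#' @export
print.carma_schedule <- function(x, ...) {
  cat(sprintf("<carma_schedule> %d epochs, %d states, %.1f s at %.2g-s steps\n",
              nrow(x$epochs), length(unique(x$epochs$state)), x$duration_s,
              x$sampling_interval))
  invisible(x)
}

# evaluate one response kernel on the session time grid, adding into `sig`
add_kernel <- function(sig, times, start, end, sign, amplitude, onset_s,
                       ramp_s, decay_s) {
  if (sign == 0 || amplitude == 0) return(sig)
  t_on <- start + onset_s
  in_epoch <- times >= t_on & times < end
  sig[in_epoch] <- sig[in_epoch] +
    sign * amplitude * (1 - exp(-(times[in_epoch] - t_on) / ramp_s))
  r_end <- sign * amplitude * (1 - exp(-max(end - t_on, 0) / ramp_s))
  post <- times >= end & times < end + 8 * decay_s
  sig[post] <- sig[post] + r_end * exp(-(times[post] - end) / decay_s)
  sig
}

#' Sample calcium traces with type-coherent state responses
#'
#' For every neuron, each state's response follows its type's kernel
#' (`sign * amplitude * (1 - exp(-(t - onset)/ramp))` during the stimulus
#' epoch, exponential decay after offset) if the neuron is a coherent member;
#' incoherent members draw an independent random kernel per state. A
#' per-neuron log-normal gain scales the clean signal, and stationary AR(1)
#' noise is added. For conductor-spanned types, a neuron's overall response
#' gain increases with its conductor-gene expression, and neurons below the
#' planted conductor threshold respond with flipped sign in conductor states.
#'
#' @param templates output of [build_templates()].
#' @param ground_truth `carma_ground_truth` from [sample_expression()].
#' @param schedule a [carma_schedule()]; must contain every state named in the
#'   templates' kernels.
#' @param seed integer seed.
#' @param expression optional expression tibble enabling the conductor
#'   expression-to-response coupling; omit for purely type-level kernels.
#' @param noise_sd,ar_coef,gain_sdlog optional overrides of the generator
#'   config values.
#' @return Numeric matrix (neurons x timepoints, dF/F) with attributes
#'   `sampling_interval`, `times` (bin start times, s) and `coherent` (named
#'   logical; which neurons followed their type kernel).
#' @export
sample_traces <- function(templates, ground_truth, schedule, seed = 1L,
                          expression = NULL, noise_sd = NULL, ar_coef = NULL,
                          gain_sdlog = NULL) {
  stopifnot(inherits(templates, "carma_templates"),
            inherits(ground_truth, "carma_ground_truth"),
            inherits(schedule, "carma_schedule"))
  config <- attr(templates, "config")
  noise_sd <- noise_sd %||% config$noise_sd
  ar_coef <- ar_coef %||% config$ar_coef
  gain_sdlog <- gain_sdlog %||% config$gain_sdlog

  kernel_states <- unique(unlist(lapply(templates, function(tp) {
    tp$response_kernels$state[tp$response_kernels$sign != 0]
  })))
  missing_states <- setdiff(kernel_states, schedule$epochs$state)
  if (length(missing_states)) {
    abort(paste0("states in templates absent from schedule: ",
                 paste(missing_states, collapse = ", ")),
          class = "carma_schedule_mismatch")
  }

  dt <- schedule$sampling_interval
  n_t <- floor(schedule$duration_s / dt + 1e-9)
  times <- (seq_len(n_t) - 1) * dt
  cells <- ground_truth$types$cell
  type_of <- ground_truth$types$type
  cond_gene <- ground_truth$conductor_gene
  thr <- unname(ground_truth$planted_thresholds[cond_gene])
  cond_expr <- NULL
  if (!is.null(expression) && cond_gene %in% names(expression)) {
    cond_expr <- setNames(expression[[cond_gene]], expression$cell)
  }
  innov_sd <- if (abs(ar_coef) < 1) noise_sd * sqrt(1 - ar_coef^2) else noise_sd

  with_seed(seed, {
    out <- matrix(0, length(cells), n_t,
                  dimnames = list(cells, NULL))
    coherent <- setNames(logical(length(cells)), cells)
    for (i in seq_along(cells)) {
      tp <- templates[[type_of[i]]]
      coh <- runif(1) < tp$coherence
      coherent[i] <- coh
      kern <- tp$response_kernels
      gain <- exp(rnorm(1, 0, gain_sdlog))
      flip_states <- character()
      if (!is.null(cond_expr) && type_of[i] %in% config$conductor_types) {
        e <- cond_expr[[cells[i]]]
        gain <- gain * min(max((max(e, 1e-3) / thr)^config$conductor_coupling,
                               0.3), 3)
        if (coh && e < thr) flip_states <- config$conductor_states
      }
      sig <- numeric(n_t)
      for (j in seq_len(nrow(schedule$epochs))) {
        ep <- schedule$epochs[j, ]
        if (coh) {
          k <- kern[kern$state == ep$state, ]
          if (nrow(k) == 0) next
          s <- if (ep$state %in% flip_states) -k$sign else k$sign
          sig <- add_kernel(sig, times, ep$start_s, ep$end_s, s, k$amplitude,
                            k$onset_s, k$ramp_s, k$decay_s)
        } else {
          # incoherent members: a fresh random kernel per epoch, so their
          # responses are unreliable across trials as well as across neurons
          sig <- add_kernel(sig, times, ep$start_s, ep$end_s,
                            sample(c(1, -1), 1),
                            abs(rnorm(1, 0, mean(config$amp_range))),
                            runif(1, config$onset_range[1], config$onset_range[2]),
                            runif(1, config$ramp_fast, config$ramp_slow),
                            runif(1, config$decay_range[1], config$decay_range[2]))
        }
      }
      noise <- if (noise_sd > 0) {
        as.numeric(stats::filter(rnorm(n_t, 0, innov_sd), ar_coef,
                                 method = "recursive"))
      } else 0
      out[i, ] <- gain * sig + noise
    }
    attr(out, "sampling_interval") <- dt
    attr(out, "times") <- times
    attr(out, "coherent") <- coherent
    out
  })
}

#' Generate a complete synthetic CaRMA dataset
#'
#' One deterministic call producing expression, traces, schedule and ground
#' truth; sub-stage seeds are derived from `seed` (templates: `seed`,
#' expression: `seed + 1`, traces: `seed + 2`). If `out_dir` is given, all
#' components are also written to disk as tab-delimited tables (see
#' [write_dataset()]).
#'
#' @param config a [synth_config()] list.
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @return A list of class `carma_dataset`: `expression` (tibble), `traces`
#'   (matrix), `schedule` (`carma_schedule`), `ground_truth`, `templates`,
#'   `config`, `seed`.
#' @export
generate_dataset <- function(config = synth_config(), seed = 1L,
                             out_dir = NULL) {
  seed <- as.integer(seed)
  templates <- build_templates(config, seed)
  schedule <- build_schedule(config)
  xp <- sample_expression(templates, config$n_cells, seed + 1L)
  traces <- sample_traces(templates, xp$ground_truth, schedule, seed + 2L,
                          expression = xp$expression)
  xp$ground_truth$coherent <- attr(traces, "coherent")
  ds <- structure(
    list(expression = xp$expression, traces = traces, schedule = schedule,
         ground_truth = xp$ground_truth, templates = templates,
         config = config, seed = seed),
    class = "carma_dataset"
  )
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' @export
print.carma_dataset <- function(x, ...) {
  cat(sprintf(paste0("<carma_dataset> %d cells x %d genes; traces %d x %d ",
                     "(%.2g-s steps); %d states\n"),
              nrow(x$expression), ncol(x$expression) - 1L, nrow(x$traces),
              ncol(x$traces), x$schedule$sampling_interval,
              length(unique(x$schedule$epochs$state))))
  invisible(x)
}
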