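#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-neuron decoding results
#' @param x a `carma_decoding` object.
#' @param ... unused.
#' @return tibble with one row per neuron.
#' @export
tidy.carma_decoding <- function(x, ...) x$per_neuron

#' @rdname tidy.carma_decoding
#' @export
glance.carma_decoding <- function(x, ...) {
  tibble::tibble(
    accuracy = mean(x$per_neuron$accuracy),
    n_neurons = nrow(x$per_neuron),
    n_states = length(x$states)
  )
}

#' Tidy grouped-ensemble decoding results
#' @param x a `carma_grouped` object.
#' @param ... unused.
#' @return tibble with one row per resample.
#' @export
tidy.carma_grouped <- function(x, ...) {
  tibble::tibble(resample = seq_along(x$accuracy), accuracy = x$accuracy)
}

#' @rdname tidy.carma_grouped
#' @export
glance.carma_grouped <- function(x, ...) {
  tibble::tibble(accuracy = mean(x$accuracy), sd = sd(x$accuracy),
                 n_resamples = length(x$accuracy),
                 n_types = length(x$types), n_states = length(x$states))
}

#' Tidy an SFFS selection path
#' @param x an `sffs_report`.
#' @param ... unused.
#' @return the steps tibble (step, gene, accuracy).
#' @export
tidy.sffs_report <- function(x, ...) x$steps

#' @rdname tidy.sffs_report
#' @export
glance.sffs_report <- function(x, ...) {
  tibble::tibble(n_genes = length(x$selected), accuracy = x$accuracy,
                 auroc = x$auroc)
}

#' Tidy a fitted FC-prediction model
#' @param x a `carma_fc_fit`.
#' @param ... unused.
#' @return tibble of model coefficients.
#' @export
tidy.carma_fc_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.carma_fc_fit
#' @export
glance.carma_fc_fit <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auroc = x$auroc,
                 n = nrow(x$predictions))
}

#' Tidy a Youden cutpoint result
#' @param x a `carma_youden`.
#' @param ... unused.
#' @return single-row tibble.
#' @export
tidy.carma_youden <- function(x, ...) {
  tibble::as_tibble(x[!vapply(x, is.null, logical(1))])
}

#' Tidy per-timestamp FDE results
#' @param x a `carma_temporal_fde`.
#' @param ... unused.
#' @return tibble (timestamp, model, fde).
#' @export
tidy.carma_temporal_fde <- function(x, ...) x$fde

#' @rdname tidy.carma_temporal_fde
#' @export
glance.carma_temporal_fde <- function(x, ...) {
  x$fde |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_fde = mean(.data$fde), max_fde = max(.data$fde),
                     .groups = "drop")
}
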