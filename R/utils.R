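#' @importFrom rlang %||% abort warn .data
#' @importFrom stats sd cor rnorm runif rbinom quantile fisher.test wilcox.test
#'   ks.test chisq.test qtukey pf aov lm coef predict median setNames
#' @importFrom utils combn head
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Expression tables travel as tibbles with a `cell` id column; models want a
# numeric matrix with cell rownames.
expr_to_matrix <- function(expression) {
  stopifnot(is.data.frame(expression))
  if (!"cell" %in% names(expression)) {
    abort("expression table must have a `cell` id column")
  }
  m <- as.matrix(expression[setdiff(names(expression), "cell")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(expression$cell)
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(cell = rownames(m), .before = 1)
}

# Stratified fold assignment: within each class, samples are dealt round-robin
# across folds (in a seeded random order). If any class has fewer members than
# `folds`, the fold count is reduced with a warning so every fold sees every
# class.
stratified_folds <- function(labels, folds, seed = NULL) {
  labels <- as.factor(labels)
  min_n <- min(table(labels))
  if (min_n < folds) {
    warn(sprintf("reducing folds from %d to %d (smallest class has %d samples)",
                 folds, min_n, min_n))
    folds <- min_n
  }
  if (folds < 2) abort("need at least 2 samples per class for cross-validation")
  assign_fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign_fold
}

# Pick a CV fold count so that every training split keeps >= 2 samples of
# every class (the ridge solver needs two); requires >= 3 samples per class.
safe_folds <- function(labels, folds, what = "samples") {
  c_min <- min(table(labels))
  if (c_min < 3) {
    abort(sprintf("each class needs >= 3 %s for cross-validated fitting",
                  what))
  }
  f <- min(folds, c_min)
  while (c_min - ceiling(c_min / f) < 2 && f < c_min) f <- f + 1L
  f
}

# glmnet wants >= 2 predictor columns; pad a constant zero column when given
# one (its coefficient is identically zero and does not affect predictions).
pad_x <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `.pad` = 0)
}

check_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s", name, min))
  }
  invisible(x)
}
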