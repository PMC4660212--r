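#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for a named random stream
#'
#' Generators draw every (assay, cell line) block from its own stream so that
#' adding an assay or line never perturbs draws belonging to other blocks.
#' The sub-seed is a deterministic arithmetic hash of the base seed and a key
#' string; all intermediates stay below 2^31 so the result is exact in doubles.
#'
#' @param seed base integer seed.
#' @param key character scalar naming the stream (e.g. "screen/apoptosis/L03").
#' @return an integer in [0, 2^31 - 2] usable with [set.seed()].
#' @keywords internal
stream_seed <- function(seed, key) {
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

## Log-normal multiplicative noise with unit mean and coefficient of
## variation cv: E[X] = 1, sd(X)/E[X] = cv.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -sigma2 / 2, sdlog = sqrt(sigma2))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

stopifnot_probability <- function(x, name) {
  stopifnot_scalar_number(x, name)
  if (x < 0 || x > 1)
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

## Columns of a MeasurementTable, in canonical order.
MEASUREMENT_COLUMNS <- c(
  "screen_id", "cell_line", "assay", "condition", "gene", "reagent_type",
  "reagent_id", "replicate", "raw_value", "paired_viability_value",
  "plate", "well"
)

#' Validate a MeasurementTable
#'
#' Checks the long-format screen measurement schema shared by the simulator,
#' the normalization pipeline and the hit-calling rules.
#'
#' @param x a data.frame of screen measurements.
#' @return `x`, invisibly, with columns in canonical order.
#' @export
validate_measurements <- function(x) {
  if (!is.data.frame(x)) stop("measurements must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(x))
  if (length(missing_cols))
    stop("measurement table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad_type <- setdiff(unique(x$reagent_type),
                      c("pool", "single", "control_nt", "control_ubb"))
  if (length(bad_type))
    stop("unknown reagent_type values: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  bad_cond <- setdiff(unique(x$condition), c("vehicle", "ligand", "na"))
  if (length(bad_cond))
    stop("unknown condition values: ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x$raw_value)))
    stop("raw_value contains non-finite entries", call. = FALSE)
  invisible(x[, MEASUREMENT_COLUMNS])
}
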