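#' Default predictor scaling ranges
#'
#' Ranges over which model predictors are rescaled to \[0, 1\] before
#' fitting, so that a coefficient reads as the expected change in the
#' outcome over the predictor's full observed range (e.g. valence
#' intensity from 0 to 50, pre-trial baseline from 3.0 to 7.0 mm).
#'
#' @return Named list of length-2 numeric vectors `c(lo, hi)`.
#' @export
#' @examples
#' pc_scaling_ranges()$valence_intensity
pc_scaling_ranges <- function() {
  list(
    valence_intensity = c(0, 50),
    confidence        = c(0, 100),
    duration          = c(0.5, 6),
    response_time     = c(0.6, 9),
    pretrial_baseline = c(3.0, 7.0),
    peak_dilation     = c(3.6, 7.6)
  )
}

# scale x to [0,1] over a stated range (values outside the range are allowed
# and map outside [0,1]; the scaling is affine, not a clamp)
scale_range <- function(x, range) {
  (x - range[1]) / (range[2] - range[1])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# strictly positive scalar check
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

check_series <- function(series, require = c("t_s", "pupil_mm")) {
  if (!is.data.frame(series)) abort("`series` must be a data frame.")
  missing_cols <- setdiff(require, names(series))
  if (length(missing_cols)) {
    abort(sprintf("`series` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  invisible(series)
}

# logical runs -> integer start/end indices (inclusive)
runs_of <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
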