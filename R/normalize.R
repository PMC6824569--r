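#' Zero-mean unit-variance normalization
#'
#' Standardizes a grid to zero mean and unit (population) standard
#' deviation, `(I - mean(I)) / std(I)`, keeping the source statistics so the
#' transform can be inverted after processing.
#'
#' @param x Numeric matrix or array (non-empty, non-constant).
#' @return An object of class `normalized_grid` with fields `values`,
#'   `source_mean`, `source_sd`.
#' @examples
#' n <- normalize_grid(matrix(1:4, 2))
#' round(n$values, 4)
#' @export
normalize_grid <- function(x) {
  if (length(x) == 0) stop("empty grid")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s < 1e-12) stop("degenerate input: grid is constant")
  structure(list(values = (x - m) / s, source_mean = m, source_sd = s),
            class = "normalized_grid")
}

#' Invert the normalization
#'
#' Maps a normalized grid back to its physical scale using the recorded (or
#' overridden) source statistics: `values * source_sd + source_mean`.
#'
#' @param x A `normalized_grid`.
#' @param source_mean,source_sd Statistics to invert with; default the ones
#'   recorded on `x`.
#' @return Numeric matrix/array on the original scale.
#' @export
denormalize_grid <- function(x, source_mean = x$source_mean,
                             source_sd = x$source_sd) {
  if (!inherits(x, "normalized_grid")) stop("expected a normalized_grid")
  x$values * source_sd + source_mean
}

#' @export
print.normalized_grid <- function(x, ...) {
  cat(sprintf("normalized_grid: %s, source mean %.4g, source sd %.4g\n",
              paste(dim(x$values), collapse = " x "),
              x$source_mean, x$source_sd))
  invisible(x)
}
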