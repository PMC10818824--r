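#' Ordinary least-squares line
#'
#' Straight-line fit used by both quenching analyses, with the conventions
#' the transformed coordinates need: at least 3 points, a non-degenerate
#' abscissa, and R^2 defined as 1 when the response is constant (SS_tot = 0,
#' i.e. the line reproduces the data exactly).
#'
#' @param x,y Numeric vectors of equal length `>= 3`, finite.
#' @return A one-row tibble with columns `slope`, `intercept`, `r_squared`
#'   and `n_points`.
#' @examples
#' ols_line(1:5, 2 * (1:5) + 1)
#' @export
ols_line <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    fq_abort("`x` and `y` must be numeric vectors of equal length.", "domain")
  }
  if (length(x) < 3L) {
    fq_abort(sprintf("At least 3 points are required to fit a line (got %d).", length(x)),
             "insufficient_data")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    fq_abort("All coordinates must be finite.", "domain")
  }
  if (diff(range(x)) == 0) {
    fq_abort("`x` is degenerate (all values equal); the slope is undefined.", "domain")
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    # constant response: the horizontal line is exact, slope identically 0
    return(tibble::tibble(slope = 0, intercept = y[1], r_squared = 1,
                          n_points = length(x)))
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  tibble::tibble(
    slope = unname(cf[2]),
    intercept = unname(cf[1]),
    r_squared = 1 - sum(stats::residuals(fit)^2) / ss_tot,
    n_points = length(x)
  )
}
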