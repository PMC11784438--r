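#' Autoagglutination ratio from optical density
#'
#' Percent drop in suspension optical density (OD at 660 nm) after
#' standing, due to sedimentation of autoagglutinated cell clumps:
#' \code{100 * (od_initial - od_after) / od_initial}. Scale-invariant in
#' the pair of readings. A negative ratio (the suspension got denser, e.g.
#' growth or mixing artifact) is returned as-is with a warning.
#'
#' @param od_initial Initial OD660 reading(s); must be > 0.
#' @param od_after OD660 after standing; must be >= 0.
#' @return Numeric percentage(s) in (-Inf, 100]; 100 only when
#'   \code{od_after} is 0.
#' @examples
#' autoagglutination_ratio(1.0, 0.5)  # 50
#' @export
autoagglutination_ratio <- function(od_initial, od_after) {
  if (any(!is.finite(od_initial)) || any(od_initial <= 0))
    stop_input("'od_initial' must be positive")
  if (any(!is.finite(od_after)) || any(od_after < 0))
    stop_input("'od_after' must be non-negative")
  ratio <- 100 * (od_initial - od_after) / od_initial
  if (any(ratio < 0))
    warning("negative autoagglutination ratio: OD increased after standing")
  ratio
}

#' Replicate summary statistics
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of
#' replicate measurements; the standard deviation is undefined (NA) for a
#' single replicate.
#'
#' @param values Numeric vector, length >= 1.
#' @return List with \code{mean}, \code{sd}, \code{n}.
#' @export
replicate_summary <- function(values) {
  if (length(values) == 0L) stop_input("no replicate values supplied")
  if (any(!is.finite(values))) stop_input("replicate values must be finite")
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Two-group comparison of replicate measurements
#'
#' Convenience wrapper around a two-tailed two-sample Student's t test
#' (equal-variance), for comparing phenotype readouts between two strains.
#'
#' @param x,y Numeric vectors of replicate values.
#' @return The \code{htest} object from \code{\link[stats]{t.test}}.
#' @export
group_ttest <- function(x, y) {
  stats::t.test(x, y, alternative = "two.sided", var.equal = TRUE)
}
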