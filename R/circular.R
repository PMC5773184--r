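#' Wrap phases to the centered interval (-0.5, 0.5]
#'
#' Phase differences are reported in a centered convention so that small
#' leads and lags around synchrony keep their sign. All circular arithmetic
#' inside the package is done on the unit circle; this is the canonical
#' reporting representation.
#'
#' @param x numeric vector of phases (cycle fractions, any real value).
#' @return numeric vector in (-0.5, 0.5].
#' @export
#' @examples
#' wrap_phase(0.95)  # -0.05
#' wrap_phase(-0.3)  # -0.3
wrap_phase <- function(x) {
  -(((0.5 - x) %% 1) - 0.5)
}

#' Wrap phases to [0, 1)
#'
#' @param x numeric vector of phases (cycle fractions).
#' @return numeric vector in [0, 1).
#' @export
wrap_unit <- function(x) {
  x %% 1
}

# Wrapped-normal helpers. A wrapped normal with (unwrapped) standard
# deviation sigma radians has mean resultant length r = exp(-sigma^2/2),
# hence angular variance 2(1 - exp(-sigma^2/2)) rad^2. These convert between
# an angular variance expressed in phase-fraction units squared
# (rad^2 / 4 pi^2) and sigma^2 in rad^2. The inversion only
# exists for v < 1/(2 pi^2) ~ 0.0507 phase^2 (r > 0).
angvar_to_sigma2 <- function(v) {
  if (any(v < 0)) stop("angular variance must be nonnegative")
  arg <- 1 - 2 * pi^2 * v
  if (any(arg <= 0)) {
    stop("angular variance ", paste(format(v[arg <= 0]), collapse = ", "),
         " phase^2 is too large for unimodal wrapped-normal sampling ",
         "(must be < 1/(2*pi^2) ~ ", format(1 / (2 * pi^2), digits = 4), ")")
  }
  -2 * log(arg)
}

sigma2_to_angvar <- function(s2) {
  (1 - exp(-s2 / 2)) / (2 * pi^2)
}

#' Draw wrapped-normal phases with a given angular variance
#'
#' Samples from a wrapped normal distribution parameterized directly by its
#' angular variance \eqn{s^2 = 2(1-r)} expressed in phase-fraction units
#' squared, the dispersion measure used throughout the package. The
#' population angular variance of the draws equals `v` exactly (not just in
#' the small-dispersion limit), which makes this the sampling primitive for
#' all synthetic-data noise.
#'
#' @param n number of draws.
#' @param mean mean phase (cycle fraction).
#' @param v angular variance in phase^2; must be < 1/(2*pi^2).
#' @return numeric vector of phases in [0, 1).
#' @export
rwrapnorm <- function(n, mean = 0, v = 0.001) {
  if (v == 0) return(wrap_unit(rep(mean, n)))
  sigma_phase <- sqrt(angvar_to_sigma2(v)) / (2 * pi)
  wrap_unit(stats::rnorm(n, mean, sigma_phase))
}

#' Circular summary by vector summation
#'
#' Converts phases (cycle fractions) to unit vectors at angle \eqn{2\pi\phi},
#' averages them, and reports the mean vector phase, the mean resultant
#' length \eqn{r}, the angular variance \eqn{s^2 = 2(1-r)} and angular
#' standard deviation \eqn{s = \sqrt{s^2}}. Dispersion is reported both in
#' radian units and in phase-fraction units (dividing by \eqn{4\pi^2} and
#' \eqn{2\pi}, respectively).
#'
#' @param phases numeric vector of phases (cycle fractions); NA not allowed.
#' @return an object of class `circular_summary`: a list with elements
#'   `n`, `mean_phase` (in [0,1)), `r`, `s2_rad`, `s2_phase`, `s_rad`,
#'   `s_phase`.
#' @export
#' @examples
#' circular_summary(c(0.1, 0.2))      # mean 0.15, r ~ 0.951
#' circular_summary(c(0, .25, .5, .75))$r  # 0: four-fold symmetry
circular_summary <- function(phases) {
  if (length(phases) < 1) stop("need at least one phase")
  if (anyNA(phases)) stop("phases contain NA")
  a <- 2 * pi * phases
  C <- mean(cos(a))
  S <- mean(sin(a))
  r <- min(sqrt(C^2 + S^2), 1)
  s2_rad <- 2 * (1 - r)
  out <- list(
    n = length(phases),
    mean_phase = wrap_unit(atan2(S, C) / (2 * pi)),
    r = r,
    s2_rad = s2_rad,
    s2_phase = s2_rad / (4 * pi^2),
    s_rad = sqrt(s2_rad),
    s_phase = sqrt(s2_rad) / (2 * pi)
  )
  class(out) <- "circular_summary"
  out
}

#' @export
print.circular_summary <- function(x, ...) {
  cat("Circular summary (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  mean phase: %.4f  r: %.4f\n", x$mean_phase, x$r))
  cat(sprintf("  angular variance s^2: %.6g rad^2 = %.6g phase^2\n",
              x$s2_rad, x$s2_phase))
  cat(sprintf("  angular SD s: %.6g rad = %.6g phase\n", x$s_rad, x$s_phase))
  invisible(x)
}

#' Angular variance of a phase sample, in phase-fraction units squared
#'
#' Convenience wrapper around [circular_summary()] returning only
#' \eqn{s^2/(4\pi^2)}, the quantity every variance level of the analysis is
#' expressed in.
#'
#' @param phases numeric vector of phases (cycle fractions).
#' @return angular variance in phase^2.
#' @export
angular_variance <- function(phases) {
  circular_summary(phases)$s2_phase
}

#' Circular difference of two phases, centered
#'
#' Computes `a - b` on the unit circle and canonicalizes the result to
#' (-0.5, 0.5], so that e.g. 0.95 - 0.05 gives -0.10 rather than +0.90.
#' This is the \eqn{\Delta\Delta\phi} primitive of the repetition and
#' bilateral analyses.
#'
#' @param a,b numeric vectors of phases (cycle fractions); recycled.
#' @return centered circular differences in (-0.5, 0.5].
#' @export
circular_mean_difference <- function(a, b) {
  wrap_phase(a - b)
}

#' Coefficient of variation of cycle periods
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param periods numeric vector of cycle periods in seconds; all > 0,
#'   length >= 2.
#' @return CV as a dimensionless fraction.
#' @export
period_cv <- function(periods) {
  if (length(periods) < 2) stop("need at least two periods")
  if (any(!is.finite(periods)) || any(periods <= 0)) {
    stop("periods must be positive and finite")
  }
  stats::sd(periods) / mean(periods)
}

#' Mean absolute centered circular difference
#'
#' Summary used to compare the magnitude of repetition and bilateral
#' \eqn{\Delta\Delta\phi} distributions: the mean of the absolute values of
#' the centered circular differences.
#'
#' @param ddphis numeric vector of phase differences (cycle fractions).
#' @return mean of `abs(wrap_phase(ddphis))`.
#' @export
abs_ddphi_summary <- function(ddphis) {
  if (length(ddphis) < 1) stop("need at least one value")
  mean(abs(wrap_phase(ddphis)))
}
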