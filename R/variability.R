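# ---- internal vectorized circular machinery ----------------------------

# angular variance (phase^2) of each row of a matrix of phases
.angvar_rows <- function(m) {
  a <- 2 * pi * m
  r <- sqrt(rowMeans(cos(a))^2 + rowMeans(sin(a))^2)
  2 * (1 - pmin(r, 1)) / (4 * pi^2)
}

# jackknife SE of the angular variance of a single sample
.angvar_jack_se <- function(x) {
  n <- length(x)
  a <- 2 * pi * x
  cs <- sum(cos(a)); ss <- sum(sin(a))
  cl <- (cs - cos(a)) / (n - 1)
  sl <- (ss - sin(a)) / (n - 1)
  v <- 2 * (1 - pmin(sqrt(cl^2 + sl^2), 1)) / (4 * pi^2)
  sqrt((n - 1) / n * sum((v - mean(v))^2))
}

# jackknife SEs of the angular variance of each row
.angvar_jack_se_rows <- function(m) {
  n <- ncol(m)
  a <- 2 * pi * m
  ca <- cos(a); sa <- sin(a)
  cl <- (rowSums(ca) - ca) / (n - 1)
  sl <- (rowSums(sa) - sa) / (n - 1)
  v <- 2 * (1 - pmin(sqrt(cl^2 + sl^2), 1)) / (4 * pi^2)
  sqrt((n - 1) / n * rowSums((v - rowMeans(v))^2))
}

# ---- per-episode and population variance --------------------------------

#' Cycle-to-cycle variance of one coordination episode
#'
#' Circular summary of the per-cycle intersegmental phase differences of a
#' single episode. Episodes shorter than `min_cycles` (default 7, the
#' smallest episode entering the reference analyses) are excluded with a
#' warning.
#'
#' @param dphi numeric vector of per-cycle phase differences (cycle
#'   fractions) of one episode; NA entries (skipped cycles) are dropped.
#' @param min_cycles minimum usable cycles; below this `NULL` is returned
#'   with a warning.
#' @return a [circular_summary()] or `NULL`.
#' @export
cycle_to_cycle_variance <- function(dphi, min_cycles = 7) {
  dphi <- dphi[!is.na(dphi)]
  if (length(dphi) < min_cycles) {
    warning("episode excluded: only ", length(dphi), " usable cycles (< ",
            min_cycles, ")")
    return(NULL)
  }
  circular_summary(dphi)
}

#' Population variance of per-animal mean phase differences, with bootstrap CI
#'
#' The population variance of a stratum is the angular variance of the
#' per-animal mean intersegmental phase differences (one mean per animal,
#' from a single switch cycle). Its confidence interval is obtained by
#' resampling animals with replacement. The default interval is studentized
#' (bootstrap-t with jackknife standard errors), which is second-order
#' accurate for variance-type statistics; the plain percentile interval is
#' available as `method = "percentile"`.
#'
#' @param per_animal_means numeric vector of per-animal mean phase
#'   differences (cycle fractions); n >= 3.
#' @param n_boot bootstrap resamples (default 10000).
#' @param ci confidence level (default 0.95).
#' @param seed optional integer seed for the resampling.
#' @param method `"studentized"` (default) or `"percentile"`.
#' @return an object of class `variance_report`: list with `n`, `mean_dphi`
#'   (centered circular mean), `s2` (angular variance, phase^2), `ci_lo`,
#'   `ci_hi`, `ci_level`, `n_boot`, `method`.
#' @export
population_variance <- function(per_animal_means, n_boot = 10000, ci = 0.95,
                                seed = NULL, method = c("studentized",
                                                        "percentile")) {
  method <- match.arg(method)
  x <- per_animal_means
  if (anyNA(x)) x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("population variance needs at least 3 animals")
  if (!is.null(seed)) set.seed(seed)
  th <- angular_variance(x)
  mu <- wrap_phase(circular_summary(x)$mean_phase)
  alpha <- (1 - ci) / 2
  xm <- matrix(x[sample.int(n, n * n_boot, replace = TRUE)], n_boot, n)
  bs <- .angvar_rows(xm)
  if (method == "percentile") {
    q <- stats::quantile(bs, c(alpha, 1 - alpha), names = FALSE)
    lo <- q[1]; hi <- q[2]
  } else {
    se <- .angvar_jack_se(x)
    if (se < 1e-14) {
      lo <- hi <- th
    } else {
      seb <- .angvar_jack_se_rows(xm)
      tstat <- (bs - th) / seb
      tstat <- tstat[is.finite(tstat)]
      q <- stats::quantile(tstat, c(alpha, 1 - alpha), names = FALSE)
      lo <- max(0, th - q[2] * se)
      # an angular variance cannot exceed 2 rad^2 = 1/(2 pi^2) phase^2
      hi <- min(th - q[1] * se, 1 / (2 * pi^2))
    }
  }
  out <- list(n = n, mean_dphi = mu, s2 = th, ci_lo = lo, ci_hi = hi,
              ci_level = ci, n_boot = n_boot, method = method)
  class(out) <- "variance_report"
  out
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf(
    "Population variance (n = %d animals): s^2 = %.5g phase^2, %d%% CI [%.5g, %.5g] (%s, %d resamples)\n",
    x$n, x$s2, round(100 * x$ci_level), x$ci_lo, x$ci_hi, x$method, x$n_boot))
  cat(sprintf("  mean dphi = %.4f\n", x$mean_dphi))
  invisible(x)
}

# ---- scrambling tests ---------------------------------------------------

# shared engine: observed variance of centered circular differences d1 - d2
# against the variances of cross-animal re-pairings
.scramble_test <- function(d1, d2, n_scramble, seed, scheme, what) {
  keep <- !(is.na(d1) | is.na(d2))
  if (any(!keep)) {
    message(sum(!keep), " animals dropped (missing ", what, " value)")
    d1 <- d1[keep]; d2 <- d2[keep]
  }
  n <- length(d1)
  if (n < 5) stop(what, " test needs at least 5 complete animals")
  if (!is.null(seed)) set.seed(seed)
  observed <- angular_variance(circular_mean_difference(d1, d2))
  if (scheme == "repair") {
    # independent partner per animal, uniform over the other n - 1 animals
    J <- matrix(sample.int(n - 1, n * n_scramble, replace = TRUE),
                n_scramble, n)
    shift <- matrix(seq_len(n), n_scramble, n, byrow = TRUE)
    J <- J + (J >= shift)
  } else {
    J <- matrix(0L, n_scramble, n)
    for (i in seq_len(n_scramble)) {
      repeat {
        p <- sample.int(n)
        if (!any(p == seq_len(n))) break
      }
      J[i, ] <- p
    }
  }
  D <- wrap_phase(matrix(d1, n_scramble, n, byrow = TRUE) -
                    matrix(d2[J], n_scramble, n))
  draws <- .angvar_rows(D)
  null_mean <- mean(draws)
  null_sd <- stats::sd(draws)
  if (null_sd < 1e-15) {
    z <- if (abs(observed - null_mean) < 1e-15) 0 else
      sign(observed - null_mean) * Inf
  } else {
    z <- (observed - null_mean) / null_sd
  }
  out <- list(observed = observed, null_mean = null_mean, null_sd = null_sd,
              z = z, p = stats::pnorm(z),
              p_two_sided = 2 * stats::pnorm(-abs(z)),
              n = n, n_scramble = n_scramble, scheme = scheme,
              comparison = what, draws = draws)
  class(out) <- "scrambling_result"
  out
}

#' @export
print.scrambling_result <- function(x, ...) {
  cat(sprintf("Scrambling test (%s, n = %d animals, %d scrambles, %s)\n",
              x$comparison, x$n, x$n_scramble, x$scheme))
  cat(sprintf("  observed variance %.5g phase^2, scrambled %.5g +- %.5g\n",
              x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  z = %.3f, one-sided (lower) p = %.4g, two-sided p = %.4g\n",
              x$z, x$p, x$p_two_sided))
  invisible(x)
}

#' Repetition variability test by cross-animal scrambling
#'
#' Asks whether repeating the same coordination a few minutes later on the
#' same side gives tighter phase differences than expected across animals.
#' The per-animal statistic is the centered circular difference of the mean
#' phase differences of two consecutive switch cycles
#' (\eqn{\Delta\Delta\phi = \Delta\phi_1 - \Delta\phi_2}), whose angular
#' variance is compared with a null distribution built by pairing switch
#' cycle 1 of each animal with switch cycle 2 of a randomly chosen
#' different animal, `n_scramble` times. The p value is the lower-tail
#' probability of the observed variance under a normal fit to the scrambled
#' variances (from its z score); the two-sided value is also reported.
#'
#' @param dphi_cycle1,dphi_cycle2 per-animal mean phase differences (cycle
#'   fractions) of the first and second switch cycle; animals with either
#'   value missing are dropped with a message. At least 5 complete animals.
#' @param n_scramble number of scrambled populations (default 10000).
#' @param seed optional integer seed.
#' @param scheme `"derangement"` (default: one fixed-point-free permutation
#'   per iteration, so every animal is used exactly once, mirroring the
#'   structure of the observed pairing) or `"repair"` (each animal is
#'   independently paired with a random different animal per iteration).
#' @return an object of class `scrambling_result`.
#' @export
repetition_test <- function(dphi_cycle1, dphi_cycle2, n_scramble = 10000,
                            seed = NULL,
                            scheme = c("derangement", "repair")) {
  .scramble_test(dphi_cycle1, dphi_cycle2, n_scramble, seed,
                 match.arg(scheme), "repetition")
}

#' Bilateral variability test by cross-animal scrambling
#'
#' As [repetition_test()], but the per-animal statistic is the difference of
#' the mean phase differences of the left and right body side within one
#' coordination (\eqn{\Delta\Delta\phi = \Delta\phi_L - \Delta\phi_R}), and
#' the null re-pairs left sides with right sides of different animals.
#'
#' @param dphi_left,dphi_right per-animal mean phase differences of the two
#'   sides within one coordination.
#' @inheritParams repetition_test
#' @return an object of class `scrambling_result`.
#' @export
bilateral_test <- function(dphi_left, dphi_right, n_scramble = 10000,
                           seed = NULL,
                           scheme = c("derangement", "repair")) {
  .scramble_test(dphi_left, dphi_right, n_scramble, seed,
                 match.arg(scheme), "bilateral")
}

# ---- level comparison, outliers, components -----------------------------

#' Compare mean phase differences between two levels or groups
#'
#' Two-sample t test (paired or unpaired) on phase values linearized around
#' their pooled circular mean: each phase is represented as its centered
#' circular deviation from the pooled mean, which avoids wrap artifacts
#' while preserving group differences. Justified by the small dispersions of
#' these data; the result is rotation invariant.
#'
#' @param a,b numeric vectors of per-animal mean phase differences (cycle
#'   fractions); `paired = TRUE` requires equal-length, animal-aligned
#'   vectors.
#' @param paired logical.
#' @return list of class `level_comparison` with `p.value`, `statistic`,
#'   `df`, `mean_a`, `mean_b` (centered circular means), `n_a`, `n_b`,
#'   `paired`.
#' @export
compare_levels <- function(a, b, paired = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  if (paired && length(a) != length(b)) {
    stop("paired comparison needs aligned samples of equal length")
  }
  mu <- circular_summary(c(a, b))$mean_phase
  la <- wrap_phase(a - mu)
  lb <- wrap_phase(b - mu)
  degen <- if (paired) stats::sd(la - lb) < 1e-14 else
    (stats::sd(la) < 1e-14 && stats::sd(lb) < 1e-14 &&
       abs(mean(la) - mean(lb)) < 1e-14)
  if (degen) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(la) - 1),
               p.value = 1)
  } else {
    tt <- stats::t.test(la, lb, paired = paired)
  }
  out <- list(
    p.value = tt$p.value,
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    mean_a = wrap_phase(circular_summary(a)$mean_phase),
    mean_b = wrap_phase(circular_summary(b)$mean_phase),
    n_a = length(a), n_b = length(b), paired = paired
  )
  class(out) <- "level_comparison"
  out
}

#' @export
print.level_comparison <- function(x, ...) {
  cat(sprintf("%s t test: mean dphi %.4f vs %.4f, t = %.3f, df = %.1f, p = %.4g\n",
              if (x$paired) "Paired" else "Unpaired",
              x$mean_a, x$mean_b, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Flag outliers by the 1.5 x interquartile-range rule
#'
#' Values below Q1 - 1.5 IQR or above Q3 + 1.5 IQR (the whiskers of a
#' standard box plot) are flagged. Flagged animals can then be excluded from
#' downstream strata with a logged justification.
#'
#' @param values numeric vector, length >= 4 (quartiles are not meaningful
#'   below that).
#' @return logical vector of flags, same length as `values`.
#' @export
outlier_screen <- function(values) {
  if (length(values) < 4) stop("outlier screen needs at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Method-of-moments decomposition into four variance components
#'
#' Recovers the cycle-to-cycle, repetition, bilateral, and population
#' variance components from per-stratum summaries, per level and
#' coordination. The decomposition works on the wrapped-normal
#' \eqn{\sigma^2} scale, where independent components add exactly:
#'
#' * cycle-to-cycle: mean within-episode angular variance;
#' * repetition: half the variance of \eqn{\Delta\phi_1 - \Delta\phi_2}
#'   across animal-sides, minus the averaged-noise term;
#' * bilateral: half the variance of \eqn{\Delta\phi_L - \Delta\phi_R},
#'   minus the repetition and noise terms;
#' * population: across-animal variance of the per-animal means (averaged
#'   over side x switch-cycle strata), minus all lower components.
#'
#' Subtractions are floored at zero. Results are reported as angular
#' variances in phase^2.
#'
#' @param strata data frame with one row per (animal, side, level,
#'   coordination, switch_cycle): columns `animal`, `side`, `level`,
#'   `coordination`, `switch_cycle`, `mean_dphi`, `s2_cycle`, `n_cycles`.
#' @return data frame with one row per (level, coordination):
#'   `var_cycle`, `var_repetition`, `var_bilateral`, `var_population`, and
#'   the pair counts used.
#' @export
estimate_variance_components <- function(strata) {
  need <- c("animal", "side", "level", "coordination", "switch_cycle",
            "mean_dphi", "s2_cycle", "n_cycles")
  if (!all(need %in% names(strata))) {
    stop("strata must have columns: ", paste(need, collapse = ", "))
  }
  # sample angular variance with the small-sample n/(n-1) correction (the
  # vector-summation estimator, like the n-denominator linear variance, is
  # biased low by that factor to first order)
  av <- function(x) angular_variance(x) * length(x) / (length(x) - 1)
  out <- list()
  for (lv in unique(strata$level)) {
    for (co in unique(strata$coordination)) {
      sub <- strata[strata$level == lv & strata$coordination == co &
                      !is.na(strata$mean_dphi), ]
      if (nrow(sub) < 6) next
      # median across episodes: robust to the occasional episode whose
      # boundaries were misplaced in hard-to-segment recordings
      v_cyc <- stats::median(sub$s2_cycle * sub$n_cycles / (sub$n_cycles - 1),
                             na.rm = TRUE)
      s2c <- angvar_to_sigma2(v_cyc)
      noise <- s2c * mean(1 / sub$n_cycles)

      # repetition: switch cycle 1 vs 2 within animal-side
      key <- paste(sub$animal, sub$side)
      m1 <- sub$mean_dphi[sub$switch_cycle == 1]
      names(m1) <- key[sub$switch_cycle == 1]
      m2 <- sub$mean_dphi[sub$switch_cycle == 2]
      names(m2) <- key[sub$switch_cycle == 2]
      common <- intersect(names(m1), names(m2))
      s2_rep <- NA_real_
      if (length(common) >= 3) {
        dd <- circular_mean_difference(m1[common], m2[common])
        s2_rep <- max(0, (angvar_to_sigma2(av(dd)) - 2 * noise) / 2)
      }

      # bilateral: left vs right within animal-switch cycle
      keyb <- paste(sub$animal, sub$switch_cycle)
      mL <- sub$mean_dphi[sub$side == "L"]
      names(mL) <- keyb[sub$side == "L"]
      mR <- sub$mean_dphi[sub$side == "R"]
      names(mR) <- keyb[sub$side == "R"]
      commonb <- intersect(names(mL), names(mR))
      s2_bil <- NA_real_
      if (length(commonb) >= 3 && !is.na(s2_rep)) {
        dd <- circular_mean_difference(mL[commonb], mR[commonb])
        s2_bil <- max(0, angvar_to_sigma2(av(dd)) / 2 -
                        s2_rep - noise)
      }

      # population: across animals within (side, switch cycle), averaged
      tot <- c()
      for (sd_ in unique(sub$side)) for (k in unique(sub$switch_cycle)) {
        m <- sub$mean_dphi[sub$side == sd_ & sub$switch_cycle == k]
        if (length(m) >= 3) {
          tot <- c(tot, angvar_to_sigma2(av(m)))
        }
      }
      s2_pop <- if (length(tot) && !is.na(s2_bil)) {
        max(0, mean(tot) - s2_bil - s2_rep - noise)
      } else NA_real_

      out[[length(out) + 1L]] <- data.frame(
        level = lv, coordination = co,
        var_cycle = v_cyc,
        var_repetition = sigma2_to_angvar(s2_rep),
        var_bilateral = sigma2_to_angvar(s2_bil),
        var_population = sigma2_to_angvar(s2_pop),
        n_animals = length(unique(sub$animal)),
        n_rep_pairs = length(common),
        n_bil_pairs = length(commonb)
      )
    }
  }
  do.call(rbind, out)
}

#' Correlation between phase difference and cycle period
#'
#' Plain utility: Pearson correlation test between centered phase
#' differences and their cycle periods.
#'
#' @param dphi per-cycle phase differences (cycle fractions).
#' @param periods matching cycle periods (s).
#' @return the `htest` object from [stats::cor.test()].
#' @export
phase_period_correlation <- function(dphi, periods) {
  keep <- !(is.na(dphi) | is.na(periods))
  stats::cor.test(wrap_phase(dphi[keep]), periods[keep])
}
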