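#' Spike-triggered average of a voltage-clamp current trace
#'
#' Averages trace segments aligned on presynaptic spike times to isolate the
#' unitary postsynaptic current. Each segment is baseline-subtracted using
#' the mean of a pre-trigger window, and the amplitude is the signed
#' extremum of the average within the post-trigger window. Triggers whose
#' window overlaps a trace edge are dropped. Triggers are grouped into
#' bursts (gaps >= `ibi_threshold`); at least `min_bursts` bursts are
#' required unless `override = TRUE`.
#'
#' @param trace data frame with columns `time` (s, uniform) and `current`
#'   (pA), e.g. from [generate_clamp_trace()] or [read_trace()].
#' @param triggers numeric vector of presynaptic spike times (s).
#' @param window post-trigger window length (s), default 0.2.
#' @param baseline_window pre-trigger baseline window (s), default 0.05.
#' @param min_bursts minimum trigger bursts (default 10).
#' @param ibi_threshold gap defining a new trigger burst (s).
#' @param override set `TRUE` to compute despite too few bursts.
#' @return object of class `sta_result`: list with `lags` (s), `average`
#'   (pA, baseline-subtracted), `peak_pA` (signed extremum after the
#'   trigger), `n_triggers`, `n_bursts`.
#' @export
spike_triggered_average <- function(trace, triggers, window = 0.2,
                                    baseline_window = 0.05, min_bursts = 10,
                                    ibi_threshold = 1, override = FALSE) {
  if (!all(c("time", "current") %in% names(trace))) {
    stop("trace must have columns time and current")
  }
  tt <- trace$time
  dt <- stats::median(diff(tt))
  triggers <- sort(triggers)
  ok <- triggers - baseline_window >= tt[1] & triggers + window <= tt[length(tt)]
  if (any(!ok)) {
    message(sum(!ok), " triggers dropped at trace edges")
    triggers <- triggers[ok]
  }
  if (length(triggers) == 0) stop("no usable triggers")
  n_bursts <- if (length(triggers) == 1) 1L else
    1L + sum(diff(triggers) >= ibi_threshold)
  if (n_bursts < min_bursts && !override) {
    stop("only ", n_bursts, " trigger bursts (< ", min_bursts,
         "); set override = TRUE to average anyway")
  }
  nb <- round(baseline_window / dt)
  nw <- round(window / dt)
  lags <- seq(-nb, nw) * dt
  acc <- numeric(nb + nw + 1)
  for (s in triggers) {
    i0 <- round((s - tt[1]) / dt) + 1L
    seg <- trace$current[(i0 - nb):(i0 + nw)]
    acc <- acc + (seg - mean(seg[seq_len(nb)]))
  }
  avg <- acc / length(triggers)
  post <- which(lags > 0)
  peak <- avg[post][which.max(abs(avg[post]))]
  out <- list(lags = lags, average = avg, peak_pA = peak,
              n_triggers = length(triggers), n_bursts = n_bursts)
  class(out) <- "sta_result"
  out
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf(
    "Spike-triggered average: %d triggers in %d bursts, peak %.3g pA\n",
    x$n_triggers, x$n_bursts, x$peak_pA))
  invisible(x)
}

#' Convert a peak synaptic current to a conductance
#'
#' \eqn{g = I / (V_{hold} - E_{rev})}, in nS for I in pA and potentials in
#' mV. Holding potentials are only accurate to about +-`holding_error` mV,
#' which is propagated into an uncertainty band on g.
#'
#' @param peak_pA peak current (pA).
#' @param holding holding potential (mV).
#' @param reversal reversal potential (mV), default -62.
#' @param holding_error holding-potential accuracy (mV), default 5.
#' @return list with `g` (nS) and `band` (length-2 vector; the band is
#'   unbounded, `Inf`, when the holding error can cancel the driving
#'   force).
#' @export
#' @examples
#' to_conductance(40, holding = -42)$g  # 2 nS
to_conductance <- function(peak_pA, holding, reversal = -62,
                           holding_error = 5) {
  drive <- holding - reversal
  if (drive == 0) stop("holding potential equals the reversal potential")
  g <- peak_pA / drive
  d_lo <- drive - holding_error
  d_hi <- drive + holding_error
  band <- if (sign(d_lo) != sign(d_hi) || d_lo == 0 || d_hi == 0) {
    c(min(peak_pA / d_hi, peak_pA / d_lo, na.rm = TRUE), Inf)
  } else {
    sort(c(peak_pA / d_lo, peak_pA / d_hi))
  }
  list(g = g, band = band)
}

#' Proportional synaptic strength of the front premotor input
#'
#' The proportion of the summed premotor conductance contributed by the
#' front premotor interneuron, \eqn{g_4 / (g_4 + g_7)}, computed separately
#' per side. Being a ratio, it cancels any common recording-quality scale
#' factor exactly.
#'
#' @param g4,g7 conductances in nS (vectors recycled); both must be
#'   nonnegative and their sum positive.
#' @return fractions in \[0, 1\].
#' @export
proportional_strength <- function(g4, g7) {
  if (any(g4 < 0) || any(g7 < 0)) stop("conductances must be nonnegative")
  s <- g4 + g7
  if (any(s <= 0)) stop("proportional strength undefined: g4 + g7 must be > 0")
  g4 / s
}

#' Bilateral comparison of proportional synaptic strengths
#'
#' Paired t test of the per-animal left and right proportional strengths,
#' plus the distribution of paired-t p values over side-scrambled pairings
#' (left of each animal paired with the right of a random different
#' animal), whose mean is reported alongside the original p value.
#'
#' @param left,right per-animal proportional strengths, aligned; n >= 5,
#'   no missing values.
#' @param n_scramble number of scrambled pairings (default 10000).
#' @param seed optional integer seed.
#' @return list with `p` (paired t, original pairing), `statistic`, `df`,
#'   `scrambled_p_mean`, `scrambled_p` (all scrambled p values), `n`,
#'   `n_scramble`.
#' @export
bilateral_strength_test <- function(left, right, n_scramble = 10000,
                                    seed = NULL) {
  if (length(left) != length(right) || anyNA(left) || anyNA(right)) {
    stop("need complete, paired per-animal left/right proportions")
  }
  n <- length(left)
  if (n < 5) stop("need at least 5 animals")
  if (!is.null(seed)) set.seed(seed)
  d <- left - right
  if (stats::sd(d) < 1e-14) {
    p0 <- 1; t0 <- 0
  } else {
    tt <- stats::t.test(left, right, paired = TRUE)
    p0 <- tt$p.value; t0 <- unname(tt$statistic)
  }
  J <- matrix(sample.int(n - 1, n * n_scramble, replace = TRUE), n_scramble, n)
  J <- J + (J >= matrix(seq_len(n), n_scramble, n, byrow = TRUE))
  D <- matrix(left, n_scramble, n, byrow = TRUE) -
    matrix(right[J], n_scramble, n)
  m <- rowMeans(D)
  s <- sqrt(pmax(rowSums((D - m)^2) / (n - 1), 0))
  tstat <- m / (s / sqrt(n))
  ps <- 2 * stats::pt(-abs(tstat), df = n - 1)
  ps[s < 1e-14] <- 1
  list(p = p0, statistic = t0, df = n - 1,
       scrambled_p_mean = mean(ps), scrambled_p = ps,
       n = n, n_scramble = n_scramble)
}
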