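#' Configuration for the hierarchical synthetic-recording generator
#'
#' Defines the study conditions that synthetic recordings emulate: bilateral
#' pairs of bursting units at two network levels (interneuron-like "cpg" and
#' motor-neuron-like "motor") in two segments per side, alternating
#' peristaltic/synchronous coordination episodes of 15-60 cycles, burst
#' periods of a few seconds with small coefficient of variation, and
#' coordination-specific intersegmental phase differences built from four
#' independent wrapped-normal variance components:
#'
#' * `var_population` - an animal-level offset per level and coordination,
#' * `var_bilateral` - an independent side offset,
#' * `var_repetition` - an independent offset per switch cycle,
#' * `var_cycle` - independent per-cycle circular noise.
#'
#' All variances are angular variances in phase-fraction units squared and
#' add on the wrapped-normal \eqn{\sigma^2} scale. The two sides always
#' execute opposite coordinations and switch simultaneously.
#'
#' @param n_animals number of synthetic animals.
#' @param period_mean mean burst period (s).
#' @param period_cv coefficient of variation of per-cycle periods, in
#'   \[0, 0.2\]; periods are drawn independently per cycle.
#' @param cycles_per_episode integer range (length 2) of episode lengths in
#'   cycles; default 15-60.
#' @param n_switch_cycles number of complete switch cycles to generate; each
#'   spans one episode of each coordination, so `2 * n_switch_cycles`
#'   episodes are emitted.
#' @param levels character vector of spiking levels to generate ("cpg",
#'   "motor").
#' @param dphi_mean named list, per level, of named numeric vectors with
#'   entries `peristaltic` and `synchronous`: the mean intersegmental phase
#'   difference (cycle fraction in \[0, 1)) for each coordination.
#' @param var_population,var_bilateral,var_repetition,var_cycle variance
#'   components in phase^2; either a scalar applied everywhere or a named
#'   list per level of named vectors per coordination.
#' @param spikes_per_burst spikes per burst (odd counts make middle-spike
#'   recovery exact).
#' @param burst_duty_cycle burst duration as a fraction of the period.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_animals = 26,
                             period_mean = 8,
                             period_cv = 0.03,
                             cycles_per_episode = c(15, 60),
                             n_switch_cycles = 2,
                             levels = c("cpg", "motor"),
                             dphi_mean = list(
                               cpg = c(peristaltic = 0.23, synchronous = 0.02),
                               motor = c(peristaltic = 0.13, synchronous = 0.02),
                               beat = c(peristaltic = 0.21, synchronous = 0.02)
                             ),
                             var_population = 0.004,
                             var_bilateral = 0.005,
                             var_repetition = 0.001,
                             var_cycle = 0.001,
                             spikes_per_burst = 9,
                             burst_duty_cycle = 0.3,
                             seed = 1L) {
  stopifnot(n_animals >= 1, period_mean > 0, n_switch_cycles >= 1,
            spikes_per_burst >= 1,
            burst_duty_cycle > 0, burst_duty_cycle < 1)
  if (period_cv < 0 || period_cv > 0.2) {
    stop("period_cv must lie in [0, 0.2]")
  }
  cycles_per_episode <- as.integer(round(cycles_per_episode))
  if (length(cycles_per_episode) != 2 ||
      cycles_per_episode[1] < 2 ||
      cycles_per_episode[1] > cycles_per_episode[2]) {
    stop("cycles_per_episode must be an increasing integer range >= 2")
  }
  mus <- unlist(dphi_mean)
  if (any(mus < 0 | mus >= 1)) stop("dphi_mean values must lie in [0, 1)")
  cfg <- list(
    n_animals = as.integer(n_animals),
    period_mean = period_mean,
    period_cv = period_cv,
    cycles_per_episode = cycles_per_episode,
    n_switch_cycles = as.integer(n_switch_cycles),
    levels = levels,
    dphi_mean = dphi_mean,
    var_population = var_population,
    var_bilateral = var_bilateral,
    var_repetition = var_repetition,
    var_cycle = var_cycle,
    spikes_per_burst = as.integer(spikes_per_burst),
    burst_duty_cycle = burst_duty_cycle,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  # reject dispersions too large for unimodal wrapped-normal sampling:
  # each component must be invertible and the summed sigma must keep the
  # two coordinations' distributions distinguishable
  for (lv in names(dphi_mean)) {
    for (co in c("peristaltic", "synchronous")) {
      s2 <- sum(vapply(c("var_population", "var_bilateral",
                         "var_repetition", "var_cycle"),
                       function(w) angvar_to_sigma2(.gen_var(cfg[[w]], lv, co)),
                       0))
      if (sqrt(s2) / (2 * pi) > 0.15) {
        stop("summed variance components for level ", lv, ", ", co,
             " give phase SD ", format(sqrt(s2) / (2 * pi), digits = 3),
             " > 0.15: dispersion too large for unimodal wrapped-normal ",
             "sampling")
      }
    }
  }
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic-recording generator config:\n")
  cat("  ", x$n_animals, " animals, ", 2 * x$n_switch_cycles,
      " episodes of ", x$cycles_per_episode[1], "-", x$cycles_per_episode[2],
      " cycles, period ", x$period_mean, " s (CV ", x$period_cv, ")\n",
      sep = "")
  cat("  levels:", paste(x$levels, collapse = ", "), " seed:", x$seed, "\n")
  invisible(x)
}

# look up a variance component: scalar, or list per level of vector per
# coordination
.gen_var <- function(v, level, coordination) {
  if (is.numeric(v) && length(v) == 1) return(v)
  if (is.list(v)) {
    out <- v[[level]][[coordination]]
    if (is.null(out)) stop("no variance entry for ", level, "/", coordination)
    return(out)
  }
  stop("variance components must be scalars or per-level lists")
}

.sigma_phase <- function(v) {
  if (v == 0) return(0)
  sqrt(angvar_to_sigma2(v)) / (2 * pi)
}

# Draw the hierarchical episode/phase structure for one set of levels.
# Assumes the RNG is already seeded. Returns a list with tidy truth frames
# and per-animal timing (reference middles, periods, per-cycle dphi).
.draw_structure <- function(config, levels) {
  n_ep <- 2L * config$n_switch_cycles
  lo <- config$cycles_per_episode[1]
  hi <- config$cycles_per_episode[2]
  animals <- sprintf("A%03d", seq_len(config$n_animals))
  coords <- c("peristaltic", "synchronous")

  ep_rows <- vector("list", config$n_animals)
  cyc_rows <- list()
  strata_rows <- list()
  timing <- vector("list", config$n_animals)
  names(timing) <- animals

  for (ai in seq_along(animals)) {
    an <- animals[ai]
    ep_len <- if (lo == hi) rep(lo, n_ep) else
      sample(seq.int(lo, hi), n_ep, replace = TRUE)
    n_cyc <- sum(ep_len)
    ep_id <- rep(seq_len(n_ep), ep_len)
    sc_id <- ceiling(ep_id / 2)
    first_cycle <- cumsum(c(1L, ep_len[-n_ep]))
    last_cycle <- cumsum(ep_len)
    left_start <- sample(coords, 1)
    left_lab <- rep(c(left_start, setdiff(coords, left_start)),
                    length.out = n_ep)
    # side R is always in the opposite coordination
    coord_of <- list(
      L = left_lab,
      R = ifelse(left_lab == "peristaltic", "synchronous", "peristaltic")
    )

    periods <- stats::rnorm(n_cyc, config$period_mean,
                            config$period_cv * config$period_mean)
    periods <- pmax(periods, 0.2 * config$period_mean)
    t_ref <- 2 * config$period_mean + cumsum(c(0, periods))  # n_cyc + 1 markers

    ep_rows[[ai]] <- data.frame(
      animal = an, episode = seq_len(n_ep), switch_cycle = ceiling(seq_len(n_ep) / 2),
      first_cycle = first_cycle, last_cycle = last_cycle, n_cycles = ep_len,
      coordination_left = left_lab,
      coordination_right = coord_of$R[seq_len(n_ep)]
    )

    dphi_store <- list()
    for (lv in levels) {
      mu <- config$dphi_mean[[lv]]
      if (is.null(mu)) stop("dphi_mean has no entry for level ", lv)
      A <- stats::setNames(stats::rnorm(2, 0, c(
        .sigma_phase(.gen_var(config$var_population, lv, coords[1])),
        .sigma_phase(.gen_var(config$var_population, lv, coords[2])))), coords)
      for (sd_ in c("L", "R")) {
        S <- stats::setNames(stats::rnorm(2, 0, c(
          .sigma_phase(.gen_var(config$var_bilateral, lv, coords[1])),
          .sigma_phase(.gen_var(config$var_bilateral, lv, coords[2])))), coords)
        co_cycle <- coord_of[[sd_]][ep_id]
        R_draw <- matrix(0, config$n_switch_cycles, 2,
                         dimnames = list(NULL, coords))
        for (co in coords) {
          R_draw[, co] <- stats::rnorm(
            config$n_switch_cycles, 0,
            .sigma_phase(.gen_var(config$var_repetition, lv, co)))
        }
        eps_sd <- vapply(coords, function(co)
          .sigma_phase(.gen_var(config$var_cycle, lv, co)), 0)
        eps <- stats::rnorm(n_cyc, 0, eps_sd[co_cycle])
        raw <- mu[co_cycle] + A[co_cycle] +
          S[co_cycle] + R_draw[cbind(sc_id, match(co_cycle, coords))] + eps
        dphi <- wrap_phase(raw)
        # keep the unwrapped phase for marker placement: it is continuous
        # across cycles, so bursts stay ordered even when dphi wraps
        dphi_store[[paste(lv, sd_, sep = ".")]] <- raw
        cyc_rows[[length(cyc_rows) + 1L]] <- data.frame(
          animal = an, side = sd_, level = lv, cycle = seq_len(n_cyc),
          episode = ep_id, switch_cycle = sc_id, coordination = co_cycle,
          period = periods, dphi = dphi
        )
        for (k in seq_len(config$n_switch_cycles)) {
          for (co in coords) {
            strata_rows[[length(strata_rows) + 1L]] <- data.frame(
              animal = an, side = sd_, level = lv, coordination = co,
              switch_cycle = k,
              target_dphi = wrap_phase(mu[co] + A[co] + S[co] + R_draw[k, co])
            )
          }
        }
      }
    }
    timing[[an]] <- list(t_ref = t_ref, periods = periods, dphi = dphi_store,
                         n_cycles = n_cyc)
  }
  list(
    episodes = do.call(rbind, ep_rows),
    cycles = do.call(rbind, cyc_rows),
    strata = do.call(rbind, strata_rows),
    timing = timing,
    animals = animals
  )
}

# spikes of one channel: bursts centered on `middles`, spread over
# duty * period, n_s spikes at uniform intra-burst intervals. Bursts whose
# neighbors sit unusually close (large phase jumps at coordination
# switches) are shortened so that the interburst gap stays above the 1 s
# grouping threshold; the middle spike is unaffected.
.burst_spikes <- function(middles, periods, n_s, duty, min_gap = 1.05) {
  if (n_s == 1) return(middles)
  hw <- duty * periods / 2
  if (length(middles) > 1) {
    d <- diff(middles)
    allowed <- d - min_gap
    if (any(allowed <= 0)) {
      stop("phase markers closer than ", min_gap,
           " s: dispersion too large to emit separable bursts")
    }
    f <- pmin(1, allowed / (hw[-length(hw)] + hw[-1]))
    fac <- pmin(c(1, f), c(f, 1))
    hw <- hw * fac
  }
  offs <- (seq_len(n_s) - (n_s + 1) / 2) / ((n_s - 1) / 2)
  as.numeric(t(outer(middles, rep(1, n_s)) + outer(hw, offs)))
}

#' Generate a synthetic population of bilateral burst recordings
#'
#' Draws the hierarchical phase structure defined by a [generator_config()]
#' and emits, for every animal, four spike-train channels per side: an
#' interneuron-like reference/target pair (level "cpg") and a motor-like
#' pair (level "motor"). The target channel's middle spikes realize the
#' per-cycle intersegmental phase differences exactly: the target marker of
#' cycle \eqn{k} is placed at \eqn{t_k + \Delta\phi_k T_k} using the
#' centered \eqn{\Delta\phi}, so noise-free settings are recovered exactly
#' by [pair_cycles()].
#'
#' @param config a [generator_config()].
#' @return a list of class `synthetic_population` with elements
#'   `recordings` (per-animal list with a named list `trains` of
#'   [spike_train()] objects) and `truth` (ground-truth tables: `episodes`,
#'   `cycles` with per-cycle realized `dphi`, `strata` with per-stratum
#'   target phases, and the `config`).
#' @export
#' @examples
#' pop <- generate_population(generator_config(n_animals = 2, seed = 7))
#' names(pop$recordings[[1]]$trains)
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  levels <- intersect(config$levels, c("cpg", "motor"))
  if (length(levels) == 0) stop("config$levels must include 'cpg' or 'motor'")
  st <- .draw_structure(config, levels)

  unit_names <- list(cpg = c(reference = "HN4", target = "HN7"),
                     motor = c(reference = "HE8", target = "HE12"))
  recordings <- vector("list", config$n_animals)
  for (ai in seq_along(st$animals)) {
    an <- st$animals[ai]
    tm <- st$timing[[an]]
    trains <- list()
    for (lv in levels) {
      for (sd_ in c("L", "R")) {
        ref_mid <- tm$t_ref
        ref_per <- c(tm$periods, tm$periods[length(tm$periods)])
        tgt_mid <- tm$t_ref[seq_len(tm$n_cycles)] +
          tm$dphi[[paste(lv, sd_, sep = ".")]] * tm$periods
        for (role in c("reference", "target")) {
          un <- unit_names[[lv]][[role]]
          id <- paste(an, sd_, un, sep = "_")
          mids <- if (role == "reference") ref_mid else tgt_mid
          pers <- if (role == "reference") ref_per else tm$periods
          spk <- .burst_spikes(mids, pers, config$spikes_per_burst,
                               config$burst_duty_cycle)
          trains[[id]] <- spike_train(spk, id = id, side = sd_, level = lv,
                                      role = role)
        }
      }
    }
    recordings[[ai]] <- list(animal = an, trains = trains)
  }
  out <- list(
    recordings = recordings,
    truth = list(episodes = st$episodes, cycles = st$cycles,
                 strata = st$strata, config = config)
  )
  class(out) <- "synthetic_population"
  out
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("Synthetic population:", length(x$recordings), "animals,",
      length(x$recordings[[1]]$trains), "channels each\n")
  invisible(x)
}

#' Generate constriction-like traces per heart segment
#'
#' Produces uniformly sampled periodic waveforms for the motor-plant
#' ("beat") level: each beat is a raised-cosine constriction pulse whose
#' point of maximum derivative (the maximum rate of rise, MRR) falls at the
#' target phase marker. The reference segment's MRR marks the cycle start;
#' the target segment's MRR realizes the per-cycle intersegmental phase
#' difference, drawn from the same hierarchical structure as the spiking
#' levels.
#'
#' @param config a [generator_config()] whose `dphi_mean` includes a
#'   `beat` entry.
#' @param fs sampling rate in Hz; must resolve the constriction rise
#'   (at least 16 samples per pulse) or an error is raised.
#' @param amplitude pulse amplitude (arbitrary units), > 0.
#' @param duty pulse width as a fraction of the period.
#' @param noise_sd additive white-noise standard deviation.
#' @return list with `traces` (named list `<animal>_<side>_<segment>` of
#'   data frames `time`, `value`), `markers` (ground-truth MRR times),
#'   `cycles` (per-cycle realized phase differences) and `episodes`.
#' @export
generate_constriction_traces <- function(config, fs = 20, amplitude = 1,
                                         duty = 0.4, noise_sd = 0) {
  stopifnot(inherits(config, "generator_config"))
  if (amplitude <= 0) stop("zero-amplitude trace: no constriction to generate")
  pulse_samples <- fs * duty * config$period_mean * (1 - config$period_cv * 3)
  if (pulse_samples < 16) {
    stop("sampling rate ", fs, " Hz too low to localize the MRR: fewer than ",
         "16 samples per constriction pulse")
  }
  set.seed(config$seed + 1L)
  st <- .draw_structure(config, "beat")

  traces <- list()
  marker_rows <- list()
  for (an in st$animals) {
    tm <- st$timing[[an]]
    n_cyc <- tm$n_cycles
    t_end <- tm$t_ref[n_cyc + 1] + config$period_mean
    tt <- seq(0, t_end, by = 1 / fs)
    for (sd_ in c("L", "R")) {
      mrr <- list(
        `8` = tm$t_ref,
        `12` = tm$t_ref[seq_len(n_cyc)] +
          tm$dphi[[paste("beat", sd_, sep = ".")]] * tm$periods
      )
      for (seg in c("8", "12")) {
        v <- numeric(length(tt))
        per <- if (seg == "8") c(tm$periods, tm$periods[n_cyc]) else tm$periods
        w <- duty * per
        t0 <- mrr[[seg]] - w / 4  # raised cosine: max slope one quarter in
        for (j in seq_along(t0)) {
          i1 <- max(1L, ceiling(t0[j] * fs) + 1L)
          i2 <- min(length(tt), floor((t0[j] + w[j]) * fs) + 1L)
          if (i2 < i1) next
          x <- tt[i1:i2] - t0[j]
          v[i1:i2] <- v[i1:i2] +
            amplitude * 0.5 * (1 - cos(2 * pi * x / w[j]))
        }
        if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
        traces[[paste(an, sd_, seg, sep = "_")]] <-
          data.frame(time = tt, value = v)
        marker_rows[[length(marker_rows) + 1L]] <- data.frame(
          animal = an, side = sd_, segment = seg,
          cycle = seq_along(mrr[[seg]]), t_mrr = mrr[[seg]]
        )
      }
    }
  }
  list(traces = traces, markers = do.call(rbind, marker_rows),
       cycles = st$cycles, episodes = st$episodes, fs = fs)
}

#' Generate a voltage-clamp current trace with known synaptic strengths
#'
#' Sums an alpha-function postsynaptic-current kernel over the spikes of one
#' or more presynaptic units. Each unit's kernel is scaled by its synaptic
#' conductance times the driving force, \eqn{g (V_{hold} - E_{rev})}, so the
#' peak current per spike is exactly `g * (holding - reversal)` pA (with g
#' in nS and potentials in mV). Overlapping kernels sum.
#'
#' @param spike_times numeric vector, or list of numeric vectors (one per
#'   presynaptic unit), of spike times (s).
#' @param strengths synaptic conductances in nS, one per unit; must be
#'   nonnegative.
#' @param holding,reversal holding and reversal potentials (mV); must
#'   differ. The default reversal is -62 mV.
#' @param noise_sd baseline current noise SD (pA).
#' @param fs sampling rate (Hz).
#' @param tau alpha-function time constant (s); the kernel peaks at `tau`.
#' @param t_pad trace padding before the first and after the last spike (s).
#' @param seed optional seed for the noise.
#' @return data frame with columns `time` (s) and `current` (pA); the true
#'   strengths are kept in the `strengths` attribute.
#' @export
#' @examples
#' tr <- generate_clamp_trace(1, strengths = 2, holding = -42)
#' max(tr$current)  # 40 pA = 2 nS * 20 mV
generate_clamp_trace <- function(spike_times, strengths, holding,
                                 reversal = -62, noise_sd = 0, fs = 5000,
                                 tau = 0.01, t_pad = 0.5, seed = NULL) {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  if (length(strengths) != length(spike_times)) {
    stop("need one strength per presynaptic unit")
  }
  if (any(strengths < 0)) stop("synaptic conductances must be nonnegative")
  if (holding == reversal) stop("holding potential must differ from reversal")
  if (!is.null(seed)) set.seed(seed)
  drive <- holding - reversal  # mV; nS * mV = pA
  all_t <- unlist(spike_times)
  t0 <- if (length(all_t)) max(0, min(all_t) - t_pad) else 0
  t1 <- if (length(all_t)) max(all_t) + t_pad else t_pad
  tt <- seq(t0, t1, by = 1 / fs)
  cur <- numeric(length(tt))
  klen <- ceiling(12 * tau * fs)
  kx <- seq_len(klen) / fs
  kernel <- (kx / tau) * exp(1 - kx / tau)  # unit peak at tau
  for (u in seq_along(spike_times)) {
    amp <- strengths[u] * drive
    if (amp == 0) next
    for (s in spike_times[[u]]) {
      i0 <- floor((s - t0) * fs) + 1L
      ii <- i0 + seq_len(klen)
      keep <- ii >= 1 & ii <= length(tt)
      cur[ii[keep]] <- cur[ii[keep]] + amp * kernel[keep]
    }
  }
  if (noise_sd > 0) cur <- cur + stats::rnorm(length(cur), 0, noise_sd)
  out <- data.frame(time = tt, current = cur)
  attr(out, "strengths") <- strengths
  attr(out, "driving_force") <- drive
  out
}
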