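#' Construct a spike train
#'
#' A labelled vector of spike times in seconds. Times must be strictly
#' increasing and nonnegative; spike detection itself (threshold crossing on
#' analog voltage) is upstream of this package.
#'
#' @param times numeric vector of spike times (s), strictly increasing.
#' @param id channel identifier.
#' @param side body side label ("L"/"R"), optional.
#' @param level pattern level label (e.g. "cpg", "motor"), optional.
#' @param role "reference" or "target" within an intersegmental pair,
#'   optional.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, id = "", side = NA_character_,
                        level = NA_character_, role = NA_character_) {
  if (!is.numeric(times)) stop("spike times must be numeric")
  if (anyNA(times)) stop("spike times contain NA")
  if (length(times) && any(times < 0)) stop("spike times must be nonnegative")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("spike times must be strictly increasing (channel ", id, ")")
  }
  structure(list(times = as.numeric(times), id = id, side = side,
                 level = level, role = role),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("Spike train ", x$id, ": ", length(x$times), " spikes",
      if (length(x$times)) sprintf(" spanning %.2f-%.2f s",
                                   min(x$times), max(x$times)), "\n", sep = "")
  invisible(x)
}

#' Group spikes into bursts and assign middle-spike phase markers
#'
#' Consecutive spikes separated by less than `ibi_threshold` belong to the
#' same burst; a gap of at least `ibi_threshold` (default 1 s) starts a new
#' burst. Groups with fewer than `min_spikes` spikes are discarded as stray
#' spikes. The phase marker of each burst is its middle spike by count,
#' index `ceiling(n/2)` (for an even count, the earlier of the two central
#' spikes). Burst periods are middle-spike to middle-spike intervals.
#'
#' @param x a [spike_train()] or a numeric vector of spike times.
#' @param ibi_threshold interburst interval in seconds (default 1).
#' @param min_spikes minimum spikes per burst; smaller groups are dropped
#'   (default 3).
#' @return an object of class `burst_series`: list with `channel` (the input
#'   labels), `spikes` (list of per-burst spike-time vectors), `middles`
#'   (middle-spike times), `n_spikes`, and `periods`
#'   (`diff(middles)`, empty when fewer than two bursts survive).
#' @export
#' @examples
#' b <- group_bursts(c(0, 0.1, 0.2, 2.0, 2.1, 2.2))
#' b$middles   # 0.1, 2.1
#' b$periods   # 2.0
group_bursts <- function(x, ibi_threshold = 1, min_spikes = 3) {
  tr <- if (inherits(x, "spike_train")) x else spike_train(x)
  times <- tr$times
  if (length(times) < 1) stop("need at least one spike")
  if (ibi_threshold <= 0) stop("ibi_threshold must be positive")
  grp <- cumsum(c(1, as.integer(diff(times) >= ibi_threshold)))
  spikes <- unname(split(times, grp))
  keep <- lengths(spikes) >= min_spikes
  spikes <- spikes[keep]
  if (length(spikes) == 0) {
    warning("no burst survives filtering (channel ", tr$id, ")")
  }
  middles <- vapply(spikes, function(s) s[ceiling(length(s) / 2)], 0)
  out <- list(
    channel = tr[c("id", "side", "level", "role")],
    spikes = spikes,
    middles = middles,
    n_spikes = lengths(spikes),
    periods = if (length(middles) > 1) diff(middles) else numeric(0)
  )
  class(out) <- "burst_series"
  out
}

#' @export
print.burst_series <- function(x, ...) {
  cat("Burst series ", x$channel$id, ": ", length(x$middles), " bursts, ",
      length(x$periods), " periods",
      if (length(x$periods)) sprintf(" (mean T = %.2f s)", mean(x$periods)),
      "\n", sep = "")
  invisible(x)
}

#' Phase of an event within a reference cycle
#'
#' \eqn{\phi = (t_i - t_r)/T_r} reduced modulo 1 into [0, 1): the time of an
#' event relative to the reference phase marker, as a fraction of the
#' reference cycle period.
#'
#' @param t_i event time (s).
#' @param t_r reference marker time (s).
#' @param T_r reference cycle period (s), > 0. Arguments are recycled.
#' @return phase fraction in [0, 1).
#' @export
phase_of <- function(t_i, t_r, T_r) {
  if (any(T_r <= 0)) stop("reference period must be positive")
  wrap_unit((t_i - t_r) / T_r)
}

#' Per-cycle intersegmental phase differences between two burst series
#'
#' For each reference cycle, defined as the half-open interval from one
#' reference middle spike to the next, the target middle spike falling in
#' that cycle is matched and its phase computed with [phase_of()]. Reference
#' cycles containing zero or more than one target marker are flagged and
#' skipped (NA phase).
#'
#' @param reference,target [group_bursts()] outputs; the reference needs at
#'   least two bursts and the two series must overlap in time.
#' @return a data frame of class `phase_series` with one row per reference
#'   cycle: `cycle`, `t_ref` (reference marker time), `period`, `n_target`
#'   (target markers in the cycle), `phi` (phase in [0,1)), and `dphi`
#'   (centered to (-0.5, 0.5]). Channel labels are kept as attributes
#'   `reference` and `target`.
#' @export
pair_cycles <- function(reference, target) {
  if (!inherits(reference, "burst_series") || !inherits(target, "burst_series")) {
    stop("reference and target must be burst_series objects")
  }
  mr <- reference$middles
  mt <- target$middles
  if (length(mr) < 2) stop("need at least two reference bursts")
  if (length(mt) < 1 || max(mt) < min(mr) || min(mt) > max(mr)) {
    stop("reference and target series do not overlap in time")
  }
  n_cyc <- length(mr) - 1
  # cycle k covers [mr[k], mr[k+1]); findInterval with left-closed intervals
  idx <- findInterval(mt, mr)
  idx <- idx[idx >= 1 & idx <= n_cyc]
  counts <- tabulate(idx, nbins = n_cyc)
  periods <- diff(mr)
  phi <- rep(NA_real_, n_cyc)
  one <- which(counts == 1)
  if (length(one)) {
    pos <- match(one, idx)
    phi[one] <- phase_of(mt[pos], mr[one], periods[one])
  }
  skipped <- sum(counts != 1)
  if (skipped > 0) {
    message(skipped, " of ", n_cyc,
            " reference cycles skipped (0 or >1 target markers)")
  }
  out <- data.frame(
    cycle = seq_len(n_cyc),
    t_ref = mr[seq_len(n_cyc)],
    period = periods,
    n_target = counts,
    phi = phi,
    dphi = wrap_phase(phi)
  )
  attr(out, "reference") <- reference$channel
  attr(out, "target") <- target$channel
  class(out) <- c("phase_series", class(out))
  out
}

#' Maximum-rate-of-rise phase markers from a constriction trace
#'
#' For optically recorded constriction signals the per-cycle phase marker is
#' the time of the maximum rate of rise (MRR): the maximum first difference
#' of the smoothed signal within each beat. Candidate samples are those
#' whose smoothed derivative exceeds half of the global maximum; contiguous
#' candidate stretches form one beat each, and the marker is the derivative
#' maximum of the stretch. Downstream these markers are treated exactly like
#' middle-spike markers.
#'
#' @param trace data frame with columns `time` (s, uniformly sampled) and
#'   `value`, or a numeric vector of sample values with `time` given
#'   separately.
#' @param time optional numeric vector of sample times when `trace` is a
#'   plain vector.
#' @param smoothing moving-average window in samples applied before
#'   differencing (default 5).
#' @param min_separation optional minimum separation between markers in
#'   seconds; of two closer events the one with the steeper rise is kept.
#' @return numeric vector of marker times (s); empty with a warning for a
#'   flat trace.
#' @export
mrr_phase_markers <- function(trace, time = NULL, smoothing = 5,
                              min_separation = NULL) {
  if (is.data.frame(trace)) {
    time <- trace$time
    value <- trace$value
  } else {
    value <- trace
  }
  if (is.null(time) || length(time) != length(value)) {
    stop("trace must supply matching time and value vectors")
  }
  dt <- diff(time)
  if (length(dt) < 2 || diff(range(dt)) > 1e-6 * stats::median(dt)) {
    stop("trace must be uniformly sampled")
  }
  dt <- stats::median(dt)
  if (diff(range(value)) <= .Machine$double.eps^0.5 * max(1, abs(mean(value)))) {
    warning("flat trace: no constriction events detected")
    return(numeric(0))
  }
  sm <- if (smoothing > 1) {
    as.numeric(stats::filter(value, rep(1 / smoothing, smoothing), sides = 2))
  } else value
  dv <- diff(sm) / dt
  ok <- which(!is.na(dv))
  thr <- 0.5 * max(dv[ok])
  cand <- ok[dv[ok] >= thr]
  if (length(cand) == 0) {
    warning("no rise exceeds threshold; no events detected")
    return(numeric(0))
  }
  # contiguous candidate stretches (tolerating holes up to the smoothing
  # window, which noise can punch into a single rise)
  grp <- cumsum(c(1, as.integer(diff(cand) > max(2, smoothing))))
  events <- vapply(split(cand, grp), function(ix) {
    # derivative-weighted centroid of the supra-threshold stretch: exact at
    # the steepest-rise point for symmetric rises, and it averages out the
    # sample-level jitter a bare argmax suffers where the derivative is flat
    w <- dv[ix] - thr
    if (sum(w) <= 0) {
      i <- ix[which.max(dv[ix])]
      return(time[i] + dt / 2)
    }
    sum(w * (time[ix] + dt / 2)) / sum(w)
  }, 0)
  events <- unname(sort(events))
  if (!is.null(min_separation) && length(events) > 1) {
    keep <- rep(TRUE, length(events))
    last <- 1
    for (i in 2:length(events)) {
      if (events[i] - events[last] < min_separation) {
        di <- dv[which.min(abs(time - events[i]))]
        dl <- dv[which.min(abs(time - events[last]))]
        if (di > dl) { keep[last] <- FALSE; last <- i } else keep[i] <- FALSE
      } else last <- i
    }
    events <- events[keep]
  }
  if (length(events) < 2) {
    warning("fewer than two beat cycles detected")
  }
  events
}
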