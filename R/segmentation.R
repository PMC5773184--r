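#' Segment bilateral phase series into coordination episodes
#'
#' Labels every cycle of a bilateral pair of phase series as left- or
#' right-peristaltic (the other side being synchronous), accepts label
#' changes only when sustained, and returns the resulting episodes. The two
#' sides switch simultaneously, so classification is joint: per cycle the
#' side whose rear segment leads the front by more (the larger signed
#' centered phase difference) is peristaltic. When an absolute `threshold` is supplied,
#' each accepted episode is additionally checked against it: the peristaltic
#' side must exceed the threshold and the synchronous side must not, and a
#' sustained violation raises an ambiguity error.
#'
#' Label changes are debounced: a change of the per-cycle label is accepted
#' only if it persists for at least `hysteresis` cycles, so single-cycle
#' excursions never produce a switch. Cycles within `exclude` cycles of an
#' accepted switch are marked transitional and are excluded from episode
#' statistics downstream.
#'
#' @param left,right [pair_cycles()] outputs for the two sides (same
#'   reference segment, same cycle range).
#' @param threshold optional absolute phase-difference threshold (cycle
#'   fraction) separating peristaltic from synchronous; `NULL` (default)
#'   uses only the relative left/right comparison, which is robust to
#'   animal-level offsets.
#' @param hysteresis minimum run length (cycles) for a label change to be
#'   accepted; default 3.
#' @param exclude half-width in cycles of the transitional window around
#'   each switch; defaults to `hysteresis`.
#' @param aux optional list of further `list(left = , right = )` pairs of
#'   phase series from other levels of the same animal. Because all levels
#'   switch coordination simultaneously, their left/right evidence is
#'   pooled into the per-cycle score, which makes the segmentation robust
#'   when one level's coordinations are close together.
#' @return an object of class `episode_set`: list with `cycles` (per-cycle
#'   data frame: `cycle`, `left`, `right`, `transitional`), `episodes`
#'   (side, episode, coordination, first/last cycle, cycle counts), and the
#'   parameters used.
#' @export
classify_episodes <- function(left, right, threshold = NULL, hysteresis = 3,
                              exclude = hysteresis, aux = NULL) {
  if (!inherits(left, "phase_series") || !inherits(right, "phase_series")) {
    stop("left and right must be phase_series objects")
  }
  cyc <- intersect(left$cycle, right$cycle)
  if (length(cyc) < 2) stop("the two sides' series must cover the same cycles")
  cyc <- sort(cyc)
  dl <- left$dphi[match(cyc, left$cycle)]
  dr <- right$dphi[match(cyc, right$cycle)]
  # fill skipped cycles by carrying the last observed value (then the next,
  # for a leading gap); the labels of filled cycles are still debounced
  fill <- function(x) {
    if (anyNA(x)) {
      ok <- which(!is.na(x))
      if (length(ok) == 0) stop("no matched cycles on one side")
      x <- stats::approx(ok, x[ok], xout = seq_along(x), method = "constant",
                         rule = 2)$y
    }
    x
  }
  dlf <- fill(dl)
  drf <- fill(dr)
  # the peristaltic state is a signed rear-to-front lead, the synchronous
  # state is near zero: per cycle, the side with the larger signed centered
  # phase difference is the peristaltic one
  score <- dlf - drf
  if (!is.null(aux)) {
    for (pair in aux) {
      al <- fill(pair$left$dphi[match(cyc, pair$left$cycle)])
      ar <- fill(pair$right$dphi[match(cyc, pair$right$cycle)])
      score <- score + al - ar
    }
  }
  # The score alternates between two states (left-peristaltic vs
  # right-peristaltic). Cluster it into two groups (deterministic extreme
  # initialization); the higher-score cluster is left-peristaltic. This is
  # robust to animal-level offsets that keep the score on one side of zero.
  n <- length(score)
  if (stats::sd(score) < 1e-12) {
    raw <- rep(score[1] > 0, n)
  } else {
    km <- suppressWarnings(stats::kmeans(
      score, centers = matrix(c(min(score), max(score)), 2, 1)))
    raw <- km$cluster == which.max(km$centers[, 1])
  }

  # debounce: accept a change only when sustained >= hysteresis cycles;
  # the starting label is that of the first sustained run, so a short
  # excursion at the very beginning cannot seed a spurious first episode
  n <- length(raw)
  acc <- logical(n)
  r <- rle(raw)
  sustained <- which(r$lengths >= hysteresis)
  cur <- if (length(sustained)) r$values[sustained[1]] else raw[1]
  i <- 1
  while (i <= n) {
    if (raw[i] == cur) {
      acc[i] <- cur
      i <- i + 1
    } else {
      run_end <- i
      while (run_end < n && raw[run_end + 1] != cur) run_end <- run_end + 1
      if (run_end - i + 1 >= hysteresis) cur <- raw[i]
      acc[i:run_end] <- cur
      i <- run_end + 1
    }
  }

  # validate the segmentation: genuine alternation means the contiguous
  # episodes explain most of the score variance; clustering artifacts on a
  # single-state recording (no switch) do not, and collapse to one episode
  if (any(diff(acc) != 0)) {
    ep_tmp <- cumsum(c(1L, as.integer(diff(acc) != 0)))
    ss_tot <- sum((score - mean(score))^2)
    ss_within <- sum(unlist(lapply(split(score, ep_tmp), function(s)
      (s - mean(s))^2)))
    r2 <- if (ss_tot > 0) 1 - ss_within / ss_tot else 0
    if (r2 < 0.4) acc <- rep(mean(score) > 0, n)
  }

  switches <- which(diff(acc) != 0) + 1  # first cycle of each new episode
  transitional <- rep(FALSE, n)
  for (s in switches) {
    win <- max(1, s - exclude):min(n, s + exclude - 1)
    transitional[win] <- TRUE
  }

  left_lab <- ifelse(acc, "peristaltic", "synchronous")
  right_lab <- ifelse(acc, "synchronous", "peristaltic")

  if (!is.null(threshold)) {
    peri_abs <- ifelse(acc, abs(dlf), abs(drf))
    sync_abs <- ifelse(acc, abs(drf), abs(dlf))
    bad <- (peri_abs <= threshold & sync_abs <= threshold) |
      (peri_abs > threshold & sync_abs > threshold)
    bad[transitional] <- FALSE
    r <- rle(bad)
    if (any(r$values & r$lengths >= hysteresis)) {
      ends <- cumsum(r$lengths)
      i1 <- ends[which(r$values & r$lengths >= hysteresis)[1]] -
        r$lengths[which(r$values & r$lengths >= hysteresis)[1]] + 1
      stop("ambiguous coordination: both sides on the same side of the ",
           "threshold (", threshold, ") for >= ", hysteresis,
           " cycles starting at cycle ", cyc[i1],
           " (|dphi| left ", format(abs(dlf[i1]), digits = 3), ", right ",
           format(abs(drf[i1]), digits = 3), ")")
    }
  }

  ep_id <- cumsum(c(1L, as.integer(diff(acc) != 0)))
  episodes <- do.call(rbind, lapply(split(seq_len(n), ep_id), function(ix) {
    data.frame(
      episode = ep_id[ix[1]],
      first_cycle = cyc[ix[1]], last_cycle = cyc[ix[length(ix)]],
      n_cycles = length(ix),
      n_usable = sum(!transitional[ix] & !is.na(dl[ix]) & !is.na(dr[ix])),
      coordination_left = left_lab[ix[1]],
      coordination_right = right_lab[ix[1]]
    )
  }))
  rownames(episodes) <- NULL
  out <- list(
    cycles = data.frame(cycle = cyc, episode = ep_id, left = left_lab,
                        right = right_lab, transitional = transitional,
                        dphi_left = dl, dphi_right = dr),
    episodes = episodes,
    threshold = threshold, hysteresis = hysteresis, exclude = exclude
  )
  class(out) <- "episode_set"
  out
}

#' @export
print.episode_set <- function(x, ...) {
  cat("Episode set:", nrow(x$episodes), "episodes over",
      nrow(x$cycles), "cycles;",
      sum(x$cycles$transitional), "transitional cycles\n")
  print(x$episodes)
  invisible(x)
}

#' Assemble switch cycles from an episode sequence
#'
#' A switch cycle is one complete pass of a body side through both
#' coordination states. Episodes are paired consecutively and without
#' overlap starting from the first complete episode, so a side with three
#' episodes yields one complete switch cycle and one flagged remainder, and
#' five switches (six delimited episodes, four of them complete between
#' switches) yield two complete switch cycles.
#'
#' @param episodes an `episode_set` from [classify_episodes()], or a data
#'   frame with columns `episode` and `coordination_left`/
#'   `coordination_right` (one row per episode, in time order).
#' @param side which side's switch cycles to build ("L" or "R"); with the
#'   default `"both"`, rows for both sides are returned.
#' @return data frame with one row per (side, switch cycle): `side`,
#'   `switch_cycle`, `episode_first`, `episode_second`, `coordination_first`,
#'   `coordination_second`, `complete`. An unpaired trailing episode appears
#'   with `complete = FALSE`. Fewer than two episodes give an empty data
#'   frame with a warning.
#' @export
build_switch_cycles <- function(episodes, side = "both") {
  ep <- if (inherits(episodes, "episode_set")) episodes$episodes else episodes
  sides <- if (identical(side, "both")) c("L", "R") else side
  rows <- list()
  for (sd_ in sides) {
    lab <- if (sd_ == "L") ep$coordination_left else ep$coordination_right
    n_ep <- nrow(ep)
    if (n_ep < 2) {
      warning("fewer than two episodes on side ", sd_,
              ": no complete switch cycle")
      next
    }
    starts <- seq(1, n_ep, by = 2)
    for (k in seq_along(starts)) {
      i <- starts[k]
      complete <- i + 1 <= n_ep
      rows[[length(rows) + 1L]] <- data.frame(
        side = sd_, switch_cycle = k,
        episode_first = ep$episode[i],
        episode_second = if (complete) ep$episode[i + 1] else NA_integer_,
        coordination_first = lab[i],
        coordination_second = if (complete) lab[i + 1] else NA_character_,
        complete = complete
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(side = character(), switch_cycle = integer(),
                      episode_first = integer(), episode_second = integer(),
                      coordination_first = character(),
                      coordination_second = character(),
                      complete = logical()))
  }
  do.call(rbind, rows)
}
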