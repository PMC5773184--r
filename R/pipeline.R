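# End-to-end pipeline: recordings -> phase series -> episodes -> variance
# decomposition and resampling inference, plus the run-directory plumbing.

# deterministic substream seed from a root seed and a stage tag
.substream <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Default analysis parameters
#'
#' @param ibi_threshold interburst interval (s) for [group_bursts()].
#' @param min_spikes stray-spike rule for [group_bursts()].
#' @param threshold absolute classification threshold for
#'   [classify_episodes()], or `NULL` for the relative rule.
#' @param hysteresis,exclude episode debouncing and transitional-window
#'   parameters (cycles).
#' @param min_cycles minimum usable cycles per episode.
#' @param n_boot,ci bootstrap settings for [population_variance()].
#' @param n_scramble scrambling iterations for the repetition and bilateral
#'   tests.
#' @param boot_method bootstrap CI method.
#' @param scramble_scheme scrambling pairing scheme.
#' @param screen_outliers if `TRUE` (default), animals flagged by
#'   [outlier_screen()] within a population stratum are excluded from that
#'   stratum, with a logged justification; flags are always reported.
#'   A stray badly segmented recording otherwise dominates the across-animal
#'   variances.
#' @param seed root seed; every resampling stage derives its own substream
#'   from it, so any single table can be reproduced in isolation.
#' @return list of parameters for [analyze_recordings()].
#' @export
analysis_params <- function(ibi_threshold = 1, min_spikes = 3,
                            threshold = NULL, hysteresis = 3,
                            exclude = hysteresis, min_cycles = 7,
                            n_boot = 10000, ci = 0.95, n_scramble = 10000,
                            boot_method = "studentized",
                            scramble_scheme = "derangement",
                            screen_outliers = TRUE, seed = 1L) {
  list(ibi_threshold = ibi_threshold, min_spikes = min_spikes,
       threshold = threshold, hysteresis = hysteresis, exclude = exclude,
       min_cycles = min_cycles, n_boot = n_boot, ci = ci,
       n_scramble = n_scramble, boot_method = boot_method,
       scramble_scheme = scramble_scheme, screen_outliers = screen_outliers,
       seed = as.integer(seed))
}

# summarize one animal: burst grouping, cycle pairing, episode
# classification, per-stratum means and cycle variances
.summarize_animal <- function(animal, trains, params) {
  levels_here <- sort(unique(vapply(trains, function(tr) tr$level, "")))
  strata <- list()
  episodes <- list()
  cycles <- list()
  log <- character(0)
  find_train <- function(lv, sd_, role) {
    for (tr in trains) {
      if (identical(tr$level, lv) && identical(tr$side, sd_) &&
          identical(tr$role, role)) return(tr)
    }
    NULL
  }
  # per-cycle phase series for every level and side
  ps <- list()
  for (lv in levels_here) {
    for (sd_ in c("L", "R")) {
      ref <- find_train(lv, sd_, "reference")
      tgt <- find_train(lv, sd_, "target")
      if (is.null(ref) || is.null(tgt)) {
        log <- c(log, paste0(animal, "/", lv, "/", sd_,
                             ": missing reference or target channel"))
        next
      }
      bs_ref <- group_bursts(ref, params$ibi_threshold, params$min_spikes)
      bs_tgt <- group_bursts(tgt, params$ibi_threshold, params$min_spikes)
      ps[[paste(lv, sd_, sep = ".")]] <-
        suppressMessages(pair_cycles(bs_ref, bs_tgt))
    }
  }
  ok_levels <- levels_here[vapply(levels_here, function(lv)
    all(paste(lv, c("L", "R"), sep = ".") %in% names(ps)), TRUE)]
  if (length(ok_levels) == 0) {
    return(list(strata = NULL, episodes = NULL, cycles = NULL, log = log))
  }
  # all levels switch simultaneously: classify once, pooling the bilateral
  # evidence of every level, then share the episode boundaries
  prim <- ok_levels[1]
  aux <- lapply(setdiff(ok_levels, prim), function(lv)
    list(left = ps[[paste(lv, "L", sep = ".")]],
         right = ps[[paste(lv, "R", sep = ".")]]))
  es <- tryCatch(
    classify_episodes(ps[[paste(prim, "L", sep = ".")]],
                      ps[[paste(prim, "R", sep = ".")]],
                      threshold = params$threshold,
                      hysteresis = params$hysteresis,
                      exclude = params$exclude,
                      aux = if (length(aux)) aux else NULL),
    error = function(e) {
      log <<- c(log, paste0(animal, ": ", conditionMessage(e)))
      NULL
    })
  if (is.null(es)) {
    return(list(strata = NULL, episodes = NULL, cycles = NULL, log = log))
  }
  sw <- suppressWarnings(build_switch_cycles(es))
  if (nrow(sw) == 0) {
    log <- c(log, paste0(animal, ": fewer than 2 episodes"))
    return(list(strata = NULL, episodes = NULL, cycles = NULL, log = log))
  }
  episodes[[1]] <- cbind(animal = animal, es$episodes)
  for (lv in ok_levels) {
    cyc <- es$cycles
    cyc$dphi_left <- ps[[paste(lv, "L", sep = ".")]]$dphi[
      match(cyc$cycle, ps[[paste(lv, "L", sep = ".")]]$cycle)]
    cyc$dphi_right <- ps[[paste(lv, "R", sep = ".")]]$dphi[
      match(cyc$cycle, ps[[paste(lv, "R", sep = ".")]]$cycle)]
    cycles[[lv]] <- cbind(animal = animal, level = lv, cyc)
    for (i in seq_len(nrow(sw))) {
      if (lv == prim && !sw$complete[i] && is.na(sw$episode_second[i])) {
        log <- c(log, paste0(animal, "/", sw$side[i],
                             ": incomplete trailing switch cycle flagged"))
      }
      eps_here <- c(sw$episode_first[i], sw$episode_second[i])
      coords <- c(sw$coordination_first[i], sw$coordination_second[i])
      for (j in seq_along(eps_here)) {
        if (is.na(eps_here[j])) next
        sd_ <- sw$side[i]
        sel <- cyc$episode == eps_here[j] & !cyc$transitional
        d <- if (sd_ == "L") cyc$dphi_left[sel] else cyc$dphi_right[sel]
        d <- d[!is.na(d)]
        if (length(d) < params$min_cycles) {
          log <- c(log, paste0(animal, "/", lv, "/", sd_, "/", coords[j],
                               "/sc", sw$switch_cycle[i], ": only ",
                               length(d), " usable cycles; stratum dropped"))
          next
        }
        strata[[length(strata) + 1L]] <- data.frame(
          animal = animal, side = sd_, level = lv,
          coordination = coords[j], switch_cycle = sw$switch_cycle[i],
          mean_dphi = wrap_phase(circular_summary(d)$mean_phase),
          s2_cycle = angular_variance(d), n_cycles = length(d)
        )
      }
    }
  }
  list(strata = if (length(strata)) do.call(rbind, strata) else NULL,
       episodes = if (length(episodes)) do.call(rbind, episodes) else NULL,
       cycles = if (length(cycles)) do.call(rbind, cycles) else NULL,
       log = log)
}

#' Analyze a set of bilateral recordings in memory
#'
#' Runs the full analysis on a list of per-animal channel sets (as produced
#' by [generate_population()], or assembled from files by [run_pipeline()]):
#' burst grouping, per-cycle phase differences, episode segmentation and
#' switch cycles, per-stratum circular summaries, population variances with
#' bootstrap CIs, repetition and bilateral scrambling tests, the
#' method-of-moments variance-component decomposition, and level
#' comparisons.
#'
#' @param recordings list of animals; each a list with `animal` (id) and
#'   `trains` (list of [spike_train()] objects labelled with side, level,
#'   and reference/target role).
#' @param params an [analysis_params()] list.
#' @return list of tidy result tables: `strata`, `episodes`, `cycles`,
#'   `population`, `repetition`, `bilateral`, `components`, `comparisons`,
#'   `ddphi_magnitude`, `outliers`, plus `exclusions` (log of every dropped
#'   animal/stratum with reason) and the `params` used.
#' @export
analyze_recordings <- function(recordings, params = analysis_params()) {
  strata <- list(); episodes <- list(); cycles <- list(); log <- character(0)
  for (rec in recordings) {
    res <- .summarize_animal(rec$animal, rec$trains, params)
    if (!is.null(res$strata)) strata[[length(strata) + 1L]] <- res$strata
    if (!is.null(res$episodes)) episodes[[length(episodes) + 1L]] <- res$episodes
    if (!is.null(res$cycles)) cycles[[length(cycles) + 1L]] <- res$cycles
    log <- c(log, res$log)
  }
  if (length(strata) == 0) stop("no analyzable strata in these recordings")
  strata <- do.call(rbind, strata)
  rownames(strata) <- NULL

  # outlier screening per population stratum (linearized about the
  # circular mean); always reported, exclusion is opt-in
  outliers <- list()
  key_of <- function(s) paste(s$level, s$coordination, s$side,
                              s$switch_cycle, sep = "/")
  for (k in sort(unique(key_of(strata)))) {
    sel <- key_of(strata) == k
    if (sum(sel) < 4) next
    m <- strata$mean_dphi[sel]
    lin <- wrap_phase(m - circular_summary(m)$mean_phase)
    fl <- outlier_screen(lin)
    if (any(fl)) {
      outliers[[length(outliers) + 1L]] <- data.frame(
        stratum = k, animal = strata$animal[sel][fl],
        mean_dphi = m[fl])
    }
  }
  outliers <- if (length(outliers)) do.call(rbind, outliers) else
    data.frame(stratum = character(), animal = character(),
               mean_dphi = numeric())
  if (isTRUE(params$screen_outliers) && nrow(outliers) > 0) {
    drop <- paste(key_of(strata), strata$animal) %in%
      paste(outliers$stratum, outliers$animal)
    log <- c(log, paste0("outlier excluded: ", outliers$stratum, " ",
                         outliers$animal))
    strata <- strata[!drop, ]
  }

  lvls <- sort(unique(strata$level))
  coords <- sort(unique(strata$coordination))

  pop_rows <- list(); rep_rows <- list(); bil_rows <- list()
  mag_rows <- list()
  for (lv in lvls) for (co in coords) {
    sub <- strata[strata$level == lv & strata$coordination == co, ]
    for (sd_ in sort(unique(sub$side))) for (k in sort(unique(sub$switch_cycle))) {
      m <- sub$mean_dphi[sub$side == sd_ & sub$switch_cycle == k]
      if (length(m) < 3) next
      pv <- population_variance(
        m, n_boot = params$n_boot, ci = params$ci,
        seed = .substream(params$seed, paste("boot", lv, co, sd_, k)),
        method = params$boot_method)
      pop_rows[[length(pop_rows) + 1L]] <- data.frame(
        level = lv, coordination = co, side = sd_, switch_cycle = k,
        n = pv$n, mean_dphi = pv$mean_dphi, s2 = pv$s2,
        ci_lo = pv$ci_lo, ci_hi = pv$ci_hi)
    }
    # repetition: switch cycle 1 vs 2 per side
    for (sd_ in sort(unique(sub$side))) {
      s1 <- sub[sub$side == sd_ & sub$switch_cycle == 1, ]
      s2 <- sub[sub$side == sd_ & sub$switch_cycle == 2, ]
      common <- intersect(s1$animal, s2$animal)
      if (length(common) < 5) next
      rt <- repetition_test(
        s1$mean_dphi[match(common, s1$animal)],
        s2$mean_dphi[match(common, s2$animal)],
        n_scramble = params$n_scramble,
        seed = .substream(params$seed, paste("rep", lv, co, sd_)),
        scheme = params$scramble_scheme)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        level = lv, coordination = co, side = sd_, n = rt$n,
        observed = rt$observed, null_mean = rt$null_mean, z = rt$z,
        p = rt$p, p_two_sided = rt$p_two_sided)
      mag_rows[[length(mag_rows) + 1L]] <- data.frame(
        level = lv, coordination = co, comparison = "repetition", side = sd_,
        mean_abs_ddphi = abs_ddphi_summary(circular_mean_difference(
          s1$mean_dphi[match(common, s1$animal)],
          s2$mean_dphi[match(common, s2$animal)])))
    }
    # bilateral: left vs right within switch cycle 1
    sL <- sub[sub$side == "L" & sub$switch_cycle == 1, ]
    sR <- sub[sub$side == "R" & sub$switch_cycle == 1, ]
    common <- intersect(sL$animal, sR$animal)
    if (length(common) >= 5) {
      bt <- bilateral_test(
        sL$mean_dphi[match(common, sL$animal)],
        sR$mean_dphi[match(common, sR$animal)],
        n_scramble = params$n_scramble,
        seed = .substream(params$seed, paste("bil", lv, co)),
        scheme = params$scramble_scheme)
      bil_rows[[length(bil_rows) + 1L]] <- data.frame(
        level = lv, coordination = co, n = bt$n,
        observed = bt$observed, null_mean = bt$null_mean, z = bt$z,
        p = bt$p, p_two_sided = bt$p_two_sided)
      mag_rows[[length(mag_rows) + 1L]] <- data.frame(
        level = lv, coordination = co, comparison = "bilateral", side = "LR",
        mean_abs_ddphi = abs_ddphi_summary(circular_mean_difference(
          sL$mean_dphi[match(common, sL$animal)],
          sR$mean_dphi[match(common, sR$animal)])))
    }
  }

  # level comparison (cpg vs motor), paired within animal where possible
  cmp_rows <- list()
  if (all(c("cpg", "motor") %in% lvls)) {
    for (co in coords) {
      a <- strata[strata$level == "cpg" & strata$coordination == co &
                    strata$side == "L" & strata$switch_cycle == 1, ]
      b <- strata[strata$level == "motor" & strata$coordination == co &
                    strata$side == "L" & strata$switch_cycle == 1, ]
      common <- intersect(a$animal, b$animal)
      if (length(common) < 2) next
      lc <- compare_levels(a$mean_dphi[match(common, a$animal)],
                           b$mean_dphi[match(common, b$animal)],
                           paired = TRUE)
      cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
        coordination = co, level_a = "cpg", level_b = "motor",
        n = length(common), mean_a = lc$mean_a, mean_b = lc$mean_b,
        t = lc$statistic, df = lc$df, p = lc$p.value)
    }
  }

  list(
    strata = strata,
    episodes = do.call(rbind, episodes),
    cycles = do.call(rbind, cycles),
    population = if (length(pop_rows)) do.call(rbind, pop_rows) else NULL,
    repetition = if (length(rep_rows)) do.call(rbind, rep_rows) else NULL,
    bilateral = if (length(bil_rows)) do.call(rbind, bil_rows) else NULL,
    components = estimate_variance_components(strata),
    comparisons = if (length(cmp_rows)) do.call(rbind, cmp_rows) else NULL,
    ddphi_magnitude = if (length(mag_rows)) do.call(rbind, mag_rows) else NULL,
    outliers = outliers,
    exclusions = log,
    params = params
  )
}

#' Write a synthetic run directory
#'
#' Generates a population from a [generator_config()] and writes it in the
#' package's delimited formats: one spike table per channel, a channel map,
#' the ground-truth tables, and the generator configuration as a YAML
#' sidecar. The directory is named by the seed unless given explicitly.
#'
#' @param config a [generator_config()].
#' @param dir output directory; default `run_seed<seed>` under `base_dir`.
#' @param base_dir parent directory for the default `dir`.
#' @return the run directory path, invisibly.
#' @export
simulate_run <- function(config, dir = NULL, base_dir = ".") {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(dir)) {
    dir <- file.path(base_dir, sprintf("run_seed%d", config$seed))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pop <- generate_population(config)
  map_rows <- list()
  for (rec in pop$recordings) {
    for (tr in rec$trains) {
      fn <- paste0(tr$id, ".tsv")
      write_spike_table(data.frame(channel = tr$id, time = tr$times),
                        file.path(dir, fn))
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        file = fn, channel = tr$id, animal = rec$animal, side = tr$side,
        level = tr$level, role = tr$role)
    }
  }
  write_report(do.call(rbind, map_rows), file.path(dir, "channel_map.tsv"))
  write_report(pop$truth$cycles, file.path(dir, "truth_cycles.tsv"))
  write_report(pop$truth$episodes, file.path(dir, "truth_episodes.tsv"))
  write_report(pop$truth$strata, file.path(dir, "truth_strata.tsv"))
  yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Run the full analysis pipeline on a run directory
#'
#' Reads every channel listed in `channel_map.tsv` under `input_dir`,
#' assembles the per-animal recordings, runs [analyze_recordings()], and
#' writes the tidy report tables plus a machine-readable manifest (seeds,
#' parameters, exclusions) to `output_dir`. Two runs with the same config
#' and seed produce byte-identical reports.
#'
#' @param config a list with `input_dir`, `output_dir`, and optionally any
#'   [analysis_params()] entries under `params`; or the path to a YAML file
#'   with the same structure.
#' @return the [analyze_recordings()] result list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$input_dir) || is.null(config$output_dir)) {
    stop("config must name input_dir and output_dir")
  }
  params <- do.call(analysis_params,
                    if (is.null(config$params)) list() else config$params)
  map_path <- file.path(config$input_dir, "channel_map.tsv")
  if (!file.exists(map_path)) stop("no channel_map.tsv in ", config$input_dir)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  need <- c("file", "channel", "animal", "side", "level", "role")
  if (!all(need %in% names(map))) {
    stop("channel_map.tsv must have columns: ", paste(need, collapse = ", "))
  }
  recordings <- list()
  for (an in unique(map$animal)) {
    rows <- map[map$animal == an, ]
    trains <- list()
    for (i in seq_len(nrow(rows))) {
      fp <- file.path(config$input_dir, rows$file[i])
      if (!file.exists(fp)) {
        stop("missing channel '", rows$channel[i], "': file ", rows$file[i],
             " not found in ", config$input_dir)
      }
      tab <- read_spike_table(fp)
      tab <- tab[tab$channel == rows$channel[i], ]
      trains[[rows$channel[i]]] <- spike_train(
        tab$time, id = rows$channel[i], side = rows$side[i],
        level = rows$level[i], role = rows$role[i])
    }
    recordings[[length(recordings) + 1L]] <- list(animal = an, trains = trains)
  }
  res <- analyze_recordings(recordings, params)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- c("strata", "episodes", "cycles", "population", "repetition",
            "bilateral", "components", "comparisons", "ddphi_magnitude",
            "outliers")
  for (nm in outs) {
    if (!is.null(res[[nm]])) {
      write_report(res[[nm]], file.path(config$output_dir,
                                        paste0(nm, ".tsv")))
    }
  }
  manifest <- list(
    package = "phasevar",
    version = as.character(utils::packageVersion("phasevar")),
    params = params,
    n_animals = length(recordings),
    exclusions = res$exclusions
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
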