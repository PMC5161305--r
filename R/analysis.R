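#' Centered moving average
#'
#' Centered arithmetic mean over the samples available within the window;
#' edges use truncated windows; missing samples (`NA`) are ignored.
#'
#' @param x Numeric vector sampled at 1-second spacing (may contain `NA`).
#' @param window Window width in samples (seconds), default 100.
#' @return Numeric vector of the same length (`NA` where no sample falls in
#'   the window).
#' @export
moving_average <- function(x, window = 100L) {
  stopifnot(window >= 1L)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (window == 1L) return(x)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  vals <- ifelse(is.na(x), 0, x)
  has <- as.numeric(!is.na(x))
  cs_v <- c(0, cumsum(vals))
  cs_n <- c(0, cumsum(has))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  cnt <- cs_n[hi + 1L] - cs_n[lo]
  out <- (cs_v[hi + 1L] - cs_v[lo]) / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Trigger-distance time series
#'
#' The per-second mean distance from the central vein of that second's
#' death trigger events, pooled over trials, with a 100-second centered
#' moving average to damp the considerable step-to-step variability.
#'
#' @param result An [run_bolus_experiment()] result (or a data frame with
#'   `time`, `dist_sum`, `n`, as in its `trigger_series`).
#' @param window Smoothing window in seconds.
#' @return Data frame of class `trigger_distance_series`: `time`,
#'   `mean_distance_cv` (raw per-second mean, `NA` when no events), `n`
#'   (events that second), `smoothed`.
#' @export
trigger_distance_series <- function(result, window = 100L) {
  ts <- if (inherits(result, "experiment_result")) {
    result$trigger_series
  } else result
  agg_sum <- tapply(ts$dist_sum, ts$time, sum)
  agg_n <- tapply(ts$n, ts$time, sum)
  time <- as.integer(names(agg_sum))
  o <- order(time)
  time <- time[o]
  s <- as.numeric(agg_sum)[o]
  n <- as.numeric(agg_n)[o]
  raw <- ifelse(n > 0, s / n, NA_real_)
  out <- data.frame(time = time, mean_distance_cv = raw, n = n,
                    smoothed = moving_average(raw, window))
  class(out) <- c("trigger_distance_series", "data.frame")
  out
}

#' Target Phenomenon check
#'
#' The target phenomenon is pericentral necrosis: death trigger events
#' settle adjacent to the central vein and stay there. The check passes
#' when, after a settling period, the smoothed mean trigger distance lies
#' within the zone-3 distance band (distance from the CV no larger than the
#' mean zone-3 path length) for at least `occupancy` of the remaining
#' event-bearing time points.
#'
#' @param series A [trigger_distance_series()] (or an `experiment_result`,
#'   from which one is computed).
#' @param zone3_band Zone-3 distance band in grid spaces; defaults to the
#'   result's mean zone-3 segment length.
#' @param settle_after Settling time in seconds (default 1200).
#' @param occupancy Required fraction of in-band event-bearing points.
#' @return Object of class `phenomenon_verdict`: `achieved`,
#'   `band_occupancy`, `first_settlement` (first time the smoothed series
#'   enters the band after settling), `n_points`, `zone3_band`.
#' @export
target_phenomenon_check <- function(series, zone3_band = NULL,
                                    settle_after = 1200,
                                    occupancy = 0.95) {
  if (inherits(series, "experiment_result")) {
    if (is.null(zone3_band)) zone3_band <- series$zone3_mean_length
    series <- trigger_distance_series(series)
  }
  if (is.null(zone3_band)) {
    stop("zone3_band must be supplied when passing a bare series",
         call. = FALSE)
  }
  late <- series[series$time >= settle_after & series$n > 0 &
                   !is.na(series$smoothed), , drop = FALSE]
  if (nrow(late) == 0L) {
    return(structure(list(achieved = NA, band_occupancy = NA_real_,
                          first_settlement = NA_real_, n_points = 0L,
                          zone3_band = zone3_band,
                          status = "undetermined: no events after settling"),
                     class = "phenomenon_verdict"))
  }
  inband <- late$smoothed <= zone3_band
  frac <- mean(inband)
  structure(list(achieved = frac >= occupancy, band_occupancy = frac,
                 first_settlement = if (any(inband)) {
                   late$time[which(inband)[1]]
                 } else NA_real_,
                 n_points = nrow(late), zone3_band = zone3_band,
                 status = "ok"),
            class = "phenomenon_verdict")
}

#' @export
print.phenomenon_verdict <- function(x, ...) {
  cat(sprintf(
    "<phenomenon_verdict> achieved: %s (%.1f%% of %d points within %.1f grid spaces of CV)\n",
    x$achieved, 100 * x$band_occupancy, x$n_points, x$zone3_band))
  invisible(x)
}

#' NAPQI dose fraction
#'
#' Cumulative NAPQI created, as a fraction of the administered dose,
#' pooled over the trials of a bolus experiment.
#'
#' @param result An [run_bolus_experiment()] result.
#' @return A number in `[0, 1]`.
#' @export
napqi_dose_fraction <- function(result) {
  if (result$summary$dose_objects == 0) {
    stop("NAPQI dose fraction is undefined for a zero dose", call. = FALSE)
  }
  result$summary$cum_napqi / result$summary$dose_objects
}

#' Per-zone death counts and death-time histograms
#'
#' @param death_log Death log (one row per triggered cell).
#' @param horizon Count deaths with `death_time` up to this time (seconds).
#' @param bin_width Histogram bin width in seconds.
#' @return List of class `zone_death_histogram`: `per_zone` (named counts),
#'   `total`, and `histogram` (data frame `bin_start`, `zone`, `deaths`).
#' @export
zone_death_histogram <- function(death_log, horizon = 86400L,
                                 bin_width = 60L) {
  dl <- death_log[!is.na(death_log$death_time) &
                    death_log$death_time <= horizon, , drop = FALSE]
  per_zone <- vapply(1:3, function(z) sum(dl$zone == z), numeric(1))
  names(per_zone) <- paste0("zone", 1:3)
  hist <- if (nrow(dl)) {
    b <- floor(dl$death_time / bin_width) * bin_width
    agg <- stats::aggregate(list(deaths = rep(1L, nrow(dl))),
                            by = list(bin_start = b, zone = dl$zone), sum)
    agg[order(agg$bin_start, agg$zone), , drop = FALSE]
  } else {
    data.frame(bin_start = numeric(0), zone = integer(0),
               deaths = integer(0))
  }
  structure(list(per_zone = per_zone, total = sum(per_zone),
                 histogram = hist),
            class = "zone_death_histogram")
}

#' Load the default death-curve acceptance band
#'
#' The band is an editable expert-estimate envelope (shipped as
#' `extdata/death_curve_band_synthetic.csv`, a synthetic stand-in encoding
#' the two anchors: necrosis is undetectable during the first hour, and
#' there is no appreciable further necrosis 12 hours after dosing).
#'
#' @return Data frame `time_h`, `lower`, `upper` (fractions of final
#'   deaths).
#' @export
default_death_band <- function() {
  utils::read.csv(system.file("extdata", "death_curve_band_synthetic.csv",
                              package = "vlobule"))
}

#' Death-curve band check
#'
#' Compares the cumulative death curve (as a fraction of final deaths)
#' pointwise against a lower/upper band, and checks the two anchor
#' properties: no deaths before one hour, and a plateau after 12 hours
#' (at most `plateau_tol` of final deaths accrue later).
#'
#' @param death_log Death log of a bolus experiment.
#' @param band Band data frame (`time_h`, `lower`, `upper`); default
#'   [default_death_band()].
#' @param horizon Horizon in seconds.
#' @param plateau_tol Maximum fraction of final deaths after 12 h.
#' @return List of class `death_band_check`: `pass`, `first_violation`
#'   (time in hours or `NA`), `no_deaths_first_hour`, `plateau_after_12h`,
#'   `curve` (data frame `time_h`, `fraction`).
#' @export
death_curve_band_check <- function(death_log, band = default_death_band(),
                                   horizon = 86400L, plateau_tol = 0.1) {
  dl <- death_log[!is.na(death_log$death_time) &
                    death_log$death_time <= horizon, , drop = FALSE]
  n <- nrow(dl)
  grid_h <- seq(0, horizon / 3600, by = 0.1)
  frac <- if (n > 0) {
    vapply(grid_h, function(h) mean(dl$death_time <= h * 3600), numeric(1))
  } else rep(0, length(grid_h))
  lower <- stats::approx(band$time_h, band$lower, grid_h, rule = 2)$y
  upper <- stats::approx(band$time_h, band$upper, grid_h, rule = 2)$y
  viol <- which(frac < lower - 1e-9 | frac > upper + 1e-9)
  no_first_hour <- n == 0 || min(dl$death_time) >= 3600
  plateau <- n == 0 || mean(dl$death_time > 12 * 3600) <= plateau_tol
  structure(list(pass = (length(viol) == 0L) && no_first_hour && plateau &&
                   n > 0,
                 nonzero_toxicity = n > 0,
                 first_violation = if (length(viol)) grid_h[viol[1]] else
                   NA_real_,
                 no_deaths_first_hour = no_first_hour,
                 plateau_after_12h = plateau,
                 curve = data.frame(time_h = grid_h, fraction = frac)),
            class = "death_band_check")
}

#' Deterministic miniature lobule for tests
#'
#' Six sinusoid segments (3/2/1 per zone) with fixed lengths 4/3/2 grid
#' spaces, census 30/20/10 (60 hepatocytes), and a fixed edge list. Zone
#' mean lengths give segment offsets 0/4/7 and `d_max = 9`, so every
#' hepatocyte `dPP` is hand-checkable.
#'
#' @return A `lobule` object.
#' @export
make_fixture_lobule <- function() {
  segments <- data.frame(
    id = 1:6,
    zone = c(1L, 1L, 1L, 2L, 2L, 3L),
    length = c(4L, 4L, 4L, 3L, 3L, 2L),
    circumference = c(4L, 4L, 4L, 4L, 4L, 4L),
    hepatocyte_count = c(10L, 10L, 10L, 10L, 10L, 10L),
    dpp_offset = c(0, 0, 0, 4, 4, 7))
  edges <- data.frame(
    from = c(1L, 2L, 3L, 1L, 4L, 5L),
    to = c(4L, 4L, 5L, 5L, 6L, 6L),
    type = c("z1_z2", "z1_z2", "z1_z2", "z1_z2", "z2_z3", "z2_z3"))
  geo <- lobule_geometry(zone_nodes = c(3L, 2L, 1L),
                         edge_counts = list(z1_z2 = 4L, within_z1 = 0L,
                                            z2_z3 = 2L, within_z2 = 0L,
                                            within_z3 = 0L),
                         length_range = list(c(4L, 4L), c(3L, 3L),
                                             c(2L, 2L)),
                         circumference_range = c(4L, 4L),
                         census = c(30L, 20L, 10L))
  structure(list(segments = segments, edges = edges,
                 zone_node_counts = stats::setNames(c(3L, 2L, 1L), 1:3),
                 pp_entrance_ids = 1:3,
                 zone_mean_length = c(4, 3, 2),
                 d_max = 9,
                 seed = NA_integer_,
                 geometry = geo),
            class = "lobule")
}

#' Export experiment results
#'
#' Writes the result tables as RFC-4180 CSV files plus a JSON run manifest
#' (dose, seeds, configuration name, configuration hash, package version).
#' Times are seconds, distances grid spaces.
#'
#' @param result An [run_bolus_experiment()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
export_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("body_series.csv", "regional_series.csv",
                                "death_log.csv", "manifest.json"))
  utils::write.csv(result$body_series, paths[1], row.names = FALSE)
  utils::write.csv(result$regional_series, paths[2], row.names = FALSE)
  utils::write.csv(result$death_log, paths[3], row.names = FALSE)
  manifest <- list(
    config_name = result$config_name,
    config_hash = rlang::hash(list(result$config_name, result$dose,
                                   result$horizon)),
    dose = result$dose[c("mg_per_kg", "route", "dose_scale", "n_objects")],
    horizon = result$horizon,
    master_seed = result$master_seed,
    trial_seeds = result$seeds,
    summary = result$summary,
    package_version = as.character(utils::packageVersion("vlobule")))
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read back exported results
#'
#' @param out_dir Directory written by [export_results()].
#' @return List with `body_series`, `regional_series`, `death_log`,
#'   `manifest`.
#' @export
read_results <- function(out_dir) {
  list(body_series = utils::read.csv(file.path(out_dir, "body_series.csv")),
       regional_series = utils::read.csv(file.path(out_dir,
                                                   "regional_series.csv")),
       death_log = utils::read.csv(file.path(out_dir, "death_log.csv")),
       manifest = jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                      simplifyVector = TRUE))
}
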