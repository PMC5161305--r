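#' Single-pass perfusion protocol
#'
#' Constant-rate APAP input at the periportal entrances with outflow
#' measured at the central vein; used to measure the hepatic extraction
#' ratio under the metabolism-phase configuration.
#'
#' @param input_rate APAP objects per second delivered to the entrances.
#' @param duration Total perfusion time in seconds.
#' @param stabilization_window Window (seconds) over which outflow is
#'   averaged for the stabilization test.
#' @param stabilization_tolerance Maximum relative variation of the
#'   windowed mean outflow for the run to count as stabilized.
#' @return Object of class `perfusion_protocol`.
#' @export
perfusion_protocol <- function(input_rate = 100, duration = 3000L,
                               stabilization_window = 300L,
                               stabilization_tolerance = 0.02) {
  stopifnot(duration > stabilization_window, stabilization_window > 0)
  structure(list(input_rate = input_rate, duration = as.integer(duration),
                 stabilization_window = as.integer(stabilization_window),
                 stabilization_tolerance = stabilization_tolerance),
            class = "perfusion_protocol")
}

#' Bolus toxicity protocol
#'
#' A single dose followed by a 24-hour observation horizon across
#' independent Monte Carlo lobule variants, with a polling death observer
#' and three 5-grid-space measurement bands.
#'
#' @param dose A [dose_spec()].
#' @param horizon Simulated seconds (default 86,400 = 24 h).
#' @param n_trials Number of Monte Carlo lobule variants.
#' @param poll_interval Observer polling interval in seconds.
#' @param region_band_width Width of the measurement bands in grid spaces.
#' @return Object of class `bolus_protocol`.
#' @export
bolus_protocol <- function(dose = dose_spec(), horizon = 86400L,
                           n_trials = 12L, poll_interval = 60L,
                           region_band_width = 5) {
  stopifnot(n_trials >= 1L, poll_interval >= 1L, horizon >= 1L)
  structure(list(dose = dose, horizon = as.integer(horizon),
                 n_trials = as.integer(n_trials),
                 poll_interval = as.integer(poll_interval),
                 region_band_width = region_band_width),
            class = "bolus_protocol")
}

# independent child seeds spawned from a master seed
spawn_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a single-pass liver perfusion
#'
#' Perfuses one lobule at a constant APAP input rate with the toxicity
#' phase disabled, detects stabilization of the central-vein outflow
#' (windowed mean varying less than the protocol tolerance), and reports
#' the extraction ratio `ER = 1 - outflow/input`.
#'
#' @param proto A [perfusion_protocol()].
#' @param cfg A [mechanism_config()] (its metabolism-phase gradients are
#'   used).
#' @param lobule A [build_lobule()] result.
#' @param seed Integer seed.
#' @param transport A [transport_params()].
#' @return List of class `perfusion_result`: `extraction_ratio`,
#'   `outflow_ratio`, `stabilized` (logical), `outflow` (per-second
#'   series), `input_rate`.
#' @examples
#' \donttest{
#' lob <- build_lobule(seed = 7)
#' pr <- run_single_pass_perfusion(perfusion_protocol(), mechanism_preset("MGNZ"),
#'                                 lob, seed = 7)
#' pr$extraction_ratio
#' }
#' @export
run_single_pass_perfusion <- function(proto, cfg, lobule, seed,
                                      transport = transport_params()) {
  stopifnot(inherits(proto, "perfusion_protocol"))
  set.seed(seed)
  res <- run_engine(lobule, cfg, transport, dose = NULL,
                    horizon = proto$duration,
                    poll = proto$stabilization_window,
                    perfusion = TRUE, input_rate = proto$input_rate,
                    toxicity = FALSE)
  out <- res$outflow[-1]  # per-second outflow, t = 1..duration
  w <- proto$stabilization_window
  nwin <- floor(length(out) / w)
  wins <- vapply(seq_len(nwin), function(k) {
    mean(out[((k - 1L) * w + 1L):(k * w)])
  }, numeric(1))
  stabilized <- FALSE
  ratio <- NA_real_
  for (k in seq_len(nwin)[-1]) {
    if (wins[k - 1] > 0 &&
        abs(wins[k] - wins[k - 1]) / wins[k - 1] <=
          proto$stabilization_tolerance) {
      stabilized <- TRUE
    }
  }
  # stabilized estimate: mean outflow over the final window
  ratio <- wins[nwin] / proto$input_rate
  structure(list(extraction_ratio = 1 - ratio, outflow_ratio = ratio,
                 stabilized = stabilized, window_means = wins,
                 outflow = out, input_rate = proto$input_rate,
                 seed = seed),
            class = "perfusion_result")
}

#' Run a bolus toxicity experiment
#'
#' Runs `n_trials` independent Monte Carlo lobule variants for the protocol
#' horizon at one second per step. Each trial gets its own child seed (so
#' trials are order-independent), a freshly wired lobule, and its own event
#' logs. Death events are recorded mechanism-side at trigger time with
#' their scheduled delay; the polling observer ([poll_death_observer()])
#' reads those logs without touching mechanism state.
#'
#' @param proto A [bolus_protocol()].
#' @param cfg A [mechanism_config()].
#' @param seed Master seed; spawns one child seed per trial.
#' @param transport A [transport_params()].
#' @param geometry A [lobule_geometry()].
#' @return Object of class `experiment_result` with `body_series`,
#'   `regional_series`, `death_log` (one row per triggered cell:
#'   `trigger_time`, `death_time`, `dpp`, `dist_cv`, `zone`),
#'   `trigger_series`, `summary` (deaths at the horizon per zone, NAPQI
#'   dose fraction, totals), `lobules`, `seeds`, `dose`, `config_name`.
#' @export
run_bolus_experiment <- function(proto, cfg, seed,
                                 transport = transport_params(),
                                 geometry = lobule_geometry()) {
  stopifnot(inherits(proto, "bolus_protocol"))
  seeds <- spawn_seeds(seed, proto$n_trials)
  trials <- lapply(seq_len(proto$n_trials), function(k) {
    set.seed(seeds[k])
    lob <- build_lobule(seed = NULL, geometry = geometry)
    res <- run_engine(lob, cfg, transport, dose = proto$dose,
                      horizon = proto$horizon,
                      poll = proto$poll_interval,
                      band_width = proto$region_band_width)
    res$lobule <- lob
    res
  })
  tag <- function(field) {
    do.call(rbind, lapply(seq_along(trials), function(k) {
      df <- trials[[k]][[field]]
      cbind(trial = rep(k, nrow(df)), df)
    }))
  }
  death_log <- tag("death_log")
  horizon <- proto$horizon
  dead24 <- death_log[death_log$death_time <= horizon, , drop = FALSE]
  totals <- Reduce(`+`, lapply(trials, function(x) x$totals))
  dose_total <- proto$dose$n_objects * proto$n_trials
  summary <- list(
    n_trials = proto$n_trials,
    total_hepatocytes = sum(vapply(trials, function(x) {
      sum(x$lobule$segments$hepatocyte_count)
    }, numeric(1))),
    deaths_total = nrow(dead24),
    deaths_per_zone = vapply(1:3, function(z) sum(dead24$zone == z),
                             numeric(1)),
    triggered_total = nrow(death_log),
    cum_napqi = unname(totals["cum_napqi"]),
    napqi_dose_fraction = if (dose_total > 0) {
      unname(totals["cum_napqi"]) / dose_total
    } else NA_real_,
    dose_objects = dose_total)
  structure(list(body_series = tag("body_series"),
                 regional_series = tag("regional_series"),
                 death_log = death_log,
                 trigger_series = tag("trigger_series"),
                 cells = tag("cells"),
                 summary = summary,
                 d_max = mean(vapply(trials, function(x) x$lobule$d_max,
                                     numeric(1))),
                 zone3_mean_length = mean(vapply(trials, function(x) {
                   x$lobule$zone_mean_length[3]
                 }, numeric(1))),
                 horizon = horizon,
                 dose = proto$dose,
                 seeds = seeds,
                 master_seed = seed,
                 config_name = cfg$name),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<experiment_result> %s: %d trials, %d hepatocytes\n",
              x$config_name, s$n_trials, s$total_hepatocytes))
  cat(sprintf("  deaths at %.1f h: %d (zones %s); NAPQI/dose = %.3f\n",
              x$horizon / 3600, s$deaths_total,
              paste(s$deaths_per_zone, collapse = "/"),
              s$napqi_dose_fraction))
  invisible(x)
}

#' Polling death observer
#'
#' Replays the observer over a recorded death log: at each polling time it
#' reports the cells whose death occurred since the previous poll.
#' Observation is read-only and cannot perturb a trajectory; each death is
#' reported exactly once, within `poll_interval` seconds of its true time.
#'
#' @param death_log Death log of an [run_bolus_experiment()] result.
#' @param horizon Last time to poll (seconds).
#' @param poll_interval Polling interval (seconds).
#' @return Data frame of observed deaths with `observed_time` (the poll at
#'   which each was first seen) alongside the true `death_time`.
#' @export
poll_death_observer <- function(death_log, horizon, poll_interval = 60L) {
  dl <- death_log[!is.na(death_log$death_time) &
                    death_log$death_time <= horizon, , drop = FALSE]
  dl$observed_time <- ceiling(dl$death_time / poll_interval) * poll_interval
  dl[order(dl$observed_time), , drop = FALSE]
}

#' Regional band measurements
#'
#' Returns per-hepatocyte means of NAPQI, exported G&S, cumulative
#' glutathione depletion events, total mitoD, and cumulative mitigation
#' events within the three measurement bands over time.
#'
#' @param result An [run_bolus_experiment()] result.
#' @return Data frame: `trial`, `time`, `band`, `n_cells`, and the five
#'   `mean_*` columns.
#' @export
region_band_measurements <- function(result) {
  result$regional_series
}

#' Dose-response experiment
#'
#' Runs paired bolus experiments across doses: the same trial seeds are
#' reused at every dose, so dose comparisons are paired at the lobule
#' level. Reports total dead hepatocytes at the horizon with Monte Carlo
#' standard errors and the percent reduction between consecutive doses.
#'
#' @param cfg A [mechanism_config()].
#' @param doses List of [dose_spec()] objects (or numeric mg/kg values, in
#'   which case the default dose scale and route are used); at least two.
#' @param n_trials Monte Carlo trials per dose.
#' @param seed Master seed.
#' @param proto Base [bolus_protocol()] supplying horizon and polling.
#' @param transport A [transport_params()].
#' @return Object of class `dose_response_result`: `table` (per dose:
#'   deaths mean and standard error), `percent_reduction` between
#'   consecutive doses, and `per_trial` death counts.
#' @export
run_dose_response <- function(cfg, doses, n_trials = 6L, seed = 1L,
                              proto = bolus_protocol(),
                              transport = transport_params()) {
  if (length(doses) < 2L) stop("need at least two doses", call. = FALSE)
  doses <- lapply(doses, function(d) {
    if (inherits(d, "dose_spec")) d else dose_spec(mg_per_kg = d)
  })
  per_trial <- lapply(doses, function(d) {
    p <- proto
    p$dose <- d
    p$n_trials <- as.integer(n_trials)
    res <- run_bolus_experiment(p, cfg, seed, transport)
    dl <- res$death_log
    dl <- dl[dl$death_time <= res$horizon, , drop = FALSE]
    vapply(seq_len(n_trials), function(k) sum(dl$trial == k), numeric(1))
  })
  mg <- vapply(doses, function(d) d$mg_per_kg, numeric(1))
  means <- vapply(per_trial, mean, numeric(1))
  ses <- vapply(per_trial, function(x) stats::sd(x) / sqrt(length(x)),
                numeric(1))
  reduction <- if (length(doses) > 1) {
    100 * (1 - means[-1] / pmax(means[-length(means)], .Machine$double.eps))
  } else numeric(0)
  structure(list(table = data.frame(mg_per_kg = mg, deaths_mean = means,
                                    deaths_se = ses),
                 percent_reduction = reduction,
                 per_trial = per_trial, seed = seed),
            class = "dose_response_result")
}

#' Mechanism variant sweep
#'
#' Runs the bolus protocol for every supplied mechanism variant with paired
#' trial seeds, and flags each variant as experimentally indistinguishable
#' from the reference when its total dead hepatocytes lie within a band
#' (default plus or minus 20 percent) of the reference mean.
#'
#' @param variants List of [mechanism_config()] objects (see
#'   [make_variant()]).
#' @param proto A [bolus_protocol()].
#' @param seed Master seed (shared across variants: paired comparisons).
#' @param reference Reference configuration (default the MGNZ preset).
#' @param band Half-width of the indistinguishability band as a fraction of
#'   the reference mean.
#' @param transport A [transport_params()].
#' @return Object of class `variant_sweep_result` with `table` (per
#'   variant: total deaths at the horizon, per-zone deaths,
#'   `indistinguishable` flag) and `reference_deaths`.
#' @export
run_variant_sweep <- function(variants, proto, seed,
                              reference = mechanism_preset("MGNZ"),
                              band = 0.2,
                              transport = transport_params()) {
  run_one <- function(cfg) {
    res <- run_bolus_experiment(proto, cfg, seed, transport)
    dl <- res$death_log[res$death_log$death_time <= res$horizon, ,
                        drop = FALSE]
    list(total = nrow(dl),
         zones = vapply(1:3, function(z) sum(dl$zone == z), numeric(1)))
  }
  ref <- run_one(reference)
  rows <- lapply(variants, run_one)
  tab <- data.frame(
    variant = vapply(variants, function(v) v$name, character(1)),
    deaths_total = vapply(rows, function(r) r$total, numeric(1)),
    deaths_z1 = vapply(rows, function(r) r$zones[1], numeric(1)),
    deaths_z2 = vapply(rows, function(r) r$zones[2], numeric(1)),
    deaths_z3 = vapply(rows, function(r) r$zones[3], numeric(1)))
  tab$indistinguishable <- abs(tab$deaths_total - ref$total) <=
    band * ref$total
  structure(list(table = tab, reference_deaths = ref$total,
                 reference_name = reference$name, band = band, seed = seed),
            class = "variant_sweep_result")
}
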