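#' Mechanism configuration
#'
#' Bundles the full parameter set of one mechanism hypothesis: the zonated
#' (or constant) gradients for APAP metabolism, NAPQI formation, the
#' glutathione depletion threshold and mitochondrial-damage (mitoD)
#' mitigation; the location-independent event probabilities; the damage
#' amplification draw; the death trigger threshold; and the death-delay
#' rule. All per-event probabilities are per object per one-second step.
#'
#' @param name Label for the configuration.
#' @param p_metabolize [gradient_spec()]: probability a cell-resident APAP
#'   object is metabolized per step.
#' @param p_napqi [gradient_spec()]: probability a metabolite is NAPQI
#'   (otherwise inactive G&S, exported to the body).
#' @param gsh_threshold [gradient_spec()]: cumulative glutathione depletion
#'   events a hepatocyte must accumulate before NAPQI starts producing
#'   damage products.
#' @param p_mitod_mitigation [gradient_spec()]: probability each mitoD
#'   object is destroyed per step.
#' @param p_gsh_depletion Probability per NAPQI per step, below threshold,
#'   that the NAPQI is destroyed in a glutathione depletion event.
#' @param p_react Probability per NAPQI per step, at or above threshold,
#'   that the NAPQI reacts and becomes a damage product.
#' @param p_mitod_split Probability a damage product is mitoD rather than
#'   non-mitochondrial damage (nonMD).
#' @param amplification List `list(lo, hi)`: each mitoD undergoes one
#'   amplification event adding `n ~ DiscreteUniform(lo..hi)` further mitoD.
#' @param p_nonmd_mitigation Probability each nonMD object is destroyed per
#'   step.
#' @param death_trigger_threshold Total mitoD count at which death is
#'   triggered irreversibly (6: triggered when mitoD exceeds 5).
#' @param death_delay List: either `list(dist = "uniform", lo, hi)` or
#'   `list(dist = "normal", mean, sd)`, in hours; the interval between the
#'   trigger event and the observable death event.
#' @return Object of class `mechanism_config`.
#' @export
mechanism_config <- function(name,
                             p_metabolize,
                             p_napqi,
                             gsh_threshold,
                             p_mitod_mitigation,
                             p_gsh_depletion = 0.5,
                             p_react = 0.5,
                             p_mitod_split = 0.5,
                             amplification = list(lo = 1L, hi = 6L),
                             p_nonmd_mitigation = 0.67,
                             death_trigger_threshold = 6L,
                             death_delay = list(dist = "uniform",
                                                lo = 1.2, hi = 12)) {
  for (g in list(p_metabolize, p_napqi, gsh_threshold, p_mitod_mitigation)) {
    stopifnot(inherits(g, "gradient_spec"))
  }
  for (p in c(p_gsh_depletion, p_react, p_mitod_split, p_nonmd_mitigation)) {
    stopifnot(p >= 0, p <= 1)
  }
  stopifnot(death_trigger_threshold >= 1)
  dd <- death_delay
  if (identical(dd$dist, "uniform")) {
    stopifnot(dd$lo > 0, dd$hi > dd$lo)
  } else if (identical(dd$dist, "normal")) {
    stopifnot(dd$mean > 0, dd$sd > 0)
  } else {
    stop("death_delay$dist must be 'uniform' or 'normal'", call. = FALSE)
  }
  structure(list(name = name,
                 p_metabolize = p_metabolize,
                 p_napqi = p_napqi,
                 gsh_threshold = gsh_threshold,
                 p_mitod_mitigation = p_mitod_mitigation,
                 p_gsh_depletion = p_gsh_depletion,
                 p_react = p_react,
                 p_mitod_split = p_mitod_split,
                 amplification = amplification,
                 p_nonmd_mitigation = p_nonmd_mitigation,
                 death_trigger_threshold = as.integer(death_trigger_threshold),
                 death_delay = death_delay),
            class = "mechanism_config")
}

#' @export
print.mechanism_config <- function(x, ...) {
  cat(sprintf("<mechanism_config> %s\n", x$name))
  for (f in c("p_metabolize", "p_napqi", "gsh_threshold",
              "p_mitod_mitigation")) {
    g <- x[[f]]
    cat(sprintf("  %-20s %s %g -> %g\n", f, g$shape, g$v_pp, g$v_cv))
  }
  cat(sprintf("  trigger threshold %d, delay %s\n",
              x$death_trigger_threshold, x$death_delay$dist))
  invisible(x)
}

#' Mechanism hypothesis presets
#'
#' Returns one of the four competing mechanism configurations for
#' centrilobular necrosis:
#'
#' * `NZ` (NAPQI zonation only): metabolism probability linear 0.35 to 0.95
#'   periportal to central vein, NAPQI probability linear 0.33 to 0.90;
#'   glutathione depletion threshold constant 3.5 and mitoD mitigation
#'   probability constant 0.67 (location independent).
#' * `GNZ`: as NZ, but the depletion threshold decreases linearly from 5 at
#'   the entrance, with the central-vein value calibrated so the mean over
#'   the canonical hepatocyte census equals 3.5.
#' * `MNZ`: as NZ, but mitoD mitigation follows a reverse sigmoid from 0.9
#'   to 0 with its inflection midway through zone 2, steepness calibrated so
#'   the census mean equals 0.67.
#' * `MGNZ`: both zonations combined.
#'
#' The calibrations make each zonated preset comparable to its constant
#' counterpart at the whole-lobule level.
#'
#' @param name One of `"NZ"`, `"GNZ"`, `"MNZ"`, `"MGNZ"`.
#' @param geometry Geometry defining the canonical census used for
#'   calibration.
#' @return A [mechanism_config()].
#' @examples
#' mechanism_preset("NZ")$gsh_threshold
#' @export
mechanism_preset <- function(name = c("NZ", "GNZ", "MNZ", "MGNZ"),
                             geometry = lobule_geometry()) {
  name <- match.arg(name)
  key <- paste(name, paste(unlist(geometry$length_range), collapse = ","))
  cached <- .vlobule_cache$presets[[key]]
  if (!is.null(cached)) return(cached)

  pop <- canonical_dpp_population(geometry)
  gsh_flat <- gradient_spec("constant", v_pp = 3.5)
  mit_flat <- gradient_spec("constant", v_pp = 0.67)
  if (name %in% c("GNZ", "MGNZ")) {
    gsh <- calibrate_gradient_mean(
      gradient_spec("linear", v_pp = 5, v_cv = 0),
      population = pop$dpp, target_mean = 3.5,
      free_parameter = "v_cv", d_max = pop$d_max)
  } else {
    gsh <- gsh_flat
  }
  if (name %in% c("MNZ", "MGNZ")) {
    z2_mid <- mean(pop$dpp[pop$zone == 2L])
    mit <- calibrate_gradient_mean(
      gradient_spec("reverse_sigmoid", v_pp = 0.9, v_cv = 0,
                    inflection = z2_mid, steepness = 1),
      population = pop$dpp, target_mean = 0.67,
      free_parameter = "steepness", d_max = pop$d_max)
  } else {
    mit <- mit_flat
  }
  cfg <- mechanism_config(
    name = name,
    p_metabolize = gradient_spec("linear", v_pp = 0.35, v_cv = 0.95),
    p_napqi = gradient_spec("linear", v_pp = 0.33, v_cv = 0.90),
    gsh_threshold = gsh,
    p_mitod_mitigation = mit)
  .vlobule_cache$presets[[key]] <- cfg
  cfg
}

# the ten influential configuration knobs a variant may override
variant_knobs <- c("p_metabolize", "p_napqi", "gsh_threshold",
                   "p_mitod_mitigation", "p_gsh_depletion", "p_react",
                   "death_delay", "p_mitod_split", "p_nonmd_mitigation",
                   "death_trigger_threshold")

#' Derive a mechanism variant
#'
#' Builds a new configuration from a base mechanism by overriding between
#' one and seven of the ten influential knobs: the five zonation-capable
#' features (`p_metabolize`, `p_napqi`, `gsh_threshold`,
#' `p_mitod_mitigation`, `p_gsh_depletion`) plus `p_react`, `death_delay`,
#' `p_mitod_split`, `p_nonmd_mitigation` and `death_trigger_threshold`.
#' Each variant stands for an arbitrary virtual mouse strain.
#'
#' @param base A [mechanism_config()].
#' @param overrides Named list of replacement values (gradient fields take a
#'   [gradient_spec()]).
#' @param label Variant label; defaults to base name plus override names.
#' @return A new `mechanism_config`; the base is unchanged.
#' @export
make_variant <- function(base, overrides, label = NULL) {
  stopifnot(inherits(base, "mechanism_config"), is.list(overrides))
  if (length(overrides) == 0L) {
    out <- base
    out$name <- label %||% base$name
    return(out)
  }
  bad <- setdiff(names(overrides), variant_knobs)
  if (length(bad)) {
    stop("not an overridable knob: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(overrides) > 7L) {
    stop("a variant may override at most seven knobs", call. = FALSE)
  }
  args <- unclass(base)
  args[names(overrides)] <- overrides
  args$name <- label %||%
    paste0(base$name, "+", paste(names(overrides), collapse = "+"))
  do.call(mechanism_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- single-hepatocyte reference operations --------------------------------
#
# These R implementations define the per-cell event semantics at single-cell
# granularity. The experiment engine applies identical rules to the whole
# census in compiled code; the unit tests check both against per-object
# Bernoulli oracles.

#' Create a hepatocyte state
#'
#' @param pos List with `segment_id` and `x`, or a one-row slice of
#'   [hepatocyte_positions()].
#' @param lobule The owning lobule (used to fix the cell's path-length
#'   coordinate and the gradient scale).
#' @return Object of class `hepatocyte_state`: counters `apap`, `napqi`,
#'   `gs_exported`, `gsh_depletion_events`, `mitod` (amplified pool),
#'   `mitod_unamplified`, `nonmd`, plus `triggered`, `dead`, `trigger_time`,
#'   `death_time`, and the fixed coordinates `dpp`, `dist_cv`, `d_max`.
#'   `mitod_total()` gives the trigger-relevant total.
#' @export
hepatocyte_state <- function(pos, lobule) {
  d <- dpp(pos, lobule)[1]
  structure(list(segment_id = pos$segment_id[1], x = pos$x[1],
                 dpp = d, dist_cv = max(0, lobule$d_max - d),
                 d_max = lobule$d_max,
                 apap = 0L, napqi = 0L, gs_exported = 0L,
                 gsh_depletion_events = 0L,
                 mitod = 0L, mitod_unamplified = 0L, nonmd = 0L,
                 triggered = FALSE, dead = FALSE,
                 trigger_time = NA_real_, death_time = NA_real_),
            class = "hepatocyte_state")
}

#' Total mitochondrial damage of a hepatocyte
#'
#' Amplified plus not-yet-amplified mitoD; the quantity compared against the
#' death trigger threshold.
#' @param h A [hepatocyte_state()].
#' @return Integer.
#' @export
mitod_total <- function(h) h$mitod + h$mitod_unamplified

# gradient value at this cell's position, clamped to the gradient domain
cell_grad <- function(h, spec) {
  gradient_value(spec, min(h$dpp, h$d_max), h$d_max)
}

event_row <- function(time, kind, h, count) {
  data.frame(time = time, kind = kind, segment_id = h$segment_id,
             dpp = h$dpp, count = count)
}

#' One metabolism sub-step for a single hepatocyte
#'
#' Each cell-resident APAP object may be metabolized with the
#' location-dependent probability; a metabolite is NAPQI with the
#' location-dependent NAPQI probability, otherwise G&S (exported
#' immediately toward the body). Cells that have experienced a death
#' trigger stop metabolizing.
#'
#' @param h A [hepatocyte_state()].
#' @param cfg A [mechanism_config()].
#' @param time Simulated time in seconds (event log stamp).
#' @return List with updated `state` and an `events` data frame.
#' @export
metabolism_step <- function(h, cfg, time = 0) {
  ev <- NULL
  if (!h$triggered && !h$dead && h$apap > 0L) {
    m <- stats::rbinom(1L, h$apap, cell_grad(h, cfg$p_metabolize))
    if (m > 0L) {
      k <- stats::rbinom(1L, m, cell_grad(h, cfg$p_napqi))
      h$apap <- h$apap - m
      h$napqi <- h$napqi + k
      h$gs_exported <- h$gs_exported + (m - k)
      if (k > 0L) ev <- rbind(ev, event_row(time, "metabolize_napqi", h, k))
      if (m - k > 0L) ev <- rbind(ev, event_row(time, "metabolize_gs", h, m - k))
    }
  }
  list(state = h, events = ev)
}

#' One NAPQI-fate sub-step for a single hepatocyte
#'
#' Below the glutathione depletion threshold, each NAPQI may be destroyed in
#' a depletion event; at or above it, each NAPQI may react into a damage
#' product, split between mitoD (entering the unamplified pool) and nonMD.
#'
#' @inheritParams metabolism_step
#' @return List with updated `state` and `events`.
#' @export
napqi_fate_step <- function(h, cfg, time = 0) {
  ev <- NULL
  if (!h$dead && h$napqi > 0L) {
    if (h$gsh_depletion_events < cell_grad(h, cfg$gsh_threshold)) {
      d <- stats::rbinom(1L, h$napqi, cfg$p_gsh_depletion)
      if (d > 0L) {
        h$napqi <- h$napqi - d
        h$gsh_depletion_events <- h$gsh_depletion_events + d
        ev <- event_row(time, "gsh_depletion", h, d)
      }
    } else {
      r <- stats::rbinom(1L, h$napqi, cfg$p_react)
      if (r > 0L) {
        h$napqi <- h$napqi - r
        md <- stats::rbinom(1L, r, cfg$p_mitod_split)
        h$mitod_unamplified <- h$mitod_unamplified + md
        h$nonmd <- h$nonmd + (r - md)
        if (md > 0L) ev <- rbind(ev, event_row(time, "damage_mitod", h, md))
        if (r - md > 0L) {
          ev <- rbind(ev, event_row(time, "damage_nonmd", h, r - md))
        }
      }
    }
  }
  list(state = h, events = ev)
}

#' One amplification sub-step for a single hepatocyte
#'
#' Each not-yet-amplified mitoD gains `n ~ DiscreteUniform(lo..hi)`
#' additional mitoD exactly once, then joins the amplified pool, so a single
#' reacted NAPQI yields at most `1 + hi` mitoD in total.
#'
#' @inheritParams metabolism_step
#' @return List with updated `state` and `events`.
#' @export
amplification_step <- function(h, cfg, time = 0) {
  ev <- NULL
  u <- h$mitod_unamplified
  if (!h$dead && u > 0L) {
    lo <- cfg$amplification$lo; hi <- cfg$amplification$hi
    add <- sum(resample(seq.int(lo, hi), u, replace = TRUE))
    h$mitod <- h$mitod + u + add
    h$mitod_unamplified <- 0L
    ev <- event_row(time, "amplification", h, add)
  }
  list(state = h, events = ev)
}

#' One mitigation sub-step for a single hepatocyte
#'
#' Each mitoD (amplified or not) may be destroyed with the
#' location-dependent mitigation probability; each nonMD with the constant
#' nonMD mitigation probability.
#'
#' @inheritParams metabolism_step
#' @return List with updated `state` and `events`.
#' @export
mitigation_step <- function(h, cfg, time = 0) {
  ev <- NULL
  if (!h$dead) {
    p <- cell_grad(h, cfg$p_mitod_mitigation)
    dm <- if (h$mitod > 0L) stats::rbinom(1L, h$mitod, p) else 0L
    du <- if (h$mitod_unamplified > 0L) {
      stats::rbinom(1L, h$mitod_unamplified, p)
    } else 0L
    dn <- if (h$nonmd > 0L) {
      stats::rbinom(1L, h$nonmd, cfg$p_nonmd_mitigation)
    } else 0L
    h$mitod <- h$mitod - dm
    h$mitod_unamplified <- h$mitod_unamplified - du
    h$nonmd <- h$nonmd - dn
    if (dm + du > 0L) {
      ev <- rbind(ev, event_row(time, "mitigation_mitod", h, dm + du))
    }
    if (dn > 0L) ev <- rbind(ev, event_row(time, "mitigation_nonmd", h, dn))
  }
  list(state = h, events = ev)
}

# one pseudo-random death delay draw, in seconds
draw_death_delay <- function(cfg) {
  dd <- cfg$death_delay
  if (dd$dist == "uniform") {
    stats::runif(1, dd$lo, dd$hi) * 3600
  } else {
    max(0, stats::rnorm(1, dd$mean, dd$sd)) * 3600
  }
}

#' Death trigger check for a single hepatocyte
#'
#' When total mitoD reaches the death trigger threshold, the cell is
#' triggered irreversibly: the trigger time is recorded and the death time
#' scheduled as trigger time plus a draw from the death-delay distribution.
#'
#' @inheritParams metabolism_step
#' @param time Current simulated time in seconds.
#' @return List with updated `state` and `events`.
#' @export
death_trigger_check <- function(h, cfg, time = 0) {
  ev <- NULL
  if (!h$triggered && !h$dead &&
      mitod_total(h) >= cfg$death_trigger_threshold) {
    h$triggered <- TRUE
    h$trigger_time <- time
    h$death_time <- time + draw_death_delay(cfg)
    ev <- event_row(time, "trigger", h, 1L)
  }
  list(state = h, events = ev)
}

#' One full per-second step for a single hepatocyte
#'
#' Executes the five event sub-steps (metabolism, NAPQI fate, amplification,
#' mitigation, trigger check) in a pseudo-randomly shuffled order, advancing
#' one simulated second.
#'
#' @inheritParams metabolism_step
#' @return List with updated `state` and combined `events`.
#' @export
hepatocyte_step <- function(h, cfg, time = 0) {
  steps <- list(metabolism_step, napqi_fate_step, amplification_step,
                mitigation_step, death_trigger_check)
  ev <- NULL
  for (f in steps[sample.int(5L)]) {
    out <- f(h, cfg, time)
    h <- out$state
    ev <- rbind(ev, out$events)
  }
  list(state = h, events = ev)
}
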