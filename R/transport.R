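#' Transport and flow parameters
#'
#' Movement rules for APAP objects (and the extracellular marker) through
#' the lobule, plus the two body-level transfer features: first-order
#' absorption from the dose depot into the body, and per-second metering of
#' body APAP to the lobule entrance (maps to hepatic blood flow).
#'
#' Per free object per step, in its current grid column: it may enter an
#' adjacent hepatocyte (`p_uptake`), else be captured by an endothelial
#' binder (`p_bind`), else advance one column with the forward-bias
#' probability `p_fwd`. Bound objects are released with `p_release`.
#' Unmetabolized APAP inside a hepatocyte returns to the sinusoid with
#' `p_cell_exit` per step. The marker follows flow only: it never binds and
#' never enters cells, and is never eliminated.
#'
#' The defaults are the package's validated metabolism-phase configuration:
#' `p_uptake` was calibrated with the single-pass perfusion protocol so the
#' hepatic extraction ratio is 0.6, and `k_abs`/`hepatic_fraction` were set
#' for rapid first-order absorption and a blood-flow-like hepatic delivery
#' fraction (see the methods vignette).
#'
#' @param p_fwd Forward-bias probability per free object per step.
#' @param p_bind Endothelial binding probability per free object per step.
#' @param p_release Release probability per bound object per step.
#' @param p_uptake Hepatocyte uptake probability per free object per step.
#' @param p_cell_exit Exit probability per unmetabolized cell-resident APAP
#'   per step.
#' @param k_abs First-order absorption probability per depot object per
#'   second.
#' @param hepatic_fraction Fraction of body APAP (and marker) metered to the
#'   lobule entrance per second.
#' @return Object of class `transport_params`.
#' @export
transport_params <- function(p_fwd = 0.9, p_bind = 0.05, p_release = 0.5,
                             p_uptake = 0.0175, p_cell_exit = 0.4,
                             k_abs = 0.001, hepatic_fraction = 6e-4) {
  for (p in c(p_fwd, p_bind, p_release, p_uptake, p_cell_exit, k_abs,
              hepatic_fraction)) {
    stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  }
  structure(list(p_fwd = p_fwd, p_bind = p_bind, p_release = p_release,
                 p_uptake = p_uptake, p_cell_exit = p_cell_exit,
                 k_abs = k_abs, hepatic_fraction = hepatic_fraction),
            class = "transport_params")
}

#' Dose specification
#'
#' An APAP object maps to a small fixed fraction of a real dose;
#' `dose_scale` sets how many objects represent one mg/kg. The default
#' scale, 1200 objects per mg/kg (360,000 objects, about 26 per
#' hepatocyte, for the 300 mg/kg toxic reference dose), was fixed during
#' calibration of the toxicity-phase target attributes (see the methods
#' vignette). Route `"intravenous"`
#' places the whole dose in the body at time zero; `"intraperitoneal"` and
#' `"intragastric"` place it in the depot, from which it is absorbed first
#' order.
#'
#' @param mg_per_kg Dose in mg per kg body weight.
#' @param route One of `"intragastric"`, `"intraperitoneal"`,
#'   `"intravenous"`.
#' @param dose_scale Objects per mg/kg.
#' @param marker_objects Extracellular marker objects dosed alongside (an
#'   internal flow standard, excluded from cells and never eliminated).
#' @return Object of class `dose_spec` with `n_objects` computed.
#' @export
dose_spec <- function(mg_per_kg = 300, route = c("intragastric",
                                                 "intraperitoneal",
                                                 "intravenous"),
                      dose_scale = 1200, marker_objects = 10000L) {
  route <- match.arg(route)
  stopifnot(mg_per_kg >= 0, dose_scale > 0, marker_objects >= 0)
  structure(list(mg_per_kg = mg_per_kg, route = route,
                 dose_scale = dose_scale,
                 n_objects = as.integer(round(mg_per_kg * dose_scale)),
                 marker_objects = as.integer(marker_objects)),
            class = "dose_spec")
}

#' Mouse body compartment state
#'
#' The extrahepatic compartment: an unabsorbed dose depot, circulating
#' APAP, cumulative exported G&S metabolites, and the extracellular marker.
#'
#' @param dose A [dose_spec()].
#' @param transport A [transport_params()].
#' @return Object of class `mouse_body_state` with integer counters
#'   `depot`, `body_apap`, `body_gs`, `marker_depot`, `body_marker` and the
#'   transfer parameters.
#' @export
mouse_body_state <- function(dose = dose_spec(),
                             transport = transport_params()) {
  iv <- dose$route == "intravenous"
  structure(list(depot = if (iv) 0L else dose$n_objects,
                 body_apap = if (iv) dose$n_objects else 0L,
                 body_gs = 0L,
                 marker_depot = if (iv) 0L else dose$marker_objects,
                 body_marker = if (iv) dose$marker_objects else 0L,
                 k_abs = transport$k_abs,
                 hepatic_fraction = transport$hepatic_fraction),
            class = "mouse_body_state")
}

#' First-order absorption step
#'
#' Moves `Binomial(depot, k_abs)` objects (APAP and marker alike) from the
#' depot into the circulating body compartment.
#'
#' @param body A [mouse_body_state()].
#' @return Updated state.
#' @export
absorption_step <- function(body) {
  a <- stats::rbinom(1L, body$depot, body$k_abs)
  m <- stats::rbinom(1L, body$marker_depot, body$k_abs)
  body$depot <- body$depot - a
  body$body_apap <- body$body_apap + a
  body$marker_depot <- body$marker_depot - m
  body$body_marker <- body$body_marker + m
  body
}

#' Liver inflow (metering) step
#'
#' Transfers `Binomial(body_apap, hepatic_fraction)` APAP objects (and the
#' marker analogously) from the body to the periportal entrance segments,
#' apportioned proportionally to segment circumference.
#'
#' @param body A [mouse_body_state()].
#' @param lobule A [build_lobule()] result.
#' @return List with updated `body` and `injection`, a data frame
#'   (`segment_id`, `apap`, `marker`) of objects delivered to each
#'   entrance segment's inlet column.
#' @export
liver_inflow_step <- function(body, lobule) {
  ids <- lobule$pp_entrance_ids
  w <- lobule$segments$circumference[match(ids, lobule$segments$id)]
  m <- stats::rbinom(1L, body$body_apap, body$hepatic_fraction)
  mk <- stats::rbinom(1L, body$body_marker, body$hepatic_fraction)
  body$body_apap <- body$body_apap - m
  body$body_marker <- body$body_marker - mk
  split_multinom <- function(n) {
    if (n == 0L) return(integer(length(ids)))
    as.integer(stats::rmultinom(1L, n, w))
  }
  list(body = body,
       injection = data.frame(segment_id = ids,
                              apap = split_multinom(m),
                              marker = split_multinom(mk)))
}

#' Empty intra-lobule contents
#'
#' Per-segment, per-column counts of free APAP, endothelial-bound APAP and
#' marker, plus a central-vein return buffer. The reference R percolation
#' step operates on this structure; the compiled experiment engine holds
#' the equivalent state internally.
#'
#' @param lobule A [build_lobule()] result.
#' @return Object of class `segment_contents`: list of matrices `free`,
#'   `bound`, `marker` (rows = segments via `row_of`, columns = grid
#'   columns), and `cv_apap`, `cv_marker` buffers.
#' @export
segment_contents <- function(lobule) {
  seg <- lobule$segments
  L <- max(seg$length)
  zeros <- matrix(0L, nrow(seg), L)
  structure(list(free = zeros, bound = zeros, marker = zeros,
                 lengths = seg$length, segment_ids = seg$id,
                 cv_apap = 0L, cv_marker = 0L),
            class = "segment_contents")
}

# outlet segment ids for each segment (zone 3 -> central vein, coded NA)
segment_outlets <- function(lobule) {
  seg <- lobule$segments
  out <- lapply(seg$id, function(i) lobule$edges$to[lobule$edges$from == i])
  names(out) <- seg$id
  out
}

#' One percolation step (reference implementation)
#'
#' Advances every free object by the transport rules: hepatocyte uptake
#' (`p_uptake`, crediting the `uptake` tally for the segment column),
#' endothelial binding/release, forward-biased movement, uniform routing
#' over outlet edges at the segment exit, and delivery to the central-vein
#' buffer from zone 3. The marker moves with flow only. This R version is
#' the readable reference used by the unit tests on miniature lobules; the
#' experiment engine applies identical rules in compiled code.
#'
#' @param lobule A [build_lobule()] result.
#' @param contents A [segment_contents()].
#' @param transport A [transport_params()].
#' @return List with updated `contents` and `uptake`, a data frame
#'   (`segment_id`, `x`, `count`) of objects taken up by hepatocytes.
#' @export
percolation_step <- function(lobule, contents, transport = transport_params()) {
  seg <- lobule$segments
  outlets <- segment_outlets(lobule)
  # reverse zone/index order so an object moves at most one column per step
  ord <- order(-seg$zone, -seg$id)
  up <- list()
  for (j in ord) {
    L <- seg$length[j]
    has_cells <- seg$hepatocyte_count[j] > 0L
    for (ci in rev(seq_len(L))) {
      rel <- stats::rbinom(1L, contents$bound[j, ci], transport$p_release)
      contents$bound[j, ci] <- contents$bound[j, ci] - rel
      f <- contents$free[j, ci] + rel
      contents$free[j, ci] <- 0L
      taken <- 0L; stay <- 0L
      pu <- if (has_cells) transport$p_uptake else 0
      for (k in seq_len(f)) {
        u <- stats::runif(1)
        if (u < pu) {
          taken <- taken + 1L
        } else if (u < pu + (1 - pu) * transport$p_bind) {
          contents$bound[j, ci] <- contents$bound[j, ci] + 1L
        } else if (stats::runif(1) < transport$p_fwd) {
          if (ci < L) {
            contents$free[j, ci + 1L] <- contents$free[j, ci + 1L] + 1L
          } else if (seg$zone[j] == 3L) {
            contents$cv_apap <- contents$cv_apap + 1L
          } else {
            to <- resample(outlets[[j]], 1L)
            contents$free[to, 1L] <- contents$free[to, 1L] + 1L
          }
        } else stay <- stay + 1L
      }
      contents$free[j, ci] <- contents$free[j, ci] + stay
      if (taken > 0L) {
        up[[length(up) + 1L]] <- data.frame(segment_id = seg$id[j],
                                            x = ci - 1L, count = taken)
      }
      # marker: flow only
      mk <- contents$marker[j, ci]
      contents$marker[j, ci] <- 0L
      mstay <- 0L
      for (k in seq_len(mk)) {
        if (stats::runif(1) < transport$p_fwd) {
          if (ci < L) {
            contents$marker[j, ci + 1L] <- contents$marker[j, ci + 1L] + 1L
          } else if (seg$zone[j] == 3L) {
            contents$cv_marker <- contents$cv_marker + 1L
          } else {
            to <- resample(outlets[[j]], 1L)
            contents$marker[to, 1L] <- contents$marker[to, 1L] + 1L
          }
        } else mstay <- mstay + 1L
      }
      contents$marker[j, ci] <- contents$marker[j, ci] + mstay
    }
  }
  uptake <- if (length(up)) do.call(rbind, up) else
    data.frame(segment_id = integer(0), x = integer(0), count = integer(0))
  list(contents = contents, uptake = uptake)
}

#' Central-vein return step
#'
#' Empties the central-vein buffers back into the body compartments; APAP
#' becomes re-eligible for hepatic delivery (recirculation) and the marker
#' accumulates unchanged.
#'
#' @param body A [mouse_body_state()].
#' @param contents A [segment_contents()].
#' @return List with updated `body` and `contents`.
#' @export
cv_return_step <- function(body, contents) {
  body$body_apap <- body$body_apap + contents$cv_apap
  body$body_marker <- body$body_marker + contents$cv_marker
  contents$cv_apap <- 0L
  contents$cv_marker <- 0L
  list(body = body, contents = contents)
}

#' Whole-system mass balance audit
#'
#' Checks exact integer conservation of APAP-derived objects and of the
#' marker for an experiment result: at every recorded time,
#' `depot + body + in-lobule + in-cell + cumulative NAPQI created +
#' cumulative G&S created` must equal the administered dose, and the
#' marker total must be constant. The compiled engine performs the same
#' audit at every polling step and aborts on the first violation; this
#' function re-verifies the exported series.
#'
#' @param result A [run_bolus_experiment()] result.
#' @return Invisibly `TRUE`; stops with a per-compartment diff otherwise.
#' @export
mass_balance_audit <- function(result) {
  bs <- result$body_series
  dose <- result$dose$n_objects
  tot <- bs$depot + bs$body_apap + bs$liver_apap + bs$cell_apap +
    bs$cum_napqi + bs$cum_gs
  if (any(tot != dose)) {
    i <- which(tot != dose)[1]
    stop(sprintf(paste0(
      "mass balance violated at t=%ds (trial %d): depot=%d body=%d ",
      "liver=%d cells=%d napqi=%d gs=%d, total %d != dose %d"),
      bs$time[i], bs$trial[i], bs$depot[i], bs$body_apap[i],
      bs$liver_apap[i], bs$cell_apap[i], bs$cum_napqi[i], bs$cum_gs[i],
      tot[i], dose), call. = FALSE)
  }
  mtot <- bs$marker_depot + bs$body_marker + bs$liver_marker
  if (any(mtot != result$dose$marker_objects)) {
    stop("marker conservation violated", call. = FALSE)
  }
  invisible(TRUE)
}
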