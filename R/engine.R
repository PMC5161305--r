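# Internal bridge between the R-level objects and the compiled engine.

# Band assignment for the three 5-grid-space measurement regions:
# PP adjacent to the lobule entrance, CV adjacent to the central vein,
# midzonal centered at d_max / 2. 0 = outside every band.
assign_bands <- function(pos, d_max, band_width) {
  w <- band_width
  band <- integer(nrow(pos))
  band[pos$dpp < w] <- 1L
  band[abs(pos$dpp - d_max / 2) < w / 2] <- 2L
  band[pos$dist_cv < w] <- 3L
  band
}

# gradient values for every hepatocyte, clamped to the gradient domain
cell_gradients <- function(cfg, pos, d_max) {
  d <- pmin(pos$dpp, d_max)
  list(p_met = gradient_value(cfg$p_metabolize, d, d_max),
       p_nap = gradient_value(cfg$p_napqi, d, d_max),
       thr = gradient_value(cfg$gsh_threshold, d, d_max),
       p_mit = gradient_value(cfg$p_mitod_mitigation, d, d_max))
}

# Run the compiled engine for one lobule variant. Uses the current RNG
# stream; callers seed per trial. Returns tidied logs.
run_engine <- function(lobule, cfg, transport, dose = NULL,
                       horizon = 86400L, poll = 60L, band_width = 5,
                       perfusion = FALSE, input_rate = 0,
                       toxicity = TRUE, audit = TRUE) {
  seg <- lobule$segments
  nseg <- nrow(seg)
  col_off <- c(0L, cumsum(seg$length))
  pos <- hepatocyte_positions(lobule)
  grads <- cell_gradients(cfg, pos, lobule$d_max)
  band <- assign_bands(pos, lobule$d_max, band_width)

  # flattened outlet adjacency (0-based); zone 3 drains to the CV
  out_list <- lapply(seg$id, function(i) {
    if (seg$zone[match(i, seg$id)] == 3L) return(integer(0))
    lobule$edges$to[lobule$edges$from == i] - 1L
  })
  out_off <- c(0L, cumsum(lengths(out_list)))
  out_idx <- as.integer(unlist(out_list))

  entr <- match(lobule$pp_entrance_ids, seg$id)
  dd <- cfg$death_delay
  cpp_cfg <- list(
    p_gsh_depletion = cfg$p_gsh_depletion, p_react = cfg$p_react,
    p_mitod_split = cfg$p_mitod_split,
    amp_lo = as.integer(cfg$amplification$lo),
    amp_hi = as.integer(cfg$amplification$hi),
    p_nonmd_mitigation = cfg$p_nonmd_mitigation,
    death_trigger_threshold = cfg$death_trigger_threshold,
    delay_type = if (dd$dist == "uniform") 0L else 1L,
    delay_a = (if (dd$dist == "uniform") dd$lo else dd$mean) * 3600,
    delay_b = (if (dd$dist == "uniform") dd$hi else dd$sd) * 3600,
    k_abs = transport$k_abs, hepatic_fraction = transport$hepatic_fraction,
    p_fwd = transport$p_fwd, p_bind = transport$p_bind,
    p_release = transport$p_release, p_uptake = transport$p_uptake,
    p_cell_exit = transport$p_cell_exit,
    depot0 = 0, body0 = 0, marker_depot0 = 0, marker_body0 = 0)
  if (!is.null(dose)) {
    iv <- dose$route == "intravenous"
    cpp_cfg$depot0 <- if (iv) 0 else dose$n_objects
    cpp_cfg$body0 <- if (iv) dose$n_objects else 0
    cpp_cfg$marker_depot0 <- if (iv) 0 else dose$marker_objects
    cpp_cfg$marker_body0 <- if (iv) dose$marker_objects else 0
  }

  raw <- cpp_sim_run(
    as.integer(seg$zone), as.integer(seg$length), as.integer(col_off),
    as.integer(out_off), out_idx,
    as.integer(entr - 1L), as.numeric(seg$circumference[entr]),
    as.integer(col_off[pos$segment_id] + pos$x), band,
    pos$dist_cv, grads$p_met, grads$p_nap, grads$thr, grads$p_mit,
    cpp_cfg, as.integer(horizon), as.integer(poll), perfusion,
    input_rate, toxicity, audit)

  body <- as.data.frame(raw$body)
  names(body) <- c("time", "depot", "body_apap", "body_gs", "marker_depot",
                   "body_marker", "liver_apap", "cell_apap", "liver_marker",
                   "cum_napqi", "cum_gs", "cum_triggered", "cum_dead")

  metrics <- c("napqi", "gs", "gsh_depletion", "mitod", "mitigation")
  bandnm <- c("PP", "midzonal", "CV")
  ncells_band <- tabulate(band, nbins = 3L)
  regional <- do.call(rbind, lapply(1:3, function(b) {
    m <- raw$bands[, (b - 1L) * 5L + seq_len(5L), drop = FALSE]
    colnames(m) <- metrics
    data.frame(time = body$time, band = bandnm[b], n_cells = ncells_band[b],
               sweep(m, 2L, max(ncells_band[b], 1L), "/"))
  }))
  names(regional)[4:8] <- paste0("mean_", metrics)

  trig_idx <- which(raw$trigger_time >= 0)
  death_log <- data.frame(
    cell = trig_idx,
    segment_id = pos$segment_id[trig_idx],
    zone = pos$zone[trig_idx],
    dpp = pos$dpp[trig_idx],
    dist_cv = pos$dist_cv[trig_idx],
    trigger_time = raw$trigger_time[trig_idx],
    death_time = raw$death_time[trig_idx],
    dead_in_run = raw$dead[trig_idx] == 1L)

  list(body_series = body,
       regional_series = regional,
       death_log = death_log,
       trigger_series = data.frame(time = seq(0L, horizon),
                                   dist_sum = as.numeric(raw$trig_sum),
                                   n = as.numeric(raw$trig_cnt)),
       outflow = if (perfusion) as.numeric(raw$outflow) else NULL,
       totals = raw$totals,
       cells = cbind(pos, band = band, gsh_depletion_events = raw$gshev,
                     apap_final = raw$final_apap,
                     dead = raw$dead == 1L))
}
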