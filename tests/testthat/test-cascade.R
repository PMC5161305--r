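fixture_cell <- function(x = 0L, segment_id = 1L,
                         lob = make_fixture_lobule()) {
  hepatocyte_state(list(segment_id = segment_id, x = x), lob)
}

test_that("mechanism presets encode the four zonation hypotheses", {
  nz <- mechanism_preset("NZ")
  expect_equal(nz$gsh_threshold$shape, "constant")
  expect_equal(nz$gsh_threshold$v_pp, 3.5)
  expect_equal(nz$p_mitod_mitigation$v_pp, 0.67)
  expect_equal(nz$p_metabolize$v_pp, 0.35)
  expect_equal(nz$p_metabolize$v_cv, 0.95)
  expect_equal(nz$p_napqi$v_pp, 0.33)
  expect_equal(nz$p_napqi$v_cv, 0.90)

  gnz <- mechanism_preset("GNZ")
  expect_equal(gnz$gsh_threshold$shape, "linear")
  expect_equal(gnz$gsh_threshold$v_pp, 5)
  # GNZ differs from NZ only in the depletion-threshold gradient
  same <- setdiff(names(unclass(nz)), c("name", "gsh_threshold"))
  expect_equal(unclass(gnz)[same], unclass(nz)[same])

  mnz <- mechanism_preset("MNZ")
  expect_equal(mnz$p_mitod_mitigation$shape, "reverse_sigmoid")
  expect_equal(mnz$gsh_threshold, nz$gsh_threshold)

  mgnz <- mechanism_preset("MGNZ")
  expect_equal(mgnz$gsh_threshold, gnz$gsh_threshold)
  expect_equal(mgnz$p_mitod_mitigation, mnz$p_mitod_mitigation)
})

test_that("zonated preset gradients average to their constant counterparts", {
  pop <- canonical_dpp_population()
  mgnz <- mechanism_preset("MGNZ")
  thr <- mean(gradient_value(mgnz$gsh_threshold, pop$dpp, pop$d_max))
  expect_equal(thr, 3.5, tolerance = 1e-6)
  mit <- mean(gradient_value(mgnz$p_mitod_mitigation,
                             pmin(pop$dpp, pop$d_max), pop$d_max))
  expect_equal(mit, 0.67, tolerance = 1e-6)
})

test_that("variants override only the ten knobs, at most seven at a time", {
  base <- mechanism_preset("MGNZ")
  v <- make_variant(base, list(gsh_threshold = gradient_spec(
    "linear", v_pp = 8, v_cv = base$gsh_threshold$v_cv)))
  expect_equal(v$gsh_threshold$v_pp, 8)
  expect_equal(base$gsh_threshold$v_pp, 5)  # base untouched
  v3 <- make_variant(base, list(gsh_threshold = gradient_spec(
    "linear", v_pp = 3, v_cv = 1)))
  expect_equal(v3$gsh_threshold$v_pp, 3)
  expect_error(make_variant(base, list(amplification = list(lo = 1, hi = 2))),
               "knob")
  too_many <- stats::setNames(
    as.list(rep(0.5, 8)),
    c("p_gsh_depletion", "p_react", "p_mitod_split", "p_nonmd_mitigation",
      "death_trigger_threshold", "p_metabolize", "p_napqi",
      "gsh_threshold"))
  expect_error(make_variant(base, too_many), "seven")
  same <- make_variant(base, list())
  expect_equal(unclass(same), unclass(base))
})

test_that("metabolism is suppressed in triggered cells and splits NAPQI/G&S", {
  lob <- make_fixture_lobule()
  cfg <- mechanism_preset("NZ")
  h <- fixture_cell(x = 1L, segment_id = 6L, lob)  # deep zone 3
  h$apap <- 10L
  h$triggered <- TRUE
  set.seed(1)
  out <- metabolism_step(h, cfg)
  expect_equal(out$state$apap, 10L)
  expect_null(out$events)

  h$triggered <- FALSE
  set.seed(2)
  reps <- replicate(2000, {
    o <- metabolism_step(h, cfg)$state
    c(o$apap, o$napqi)
  })
  d <- min(h$dpp, lob$d_max)
  p_met <- gradient_value(cfg$p_metabolize, d, lob$d_max)
  p_nap <- gradient_value(cfg$p_napqi, d, lob$d_max)
  consumed <- 10 - mean(reps[1, ])
  expect_equal(consumed, 10 * p_met, tolerance = 0.1)
  expect_equal(mean(reps[2, ]), 10 * p_met * p_nap, tolerance = 0.1)
})

test_that("NAPQI fate depletes glutathione below threshold, damages above", {
  lob <- make_fixture_lobule()
  cfg <- mechanism_preset("NZ")  # threshold 3.5 everywhere
  h <- fixture_cell(lob = lob)
  h$napqi <- 4L
  set.seed(3)
  reps <- replicate(3000, napqi_fate_step(h, cfg)$state$gsh_depletion_events)
  expect_equal(mean(reps), 2, tolerance = 0.1)   # Binomial(4, 0.5) mean
  expect_true(all(replicate(200, {
    s <- napqi_fate_step(h, cfg)$state
    s$mitod_unamplified + s$nonmd
  }) == 0))

  h$gsh_depletion_events <- 4L  # beyond threshold
  h$napqi <- 10L
  set.seed(4)
  reps2 <- replicate(3000, {
    s <- napqi_fate_step(h, cfg)$state
    c(s$mitod_unamplified, s$nonmd)
  })
  expect_equal(mean(reps2[1, ]), 2.5, tolerance = 0.15)
  expect_equal(mean(reps2[2, ]), 2.5, tolerance = 0.15)

  h$napqi <- 0L
  expect_equal(napqi_fate_step(h, cfg)$state[c("napqi", "nonmd")],
               list(napqi = 0L, nonmd = 0L))
})

test_that("each mitoD is amplified exactly once, gaining 1 to 6 extras", {
  cfg <- mechanism_preset("NZ")
  h <- fixture_cell()
  h$mitod_unamplified <- 1L
  set.seed(5)
  totals <- replicate(4000, amplification_step(h, cfg)$state$mitod)
  expect_true(all(totals >= 2 & totals <= 7))
  expect_equal(mean(totals), 1 + 3.5, tolerance = 0.05)
  after <- amplification_step(h, cfg)$state
  expect_equal(after$mitod_unamplified, 0L)
  # empty unamplified pool is a no-op
  h2 <- fixture_cell(); h2$mitod <- 3L
  expect_equal(amplification_step(h2, cfg)$state$mitod, 3L)
})

test_that("mitigation removes the expected fraction of damage products", {
  cfg <- mechanism_preset("NZ")  # constant 0.67
  h <- fixture_cell()
  h$mitod <- 100L; h$nonmd <- 100L
  set.seed(6)
  reps <- replicate(500, {
    s <- mitigation_step(h, cfg)$state
    c(s$mitod, s$nonmd)
  })
  expect_equal(mean(reps[1, ]), 33, tolerance = 1.5)
  expect_equal(mean(reps[2, ]), 33, tolerance = 1.5)
  # MGNZ mitigation collapses toward zero adjacent to the CV
  mgnz <- mechanism_preset("MGNZ")
  lob <- make_fixture_lobule()
  pop <- canonical_dpp_population()
  p_cv <- gradient_value(mgnz$p_mitod_mitigation, pop$d_max, pop$d_max)
  expect_lt(p_cv, 0.15)
})

test_that("the death trigger is a threshold on total mitoD and irreversible", {
  cfg <- mechanism_preset("NZ")
  h <- fixture_cell()
  h$mitod <- 5L
  out <- death_trigger_check(h, cfg, time = 100)
  expect_false(out$state$triggered)  # 5 is not more than 5
  h$mitod <- 6L
  set.seed(7)
  out2 <- death_trigger_check(h, cfg, time = 100)
  expect_true(out2$state$triggered)
  expect_equal(out2$state$trigger_time, 100)
  delay <- out2$state$death_time - out2$state$trigger_time
  expect_gte(delay, 1.2 * 3600)
  expect_lte(delay, 12 * 3600)
  # unamplified mitoD counts toward the threshold
  h3 <- fixture_cell(); h3$mitod <- 3L; h3$mitod_unamplified <- 3L
  expect_true(death_trigger_check(h3, cfg)$state$triggered)
})

test_that("death delay draws follow the configured distribution", {
  cfg <- mechanism_preset("NZ")
  set.seed(8)
  d <- replicate(2000, draw_death_delay(cfg)) / 3600
  expect_true(all(d >= 1.2 & d <= 12))
  expect_equal(mean(d), (1.2 + 12) / 2, tolerance = 0.15)
  ncfg <- make_variant(cfg, list(death_delay = list(dist = "normal",
                                                    mean = 7.2, sd = 4.1)))
  dn <- replicate(4000, draw_death_delay(ncfg)) / 3600
  expect_true(all(dn >= 0))
  expect_equal(mean(dn[dn > 0]), 7.4, tolerance = 0.3)
})

test_that("an all-zero hepatocyte is an absorbing state of the full step", {
  cfg <- mechanism_preset("MGNZ")
  h <- fixture_cell()
  set.seed(9)
  out <- hepatocyte_step(h, cfg, time = 1)
  expect_equal(out$state[c("apap", "napqi", "mitod", "nonmd")],
               h[c("apap", "napqi", "mitod", "nonmd")])
  expect_null(out$events)
})

test_that("a deterministic limit case traces APAP through to a trigger", {
  # all probabilities 1, amplification forced to 6 extras
  lob <- make_fixture_lobule()
  cfg <- mechanism_config(
    name = "limit",
    p_metabolize = gradient_spec("constant", 1),
    p_napqi = gradient_spec("constant", 1),
    gsh_threshold = gradient_spec("constant", 0),
    p_mitod_mitigation = gradient_spec("constant", 0),
    p_gsh_depletion = 1, p_react = 1, p_mitod_split = 1,
    amplification = list(lo = 6L, hi = 6L),
    p_nonmd_mitigation = 0)
  h <- fixture_cell(lob = lob)
  h$apap <- 1L
  set.seed(10)
  for (t in 1:5) {
    if (h$triggered) break
    h <- hepatocyte_step(h, cfg, time = t)$state
  }
  # 1 APAP -> 1 NAPQI -> 1 mitoD -> amplified to 7 >= threshold 6
  expect_true(h$triggered)
  expect_lte(h$trigger_time, 5)
})

test_that("counts are conserved through every sub-step", {
  cfg <- mechanism_preset("MGNZ")
  lob <- make_fixture_lobule()
  set.seed(11)
  for (rep in 1:50) {
    h <- fixture_cell(x = sample(0:1, 1), segment_id = sample(1:6, 1), lob)
    h$apap <- sample(0:20, 1)
    h$napqi <- sample(0:10, 1)
    h$gsh_depletion_events <- sample(0:6, 1)
    before <- h
    out <- metabolism_step(h, cfg)$state
    # consumed APAP becomes NAPQI plus exported G&S, exactly
    expect_equal(before$apap - out$apap,
                 (out$napqi - before$napqi) +
                   (out$gs_exported - before$gs_exported))
    out2 <- napqi_fate_step(out, cfg)$state
    destroyed <- out$napqi - out2$napqi
    expect_equal(destroyed,
                 (out2$gsh_depletion_events - out$gsh_depletion_events) +
                   (out2$mitod_unamplified - out$mitod_unamplified) +
                   (out2$nonmd - out$nonmd))
  }
})

test_that("full mitigation without amplification prevents mitoD accumulation", {
  # one NAPQI reacts per step at most; with p-mitigation 1 and the
  # amplification draw forced to zero extras, mitoD can never accumulate
  # across steps, so a trigger threshold of 3 is unreachable
  lob <- make_fixture_lobule()
  cfg <- mechanism_config(
    name = "limit2",
    p_metabolize = gradient_spec("constant", 1),
    p_napqi = gradient_spec("constant", 1),
    gsh_threshold = gradient_spec("constant", 0),
    p_mitod_mitigation = gradient_spec("constant", 1),
    p_react = 1, p_mitod_split = 1,
    amplification = list(lo = 0L, hi = 0L),
    death_trigger_threshold = 3L)
  set.seed(12)
  h <- fixture_cell(lob = lob)
  for (t in 1:200) {
    h$napqi <- 1L  # steady trickle, one damage product per step at most
    h <- hepatocyte_step(h, cfg, time = t)$state
    expect_lte(h$mitod + h$mitod_unamplified, 2L)
  }
  expect_false(h$triggered)
})
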