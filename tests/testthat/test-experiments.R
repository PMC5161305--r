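test_that("experiments are bit-reproducible under a fixed master seed", {
  proto <- fixture_bolus()
  a <- run_bolus_experiment(proto, mechanism_preset("MGNZ"), seed = 21,
                            geometry = fixture_geometry_for_tests())
  b <- run_bolus_experiment(proto, mechanism_preset("MGNZ"), seed = 21,
                            geometry = fixture_geometry_for_tests())
  expect_identical(a$death_log, b$death_log)
  expect_identical(a$body_series, b$body_series)
  expect_identical(a$trigger_series, b$trigger_series)
  c <- run_bolus_experiment(proto, mechanism_preset("MGNZ"), seed = 22,
                            geometry = fixture_geometry_for_tests())
  expect_false(identical(a$body_series, c$body_series))
})

test_that("the death observer is passive: polling frequency changes nothing", {
  proto60 <- fixture_bolus()
  proto600 <- fixture_bolus()
  proto600$poll_interval <- 600L
  a <- run_bolus_experiment(proto60, mechanism_preset("MGNZ"), seed = 33,
                            geometry = fixture_geometry_for_tests())
  b <- run_bolus_experiment(proto600, mechanism_preset("MGNZ"), seed = 33,
                            geometry = fixture_geometry_for_tests())
  # mechanism trajectories identical: same triggers, deaths, totals
  expect_identical(a$death_log, b$death_log)
  expect_identical(a$trigger_series, b$trigger_series)
  expect_identical(a$summary, b$summary)
})

test_that("polled death observations are unique, ordered, and within one
           polling interval of the true death time", {
  proto <- fixture_bolus(horizon = 14400L)
  res <- run_bolus_experiment(proto, mechanism_preset("MGNZ"), seed = 44,
                              geometry = fixture_geometry_for_tests())
  obs <- poll_death_observer(res$death_log, horizon = 14400L,
                             poll_interval = 60L)
  truth <- res$death_log[!is.na(res$death_log$death_time) &
                           res$death_log$death_time <= 14400, ]
  expect_equal(nrow(obs), nrow(truth))
  expect_false(any(duplicated(obs[c("trial", "cell")])))
  expect_true(all(obs$observed_time - obs$death_time >= 0))
  expect_true(all(obs$observed_time - obs$death_time < 60))
})

test_that("trigger and death share the same lobular location", {
  proto <- fixture_bolus()
  res <- run_bolus_experiment(proto, mechanism_preset("MGNZ"), seed = 55,
                              geometry = fixture_geometry_for_tests())
  dl <- res$death_log
  expect_gt(nrow(dl), 0)
  # one row per cell carries both events: position fields are shared, and
  # the death time is always trigger time plus a delay in the support
  delay_h <- (dl$death_time - dl$trigger_time) / 3600
  expect_true(all(delay_h >= 1.2 & delay_h <= 12))
})

test_that("a zero dose produces no NAPQI and no deaths", {
  proto <- fixture_bolus(mg = 0, marker = 0, horizon = 3600L)
  res <- run_bolus_experiment(proto, mechanism_preset("MGNZ"), seed = 66,
                              geometry = fixture_geometry_for_tests())
  expect_equal(res$summary$deaths_total, 0)
  expect_equal(unname(res$summary$cum_napqi), 0)
})

test_that("perfusion with metabolism off extracts nothing", {
  lob <- build_lobule(seed = 9)
  cfg <- make_variant(mechanism_preset("NZ"),
                      list(p_metabolize = gradient_spec("constant", 0)))
  pr <- run_single_pass_perfusion(perfusion_protocol(duration = 2000L),
                                  cfg, lob, seed = 9)
  expect_lt(abs(pr$extraction_ratio), 0.05)
})

test_that("extraction is monotone in the metabolism probability scale", {
  lob <- build_lobule(seed = 10)
  scale_met <- function(f) {
    make_variant(mechanism_preset("NZ"), list(
      p_metabolize = gradient_spec("linear", v_pp = 0.35 * f,
                                   v_cv = 0.95 * f)))
  }
  ers <- vapply(c(0.25, 1), function(f) {
    run_single_pass_perfusion(perfusion_protocol(duration = 2000L),
                              scale_met(f), lob, seed = 10)$extraction_ratio
  }, numeric(1))
  expect_lt(ers[1], ers[2])
})

test_that("deaths increase with dose and drop when the dose is halved", {
  dr <- run_dose_response(mechanism_preset("MGNZ"),
                          list(dose_spec(4, dose_scale = 400,
                                         marker_objects = 0),
                               dose_spec(2, dose_scale = 400,
                                         marker_objects = 0),
                               dose_spec(0, dose_scale = 400,
                                         marker_objects = 0)),
                          n_trials = 3, seed = 77,
                          proto = bolus_protocol(horizon = 14400L))
  expect_error(run_dose_response(mechanism_preset("NZ"), list(dose_spec(1))),
               "two doses")
  d <- dr$table$deaths_mean
  expect_true(all(diff(d) <= 0))  # doses are descending
  expect_equal(d[3], 0)
})

test_that("the variant sweep flags the reference-equivalent configurations", {
  proto <- fixture_bolus(horizon = 28800L, mg = 25)
  base <- mechanism_preset("MGNZ")
  variants <- list(
    make_variant(base, list(), label = "MGNZ-copy"),
    make_variant(base, list(death_trigger_threshold = 40L),
                 label = "hard-trigger"))
  sw <- run_variant_sweep(variants, proto, seed = 88, reference = base)
  tab <- sw$table
  # the reference rerun under identical seeds is exactly reference-like
  expect_true(tab$indistinguishable[tab$variant == "MGNZ-copy"])
  # an implausibly high trigger threshold collapses toxicity
  expect_lt(tab$deaths_total[2], 0.8 * sw$reference_deaths)
  expect_false(tab$indistinguishable[2])
  expect_equal(tab$deaths_z1 + tab$deaths_z2 + tab$deaths_z3,
               tab$deaths_total)
})
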