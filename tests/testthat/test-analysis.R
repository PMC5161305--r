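test_that("moving average matches brute-force window means", {
  x <- c(2, 4, 6, 8, 10)
  got <- moving_average(x, window = 3)
  brute <- vapply(seq_along(x), function(i) {
    mean(x[max(1, i - 1):min(5, i + 1)])
  }, numeric(1))
  expect_equal(got, brute)
  expect_equal(moving_average(x, window = 1), x)
  expect_equal(moving_average(rep(7, 50), window = 100), rep(7, 50))
  expect_equal(moving_average(numeric(0)), numeric(0))
  # NA samples are skipped, not propagated
  y <- c(1, NA, 3)
  expect_equal(moving_average(y, window = 3), c(1, 2, 3))
})

test_that("trigger-distance series pools per-second means across trials", {
  ts <- data.frame(time = c(0:4, 0:4),
                   dist_sum = c(0, 3, 0, 10, 0, 0, 5, 0, 30, 0),
                   n = c(0, 1, 0, 2, 0, 0, 1, 0, 2, 0))
  out <- trigger_distance_series(ts, window = 1)
  expect_equal(out$mean_distance_cv[out$time == 1], 4)   # (3+5)/2
  expect_equal(out$mean_distance_cv[out$time == 3], 10)  # (10+30)/4
  expect_true(is.na(out$mean_distance_cv[out$time == 2]))
  expect_true(all(stats::na.omit(out$mean_distance_cv) >= 0))
})

test_that("the phenomenon check accepts CV-settled series and rejects
           periportal ones", {
  mk <- function(dist) {
    data.frame(time = 0:4000, dist_sum = dist, n = 1)
  }
  v_cv <- target_phenomenon_check(trigger_distance_series(mk(2)),
                                  zone3_band = 10)
  expect_true(v_cv$achieved)
  expect_equal(v_cv$band_occupancy, 1)
  v_pp <- target_phenomenon_check(trigger_distance_series(mk(45)),
                                  zone3_band = 10)
  expect_false(v_pp$achieved)
  # no events after the settling period -> undetermined
  empty <- data.frame(time = 0:2000, dist_sum = 0, n = 0)
  v_na <- target_phenomenon_check(trigger_distance_series(empty),
                                  zone3_band = 10)
  expect_true(is.na(v_na$achieved))
})

test_that("NAPQI dose fraction has its limits and guards", {
  proto <- fixture_bolus(horizon = 3600L)
  res <- run_bolus_experiment(proto, mechanism_preset("MGNZ"), seed = 14,
                              geometry = fixture_geometry_for_tests())
  f <- napqi_dose_fraction(res)
  expect_gte(f, 0); expect_lte(f, 1)
  res0 <- run_bolus_experiment(fixture_bolus(mg = 0, marker = 0,
                                             horizon = 600L),
                               mechanism_preset("MGNZ"), seed = 14,
                               geometry = fixture_geometry_for_tests())
  expect_error(napqi_dose_fraction(res0), "zero dose")
  # with metabolism off the fraction is exactly zero
  nomet <- make_variant(mechanism_preset("MGNZ"),
                        list(p_metabolize = gradient_spec("constant", 0)))
  resn <- run_bolus_experiment(fixture_bolus(horizon = 3600L), nomet,
                               seed = 14,
                               geometry = fixture_geometry_for_tests())
  expect_equal(napqi_dose_fraction(resn), 0)
})

test_that("zone death histograms partition the death log", {
  dl <- data.frame(zone = c(1, 1, 2, 3, 3, 3),
                   death_time = c(5000, 7000, 9000, 10000, 90000, 11000),
                   dpp = 0, dist_cv = 0)
  zh <- zone_death_histogram(dl, horizon = 86400)
  expect_equal(unname(zh$per_zone), c(2, 1, 2))  # one death past horizon
  expect_equal(zh$total, 5)
  expect_equal(sum(zh$histogram$deaths), 5)
  empty <- zone_death_histogram(dl[0, ])
  expect_equal(unname(empty$per_zone), c(0, 0, 0))
})

test_that("per-zone death counts never exceed the canonical census", {
  proto <- bolus_protocol(n_trials = 1L, horizon = 3600L,
                          dose = dose_spec(marker_objects = 0))
  res <- run_bolus_experiment(proto, mechanism_preset("MGNZ"), seed = 2)
  zh <- zone_death_histogram(res$death_log, horizon = 86400)
  expect_true(all(zh$per_zone <= c(9310, 3948, 742)))
})

test_that("the death-curve checker reproduces the uniform-delay closed form", {
  # all triggers at t0: cumulative deaths are linear between t0 + 1.2 h
  # and t0 + 12 h under the uniform delay rule
  set.seed(3)
  n <- 20000
  dl <- data.frame(zone = 3, dpp = 50, dist_cv = 0, trigger_time = 0,
                   death_time = stats::runif(n, 1.2, 12) * 3600)
  chk <- death_curve_band_check(dl)
  expect_true(chk$no_deaths_first_hour)
  expect_true(chk$plateau_after_12h)
  crv <- chk$curve
  mid <- crv$fraction[crv$time_h >= 2 & crv$time_h <= 11]
  th <- crv$time_h[crv$time_h >= 2 & crv$time_h <= 11]
  expect_equal(mid, (th - 1.2) / 10.8, tolerance = 0.02)
  expect_true(chk$pass)
  # the same checker accepts the normal-delay alternative
  dn <- data.frame(zone = 3, dpp = 50, dist_cv = 0, trigger_time = 0,
                   death_time = pmax(0, stats::rnorm(n, 7.2, 4.1)) * 3600)
  dn <- dn[dn$death_time > 3600 & dn$death_time < 13 * 3600, ]
  chkn <- death_curve_band_check(dn)
  expect_true(chkn$no_deaths_first_hour)
  # zero deaths: plateau vacuously holds, toxicity check fails
  chk0 <- death_curve_band_check(dl[0, ])
  expect_false(chk0$pass)
  expect_false(chk0$nonzero_toxicity)
  expect_true(chk0$plateau_after_12h)
})

test_that("the fixture lobule matches its hand-computed dpp table", {
  lob <- make_fixture_lobule()
  expect_equal(nrow(lob$segments), 6L)
  expect_equal(sum(lob$segments$hepatocyte_count), 60L)
  expect_equal(lob$d_max, 9)
  # offsets: zone 1 -> 0, zone 2 -> mean zone-1 length 4, zone 3 -> 4+3
  expect_equal(dpp(list(segment_id = 1L, x = 3L), lob), 3)
  expect_equal(dpp(list(segment_id = 4L, x = 0L), lob), 4)
  expect_equal(dpp(list(segment_id = 5L, x = 2L), lob), 6)
  expect_equal(dpp(list(segment_id = 6L, x = 1L), lob), 8)
  expect_equal(distance_to_cv(list(segment_id = 6L, x = 1L), lob), 1)
  pos <- hepatocyte_positions(lob)
  expect_equal(nrow(pos), 60L)
  expect_equal(range(pos$dpp), c(0, 8))
})

test_that("results export to CSV + manifest and round-trip identically", {
  proto <- fixture_bolus(horizon = 3600L)
  res <- run_bolus_experiment(proto, mechanism_preset("MGNZ"), seed = 25,
                              geometry = fixture_geometry_for_tests())
  dir1 <- file.path(withr::local_tempdir(), "run1")
  paths <- export_results(res, dir1)
  back <- read_results(dir1)
  expect_equal(nrow(back$death_log), nrow(res$death_log))
  expect_equal(back$manifest$summary$deaths_total,
               res$summary$deaths_total)
  expect_equal(back$manifest$master_seed, 25)
  # write -> read -> write produces identical bytes
  dir2 <- file.path(withr::local_tempdir(), "run2")
  export_results(res, dir2)
  for (f in basename(paths)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # the manifest hash tracks the configuration
  res2 <- res
  res2$config_name <- "other"
  dir3 <- file.path(withr::local_tempdir(), "run3")
  export_results(res2, dir3)
  expect_false(identical(back$manifest$config_hash,
                         read_results(dir3)$manifest$config_hash))
})

test_that("summaries are pure functions of the exported logs", {
  proto <- fixture_bolus(horizon = 7200L)
  res <- run_bolus_experiment(proto, mechanism_preset("MGNZ"), seed = 36,
                              geometry = fixture_geometry_for_tests())
  dl <- res$death_log
  recomputed <- sum(!is.na(dl$death_time) & dl$death_time <= res$horizon)
  expect_equal(recomputed, res$summary$deaths_total)
  zh <- zone_death_histogram(dl, horizon = res$horizon)
  expect_equal(unname(zh$per_zone), unname(res$summary$deaths_per_zone))
})
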