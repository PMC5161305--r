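# Miniature geometry for engine-level tests: Monte Carlo builds with the
# same shape as the deterministic fixture lobule (6 segments, census 60).
fixture_geometry_for_tests <- function() {
  make_fixture_lobule()$geometry
}

# small, fast bolus protocol against the fixture geometry
fixture_bolus <- function(horizon = 7200L, n_trials = 2L, mg = 5,
                          scale = 200, marker = 500) {
  bolus_protocol(dose = dose_spec(mg_per_kg = mg, dose_scale = scale,
                                  marker_objects = marker),
                 horizon = horizon, n_trials = n_trials)
}
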