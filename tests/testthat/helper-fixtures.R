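# Shared fixtures: the default rodent geometry and a calibrated parameter
# set cached per test run (calibration is deterministic, ~2 s).
default_geom <- build_half_filament()

calibrated_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_baseline(default_geom)
    cache
  }
})
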