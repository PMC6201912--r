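# Shared small fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# ~250-cone phantom, 84x84 px image: big enough for a 48x48 scan window
# plus drift margin.
small_phantom <- function() {
  fixture("small_phantom", function() {
    build_phantom(n_cones = 250, radius = 8, px_per_arcmin = 5,
                  psf_sigma = 0.2, seed = 42)
  })
}

# ~1000-cone phantom for statistics that need a field many spacings wide
# (packing regularity, Yellott's ring).
medium_phantom <- function() {
  fixture("medium_phantom", function() {
    build_phantom(n_cones = 1000, radius = 16, px_per_arcmin = 5,
                  psf_sigma = 0.2, seed = 41)
  })
}

small_scan <- function() {
  scan_params(n_rows = 48L, n_cols = 48L, line_rate = 48 / 0.033)
}

# 12-frame warped series on the small phantom.
small_series <- function() {
  fixture("small_series", function() {
    simulate_series(small_phantom(), small_scan(), 12, seed = 43)
  })
}

# 100 one-second drift traces at a modest line rate, reused by the
# calibration and decorrelation tests.
drift_traces <- function() {
  fixture("drift_traces", function() {
    lapply(1:100, function(s) simulate_drift(1, 500, seed = s))
  })
}

# Tiny two-band volume series with known axial motion.
tiny_volume_phantom <- function() {
  fixture("tiny_volume_phantom", function() {
    build_phantom(n_cones = 60, radius = 4, px_per_arcmin = 5,
                  psf_sigma = 0.2, seed = 77)
  })
}

# One fixed retina (common stagger draw) imaged n_vol times through
# independent zero-mean axial motion traces; volume 1 gets a known sinusoid
# so its recovery can be scored against the truth.
make_volumes <- function(n_vol, stagger = 1.5, trace_amp = 3, seed = 1) {
  ph <- tiny_volume_phantom()
  ny <- nrow(ph$image)
  set.seed(seed)
  phases <- runif(n_vol, 0, 2 * pi)
  freqs <- runif(n_vol, 0.06, 0.2)
  lapply(seq_len(n_vol), function(i) {
    tr <- if (trace_amp > 0) {
      if (i == 1) trace_amp * sin(seq_len(ny) / 8) else
        trace_amp * sin(freqs[i] * seq_len(ny) + phases[i])
    } else NULL
    synth_volume(ph, band_depths_um = c(20, 45), stagger_rms = stagger,
                 axial_trace = tr, n_z = 64, seed = seed)
  })
}

# 50-volume series plus its axial lag-bias correction, shared by the
# volumetric tests and the acceptance suite.
axial_fixture <- function() {
  fixture("axial_fixture", function() {
    vols <- make_volumes(50, stagger = 1.5, trace_amp = 3, seed = 10)
    res <- axial_lag_bias_correct(vols, reference_index = 1, W = 7, k = 3,
                                  increment = 2, max_lag = 12)
    list(vols = vols, res = res)
  })
}
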