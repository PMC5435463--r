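test_that("stimuli translate in time along the motion direction", {
  spec <- stimulus_spec("moving_edge", direction = 0, speed = 2,
                        duration = 4)
  times <- seq(0, 4, by = 0.001)
  s0 <- sample_stimulus(spec, c(0, 0), times)
  s1 <- sample_stimulus(spec, c(1, 0), times)
  # a point 1 unit downstream sees the same edge 1/speed seconds later
  shift <- round(1 / 2 / 0.001)
  expect_equal(s1[(shift + 1):length(s1)],
               s0[1:(length(s0) - shift)])
  # edge crosses the origin at duration/2
  expect_equal(s0[times < 2][1], 0)
  expect_equal(s0[length(s0)], 1)
  # a point offset orthogonally sees the identical signal
  expect_equal(sample_stimulus(spec, c(0, 3), times), s0)
  expect_error(sample_stimulus(spec, c(0, 0), c(1, 0)), "increasing")
})

test_that("the low-pass delay has unit DC gain and the closed-form attenuation", {
  dt <- 5e-4; tau <- 0.15
  const <- lowpass(rep(2.5, 4000), tau, dt)
  expect_equal(const[4000], 2.5, tolerance = 1e-4)

  imp <- lowpass(c(1, rep(0, 999)), tau, dt)
  expect_equal(imp[2] / imp[1], exp(-dt / tau), tolerance = 1e-9)

  f <- 1  # Hz
  times <- seq(0, 6, by = dt)
  y <- lowpass(sin(2 * pi * f * times), tau, dt)
  gain <- max(y[times > 2]) # steady-state amplitude
  expect_equal(gain, 1 / sqrt(1 + (2 * pi * f * tau)^2), tolerance = 0.02)
})

test_that("the HR correlator is null for non-moving input and antisymmetric under swap", {
  cfg <- detector_config(c(0, 0), c(1, 0), model = "HR")
  # motion orthogonal to the channel separation: both channels see the same
  # signal, and the opponent product cancels exactly
  spec_orth <- stimulus_spec("drifting_sinusoid", direction = pi / 2,
                             speed = 4, duration = 3)
  expect_equal(detector_response(cfg, spec_orth), 0)

  spec <- stimulus_spec("drifting_sinusoid", direction = 0, speed = 4,
                        duration = 3)
  swapped <- detector_config(c(1, 0), c(0, 0), model = "HR")
  expect_equal(detector_response(cfg, spec),
               -detector_response(swapped, spec), tolerance = 1e-12)
  expect_gt(detector_response(cfg, spec), 0)
})

test_that("mirrored offsets with reversed motion give identical responses", {
  for (model in c("HR", "BL")) {
    cfg <- detector_config(c(-0.3, 0), c(0.4, 0), model = model)
    mir <- detector_config(c(0.3, 0), c(-0.4, 0), model = model)
    for (v in c(1, 4)) {
      spec_f <- stimulus_spec("moving_edge", direction = 0, speed = v,
                              duration = 6)
      spec_b <- stimulus_spec("moving_edge", direction = pi, speed = v,
                              duration = 6)
      expect_equal(detector_response(cfg, spec_f),
                   detector_response(mir, spec_b), tolerance = 1e-9)
    }
  }
})

test_that("an HR pair tuned to a drifting grating prefers the offset direction", {
  cfg <- detector_config(c(0, 0), c(1, 0), tau = 0.15, model = "HR")
  # 1 Hz temporal frequency: speed = period / 1 s; the HR pair prefers
  # motion from the delayed channel towards the non-delayed one (+x here)
  spec_pd <- stimulus_spec("drifting_sinusoid", direction = 0, speed = 4,
                           duration = 4, spatial_period = 4)
  spec_nd <- stimulus_spec("drifting_sinusoid", direction = pi, speed = 4,
                           duration = 4, spatial_period = 4)
  r_pd <- detector_response(cfg, spec_pd)
  r_nd <- detector_response(cfg, spec_nd)
  expect_equal(r_pd, -r_nd, tolerance = 1e-9)  # full opponency
  expect_gt(dsi(r_pd, r_nd), 0.2)
})

test_that("the direction selectivity index handles its boundary cases", {
  expect_equal(dsi(1, 1), 0)
  expect_equal(dsi(2, 0), 1)
  expect_equal(dsi(0, 2), -1)
  expect_equal(dsi(0.5, -0.5), 1)  # offset to non-negative first
  expect_error(dsi(0, 0), "degenerate")
})

test_that("anatomy-derived BL detectors prefer the excitatory-to-inhibitory direction", {
  # T4a-like anatomy: shaft (excitatory) centre ahead of the base
  # (inhibitory) centre along +x, so the PD points along -x
  cfg <- circuit_from_anatomy(excitatory = c(0.25, 0),
                              inhibitory = list(Mi4 = c(-0.25, 0),
                                                C3 = c(-0.2, 0)),
                              weights_inh = c(20, 10))
  expect_equal(attr(cfg, "predicted_pd"), pi)
  tun <- direction_tuning(cfg)
  expect_true(all(tun$r_pd > tun$r_nd))
  expect_true(all(tun$dsi > 0))

  # mirrored anatomy flips the preferred direction
  mir <- circuit_from_anatomy(excitatory = c(-0.25, 0),
                              inhibitory = c(0.233, 0))
  expect_equal(attr(mir, "predicted_pd"), 0)

  # no displacement, no selectivity
  expect_warning(
    zero <- circuit_from_anatomy(excitatory = c(0.1, 0),
                                 inhibitory = c(0.1, 0)),
    "coincide")
  tun0 <- direction_tuning(zero, pd = 0, speeds = c(1, 4))
  expect_true(all(abs(tun0$dsi) < 0.05))
})
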