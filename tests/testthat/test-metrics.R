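make_pulse_channels <- function(shifts_samples, f0 = 1.2e6, fs = 20e6,
                                nt = 1200, t0_frac = 0.45, noise = 0,
                                scale = rep(1, length(shifts_samples))) {
  dt <- 1 / fs
  tt <- (seq_len(nt) - 1) * dt
  sigma <- 2 / (2.355 * f0)
  tc <- t0_frac * nt * dt
  rf <- vapply(seq_along(shifts_samples), function(e) {
    ts <- tt - tc - shifts_samples[e] * dt
    scale[e] * sin(2 * pi * f0 * ts) * exp(-ts^2 / (2 * sigma^2))
  }, numeric(nt))
  xd <- transducer(n_elements = length(shifts_samples), pitch = 0.4e-3,
                   radius_of_curvature = 40e-3, f0 = f0)
  channel_data(rf + noise, dt = dt, transducer = xd,
               events = list(transmit_event(c(30e-3, 0),
                                            rep(0, length(shifts_samples)))),
               meta = list(apex_depth = 0, x_mid = 0))
}

test_that("adjacent-element lag estimation recovers known shifts", {
  # identical signals: lag 0, coefficient 1
  cd <- make_pulse_channels(c(0, 0, 0))
  lg <- interelement_lags(cd)
  expect_lt(max(abs(lg$lag)), 1e-4)
  expect_equal(lg$rho, c(1, 1), tolerance = 1e-6)

  # integer and fractional shifts recovered to 0.05 samples
  shifts <- c(0, 3, 3.6, 2.1, 2.35)
  cd2 <- make_pulse_channels(shifts)
  lg2 <- interelement_lags(cd2)
  expect_lt(max(abs(lg2$lag - diff(shifts))), 0.05)

  # positive per-channel scaling changes neither lag nor coefficient
  cd3 <- make_pulse_channels(shifts, scale = c(1, 0.2, 5, 1, 3))
  lg3 <- interelement_lags(cd3)
  expect_equal(lg3$lag, lg2$lag, tolerance = 1e-6)
  expect_equal(lg3$rho, lg2$rho, tolerance = 1e-4)

  # zero-variance window errors
  cdz <- make_pulse_channels(c(0, 0))
  cdz$rf[, 1, 1] <- 0
  expect_error(interelement_lags(cdz, window = c(1, 100)),
               "undefined-correlation")
})

test_that("arrival-time profiles integrate lags with mean removal", {
  p0 <- arrival_time_profile(rep(0, 7), 1e-8)
  expect_equal(p0$delays, rep(0, 8))

  p1 <- arrival_time_profile(rep(2, 7), 1e-8)
  expect_equal(mean(p1$delays), 0)
  expect_equal(diff(p1$delays), rep(2e-8, 7))

  expect_equal(rms_aberration(p1, p1), 0)
  p2 <- arrival_time_profile(rep(0, 9), 1e-8)
  expect_error(rms_aberration(p1, p2), "incompatibility")
})

test_that("rms aberration round-trips an injected phase screen", {
  fx <- fixture_tiny_echo()
  sub <- subtract_clutter(fx$full, fx$clutter)
  for (rms_req in c(20, 40)) {
    ab <- apply_phase_screen(sub, screen_rms = rms_req, corr_len = 5, seed = 3)
    est <- estimate_rms_aberration(ab, sub)
    expect_lt(abs(est - rms_req) / rms_req, 0.05)
  }
  # doubling the screen doubles the estimate
  ab1 <- apply_phase_screen(sub, 15, corr_len = 5, seed = 4)
  ab2 <- apply_phase_screen(sub, 30, corr_len = 5, seed = 4)
  e1 <- estimate_rms_aberration(ab1, sub)
  e2 <- estimate_rms_aberration(ab2, sub)
  expect_lt(abs(e2 / e1 - 2), 0.1)
})

test_that("reverberation curves follow log arithmetic", {
  img <- matrix(2.5, 64, 8)
  bm <- bmode_image(img, depth = seq_len(64) * 1e-4)
  rc <- reverberation_curve(bm)
  expect_lt(diff(range(rc$level)), 1e-9)          # uniform image: flat

  bm2 <- bm; bm2$image <- 2 * img
  rc2 <- reverberation_curve(bm2)
  expect_equal(rc2$level - rc$level, rep(20 * log10(2), 64))
})

test_that("coherence curves behave at their limits", {
  # identical channels: rho(m) = 1 for all m
  cd <- make_pulse_channels(rep(0, 8))
  cc <- coherence_curve(cd, window = c(400, 700), align = FALSE)
  expect_equal(cc$rho, rep(1, 8), tolerance = 1e-9)
  expect_equal(cc$rho[cc$lag == 0], 1)
  expect_equal(lag_one_coherence(cc), 1)

  # independent white noise: lag-one coherence near zero on average
  set.seed(99)
  n <- 400
  vals <- vapply(1:40, function(s) {
    rf <- matrix(rnorm(n * 6), n, 6)
    cdn <- channel_data(rf, dt = 5e-8,
                        transducer = transducer(n_elements = 6),
                        events = list(transmit_event(c(30e-3, 0), rep(0, 6))),
                        meta = list(apex_depth = 0, x_mid = 0))
    lag_one_coherence(coherence_curve(cdn, window = c(1, n), align = FALSE))
  }, 0)
  expect_lt(mean(abs(vals)), 3 / sqrt(n))

  # added uncorrelated noise lowers the lag-one coherence monotonically
  set.seed(7)
  locs <- vapply(c(0, 0.05, 0.2), function(nz) {
    mean(vapply(1:10, function(s) {
      set.seed(100 + s)
      cdn <- make_pulse_channels(rep(0, 8), noise = 0)
      cdn$rf <- cdn$rf + nz * array(rnorm(length(cdn$rf)), dim(cdn$rf))
      lag_one_coherence(coherence_curve(cdn, window = c(400, 700), align = FALSE))
    }, 0))
  }, 0)
  expect_true(all(diff(locs) < 0))

  expect_error(coherence_curve(cd, window = c(0, 50)), "range")
})

test_that("speckle brightness and CNR follow their definitions", {
  img <- matrix(-43, 40, 40)
  bm <- bmode_image(img, depth = seq_len(40) * 1e-4, is_log = TRUE,
                    norm_ref = "max")
  roi <- matrix(TRUE, 40, 40)
  expect_equal(speckle_brightness(bm, roi), -43)
  expect_error(speckle_brightness(bm, matrix(FALSE, 40, 40)), "ROI")

  # identical distributions in both masks: CNR 0, not detectable
  set.seed(5)
  v <- rnorm(1600, -30, 5)
  bm2 <- bmode_image(matrix(v, 40, 40), depth = seq_len(40) * 1e-4,
                     is_log = TRUE)
  les <- matrix(FALSE, 40, 40); les[, 1:20] <- TRUE
  bg <- !les
  same <- bm2
  same$image[les] <- same$image[bg]        # copy: identical samples
  r0 <- cnr(same, les, bg)
  expect_lt(r0$cnr, 0.1)
  expect_false(r0$detectable)

  # closed form: mean difference sigma with equal sigmas gives 1/sqrt(2)
  sigma <- 4
  a <- rnorm(20000, 0, sigma); b <- rnorm(20000, sigma, sigma)
  a <- (a - mean(a)) / sd(a) * sigma
  b <- (b - mean(b)) / sd(b) * sigma + sigma
  bm3 <- bmode_image(matrix(c(a, b), 200, 200), depth = seq_len(200) * 1e-4,
                     is_log = TRUE)
  les3 <- matrix(c(rep(TRUE, 20000), rep(FALSE, 20000)), 200, 200)
  r3 <- cnr(bm3, les3, !les3)
  expect_equal(r3$cnr, 1 / sqrt(2), tolerance = 1e-6)

  expect_error(cnr(bm3, les3, les3), "mask")
})

test_that("speckle brightness rises with scatterer contrast", {
  pr <- tiny_profile(f0 = 1.0e6)
  xd <- pr$transducer
  dx <- 1450 / 1.0e6 / 12
  base <- tiny_homog_maps(depth = 34e-3, width = 30e-3, dx = dx)
  apex <- tiny_apex(base, xd, pr$config)
  cfg <- pr$config; cfg$apex_depth <- apex
  co <- map_coords(base)
  x_mid <- (min(co$x) + max(co$x)) / 2
  focus <- c(apex + 18e-3, x_mid)
  ev <- transmit_event(focus, focusing_delays(xd, focus, 1540, apex, x_mid))
  ev$theta <- 0
  rc <- resolution_cell_area(xd, 18e-3, 1570)
  bright <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(ct) {
    m <- add_scatterers(base, scatterer_spec(18, ct, rc, 11))
    cd <- simulate_transmit(m, xd, ev, cfg)
    cd$events[[1]]$theta <- 0
    bm <- envelope_logcompress(das_beamform(cd, c_bf = 1540), "none")
    roi <- abs(bm$depth - 18e-3) < 4e-3
    speckle_brightness(bm, matrix(roi, length(bm$depth), 1))
  }, 0)
  expect_true(all(diff(bright) > 0))
})
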