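test_that("phase screens are exact in RMS, invertible, and seeded", {
  cd <- synthetic_echo_channels()
  # zero request returns the input exactly
  s0 <- apply_phase_screen(cd, 0)
  expect_identical(s0$rf, cd$rf)

  s1 <- apply_phase_screen(cd, 25, corr_len = 5, seed = 12)
  # applied screen has exactly the requested RMS, zero mean
  scr <- s1$meta$phase_screen
  expect_equal(sqrt(mean(scr^2)) * 1e9, 25, tolerance = 1e-9)
  expect_equal(mean(scr), 0, tolerance = 1e-20)
  # deterministic per seed
  s1b <- apply_phase_screen(cd, 25, corr_len = 5, seed = 12)
  expect_identical(s1$rf, s1b$rf)
  s2 <- apply_phase_screen(cd, 25, corr_len = 5, seed = 13)
  expect_false(identical(s1$rf, s2$rf))
  # inverted exactly by the negated screen
  inv <- apply_phase_screen(s1, screen = -scr)
  expect_lt(max(abs(inv$rf - cd$rf)), 1e-10 * max(abs(cd$rf)))
  # sanity bound on the request
  expect_error(apply_phase_screen(cd, 1e7), "sanity")
})

test_that("reverberation scaling interpolates between identity and subtraction", {
  fx <- fixture_tiny_echo()
  expect_identical(scale_reverberation(fx$full, fx$clutter, 0)$rf, fx$full$rf)
  s1 <- scale_reverberation(fx$full, fx$clutter, 1)
  expect_equal(s1$rf, subtract_clutter(fx$full, fx$clutter)$rf)
  expect_error(scale_reverberation(fx$full, fx$clutter, 1.5), "beta")
  bad <- fx$clutter; bad$dt <- bad$dt * 2
  expect_error(scale_reverberation(fx$full, bad, 0.5), "incompatibility")
})

test_that("pre-target clutter level decreases monotonically in beta", {
  st <- fixture_psf_study()
  d2 <- st$depth[[2]]
  depth_t <- d2$event$focus[1] - st$geometry$apex
  lv <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(b) {
    sc <- scale_reverberation(d2$full, d2$clutter, b)
    bm <- envelope_logcompress(das_beamform(sc, c_bf = 1540), "none")
    rc <- reverberation_curve(bm)
    sel <- rc$depth > 14e-3 & rc$depth < depth_t - 8e-3
    mean(rc$level[sel])
  }, 0)
  expect_true(all(diff(lv) < 0))
})

test_that("trailing kernels are causal identities at zero strength", {
  cd <- synthetic_echo_channels()
  expect_identical(add_trailing_clutter(cd, 0, 0.5), cd)
  expect_identical(add_trailing_clutter(cd, 150, 0), cd)
  expect_error(add_trailing_clutter(cd, -1, 0.5), "parameter")

  # causality: an impulse input gains no energy before its onset
  imp <- cd
  imp$rf[] <- 0
  i0 <- 300
  imp$rf[i0, , 1] <- 1
  tr <- add_trailing_clutter(imp, 200, 0.5)
  expect_lt(max(abs(tr$rf[seq_len(i0 - 1), , 1])),
            1e-12 * max(abs(tr$rf)))
  expect_gt(sum(abs(tr$rf[(i0 + 1):dim(tr$rf)[1], , 1])), 0)
})

test_that("echo duration grows monotonically with the trailing decay time", {
  cd <- synthetic_echo_channels()
  dur20 <- function(x, dt) {
    env <- Mod(usdecon:::analytic_signal(x))
    above <- which(env >= 0.1 * max(env))    # -20 dB span
    (max(above) - min(above)) * dt
  }
  durs <- vapply(c(50, 150, 250), function(tau) {
    tr <- add_trailing_clutter(cd, tau, 0.8)
    dur20(tr$rf[, 16, 1], tr$dt)
  }, 0)
  expect_true(all(diff(durs) > 0))
  expect_gt(durs[1], dur20(cd$rf[, 16, 1], cd$dt) - 1e-12)
})

test_that("trailing isolation scales only the post-pulse segment", {
  cd <- synthetic_echo_channels()
  # give the echo a synthetic trailing tail so there is something to scale
  cdt <- add_trailing_clutter(cd, 250, 0.6)
  ref <- pulse_waveform(cd$transducer, cd$dt)$w

  expect_identical(isolate_and_scale_trailing(cdt, ref, 1), cdt)

  s0 <- isolate_and_scale_trailing(cdt, ref, 0)
  s2 <- isolate_and_scale_trailing(cdt, ref, 2)
  env <- Mod(usdecon:::analytic_signal(cdt$rf[, 10, 1]))
  pk <- which.max(env)
  # emission support after its peak, at the default 1% level
  env_ref <- Mod(usdecon:::analytic_signal(ref))
  tail_start <- pk + (max(which(env_ref >= 0.01 * max(env_ref))) -
                        which.max(env_ref)) + 1L
  nt <- length(env)
  tail_idx <- tail_start:nt
  head_idx <- seq_len(tail_start - 1L)
  expect_equal(sum(s0$rf[tail_idx, 10, 1]^2), 0)
  expect_equal(s2$rf[tail_idx, 10, 1], 2 * cdt$rf[tail_idx, 10, 1])
  expect_equal(s2$rf[head_idx, 10, 1], cdt$rf[head_idx, 10, 1],
               tolerance = 1e-12)
  r2 <- sqrt(mean(s2$rf[tail_idx, 10, 1]^2)) /
    sqrt(mean(cdt$rf[tail_idx, 10, 1]^2))
  expect_equal(r2, 2, tolerance = 1e-9)
})

test_that("augmentations are independent and composable at small magnitude", {
  st <- fixture_psf_study()
  d2 <- st$depth[[2]]
  depth_t <- d2$event$focus[1] - st$geometry$apex
  sub <- subtract_clutter(d2$full, d2$clutter)
  ref <- subtract_clutter(st$depth[[2]]$homog, st$depth[[2]]$homog_clutter)

  # a phase screen changes the aberration estimate but not the pre-target
  # reverberation curve by more than 1 dB
  scr <- apply_phase_screen(d2$full, 20, seed = 2)
  curve_of <- function(cd) {
    bm <- envelope_logcompress(das_beamform(cd, c_bf = 1540), "none")
    rc <- reverberation_curve(bm)
    rc$level[rc$depth > 14e-3 & rc$depth < depth_t - 8e-3]
  }
  expect_lt(abs(mean(curve_of(scr)) - mean(curve_of(d2$full))), 1)

  # reverberation scaling leaves the clutter-subtracted aberration
  # estimate within 10%
  # correlation window centered on the echo (the estimator needs the
  # target wavepacket, not the transmit crosstalk)
  e_env <- Mod(usdecon:::analytic_signal(sub$rf[, 32, 1]))
  ctr <- which.max(e_env)
  hw <- round(6e-6 / sub$dt)
  win <- c(max(1, ctr - hw), min(dim(sub$rf)[1], ctr + hw))
  est0 <- estimate_rms_aberration(sub, ref, window = win)
  half <- scale_reverberation(d2$full, d2$clutter, 0.5)
  est1 <- estimate_rms_aberration(half, ref, window = win)
  expect_lt(abs(est1 - est0) / est0, 0.1)

  # small-magnitude augmentations commute within 1% RMS
  a <- add_trailing_clutter(apply_phase_screen(d2$full, 10, seed = 5),
                            100, 0.05)
  b <- apply_phase_screen(add_trailing_clutter(d2$full, 100, 0.05),
                          10, seed = 5)
  expect_lt(sqrt(mean((a$rf - b$rf)^2)) / sqrt(mean(d2$full$rf^2)), 0.01)
})
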