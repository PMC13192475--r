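test_that("point-target echo arrives at the two-way travel time", {
  fx <- fixture_tiny_echo()
  xd <- fx$profile$transducer
  e_mid <- xd$n_elements %/% 2
  rf <- fx$full$rf[, e_mid, 1]
  env <- Mod(usdecon:::analytic_signal(rf))
  tt <- (seq_along(rf) - 1) * fx$full$dt
  # geometric expectation: focal arrival + return to the element, plus the
  # emission envelope peak offset
  pos <- element_positions(xd, fx$apex, fx$x_mid)
  d <- sqrt((pos[, 1] - fx$event$focus[1])^2 + (pos[, 2] - fx$event$focus[2])^2)
  t_exp <- max(fx$event$delays + d / 1570) + d[e_mid] / 1570 +
    3 * xd$n_cycles / (2.355 * xd$f0)
  # wavepacket onset (first half-max crossing after the crosstalk dies)
  sel <- tt > 0.6 * t_exp
  th <- 0.5 * max(env[sel])
  t_onset <- tt[sel][which(env[sel] >= th)[1]]
  expect_lt(abs(t_onset - t_exp), 1 / xd$f0)
})

test_that("the solver is linear in the source amplitude", {
  fx <- fixture_tiny_echo()
  ev_half <- fx$event
  ev_half$apodization <- fx$event$apodization / 2
  mt <- add_point_target(fx$maps, target_spec(fx$event$focus, 0.5))
  cd_half <- simulate_transmit(mt, fx$profile$transducer, ev_half, fx$config)
  expect_lt(max(abs(cd_half$rf - fx$full$rf / 2)), 1e-7 * max(abs(fx$full$rf)))
})

test_that("a homogeneous medium without target is quiet after the crosstalk", {
  fx <- fixture_tiny_echo()
  rf <- fx$clutter$rf[, 16, 1]
  env <- Mod(usdecon:::analytic_signal(rf))
  tt <- (seq_along(rf) - 1) * fx$clutter$dt
  t_cross <- 2 * fx$apex / 1570 + 6e-6
  expect_lt(20 * log10(max(env[tt > t_cross]) / max(env[tt <= t_cross])), -40)
})

test_that("clutter pairs are exactly matched", {
  fx <- fixture_tiny_echo()
  # reflectivity 0: the pair is identical
  pr <- clutter_pair(fx$maps, target_spec(fx$event$focus, 0),
                     fx$profile$transducer, fx$event, fx$config)
  expect_identical(pr$full$rf, pr$clutter$rf)

  # nonzero target: difference is causal (zero before the two-way horizon)
  dif <- fx$full$rf - fx$clutter$rf
  tt <- (seq_len(dim(dif)[1]) - 1) * fx$full$dt
  pos <- element_positions(fx$profile$transducer, fx$apex, fx$x_mid)
  d <- sqrt((pos[, 1] - fx$event$focus[1])^2 + (pos[, 2] - fx$event$focus[2])^2)
  horizon <- 2 * min(d) / 1570
  expect_lt(max(abs(dif[tt < 0.95 * horizon, , 1])),
            1e-6 * max(abs(dif)))
  # and contains a pulse at the target's two-way time
  e_mid <- 16
  env <- Mod(usdecon:::analytic_signal(dif[, e_mid, 1]))
  t_pk <- tt[which.max(env)]
  t_exp <- max(fx$event$delays + d / 1570) + d[e_mid] / 1570 +
    3 * 2 / (2.355 * fx$profile$transducer$f0)
  expect_lt(abs(t_pk - t_exp), 2.5 / fx$profile$transducer$f0)
})

test_that("stability and geometry violations raise errors", {
  expect_error(sim_config(cfl = 0.9), "stability")
  pr <- tiny_profile()
  maps <- tiny_homog_maps(dx = pr$dx)
  # frequency too high for the grid: points-per-wavelength check
  xd_hi <- transducer(n_elements = 32, pitch = 0.5e-3,
                      radius_of_curvature = 40e-3, f0 = 3 * pr$transducer$f0)
  ev <- transmit_event(c(20e-3, 17e-3), rep(0, 32))
  expect_error(simulate_transmit(maps, xd_hi, ev, pr$config), "wavelength")
  # transducer arc not inside the grid
  small <- tiny_homog_maps(depth = 4e-3, width = 4e-3, dx = pr$dx)
  expect_error(simulate_transmit(small, pr$transducer, ev, pr$config),
               "domain|fit")
})

test_that("scattered amplitude is linear in the impedance contrast", {
  fx <- fixture_tiny_echo()
  # fractional impedance perturbations up to 0.1; the reflectivity
  # realizing contrast c is c / (2 + c), and the first-order scattering
  # kernel for a density fluctuation is (rho1 - rho0) / rho1 = c / (1 + c)
  contrasts <- c(0.02, 0.05, 0.1)
  amps <- vapply(contrasts / (2 + contrasts), function(rr) {
    pr <- clutter_pair(fx$maps, target_spec(fx$event$focus, rr),
                       fx$profile$transducer, fx$event, fx$config)
    sqrt(sum((pr$full$rf - pr$clutter$rf)^2))
  }, 0)
  ratio <- amps / (contrasts / (1 + contrasts))
  expect_lt(diff(range(ratio)) / mean(ratio), 0.05)
})

test_that("reciprocity holds between a source and a receiver element", {
  pr <- tiny_profile()
  dx <- pr$dx
  nz <- round(30e-3 / dx); nx <- round(30e-3 / dx)
  set.seed(31)
  cmap <- matrix(1570, nz, nx)
  rmap <- matrix(1064, nz, nx)
  # a few localized heterogeneities between the elements
  rmap[round(nz / 2) + (-1:1), round(nx / 2) + (-1:1)] <- 1300
  maps <- acoustic_maps(cmap, rmap, dx)
  xd <- pr$transducer
  one_hot <- function(i) { a <- rep(0, xd$n_elements); a[i] <- 1; a }
  cfg <- pr$config
  ev_a <- transmit_event(c(20e-3, 15e-3), rep(0, xd$n_elements), one_hot(5))
  ev_b <- transmit_event(c(20e-3, 15e-3), rep(0, xd$n_elements), one_hot(28))
  cd_a <- simulate_transmit(maps, xd, ev_a, cfg)   # fire 5, listen on 28
  cd_b <- simulate_transmit(maps, xd, ev_b, cfg)   # fire 28, listen on 5
  x <- cd_a$rf[, 28, 1]; y <- cd_b$rf[, 5, 1]
  expect_lt(sqrt(mean((x - y)^2)) / sqrt(mean(x^2)), 0.01)
})

test_that("halving the grid spacing leaves the echo arrival in place", {
  # geometry-exact configuration so refinement changes only the numerical
  # scheme: linear array on a grid row, plane-wave transmit, and a planar
  # reflector at a depth commensurate with both grids
  f0 <- 0.5e6
  dx0 <- 1570 / f0 / 12
  apex <- 24 * dx0
  depth_r <- 40 * dx0                      # reflector depth below the array
  run <- function(ppw) {
    dx <- 1570 / f0 / ppw
    xd <- transducer(n_elements = 16, pitch = 0.8e-3,
                     radius_of_curvature = Inf, f0 = f0, n_cycles = 2,
                     dt_rf = 1 / (12 * f0))
    cfg <- sim_config(boundary_width = round(20 * dx0 / dx),
                      apex_depth = apex)
    maps <- tiny_homog_maps(depth = apex + depth_r + 8e-3, width = 26e-3,
                            dx = dx)
    co <- map_coords(maps)
    x_mid <- (min(co$x) + max(co$x)) / 2
    ev <- transmit_event(c(apex + depth_r, x_mid), rep(0, 16))
    i_r <- round((apex + depth_r) / dx) + 1L
    maps_r <- maps
    maps_r$rho[i_r, ] <- maps$rho[i_r, ] * 1.3
    full <- simulate_transmit(maps_r, xd, ev, cfg, x_mid = x_mid)
    none <- simulate_transmit(maps, xd, ev, cfg, x_mid = x_mid)
    list(x = rowSums(full$rf[, , 1] - none$rf[, , 1]), dt = full$dt)
  }
  a <- run(12)
  b <- run(24)
  expect_equal(a$dt, b$dt, tolerance = 1e-12)
  # sub-sample arrival difference via the cross-correlation peak
  n <- min(length(a$x), length(b$x))
  U <- 8
  xu <- usdecon:::fft_upsample(a$x[1:n], U)
  yu <- usdecon:::fft_upsample(b$x[1:n], U)
  lags <- seq(-40 * U, 40 * U)
  cc <- vapply(lags, function(l) {
    i <- seq_len(n * U - abs(l))
    if (l >= 0) stats::cor(xu[i + l], yu[i]) else stats::cor(xu[i], yu[i - l])
  }, 0)
  k <- which.max(cc)
  shift <- lags[k]
  if (k > 1 && k < length(cc)) {
    den <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
    if (den < 0) shift <- shift + 0.5 * (cc[k - 1] - cc[k + 1]) / den
  }
  expect_lt(abs(shift / U * a$dt), 0.1 / f0)
})
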