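# Shared fixtures, built once per test run and cached.
#
# The small fixtures use a deliberately coarse profile (low frequency,
# small domain) so each simulation takes well under a second; the study
# fixtures run the package's canonical desk-scale experiments and are the
# expensive part of the suite.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# tiny transducer/domain for fast solver tests
tiny_profile <- function(f0 = 0.6e6) {
  xd <- transducer(n_elements = 32, pitch = 0.5e-3,
                   radius_of_curvature = 40e-3, f0 = f0, n_cycles = 2)
  dx <- 1450 / f0 / 12
  list(transducer = xd, dx = dx, config = sim_config(boundary_width = 30L))
}

tiny_homog_maps <- function(depth = 34e-3, width = 34e-3, dx,
                            c0 = 1570, rho0 = 1064) {
  nz <- round(depth / dx); nx <- round(width / dx)
  acoustic_maps(matrix(c0, nz, nx), matrix(rho0, nz, nx), dx)
}

tiny_apex <- function(maps, xd, cfg) {
  sag <- xd$roc * (1 - cos((xd$n_elements / 2) * xd$pitch / xd$roc))
  (cfg$boundary_width + 4) * maps$dx + sag
}

# single focused transmit on a homogeneous medium with a point target
fixture_tiny_echo <- function() {
  fixture("tiny_echo", function() {
    pr <- tiny_profile()
    maps <- tiny_homog_maps(dx = pr$dx)
    apex <- tiny_apex(maps, pr$transducer, pr$config)
    cfg <- pr$config; cfg$apex_depth <- apex
    co <- map_coords(maps)
    x_mid <- (min(co$x) + max(co$x)) / 2
    depth_t <- 18e-3
    focus <- c(apex + depth_t, x_mid)
    delays <- focusing_delays(pr$transducer, focus, 1540, apex, x_mid)
    ev <- transmit_event(focus, delays)
    pair <- clutter_pair(maps, target_spec(focus, 0.5), pr$transducer, ev, cfg)
    list(profile = pr, maps = maps, apex = apex, x_mid = x_mid,
         depth_t = depth_t, event = ev, config = cfg,
         full = pair$full, clutter = pair$clutter)
  })
}

# the canonical separation study (wall + targets), shared by the
# separation and acceptance tests
fixture_psf_study <- function() {
  fixture("psf_study", function()
    psf_separation_study(reflectivities = c(0.93, 0.74, 0.5, 0.32, 0.09, 0.05)))
}

# the canonical anechoic-lesion study (10 speckle realizations)
fixture_lesion_study <- function() {
  fixture("lesion_study", function() lesion_cnr_study(n_seeds = 10, seed = 1))
}

# synthetic band-limited echo channel data at a clinical-scale sampling,
# for augmentation tests that need no solver
synthetic_echo_channels <- function(n_elements = 32, f0 = 3.7e6,
                                    fs = 40e6, t_echo = 30e-6,
                                    dur = 60e-6, noise = 0) {
  dt <- 1 / fs
  nt <- round(dur / dt)
  tt <- (seq_len(nt) - 1) * dt
  sigma <- 2 / (2.355 * f0)
  w <- sin(2 * pi * f0 * (tt - t_echo)) * exp(-(tt - t_echo)^2 / (2 * sigma^2))
  rf <- matrix(rep(w, n_elements), ncol = n_elements)
  if (noise > 0) rf <- rf + noise * matrix(stats::rnorm(length(rf)), nrow(rf))
  xd <- transducer(n_elements = n_elements, pitch = 0.508e-3,
                   radius_of_curvature = 50e-3, f0 = f0, n_cycles = 2)
  channel_data(rf, dt = dt, t0 = 0, transducer = xd,
               events = list(transmit_event(c(30e-3, 0), rep(0, n_elements))),
               meta = list(apex_depth = 0, x_mid = 0))
}
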