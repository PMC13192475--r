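#' Simulation configuration
#'
#' Numerical controls for the desk-scale 2D linear acoustic solver: grid
#' spacing is inherited from the acoustic maps; the Courant number `cfl`
#' must satisfy the 2D stability bound (<= 0.7; default 0.5); `duration` of
#' `NULL` records until the slowest two-way travel time to the bottom of
#' the grid plus the pulse length; `boundary_width` is the thickness of the
#' exponentially tapered absorbing sponge in pixels (normal-incidence
#' reflection at least 40 dB down); `apex_depth` places the transducer arc
#' apex (default just below the top sponge).
#'
#' @param cfl Courant number (dimensionless).
#' @param duration simulated time (s) or `NULL`.
#' @param boundary_width sponge thickness (pixels).
#' @param apex_depth arc apex depth (m) or `NULL` for automatic placement.
#' @param sponge_strength per-step damping coefficient of the sponge taper.
#' @param min_ppw minimum points per wavelength enforced at `f0` in the
#'   slowest medium.
#' @export
sim_config <- function(cfl = 0.5, duration = NULL, boundary_width = 40L,
                       apex_depth = NULL, sponge_strength = 0.12,
                       min_ppw = 10) {
  if (cfl <= 0 || cfl > 0.7)
    stop("stability error: cfl must be in (0, 0.7]")
  structure(list(cfl = cfl, duration = duration,
                 boundary_width = as.integer(boundary_width),
                 apex_depth = apex_depth,
                 sponge_strength = sponge_strength, min_ppw = min_ppw),
            class = "sim_config")
}

#' RF channel data
#'
#' Container for received RF traces: `rf` is a time x element x transmit
#' array (arbitrary pressure units), `dt` the sampling period, `t0` the
#' time of the first sample relative to the transmit trigger (the firing of
#' the earliest-firing element).
#'
#' @param rf numeric array `time x element x transmit` (a matrix is
#'   promoted to a single transmit).
#' @param dt sampling period (s).
#' @param t0 time of first sample (s).
#' @param transducer a [transducer()] object.
#' @param events list of [transmit_event()]s, one per transmit.
#' @param meta named list of provenance (grid, seed, placement, ...).
#' @export
channel_data <- function(rf, dt, t0 = 0, transducer = NULL, events = list(),
                         meta = list()) {
  if (is.matrix(rf)) rf <- array(rf, c(dim(rf), 1L))
  if (length(dim(rf)) != 3) stop("rf must be a time x element x transmit array")
  if (dt <= 0) stop("parameter error: dt must be positive")
  if (any(!is.finite(rf))) stop("rf contains non-finite values")
  structure(list(rf = rf, dt = dt, t0 = t0, transducer = transducer,
                 events = events, meta = meta),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  d <- dim(x$rf)
  cat(sprintf("<channel_data> %d samples x %d elements x %d transmits, dt = %.3g ns\n",
              d[1], d[2], d[3], x$dt * 1e9))
  invisible(x)
}

# element footprint pixels on the map grid; returns 0-based linear indices
# plus 0-based element ids, and the apex placement actually used
element_pixels <- function(maps, transducer, apex_depth, x_mid) {
  dx <- maps$dx
  nz <- nrow(maps$c); nx <- ncol(maps$c)
  R <- transducer$roc
  n <- transducer$n_elements
  idx <- integer(0); elem <- integer(0)
  sub <- max(3L, ceiling(transducer$pitch / (dx / 2)))
  for (e in seq_len(n)) {
    off <- ((e - (n + 1) / 2) + seq(-0.5, 0.5, length.out = sub)) *
      transducer$pitch
    if (is.infinite(R)) {
      z <- rep(apex_depth, sub)
      x <- x_mid + off
    } else {
      ths <- off / R
      z <- apex_depth - R * (1 - cos(ths))
      x <- x_mid + R * sin(ths)
    }
    i <- round((z - maps$origin[1]) / dx) + 1L
    j <- round((x - maps$origin[2]) / dx) + 1L
    ok <- i >= 1 & i <= nz & j >= 1 & j <= nx
    if (!all(ok))
      stop("domain error: transducer arc does not fit in the map grid")
    lin <- unique((j[ok] - 1L) * nz + (i[ok] - 1L))
    idx <- c(idx, lin)
    elem <- c(elem, rep(e - 1L, length(lin)))
  }
  list(idx = idx, elem = elem)
}

sponge_taper <- function(n, width, strength) {
  tp <- rep(1, n)
  if (width > 0 && n > 2 * width) {
    x <- seq_len(width) / width          # 0 -> 1 toward the boundary
    prof <- exp(-strength * x^2)         # per-step damping factor
    tp[width:1] <- prof                  # outermost pixel most damped
    tp[(n - width + 1):n] <- prof
  }
  tp
}

default_apex_depth <- function(maps, transducer, config) {
  sag <- if (is.infinite(transducer$roc)) 0 else
    transducer$roc * (1 - cos((transducer$n_elements / 2) *
                              transducer$pitch / transducer$roc))
  (config$boundary_width + 4) * maps$dx + sag
}

#' Simulate one focused transmit-receive event
#'
#' Propagates a delayed, apodized Gaussian-windowed pulse from the curved
#' array through the heterogeneous `(c, rho)` maps with the staggered-grid
#' pressure-velocity solver, and records the mean pressure over each
#' element's footprint.  Linear and lossless; deterministic for fixed
#' inputs.  The record is decimated to the transducer's RF sampling period
#' with a zero-phase anti-alias filter.
#'
#' @param maps an [acoustic_maps()] object (its `dx` is the solver grid).
#' @param transducer a [transducer()] object.
#' @param event a [transmit_event()].
#' @param config a [sim_config()].
#' @param x_mid lateral position of the arc apex (m); default grid center.
#' @return a [channel_data()] with one transmit.
#' @export
simulate_transmit <- function(maps, transducer, event, config = sim_config(),
                              x_mid = NULL) {
  stopifnot(inherits(maps, "acoustic_maps"), inherits(transducer, "transducer"),
            inherits(event, "transmit_event"), inherits(config, "sim_config"))
  dx <- maps$dx
  cmin <- min(maps$c); cmax <- max(maps$c)
  ppw <- cmin / (transducer$f0 * dx)
  if (ppw < config$min_ppw - 1e-9)
    stop(sprintf("stability error: %.1f points per wavelength < required %g",
                 ppw, config$min_ppw))
  dt <- config$cfl * dx / cmax
  if (dt * cmax / dx > 1 / sqrt(2) + 1e-12)
    stop("stability error: CFL condition violated")
  co <- map_coords(maps)
  if (is.null(x_mid)) x_mid <- (min(co$x) + max(co$x)) / 2
  apex <- if (is.null(config$apex_depth))
    default_apex_depth(maps, transducer, config) else config$apex_depth
  dur <- if (is.null(config$duration)) {
    2 * (max(co$z) - apex) / cmin + 3 * transducer$n_cycles / transducer$f0
  } else config$duration
  nsteps <- ceiling(dur / dt)
  px <- element_pixels(maps, transducer, apex, x_mid)
  # per-element waveforms with exact (sub-sample) delays
  sigma <- transducer$n_cycles / (2.355 * transducer$f0)
  t_peak <- 3 * sigma
  tt <- (seq_len(nsteps) - 1) * dt
  wave <- matrix(0, nsteps, transducer$n_elements)
  for (e in seq_len(transducer$n_elements)) {
    tc <- tt - event$delays[e] - t_peak
    wave[, e] <- event$apodization[e] * sin(2 * pi * transducer$f0 * tc) *
      exp(-tc^2 / (2 * sigma^2))
  }
  tr <- sponge_taper(nrow(maps$c), config$boundary_width, config$sponge_strength)
  tc_ <- sponge_taper(ncol(maps$c), config$boundary_width, config$sponge_strength)
  rec <- fdtd_run_cpp(maps$c, maps$rho, dx, dt, nsteps,
                      px$idx, px$elem, wave, px$idx, px$elem,
                      transducer$n_elements, tr, tc_)
  # decimate to the RF sampling period
  dt_rf <- if (is.null(transducer$dt_rf)) 1 / (12 * transducer$f0)
           else transducer$dt_rf
  q <- max(1L, round(dt_rf / dt))
  if (q > 1L) {
    # zero-phase anti-alias filtering (forward-backward FIR), so the
    # decimation introduces no group delay into the RF timing
    b <- signal::fir1(30, 0.9 / q)
    rec <- apply(rec, 2, function(x)
      signal::filtfilt(b, x)[seq(1, length(x), by = q)])
    dt <- dt * q
  }
  channel_data(rec, dt = dt, t0 = 0, transducer = transducer,
               events = list(event),
               meta = list(dx = dx, apex_depth = apex, x_mid = x_mid,
                           cfl = config$cfl, duration = dur,
                           boundary_width = config$boundary_width))
}

#' Matched full / clutter simulation pair
#'
#' Runs two simulations differing only by the presence of the imaging
#' target: the full medium with the target, and the identical medium with
#' the target removed, so that their sample-wise difference isolates the
#' target-path signal (ballistic pulse plus trailing clutter) from multiple
#' reverberation.
#'
#' @param maps target-free `acoustic_maps`.
#' @param target a [target_spec()] inserted for the full run.
#' @param transducer,event,config,x_mid as in [simulate_transmit()].
#' @return list with elements `full` and `clutter` ([channel_data()]s).
#' @export
clutter_pair <- function(maps, target, transducer, event,
                         config = sim_config(), x_mid = NULL) {
  full <- simulate_transmit(add_point_target(maps, target), transducer,
                            event, config, x_mid)
  clutter <- simulate_transmit(maps, transducer, event, config, x_mid)
  list(full = full, clutter = clutter)
}

#' Simulate a focused sector-scan sequence
#'
#' Runs one focused transmit-receive event per scan line, with foci placed
#' on the focal arc at a constant line spacing following the array
#' curvature, and concatenates the received data into a single
#' [channel_data()] (time x element x transmit).
#'
#' @param maps an [acoustic_maps()] object.
#' @param transducer a [transducer()] object.
#' @param focal_depth transmit focal depth below the array surface (m).
#' @param n_lines number of scan lines / transmits (default 64).
#' @param line_spacing focus spacing along the focal arc (m).
#' @param config a [sim_config()].
#' @param c_assumed delay-computation speed (m/s).
#' @param x_mid lateral apex position (m); default grid center.
#' @param apodization per-element transmit weights.
#' @return a [channel_data()] with `n_lines` transmits; each event carries
#'   its line angle in `$theta`.
#' @export
scan_sequence <- function(maps, transducer, focal_depth, n_lines = 64,
                          line_spacing = 0.45e-3, config = sim_config(),
                          c_assumed = 1540, x_mid = NULL,
                          apodization = NULL) {
  co <- map_coords(maps)
  if (is.null(x_mid)) x_mid <- (min(co$x) + max(co$x)) / 2
  apex <- if (is.null(config$apex_depth))
    default_apex_depth(maps, transducer, config) else config$apex_depth
  config$apex_depth <- apex
  dtheta <- line_spacing / (transducer$roc + focal_depth)
  thetas <- (seq_len(n_lines) - (n_lines + 1) / 2) * dtheta
  out_rf <- NULL
  events <- vector("list", n_lines)
  for (k in seq_len(n_lines)) {
    fp <- scanline_points(transducer, thetas[k], focal_depth, apex, x_mid)
    delays <- focusing_delays(transducer, fp[1, ], c_assumed, apex, x_mid)
    ev <- transmit_event(fp[1, ], delays, apodization)
    ev$theta <- thetas[k]
    cd <- simulate_transmit(maps, transducer, ev, config, x_mid)
    if (is.null(out_rf))
      out_rf <- array(0, c(dim(cd$rf)[1:2], n_lines))
    out_rf[, , k] <- cd$rf[, , 1]
    events[[k]] <- ev
    last <- cd
  }
  channel_data(out_rf, dt = last$dt, t0 = 0, transducer = transducer,
               events = events, meta = last$meta)
}
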