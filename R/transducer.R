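#' Curved-array transducer geometry and pulse definition
#'
#' Describes a convex (curved) array by its element count, pitch along the
#' arc, and radius of curvature, together with the transmit pulse (center
#' frequency and cycle count) and the RF sampling period.  The element arc
#' is placed with its apex (deepest point) at a configurable depth inside
#' the simulation grid; the center of curvature sits behind the array, so
#' scan lines radiate from it through the elements into the tissue.
#'
#' The clinical reference configuration this emulates is an abdominal
#' curved array with 0.508 mm pitch driven by a 3.7 MHz 2-cycle focused
#' emission; the desk-scale default is a 64-element, 0.4 mm pitch, 40 mm
#' radius array at 1.2 MHz so that a transmit simulation completes in
#' seconds.
#'
#' @param n_elements number of elements (>= 2).
#' @param pitch element spacing along the arc (m).
#' @param radius_of_curvature arc radius (m); `Inf` gives a linear array.
#' @param f0 pulse center frequency (Hz).
#' @param n_cycles pulse length in cycles.
#' @param dt_rf RF sampling period (s); `NULL` lets the simulator pick a
#'   period of about 1/(12 f0) by decimation.
#' @return object of class `transducer`.
#' @export
transducer <- function(n_elements = 64, pitch = 0.4e-3,
                       radius_of_curvature = 40e-3,
                       f0 = 1.2e6, n_cycles = 2, dt_rf = NULL) {
  if (n_elements < 2) stop("parameter error: n_elements must be >= 2")
  if (pitch <= 0 || f0 <= 0) stop("parameter error: pitch and f0 must be positive")
  structure(list(n_elements = as.integer(n_elements), pitch = pitch,
                 roc = radius_of_curvature, f0 = f0, n_cycles = n_cycles,
                 dt_rf = dt_rf),
            class = "transducer")
}

#' @export
print.transducer <- function(x, ...) {
  cat(sprintf("<transducer> %d elements, pitch %.3g mm, ROC %.3g mm, %.2f MHz x %g cycles\n",
              x$n_elements, x$pitch * 1e3, x$roc * 1e3, x$f0 / 1e6, x$n_cycles))
  invisible(x)
}

#' Element center positions
#'
#' Positions of the element centers on the arc, in `(z, x)` coordinates
#' with the arc apex at depth `apex_depth` on the lateral midline `x_mid`.
#' Edge elements curve back up (shallower) as on a convex probe.
#'
#' @param transducer a [transducer()] object.
#' @param apex_depth depth of the arc apex (m).
#' @param x_mid lateral coordinate of the apex (m).
#' @return matrix `n_elements x 2` of `(z, x)` (m).
#' @export
element_positions <- function(transducer, apex_depth = 0, x_mid = 0) {
  n <- transducer$n_elements
  R <- transducer$roc
  if (is.infinite(R)) {
    x <- x_mid + (seq_len(n) - (n + 1) / 2) * transducer$pitch
    return(cbind(z = rep(apex_depth, n), x = x))
  }
  th <- (seq_len(n) - (n + 1) / 2) * transducer$pitch / R
  cbind(z = apex_depth - R * (1 - cos(th)), x = x_mid + R * sin(th))
}

#' Scan-line geometry for a sector scan
#'
#' For a convex array, line `theta` radiates from the center of curvature;
#' a point at imaging depth `d` (distance beyond the array surface) lies at
#' `center + (R + d) * (sin(theta), cos(theta))`.
#'
#' @param transducer a [transducer()] object.
#' @param theta line angle from the midline (rad).
#' @param depths imaging depths along the line (m).
#' @param apex_depth,x_mid arc placement as in [element_positions()].
#' @return matrix `length(depths) x 2` of `(z, x)` (m).
#' @export
scanline_points <- function(transducer, theta, depths,
                            apex_depth = 0, x_mid = 0) {
  R <- transducer$roc
  if (is.infinite(R))  # linear array: vertical line, theta is a lateral offset (m)
    return(cbind(z = apex_depth + depths, x = rep(x_mid + theta, length(depths))))
  zc <- apex_depth - R
  cbind(z = zc + (R + depths) * cos(theta),
        x = x_mid + (R + depths) * sin(theta))
}

#' Geometric focusing delays
#'
#' Per-element transmit delays for a focal point:
#' `delay_i = (max_j d_j - d_i) / c_assumed` with `d_i` the element-to-focus
#' distance.  All delays are non-negative, the farthest element fires at
#' delay zero, and the wavefronts coincide at the focus at time
#' `max_j d_j / c_assumed`.
#'
#' @param transducer a [transducer()] object.
#' @param focus focal point `c(z, x)` (m).
#' @param c_assumed assumed propagation speed (m/s), conventionally 1540.
#' @param apex_depth,x_mid arc placement as in [element_positions()].
#' @return numeric vector of delays (s), minimum exactly 0.
#' @export
focusing_delays <- function(transducer, focus, c_assumed = 1540,
                            apex_depth = 0, x_mid = 0) {
  pos <- element_positions(transducer, apex_depth, x_mid)
  d <- sqrt((pos[, 1] - focus[1])^2 + (pos[, 2] - focus[2])^2)
  if (any(d < transducer$pitch / 4))
    stop("geometry error: focus coincident with an element")
  (max(d) - d) / c_assumed
}

#' Transmit event
#'
#' A focused transmit: focal point, per-element apodization, and delays.
#'
#' @param focus focal point `c(z, x)` (m).
#' @param delays per-element delays (s).
#' @param apodization per-element weights in \[0, 1\]; default uniform.
#' @export
transmit_event <- function(focus, delays, apodization = NULL) {
  n <- length(delays)
  if (is.null(apodization)) apodization <- rep(1, n)
  if (length(apodization) != n)
    stop("parameter error: apodization length must match n_elements")
  structure(list(focus = as.numeric(focus), delays = delays,
                 apodization = apodization),
            class = "transmit_event")
}

#' Transmit pulse waveform
#'
#' Gaussian-windowed sinusoid of `n_cycles` cycles at `f0`: the envelope
#' full width at half maximum equals `n_cycles / f0`, with the window
#' truncated at 3 standard deviations.
#'
#' @param transducer a [transducer()] object.
#' @param dt sampling period (s).
#' @return list with the waveform `w`, its time axis `t`, and the envelope
#'   peak time `t_peak` (s).
#' @export
pulse_waveform <- function(transducer, dt) {
  sigma <- transducer$n_cycles / (2.355 * transducer$f0)
  t_peak <- 3 * sigma
  t <- seq(0, 2 * t_peak, by = dt)
  w <- sin(2 * pi * transducer$f0 * (t - t_peak)) *
    exp(-(t - t_peak)^2 / (2 * sigma^2))
  list(w = w, t = t, t_peak = t_peak)
}
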