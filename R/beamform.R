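#' B-mode image container
#'
#' Per-pixel image values (linear envelope or dB) on a line/depth grid with
#' the physical pixel coordinates and a declared normalization reference.
#'
#' @param image matrix, rows = depth samples, columns = scan lines.
#' @param depth axial depth of each row below the array surface (m).
#' @param zpos,xpos matrices of physical pixel coordinates (m).
#' @param is_log `TRUE` for log-compressed (dB) values.
#' @param norm_ref normalization reference: `"max"`, `"speckle"`, `"none"`.
#' @export
bmode_image <- function(image, depth, zpos = NULL, xpos = NULL,
                        is_log = FALSE, norm_ref = "none") {
  if (is.unsorted(depth)) stop("depth grid must be monotonic")
  structure(list(image = image, depth = depth, zpos = zpos, xpos = xpos,
                 is_log = is_log, norm_ref = norm_ref),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d px, %s, norm = %s\n",
              nrow(x$image), ncol(x$image),
              if (x$is_log) "dB" else "linear envelope", x$norm_ref))
  invisible(x)
}

# DAS sum for arbitrary pixel positions of a single transmit.
# t_tx: transmit time of flight per pixel (s); pix: n x 2 (z, x).
das_sum <- function(rf, dt, t0, elem_pos, pix, t_tx, c_bf) {
  nt <- nrow(rf)
  zero <- if (is.complex(rf)) 0i else 0
  out <- rep(zero, nrow(pix))
  for (e in seq_len(ncol(rf))) {
    d_rx <- sqrt((pix[, 1] - elem_pos[e, 1])^2 + (pix[, 2] - elem_pos[e, 2])^2)
    ts <- (t_tx + d_rx / c_bf - t0) / dt + 1
    i0 <- floor(ts)
    frac <- ts - i0
    ok <- i0 >= 1 & i0 < nt             # outside the record contributes zero
    v <- rep(zero, length(ts))
    v[ok] <- rf[i0[ok], e] * (1 - frac[ok]) + rf[i0[ok] + 1L, e] * frac[ok]
    out <- out + v
  }
  out
}

#' Delay-and-sum beamforming
#'
#' Conventional delay-and-sum at a uniform beamforming speed `c_bf`: for
#' each pixel, the RF of every element is sampled (linear interpolation in
#' time) at the transmit time-of-flight plus the element receive
#' time-of-flight and summed over the full receive aperture.  The transmit
#' time along each focused line uses the virtual-focus convention
#' `t_tx = t_focus + (d - d_focus) / c_bf` with `t_focus` the delay-profile
#' arrival time at the focus, plus the pulse envelope peak offset.  In
#' `"line"` mode only the lateral line through each transmit focus is kept
#' (one line per transmit).
#'
#' @param channels a [channel_data()] whose events carry `$theta`.
#' @param depths axial depth samples below the array surface (m); default
#'   eighth-wavelength spacing over the recorded depth range.
#' @param c_bf beamforming speed (m/s), default 1540.
#' @param mode `"line"` (one line per transmit) is currently the imaging
#'   mode; provided for future full-grid use.
#' @param analytic beamform the analytic (IQ) channel signal, producing a
#'   complex image whose modulus is the envelope.  The Hilbert transform is
#'   applied to the densely sampled channel traces, where the band-pass
#'   pulse is well resolved, rather than to the image columns; this avoids
#'   envelope leakage from strong echoes into quiet image regions.
#' @return a [bmode_image()] of pre-envelope values (complex when
#'   `analytic`), linear and unnormalized.
#' @export
das_beamform <- function(channels, depths = NULL, c_bf = 1540,
                         mode = c("line", "grid"), analytic = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(channels, "channel_data"))
  xd <- channels$transducer
  apex <- channels$meta$apex_depth
  x_mid <- channels$meta$x_mid
  if (is.null(apex)) stop("channel data lacks transducer placement metadata")
  if (is.null(depths)) {
    # lambda/8 axial pixels: the beamformed RF oscillates at a spatial
    # period of lambda/2 (two-way), so this keeps 4 samples per cycle for
    # clean envelope detection
    lam <- c_bf / xd$f0
    t_max <- (dim(channels$rf)[1] - 1) * channels$dt + channels$t0
    d_max <- t_max * c_bf / 2 * 0.95
    depths <- seq(lam, d_max, by = lam / 8)
  }
  elem_pos <- element_positions(xd, apex, x_mid)
  sigma <- xd$n_cycles / (2.355 * xd$f0)
  t_pulse_peak <- 3 * sigma
  ntx <- dim(channels$rf)[3]
  img <- matrix(if (analytic) 0i else 0, length(depths), ntx)
  zpos <- xpos <- matrix(0, length(depths), ntx)
  for (k in seq_len(ntx)) {
    ev <- channels$events[[k]]
    theta <- if (!is.null(ev$theta)) ev$theta else 0
    pix <- scanline_points(xd, theta, depths, apex, x_mid)
    d_foc <- sqrt((elem_pos[, 1] - ev$focus[1])^2 +
                  (elem_pos[, 2] - ev$focus[2])^2)
    t_focus <- max(ev$delays + d_foc / c_bf)       # arrival time at focus
    zc <- apex - xd$roc                            # center of curvature
    d_f <- sqrt((ev$focus[1] - zc)^2 + (ev$focus[2] - x_mid)^2) - xd$roc
    t_tx <- t_focus + (depths - d_f) / c_bf + t_pulse_peak
    rfk <- channels$rf[, , k]
    if (analytic) rfk <- apply(rfk, 2, analytic_signal)
    img[, k] <- das_sum(rfk, channels$dt, channels$t0,
                        elem_pos, pix, t_tx, c_bf)
    zpos[, k] <- pix[, 1]
    xpos[, k] <- pix[, 2]
  }
  bmode_image(img, depths, zpos, xpos, is_log = FALSE, norm_ref = "none")
}

#' Envelope detection and log compression
#'
#' Computes the envelope of a beamformed image — the modulus of a complex
#' (analytic/IQ) image, or the analytic-signal magnitude along the axial
#' axis of a real RF image — and log-compresses it as `20 log10` relative
#' to the chosen reference: the image maximum (global max maps to 0 dB) or
#' the mean linear envelope over a speckle ROI (ROI mean maps to 0 dB).
#'
#' @param rf_image a [bmode_image()] holding pre-envelope values.
#' @param normalization `"max"`, `"speckle"`, or `"none"` (no reference;
#'   raw dB of the envelope).
#' @param roi for `"speckle"`: logical mask matrix over the image.
#' @export
envelope_logcompress <- function(rf_image, normalization = c("max", "speckle", "none"),
                                 roi = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(rf_image, "bmode_image"))
  env <- if (is.complex(rf_image$image)) Mod(rf_image$image)
         else analytic_envelope(rf_image$image)
  ref <- switch(normalization,
    max = {
      m <- max(env)
      if (m == 0) stop("undefined reference: all-zero image with max normalization")
      m
    },
    speckle = {
      if (is.null(roi)) stop("speckle normalization requires an roi mask")
      mean(env[roi])
    },
    none = 1)
  out <- rf_image
  out$image <- 20 * log10(pmax(env, .Machine$double.xmin) / ref)
  out$is_log <- TRUE
  out$norm_ref <- normalization
  out
}

#' Assemble a sector scan image
#'
#' Beamforms one line per transmit event and assembles the lines along the
#' array curvature into a composite pre-envelope image; the conventional
#' sequence is 64 lines at half-beamwidth spacing.
#'
#' @param channels a [channel_data()] with one transmit per line.
#' @param depths axial depth samples (m); see [das_beamform()].
#' @param c_bf beamforming speed (m/s).
#' @export
sector_scan <- function(channels, depths = NULL, c_bf = 1540) {
  das_beamform(channels, depths, c_bf, mode = "line")
}
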