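#' Clutter subtraction
#'
#' Subtracts a target-free (clutter-only) twin record from the full record,
#' sample by sample.  In a linear simulation this removes multiple
#' reverberation exactly — down to the numerical noise floor — while
#' preserving the ballistic target echo, its aberration, and the trailing
#' clutter that traveled with it.
#'
#' @param rf_full [channel_data()] of the medium with the target.
#' @param rf_clutter matched [channel_data()] with the target removed.
#' @return [channel_data()] of the difference, marked `clutter_subtracted`.
#' @export
subtract_clutter <- function(rf_full, rf_clutter) {
  stopifnot(inherits(rf_full, "channel_data"),
            inherits(rf_clutter, "channel_data"))
  if (!all(dim(rf_full$rf) == dim(rf_clutter$rf)) ||
      abs(rf_full$dt - rf_clutter$dt) > 1e-15 ||
      abs(rf_full$t0 - rf_clutter$t0) > 1e-15)
    stop("incompatibility error: records differ in shape or sampling")
  out <- rf_full
  out$rf <- rf_full$rf - rf_clutter$rf
  out$meta$clutter_subtracted <- TRUE
  out
}

#' Point-spread-function region masks
#'
#' Deterministic partition of an image grid into the three PSF regions of a
#' point target: the isochronous volume (pixels whose beamformed two-way
#' time is consistent with ballistic element-target-element paths), the
#' pre-isochronous region (earlier times), and the trailing
#' (post-isochronous) region (later times).  A pixel at beamformed depth
#' `d` maps to the two-way time `2 d / c_bf`; the isochronous band is
#' `[t_min - T, t_max + T]` with `t_min`/`t_max` the extreme two-way
#' element-target-element times and `T = pulse_len / c_bf` a one-pulse
#' tolerance pad.
#'
#' @param target target position `c(z, x)` (m).
#' @param transducer a [transducer()] object.
#' @param bmode a [bmode_image()] supplying the pixel grid (`depth`,
#'   `zpos`, `xpos`).
#' @param c_bf beamforming speed (m/s).
#' @param pulse_len axial pulse length (m); default `n_cycles * c_bf / f0`.
#' @param apex_depth,x_mid arc placement used for the element positions.
#' @return object of class `psf_regions` with logical masks `pre`, `iso`,
#'   `trail` partitioning the grid.
#' @export
psf_region_masks <- function(target, transducer, bmode, c_bf = 1540,
                             pulse_len = NULL, apex_depth = 0, x_mid = 0) {
  stopifnot(inherits(bmode, "bmode_image"))
  if (transducer$n_elements < 2)
    stop("geometry error: degenerate aperture")
  if (is.null(pulse_len))
    pulse_len <- transducer$n_cycles * c_bf / transducer$f0
  pos <- element_positions(transducer, apex_depth, x_mid)
  d <- sqrt((pos[, 1] - target[1])^2 + (pos[, 2] - target[2])^2)
  t_min <- 2 * min(d) / c_bf
  t_max <- 2 * max(d) / c_bf
  Tpad <- pulse_len / c_bf
  tw <- matrix(2 * bmode$depth / c_bf, nrow(bmode$image), ncol(bmode$image))
  iso <- tw >= (t_min - Tpad) & tw <= (t_max + Tpad)
  pre <- tw < (t_min - Tpad)
  trail <- tw > (t_max + Tpad)
  structure(list(pre = pre, iso = iso, trail = trail,
                 target = target, pulse_len = pulse_len),
            class = "psf_regions")
}

#' Region magnitude statistics of a PSF image
#'
#' Mean dB magnitude of the pre-isochronous, trailing, and isochronous
#' regions relative to the main lobe, where the main lobe is the image
#' maximum within the isochronous mask (so pre-isochronous artifacts cannot
#' corrupt the normalization).  Means are taken over dB pixel values.
#'
#' @param bmode a log-compressed [bmode_image()].
#' @param regions a [psf_region_masks()] result.
#' @return named numeric: `pre`, `trail`, `iso` (dB relative to main lobe).
#' @export
region_magnitudes <- function(bmode, regions) {
  stopifnot(inherits(bmode, "bmode_image"), inherits(regions, "psf_regions"))
  if (!bmode$is_log) stop("region magnitudes require a log-compressed image")
  if (!any(regions$iso) || !any(regions$pre) || !any(regions$trail))
    stop("region error: empty PSF region mask")
  main <- max(bmode$image[regions$iso])
  # pixels whose beamformed time fell outside the record carry no data
  # (log of zero envelope); exclude them rather than average them in
  valid <- (bmode$image - main) > -300
  m <- function(mask) {
    mask <- mask & valid
    if (!any(mask)) stop("region error: region has no recorded pixels")
    mean(bmode$image[mask]) - main
  }
  c(pre = m(regions$pre), trail = m(regions$trail), iso = m(regions$iso))
}
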