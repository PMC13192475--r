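#' Desk-scale study profiles
#'
#' Canonical configurations for the package's quantitative studies.  The
#' `"psf"` profile (1.2 MHz) is used for point-spread-function and
#' separation experiments; the `"lesion"` profile (1.0 MHz) for the
#' sector-scan anechoic-lesion experiment, whose domain is deeper and whose
#' 640-transmit budget favors the lower frequency.  Both use a 64-element,
#' 0.4 mm-pitch, 40 mm-radius curved array, a 2-cycle pulse, and a grid of
#' 12 points per wavelength in the slowest medium.
#'
#' @param name `"psf"` or `"lesion"`.
#' @return list with `transducer`, `dx`, and `config`.
#' @export
study_profile <- function(name = c("psf", "lesion")) {
  name <- match.arg(name)
  f0 <- switch(name, psf = 1.2e6, lesion = 1.0e6)
  xd <- transducer(n_elements = 64, pitch = 0.4e-3,
                   radius_of_curvature = 40e-3, f0 = f0, n_cycles = 2)
  list(transducer = xd, dx = 1450 / f0 / 12, config = sim_config())
}

# lesion / background annulus masks on an image, relative to a lesion
# center; the lesion ROI is the full lesion disc
lesion_masks <- function(bmode, center, radius,
                         inner_frac = 1.0, annulus = c(1.5e-3, 4.4e-3),
                         depth_halfband = 4e-3) {
  rl <- sqrt((bmode$zpos - center[1])^2 + (bmode$xpos - center[2])^2)
  lesion <- rl <= inner_frac * radius
  lat <- abs(bmode$xpos - center[2])
  bg <- abs(bmode$zpos - center[1]) <= depth_halfband &
    lat >= radius + annulus[1] & lat <= radius + annulus[2]
  list(lesion = lesion, background = bg)
}

#' Anechoic-lesion contrast-to-noise study
#'
#' The homogeneous-case lesion experiment at desk scale: a uniform speckle
#' phantom (18 scatterers per resolution cell) with three 5 mm-radius
#' anechoic lesions at depths scaled 0.6x from the clinical 40/60/80 mm
#' (24/36/48 mm), imaged with a 64-line focused sector scan (focus at the
#' deepest lesion), beamformed one line per transmit at 1540 m/s,
#' log-compressed, and scored with the contrast-to-noise ratio of each
#' lesion against an equal-depth background annulus, averaged over
#' independent speckle realizations.
#'
#' @param n_seeds number of speckle realizations (>= 10 for the averaged
#'   study).
#' @param seed base seed; realization `k` uses `seed * 1000 + k`.
#' @param lesion_depths lesion center depths below the array surface (m).
#' @param lesion_radius lesion radius (m).
#' @param n_lines scan lines per image.
#' @param line_spacing focus spacing along the focal arc (m).
#' @param profile a [study_profile()] list.
#' @param gamma optional impedance-mismatch scale applied to the phantom
#'   via [modulate_maps()] (gamma = 1 leaves it untouched).
#' @param wall optional `list(thickness=, seed=)` to insert a layered
#'   abdominal wall below the transducer (heterogeneous case).
#' @return list: `cnr` (n_seeds x 3 matrix), `mean_cnr`, `speckle_snr`
#'   (envelope SNR over the background of each realization), `loc`
#'   (lag-one coherence at the focal line of each realization).
#' @export
lesion_cnr_study <- function(n_seeds = 10, seed = 1,
                             lesion_depths = c(24e-3, 36e-3, 48e-3),
                             lesion_radius = 5e-3,
                             n_lines = 64, line_spacing = 0.45e-3,
                             profile = study_profile("lesion"),
                             gamma = 1, wall = NULL) {
  xd <- profile$transducer
  c0 <- 1570                       # background medium speed
  dx <- c0 / xd$f0 / 12            # slowest medium is the background
  focal_depth <- max(lesion_depths)
  cfg <- profile$config
  bw <- cfg$boundary_width
  sag <- xd$roc * (1 - cos((xd$n_elements / 2) * xd$pitch / xd$roc))
  apex <- (bw + 4) * dx + sag
  depth <- apex + focal_depth + lesion_radius + 1e-3 + (bw + 2) * dx
  half_w <- max(xd$n_elements * xd$pitch / 2,
                (xd$roc + focal_depth + lesion_radius) *
                  sin((n_lines / 2) * line_spacing / (xd$roc + focal_depth))) +
    3e-3 + (bw + 2) * dx
  domain <- c(depth, 2 * half_w)
  cfg$apex_depth <- apex
  cnr_mat <- matrix(NA_real_, n_seeds, length(lesion_depths))
  snr <- loc <- numeric(n_seeds)
  x_mid <- ((round(domain[2] / dx)) - 1) * dx / 2
  for (k in seq_len(n_seeds)) {
    maps <- speckle_lesion_phantom(domain, dx, xd, focal_depth,
                                   lesion_depths = lesion_depths,
                                   lesion_radius = lesion_radius,
                                   surface_depth = apex,
                                   seed = seed * 1000 + k)
    if (!is.null(wall)) {
      wl <- generate_layered_abdomen(domain, dx,
                                     wall_thickness = wall$thickness,
                                     wall_top = apex,
                                     seed = wall$seed %||% (seed * 1000 + k))
      wl <- smooth_maps(wl, 1.5)
      inwall <- wl$label != "background"
      maps$c[inwall] <- wl$c[inwall]
      maps$rho[inwall] <- wl$rho[inwall]
      sc_ct <- wall$scatter_contrast %||% 0.12
      if (sc_ct > 0) {
        rcell <- resolution_cell_area(xd, focal_depth, 1570)
        maps <- add_scatterers(
          maps, scatterer_spec(18, sc_ct, rcell,
                               (wall$seed %||% 7) + 500),
          region = list(z = c(apex, apex + wall$thickness),
                        x = c(0, domain[2])))
      }
    }
    if (gamma != 1)
      maps <- modulate_maps(maps, modulation_params(gamma = gamma, zeta = 1))
    cd <- scan_sequence(maps, xd, focal_depth, n_lines = n_lines,
                        line_spacing = line_spacing, config = cfg)
    bm <- das_beamform(cd, c_bf = 1540)
    bml <- envelope_logcompress(bm, "max")
    # ROIs are placed on the *imaged* lesions: beamforming at c_bf in a
    # medium of speed c0 displays a feature at true depth z at z*c_bf/c0
    disp <- 1540 / c0
    for (d in seq_along(lesion_depths)) {
      ctr <- c(apex + lesion_depths[d] * disp, x_mid)
      mk <- lesion_masks(bml, ctr, lesion_radius)
      cnr_mat[k, d] <- cnr(bml, mk$lesion, mk$background)$cnr
    }
    # speckle statistics at the focal-depth background
    mkf <- lesion_masks(bml, c(apex + focal_depth * disp, x_mid), lesion_radius)
    env <- Mod(bm$image)
    # remove the slow depth-dependent diffraction gain before the SNR
    # estimate: the row-mean profile (background columns only, so the
    # lesion cannot bias it) is smoothed over several pulse lengths so
    # speckle-scale fluctuation is preserved in the statistics
    bgcols <- sort(unique(as.vector(col(env))[mkf$background]))
    rowgain <- rowMeans(env[, bgcols, drop = FALSE])
    drow <- diff(bm$depth[1:2])
    sm <- 3e-3 / drow
    rowgain <- as.vector(gaussian_blur(matrix(rowgain, ncol = 1), sm))
    envn <- env / pmax(rowgain, .Machine$double.eps)
    snr[k] <- mean(envn[mkf$background]) / stats::sd(envn[mkf$background])
    loc[k] <- lag_one_coherence(
      coherence_curve(cd, transmit = which.min(abs(
        vapply(cd$events, function(e) e$theta, 0)))))
    rm(cd)
  }
  list(cnr = cnr_mat, mean_cnr = colMeans(cnr_mat),
       speckle_snr = snr, loc = loc,
       geometry = list(dx = dx, apex = apex, domain = domain,
                       focal_depth = focal_depth))
}

#' Point-target separation study
#'
#' Simulates matched full / clutter pairs of a point target beneath a
#' layered abdominal wall (plus a homogeneous reference), at one or more
#' target depths and reflectivities, with a single focused transmit per
#' case.  This is the machinery behind the depth- and
#' brightness-dependence analyses of aberration, reverberation, and
#' trailing clutter.
#'
#' @param target_depths target depths below the array surface (m).
#' @param reflectivities target reflectivities (applied at the middle
#'   depth unless `depth_for_reflectivity` is given).
#' @param wall_thickness layered-wall thickness (m).
#' @param wall_roughness peak interface roughness of the wall layers (m);
#'   together with the layer speed contrasts this sets the aberrator
#'   strength.
#' @param wall_interface_corr lateral correlation length of the layer
#'   interfaces (m); long relative to the aperture so the effective phase
#'   screen is sampled consistently from different target depths.
#' @param wall_scatter_contrast density contrast of sub-resolution
#'   scatterers seeded inside the wall; these generate the forward
#'   multiple scattering responsible for trailing clutter and add
#'   fine-scale reverberation.
#' @param profile a [study_profile()] list.
#' @param seed wall seed.
#' @param depth_for_reflectivity depth at which the reflectivity series is
#'   simulated (m).
#' @return nested list: `$depth[[i]]` with `full`, `clutter`, `homog`
#'   [channel_data()]s per depth (reflectivity 0.5), and
#'   `$reflectivity[[j]]` with `full` per reflectivity (sharing
#'   `$depth`'s clutter and homogeneous runs at the chosen depth).
#' @export
psf_separation_study <- function(target_depths = c(35e-3, 41e-3, 47e-3),
                                 reflectivities = 0.5,
                                 wall_thickness = 12e-3,
                                 wall_roughness = 2e-3,
                                 wall_interface_corr = 6e-3,
                                 wall_scatter_contrast = 0.12,
                                 profile = study_profile("psf"),
                                 seed = 7,
                                 depth_for_reflectivity = 41e-3) {
  xd <- profile$transducer
  dx <- 1450 / xd$f0 / 12
  cfg <- profile$config
  bw <- cfg$boundary_width
  sag <- xd$roc * (1 - cos((xd$n_elements / 2) * xd$pitch / xd$roc))
  apex <- (bw + 4) * dx + sag
  depth <- apex + max(target_depths) + 8e-3 + (bw + 2) * dx
  half_w <- xd$n_elements * xd$pitch / 2 + 4e-3 + (bw + 2) * dx
  domain <- c(depth, 2 * half_w)
  cfg$apex_depth <- apex
  nz <- round(domain[1] / dx); nx <- round(domain[2] / dx)
  x_mid <- (nx - 1) * dx / 2
  wallmaps <- generate_layered_abdomen(domain, dx,
                                       wall_thickness = wall_thickness,
                                       layers = default_wall_layers(wall_roughness),
                                       interface_corr = wall_interface_corr,
                                       wall_top = apex, seed = seed)
  wallmaps <- smooth_maps(wallmaps, 1.5)
  if (wall_scatter_contrast > 0) {
    rc <- resolution_cell_area(xd, depth_for_reflectivity, 1570)
    wallmaps <- add_scatterers(
      wallmaps, scatterer_spec(18, wall_scatter_contrast, rc, seed + 1),
      region = list(z = c(apex, apex + wall_thickness),
                    x = c(0, (nx - 1) * dx)))
  }
  homog <- acoustic_maps(matrix(1570, nz, nx), matrix(1064, nz, nx), dx)
  run <- function(maps, depth_t, refl) {
    focus <- c(apex + depth_t, x_mid)
    delays <- focusing_delays(xd, focus, 1540, apex, x_mid)
    ev <- transmit_event(focus, delays)
    tgt <- target_spec(focus, refl)
    list(full = simulate_transmit(add_point_target(maps, tgt), xd, ev, cfg),
         clutter = simulate_transmit(maps, xd, ev, cfg),
         event = ev, target = tgt)
  }
  out <- list(depth = list(), reflectivity = list(),
              geometry = list(dx = dx, apex = apex, x_mid = x_mid,
                              domain = domain, transducer = xd))
  for (i in seq_along(target_depths)) {
    r <- run(wallmaps, target_depths[i], 0.5)
    focus <- r$event$focus
    hev <- r$event
    r$homog <- simulate_transmit(add_point_target(homog, r$target), xd, hev, cfg)
    r$homog_clutter <- simulate_transmit(homog, xd, hev, cfg)
    out$depth[[i]] <- r
  }
  j_ref <- which.min(abs(target_depths - depth_for_reflectivity))
  for (rr in reflectivities) {
    if (rr == 0.5 && depth_for_reflectivity %in% target_depths) {
      out$reflectivity[[as.character(rr)]] <- out$depth[[j_ref]]
      next
    }
    focus <- c(apex + depth_for_reflectivity, x_mid)
    delays <- focusing_delays(xd, focus, 1540, apex, x_mid)
    ev <- transmit_event(focus, delays)
    tgt <- target_spec(focus, rr)
    out$reflectivity[[as.character(rr)]] <- list(
      full = simulate_transmit(add_point_target(wallmaps, tgt), xd, ev, cfg),
      clutter = out$depth[[j_ref]]$clutter, event = ev, target = tgt)
  }
  out
}

#' Aberration strength of a point-target acquisition
#'
#' Estimates the RMS phase aberration of a (clutter-subtracted) point
#' target record against a homogeneous-medium reference: adjacent-element
#' lags are integrated into arrival-time profiles for both records and the
#' RMS profile difference is returned in nanoseconds.
#'
#' @param channels_aberrated,channels_reference [channel_data()]s of the
#'   same emission.
#' @param ... passed to [interelement_lags()].
#' @return RMS aberration (ns).
#' @export
estimate_rms_aberration <- function(channels_aberrated, channels_reference,
                                    ...) {
  la <- interelement_lags(channels_aberrated, ...)
  lr <- interelement_lags(channels_reference, ...)
  pa <- arrival_time_profile(la, channels_aberrated$dt)
  pr <- arrival_time_profile(lr, channels_reference$dt)
  rms_aberration(pa, pr)
}
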