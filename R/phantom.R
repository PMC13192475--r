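#' Default tissue acoustic property table
#'
#' Speed of sound and density per tissue class.  The defaults reflect
#' standard tabulated soft-tissue values; the `background` class carries the
#' abdominal equilibrium constants (1570 m/s, 1064 kg/m^3) so that a
#' homogeneous phantom coincides with the equilibrium medium of the
#' modulation algebra.  Fully configurable: pass an edited copy wherever a
#' `props` argument is accepted.
#'
#' @return data.frame with columns `tissue`, `c` (m/s), `rho` (kg/m^3).
#' @export
tissue_properties <- function() {
  data.frame(
    tissue = c("water", "fat", "muscle", "connective", "background"),
    c   = c(1496, 1450, 1580, 1613, 1570),
    rho = c(1000,  950, 1050, 1120, 1064),
    stringsAsFactors = FALSE
  )
}

tissue_lookup <- function(props, tissue, what) {
  i <- match(tissue, props$tissue)
  if (any(is.na(i))) stop("spec error: unknown tissue class: ",
                          paste(tissue[is.na(i)], collapse = ", "))
  props[[what]][i]
}

#' Generate a layered abdominal-wall phantom
#'
#' Builds piecewise-constant speed/density maps with labeled tissue layers
#' (fat, muscle, connective, ...) separated by smooth random interfaces over
#' the first `wall_thickness` of depth below `wall_top`, and a homogeneous
#' background beneath.  A synthetic stand-in for segmented abdominal
#' cross-sections: it reproduces the speed and impedance contrasts between
#' tissue classes that generate aberration and reverberation, not any
#' specific anatomy.
#'
#' @param domain numeric `c(depth, width)` extents (m).
#' @param dx grid spacing (m).
#' @param wall_thickness total wall thickness (m); layer mean thicknesses
#'   are scaled proportionally to sum to it.
#' @param layers list of layers, each `list(tissue=, frac=, roughness=)`,
#'   `frac` the fraction of `wall_thickness`, `roughness` the peak interface
#'   perturbation (m).  Empty list gives homogeneous background maps.
#' @param wall_top depth at which the wall starts (m).
#' @param interface_corr lateral correlation length of the interfaces (m).
#' @param seed RNG seed; maps are bit-reproducible per seed.
#' @param props tissue property table, see [tissue_properties()].
#' @param background tissue class filling everything outside the wall.
#' @return an [acoustic_maps()] object with a `label` matrix.
#' @export
generate_layered_abdomen <- function(domain, dx,
                                     wall_thickness = 20e-3,
                                     layers = default_wall_layers(),
                                     wall_top = 0,
                                     interface_corr = 5e-3,
                                     seed = 1L,
                                     props = tissue_properties(),
                                     background = "background") {
  if (dx <= 0) stop("spec error: dx must be positive")
  nz <- round(domain[1] / dx); nx <- round(domain[2] / dx)
  if (wall_top + wall_thickness > domain[1])
    stop("spec error: layer thicknesses exceed the domain depth")
  cb <- tissue_lookup(props, background, "c")
  rb <- tissue_lookup(props, background, "rho")
  cmap <- matrix(cb, nz, nx)
  rmap <- matrix(rb, nz, nx)
  lmap <- matrix(background, nz, nx)
  if (length(layers) > 0) {
    fr <- vapply(layers, function(l) l$frac, 0)
    thick <- wall_thickness * fr / sum(fr)
    with_seed(seed, {
      bottoms <- wall_top + cumsum(thick)
      zc <- (seq_len(nz) - 0.5) * dx
      prev_if <- rep(wall_top, nx)
      for (k in seq_along(layers)) {
        rough <- layers[[k]]$roughness
        pert <- if (rough > 0)
          smooth_noise_1d(nx, interface_corr / dx, rough) else rep(0, nx)
        next_if <- pmin(bottoms[k] + pert, domain[1])
        for (j in seq_len(nx)) {
          rows <- which(zc > prev_if[j] & zc <= next_if[j])
          if (length(rows)) {
            lmap[rows, j] <- layers[[k]]$tissue
            cmap[rows, j] <- tissue_lookup(props, layers[[k]]$tissue, "c")
            rmap[rows, j] <- tissue_lookup(props, layers[[k]]$tissue, "rho")
          }
        }
        prev_if <- pmax(prev_if, next_if)
      }
    })
  }
  acoustic_maps(cmap, rmap, dx, label_map = lmap)
}

#' Default abdominal-wall layer specification
#'
#' Fat / muscle / connective fractions of the wall thickness with 1 mm peak
#' interface roughness, emulating the layered composition of an abdominal
#' body wall.
#' @param roughness peak interface perturbation (m).
#' @export
default_wall_layers <- function(roughness = 1e-3) {
  list(list(tissue = "fat",        frac = 0.45, roughness = roughness),
       list(tissue = "muscle",     frac = 0.35, roughness = roughness),
       list(tissue = "connective", frac = 0.20, roughness = roughness))
}

#' Gaussian smoothing of acoustic maps
#'
#' Convolves the speed and density maps with an isotropic Gaussian kernel
#' (reflect padding, so uniform maps are exactly invariant); used to reduce
#' discretization error at segmented tissue boundaries.  The conventional
#' setting is a standard deviation of 1.5 pixels.
#'
#' @param maps an `acoustic_maps` object.
#' @param sigma_px kernel standard deviation in pixels; 0 is the identity.
#' @export
smooth_maps <- function(maps, sigma_px = 1.5) {
  stopifnot(inherits(maps, "acoustic_maps"))
  if (sigma_px < 0) stop("parameter error: sigma_px must be >= 0")
  if (sigma_px == 0) return(maps)
  out <- maps
  out$c <- gaussian_blur(maps$c, sigma_px)
  out$rho <- gaussian_blur(maps$rho, sigma_px)
  out
}

#' Sub-resolution scatterer specification
#'
#' @param n_per_rescell mean number of scatterers per resolution cell; the
#'   calibrated speckle setting is 18.
#' @param contrast peak fractional impedance perturbation per scatterer, in
#'   \[0, 1).
#' @param rescell_area resolution-cell area (m^2); see
#'   [resolution_cell_area()].
#' @param seed RNG seed.
#' @export
scatterer_spec <- function(n_per_rescell = 18, contrast = 0.05,
                           rescell_area, seed = 1L) {
  if (n_per_rescell < 0) stop("parameter error: n_per_rescell must be >= 0")
  if (contrast < 0 || contrast >= 1)
    stop("parameter error: contrast must be in [0, 1)")
  structure(list(n_per_rescell = n_per_rescell, contrast = contrast,
                 rescell_area = rescell_area, seed = seed),
            class = "scatterer_spec")
}

#' Resolution-cell area for scatterer density calibration
#'
#' Axial pulse length (`n_cycles * c0 / f0`) times the lateral
#' full-width-half-maximum beamwidth at focus (`lambda * focal_depth /
#' aperture`).
#'
#' @param transducer a [transducer()] object.
#' @param focal_depth transmit focal depth (m).
#' @param c0 reference speed of sound (m/s).
#' @export
resolution_cell_area <- function(transducer, focal_depth, c0 = 1570) {
  lam <- c0 / transducer$f0
  axial <- transducer$n_cycles * lam
  aperture <- transducer$n_elements * transducer$pitch
  lateral <- lam * focal_depth / aperture
  axial * lateral
}

#' Add sub-resolution scatterers to acoustic maps
#'
#' Places single-pixel density perturbations uniformly at random at a mean
#' density of `n_per_rescell` per resolution-cell area.  Only the density is
#' perturbed (speed untouched), so scatterers contribute backscatter and
#' reverberation but no added aberration, keeping the three degradation
#' mechanisms separable by construction.  Each scatterer multiplies the
#' local density by `1 + contrast * u` with `u ~ U(-1, 1)`.  Deterministic
#' per seed; the scatterer bookkeeping is stored on the returned maps so
#' that [add_lesions()] can restore pixels exactly.
#'
#' @param maps an `acoustic_maps` object.
#' @param spec a [scatterer_spec()].
#' @param region optional `list(z = c(lo, hi), x = c(lo, hi))` restricting
#'   scatterer placement (m); default whole grid.
#' @export
add_scatterers <- function(maps, spec, region = NULL) {
  stopifnot(inherits(maps, "acoustic_maps"), inherits(spec, "scatterer_spec"))
  if (spec$n_per_rescell == 0) return(maps)
  co <- map_coords(maps)
  zi <- if (is.null(region)) seq_along(co$z) else
    which(co$z >= region$z[1] & co$z <= region$z[2])
  xi <- if (is.null(region)) seq_along(co$x) else
    which(co$x >= region$x[1] & co$x <= region$x[2])
  npix <- length(zi) * length(xi)
  area <- npix * maps$dx^2
  lambda_n <- spec$n_per_rescell * area / spec$rescell_area
  out <- maps
  with_seed(spec$seed, {
    n <- stats::rpois(1, lambda_n)
    n <- min(n, npix)
    pick <- sample.int(npix, n)
    i <- zi[((pick - 1L) %% length(zi)) + 1L]
    j <- xi[((pick - 1L) %/% length(zi)) + 1L]
    amp <- spec$contrast * stats::runif(n, -1, 1)
    idx <- cbind(i, j)
    rho_orig <- out$rho[idx]
    rho_new <- rho_orig * (1 + amp)
    if (any(rho_new <= 0))
      stop("degenerate-map error: scatterer contrast yields non-positive density")
    out$rho[idx] <- rho_new
    out$scatterers <- data.frame(i = i, j = j, rho_orig = rho_orig)
  })
  out
}

#' Carve anechoic lesions out of a scatterer field
#'
#' Removes every scatterer perturbation strictly inside a disc of the given
#' radius around each center, restoring those pixels to their
#' pre-scatterer values; pixels outside the discs are untouched.
#'
#' @param maps an `acoustic_maps` object carrying scatterer bookkeeping
#'   from [add_scatterers()].
#' @param centers list of `c(z, x)` lesion centers (m).
#' @param radius lesion radius (m); 0 is a no-op.
#' @export
add_lesions <- function(maps, centers, radius = 5e-3) {
  stopifnot(inherits(maps, "acoustic_maps"))
  if (radius < 0) stop("parameter error: radius must be >= 0")
  if (radius == 0 || is.null(maps$scatterers) || !nrow(maps$scatterers))
    return(maps)
  co <- map_coords(maps)
  out <- maps
  sc <- maps$scatterers
  keep <- rep(TRUE, nrow(sc))
  for (ctr in centers) {
    if (ctr[1] < min(co$z) || ctr[1] > max(co$z) ||
        ctr[2] < min(co$x) || ctr[2] > max(co$x))
      warning("lesion center outside domain; partial disc applied")
    d2 <- (co$z[sc$i] - ctr[1])^2 + (co$x[sc$j] - ctr[2])^2
    inside <- d2 < radius^2
    if (any(inside)) {
      idx <- cbind(sc$i[inside], sc$j[inside])
      out$rho[idx] <- sc$rho_orig[inside]
      keep <- keep & !inside
    }
  }
  out$scatterers <- sc[keep, , drop = FALSE]
  out
}

#' Point-target specification
#'
#' @param position target center `c(z, x)` (m).
#' @param reflectivity target reflectivity against the background, \[0, 1).
#' @param extent target diameter in pixels (default 1).
#' @export
target_spec <- function(position, reflectivity = 0.5, extent = 1L) {
  if (reflectivity < 0 || reflectivity >= 1)
    stop("parameter error: reflectivity must be in [0, 1)")
  structure(list(position = as.numeric(position),
                 reflectivity = reflectivity, extent = as.integer(extent)),
            class = "target_spec")
}

#' Insert a point target of prescribed reflectivity
#'
#' Adds a compact (default single-pixel) density perturbation whose
#' impedance against the local background satisfies
#' `reflectivity(Z_t, Z_b) = r`, i.e. `Z_t = Z_b (1 + r)/(1 - r)`.
#'
#' @param maps an `acoustic_maps` object.
#' @param spec a [target_spec()].
#' @export
add_point_target <- function(maps, spec) {
  stopifnot(inherits(maps, "acoustic_maps"), inherits(spec, "target_spec"))
  if (spec$reflectivity == 0) return(maps)
  co <- map_coords(maps)
  i0 <- which.min(abs(co$z - spec$position[1]))
  j0 <- which.min(abs(co$x - spec$position[2]))
  if (abs(co$z[i0] - spec$position[1]) > maps$dx ||
      abs(co$x[j0] - spec$position[2]) > maps$dx)
    stop("spec error: target position outside domain")
  r_ext <- (spec$extent - 1) / 2
  ii <- i0 + seq(-floor(r_ext), floor(r_ext))
  jj <- j0 + seq(-floor(r_ext), floor(r_ext))
  ii <- ii[ii >= 1 & ii <= nrow(maps$c)]
  jj <- jj[jj >= 1 & jj <= ncol(maps$c)]
  out <- maps
  for (i in ii) for (j in jj) {
    Zb <- maps$rho[i, j] * maps$c[i, j]
    Zt <- impedance_for_reflectivity(spec$reflectivity, Zb)
    out$rho[i, j] <- Zt / maps$c[i, j]
  }
  out
}

#' Homogeneous speckle phantom with anechoic lesions
#'
#' Convenience constructor for the anechoic-lesion imaging experiment: a
#' homogeneous background at the equilibrium constants, a sub-resolution
#' scatterer field at the calibrated density of 18 scatterers per
#' resolution cell, and circular anechoic lesions carved out by removing
#' all scatterers within the lesion radius.
#'
#' @param domain `c(depth, width)` (m).
#' @param dx grid spacing (m).
#' @param transducer a [transducer()] object (defines the resolution cell).
#' @param focal_depth transmit focal depth used for the resolution cell (m).
#' @param lesion_depths lesion center depths below the array surface (m).
#' @param lesion_radius lesion radius (m), default 5 mm.
#' @param surface_depth depth of the array surface within the grid (m).
#' @param scatter_region `list(z=, x=)` region filled with scatterers (m).
#' @param n_per_rescell,contrast scatterer field parameters.
#' @param seed RNG seed.
#' @param c0,rho0 background medium.
#' @export
speckle_lesion_phantom <- function(domain, dx, transducer, focal_depth,
                                   lesion_depths = c(24e-3, 36e-3, 48e-3),
                                   lesion_radius = 5e-3,
                                   surface_depth = 0,
                                   scatter_region = NULL,
                                   n_per_rescell = 18, contrast = 0.05,
                                   seed = 1L, c0 = 1570, rho0 = 1064) {
  nz <- round(domain[1] / dx); nx <- round(domain[2] / dx)
  maps <- acoustic_maps(matrix(c0, nz, nx), matrix(rho0, nz, nx), dx)
  rc <- resolution_cell_area(transducer, focal_depth, c0)
  spec <- scatterer_spec(n_per_rescell, contrast, rc, seed)
  maps <- add_scatterers(maps, spec, region = scatter_region)
  x_mid <- (min(map_coords(maps)$x) + max(map_coords(maps)$x)) / 2
  centers <- lapply(lesion_depths, function(d) c(surface_depth + d, x_mid))
  add_lesions(maps, centers, lesion_radius)
}
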