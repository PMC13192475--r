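#' Acoustic property maps
#'
#' Container for gridded speed-of-sound and density fields on a uniform 2D
#' grid, the substrate of every simulation and of the map-modulation
#' algebra.  Rows index axial depth (increasing downward from the
#' transducer), columns index the lateral coordinate; physical coordinates
#' refer to pixel centers and are 0-based at `origin`.
#'
#' @param c_map matrix of speed of sound per pixel (m/s), rows axial.
#' @param rho_map matrix of density per pixel (kg/m^3), same shape.
#' @param dx isotropic grid spacing (m).
#' @param label_map optional integer/character matrix of tissue classes.
#' @param origin physical coordinate (axial, lateral) of pixel (1,1) center (m).
#' @return An object of class `acoustic_maps`.
#' @export
acoustic_maps <- function(c_map, rho_map, dx, label_map = NULL,
                          origin = c(0, 0)) {
  if (!is.matrix(c_map) || !is.matrix(rho_map))
    stop("c_map and rho_map must be matrices")
  if (!all(dim(c_map) == dim(rho_map)))
    stop("invalid maps: c_map and rho_map have different shapes")
  if (any(!is.finite(c_map)) || any(!is.finite(rho_map)) ||
      any(c_map <= 0) || any(rho_map <= 0))
    stop("invalid maps: c_map and rho_map must be finite and strictly positive")
  if (!is.numeric(dx) || length(dx) != 1 || dx <= 0)
    stop("invalid maps: dx must be a positive scalar")
  if (!is.null(label_map) && !all(dim(label_map) == dim(c_map)))
    stop("invalid maps: label_map shape mismatch")
  structure(list(c = c_map, rho = rho_map, label = label_map,
                 dx = dx, origin = as.numeric(origin)),
            class = "acoustic_maps")
}

#' @export
print.acoustic_maps <- function(x, ...) {
  cat(sprintf("<acoustic_maps> %d x %d px, dx = %.4g mm\n",
              nrow(x$c), ncol(x$c), x$dx * 1e3))
  cat(sprintf("  c   [%.0f, %.0f] m/s\n", min(x$c), max(x$c)))
  cat(sprintf("  rho [%.0f, %.0f] kg/m^3\n", min(x$rho), max(x$rho)))
  invisible(x)
}

#' Axial / lateral pixel-center coordinates of a map grid
#' @param maps an `acoustic_maps` object.
#' @return list with vectors `z` (axial, m) and `x` (lateral, m).
#' @export
map_coords <- function(maps) {
  list(z = maps$origin[1] + (seq_len(nrow(maps$c)) - 1) * maps$dx,
       x = maps$origin[2] + (seq_len(ncol(maps$c)) - 1) * maps$dx)
}

#' Acoustic impedance field
#'
#' The reference impedance is the element-wise product of density and speed,
#' `Z_ref(x,y) = rho_ref(x,y) * c_ref(x,y)`, in Rayl.
#'
#' @param maps an `acoustic_maps` object.
#' @return matrix of impedance per pixel (Rayl).
#' @export
impedance_map <- function(maps) {
  stopifnot(inherits(maps, "acoustic_maps"))
  maps$rho * maps$c
}

#' Modulation parameters for the map algebra
#'
#' The control surface of the continuous degradation modulation: `gamma`
#' scales the excess impedance (reverberation strength), `zeta` scales the
#' excess sound speed (aberration strength), around the equilibrium
#' constants `c0`, `rho0`, `Z0`.  Defaults follow the calibrated abdominal
#' equilibrium values c0 = 1570 m/s, rho0 = 1064 kg/m^3, Z0 = rho0 * c0.
#'
#' @param gamma impedance-mismatch scale (>= 0).
#' @param zeta excess-speed scale (>= 0).
#' @param c0 equilibrium speed of sound (m/s).
#' @param rho0 equilibrium density (kg/m^3).
#' @param Z0 equilibrium impedance (Rayl); default `rho0 * c0` so that the
#'   gamma = 0, zeta = 0 limit homogenizes exactly to (c0, rho0).
#' @return An object of class `modulation_params`.
#' @export
modulation_params <- function(gamma = 1, zeta = 1, c0 = 1570, rho0 = 1064,
                              Z0 = rho0 * c0) {
  if (gamma < 0 || zeta < 0)
    stop("parameter error: gamma and zeta must be non-negative")
  if (c0 <= 0 || rho0 <= 0 || Z0 <= 0)
    stop("parameter error: c0, rho0, Z0 must be positive")
  structure(list(gamma = gamma, zeta = zeta, c0 = c0, rho0 = rho0, Z0 = Z0),
            class = "modulation_params")
}

#' Isovelocity transformation
#'
#' Sets the speed of sound to a constant `c0` everywhere and rescales the
#' density to `rho_iv = Z_ref / c0` so that the impedance field is preserved
#' exactly.  This removes phase aberration while preserving the
#' reverberation-generating impedance structure.
#'
#' @param maps an `acoustic_maps` object.
#' @param c0 homogeneous speed of sound (m/s).
#' @return transformed `acoustic_maps`; `label_map` is preserved.
#' @export
isovelocity <- function(maps, c0 = 1570) {
  stopifnot(inherits(maps, "acoustic_maps"))
  if (c0 <= 0) stop("parameter error: c0 must be positive")
  Z <- impedance_map(maps)
  out <- maps
  out$c <- matrix(c0, nrow(maps$c), ncol(maps$c))
  out$rho <- Z / c0
  out
}

#' Isoimpedance transformation
#'
#' Keeps the speed field unchanged and rescales the density to
#' `rho_ii = Z0 / c_ref` so that the impedance field is constant at `Z0`
#' everywhere.  This removes the impedance mismatch that generates
#' reverberation while preserving aberration.
#'
#' @param maps an `acoustic_maps` object.
#' @param Z0 homogeneous impedance (Rayl).
#' @return transformed `acoustic_maps`.
#' @export
isoimpedance <- function(maps, Z0 = 1570 * 1064) {
  stopifnot(inherits(maps, "acoustic_maps"))
  if (Z0 <= 0) stop("parameter error: Z0 must be positive")
  out <- maps
  out$rho <- Z0 / maps$c
  out
}

#' Continuous modulation of aberration and reverberation
#'
#' Generalizes the isovelocity/isoimpedance limits to a continuous algebra:
#' the excess speed is scaled by `zeta`,
#' `c_m = c0 + zeta * (c_ref - c0)`, the effective impedance
#' `Z_m = rho_ref * c_m` is decomposed as `Z0 + Z'`, and the excess
#' impedance is scaled by `gamma`, `rho_m = (Z0 + gamma * Z') / c_m`.
#' `gamma = zeta = 1` is the identity; `gamma = zeta = 0` homogenizes the
#' maps to `(c0, rho0)`; `gamma = 0, zeta = 1` is the pure isoimpedance
#' case; `zeta = 0` keeps the speed constant at `c0` (isovelocity family).
#' Values above 1 exaggerate the heterogeneities.
#'
#' @param maps an `acoustic_maps` object.
#' @param params a `modulation_params` object.
#' @return modulated `acoustic_maps`.
#' @export
modulate_maps <- function(maps, params = modulation_params()) {
  stopifnot(inherits(maps, "acoustic_maps"),
            inherits(params, "modulation_params"))
  c_m <- params$c0 + params$zeta * (maps$c - params$c0)
  if (any(c_m <= 0))
    stop("degenerate-map error: modulated speed non-positive")
  Z_excess <- maps$rho * c_m - params$Z0
  rho_m <- (params$Z0 + params$gamma * Z_excess) / c_m
  if (any(rho_m <= 0))
    stop(sprintf(
      "degenerate-map error: gamma = %g yields non-positive density (min %g)",
      params$gamma, min(rho_m)))
  out <- maps
  out$c <- c_m
  out$rho <- rho_m
  out
}

#' Target reflectivity from impedances
#'
#' Reflectivity of a target against its background, defined as the absolute
#' impedance difference over the impedance sum,
#' `|Z_b - Z_t| / (Z_b + Z_t)`; symmetric in its arguments and bounded in
#' \[0, 1).
#'
#' @param Z_target,Z_background impedances (Rayl), positive.
#' @return dimensionless reflectivity.
#' @export
reflectivity <- function(Z_target, Z_background) {
  if (any(Z_target <= 0) || any(Z_background <= 0))
    stop("parameter error: impedances must be positive")
  abs(Z_background - Z_target) / (Z_background + Z_target)
}

#' Target impedance realizing a requested reflectivity
#'
#' Inverts [reflectivity()]: returns the (brighter-side) impedance `Z_t`
#' with `reflectivity(Z_t, Z_b) = r`, i.e. `Z_t = Z_b (1 + r) / (1 - r)`.
#'
#' @param r requested reflectivity in \[0, 1).
#' @param Z_background background impedance (Rayl).
#' @export
impedance_for_reflectivity <- function(r, Z_background) {
  if (any(r < 0) || any(r >= 1))
    stop("parameter error: reflectivity must be in [0, 1)")
  Z_background * (1 + r) / (1 - r)
}
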