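#' Degradation parameters for post-processing augmentation
#'
#' The control surface for augmenting existing RF data with known amounts
#' of the three degradation mechanisms: a receive-side phase screen of
#' prescribed RMS delay (aberration), a reverberation subtraction ratio
#' `beta` (clutter scaling), and a depth-dependent damped-sinusoid trailing
#' kernel with maximum decay time `tau_max`.
#'
#' @param screen_rms requested aberration level (ns).
#' @param screen_corr_len lateral correlation length of the screen
#'   (elements).
#' @param beta reverberation subtraction ratio in \[0, 1\].
#' @param tau_max maximum trailing decay time (ns).
#' @param trail_amp trailing kernel amplitude (dimensionless).
#' @param seed RNG seed.
#' @export
degradation_params <- function(screen_rms = 0, screen_corr_len = 5,
                               beta = 0, tau_max = 0, trail_amp = 0,
                               seed = 1L) {
  if (screen_rms < 0 || tau_max < 0 || trail_amp < 0)
    stop("parameter error: screen_rms, tau_max, trail_amp must be >= 0")
  if (beta < 0 || beta > 1)
    stop("parameter error: beta must be in [0, 1]")
  structure(list(screen_rms = screen_rms, screen_corr_len = screen_corr_len,
                 beta = beta, tau_max = tau_max, trail_amp = trail_amp,
                 seed = seed),
            class = "degradation_params")
}

# zero-mean laterally correlated delay profile with exact RMS (seconds)
draw_phase_screen <- function(n_elements, rms_s, corr_len, seed) {
  with_seed(seed, {
    w <- stats::rnorm(n_elements)
    scr <- if (corr_len > 0)
      as.vector(gaussian_blur(matrix(w, ncol = 1), corr_len)) else w
    scr <- scr - mean(scr)
    r <- sqrt(mean(scr^2))
    if (r == 0) rep(0, n_elements) else scr * rms_s / r
  })
}

# apply per-element fractional delays by a frequency-domain phase ramp
delay_channels <- function(rf, dt, tau) {
  nt <- nrow(rf)
  npad <- stats::nextn(nt + 64L, 2)
  f <- c(0:(npad / 2), -(npad / 2 - 1):-1) / (npad * dt)
  out <- rf
  for (e in seq_len(ncol(rf))) {
    if (tau[e] == 0) next
    X <- stats::fft(c(rf[, e], rep(0, npad - nt)))
    shifted <- Re(stats::fft(X * exp(-2i * pi * f * tau[e]),
                             inverse = TRUE)) / npad
    out[, e] <- shifted[seq_len(nt)]
  }
  out
}

#' Augment aberration with a receive-side phase screen
#'
#' Draws a zero-mean, laterally correlated random delay profile across the
#' elements, rescales it so its RMS equals the request exactly, and applies
#' it per element as a sub-sample fractional delay (frequency-domain phase
#' ramp) to every transmit.  Deterministic per seed; the applied screen is
#' returned alongside the data and the augmentation is inverted exactly by
#' re-applying the negated screen.
#'
#' @param channels a [channel_data()].
#' @param screen_rms requested RMS delay (ns); 0 returns the input exactly.
#' @param corr_len lateral correlation length (elements).
#' @param seed RNG seed.
#' @param screen optional explicit per-element delay vector (s), overriding
#'   the random draw (used e.g. to invert a previous screen).
#' @return a [channel_data()]; the applied per-element delays (s) are in
#'   `$meta$phase_screen`.
#' @export
apply_phase_screen <- function(channels, screen_rms, corr_len = 5, seed = 1L,
                               screen = NULL) {
  stopifnot(inherits(channels, "channel_data"))
  if (is.null(screen)) {
    if (screen_rms < 0) stop("parameter error: screen_rms must be >= 0")
    dur <- dim(channels$rf)[1] * channels$dt
    if (screen_rms * 1e-9 > dur / 10)
      stop("sanity error: screen RMS exceeds a tenth of the record duration")
    if (screen_rms == 0) {
      channels$meta$phase_screen <- rep(0, dim(channels$rf)[2])
      return(channels)
    }
    screen <- draw_phase_screen(dim(channels$rf)[2], screen_rms * 1e-9,
                                corr_len, seed)
  }
  out <- channels
  for (k in seq_len(dim(channels$rf)[3]))
    out$rf[, , k] <- delay_channels(channels$rf[, , k], channels$dt, screen)
  out$meta$phase_screen <- screen
  out
}

#' Scale reverberation by clutter subtraction
#'
#' Subtracts a scaled clutter-only record from the full record,
#' `rf_het - beta * rf_clutter`: `beta = 0` is the identity, `beta = 1`
#' with the exact clutter twin removes multiple reverberation completely.
#' The clutter record must be supplied (the matched target-free twin for
#' simulated data, or a wall-only acquisition for external data); the
#' package does not estimate clutter blindly.
#'
#' @param rf_het full [channel_data()].
#' @param rf_clutter matched clutter-only [channel_data()].
#' @param beta subtraction ratio in \[0, 1\].
#' @export
scale_reverberation <- function(rf_het, rf_clutter, beta) {
  stopifnot(inherits(rf_het, "channel_data"),
            inherits(rf_clutter, "channel_data"))
  if (beta < 0 || beta > 1) stop("parameter error: beta must be in [0, 1]")
  if (!all(dim(rf_het$rf) == dim(rf_clutter$rf)) ||
      abs(rf_het$dt - rf_clutter$dt) > 1e-15)
    stop("incompatibility error: records differ in shape or sampling")
  out <- rf_het
  out$rf <- rf_het$rf - beta * rf_clutter$rf
  out$meta$beta <- beta
  out
}

#' Augment trailing clutter with a depth-dependent damped-sinusoid kernel
#'
#' Convolves each channel, in depth blocks with overlap-add, with the
#' causal kernel `k_z(t) = delta(t) + trail_amp * H(t) *
#' exp(-t / tau(z)) * sin(2 pi f0 t)`, where the decay time `tau(z)` ramps
#' linearly from 0 at the surface to `tau_max` at the maximum recorded
#' depth.  The same kernel is applied to every element (no lateral
#' variability).  `trail_amp = 0` or `tau_max = 0` is the exact identity.
#'
#' @param channels a [channel_data()].
#' @param tau_max maximum decay time (ns).
#' @param trail_amp kernel amplitude.
#' @param f0 kernel frequency (Hz); default the transducer's `f0`.
#' @param block_len overlap-add block length (samples).
#' @export
add_trailing_clutter <- function(channels, tau_max, trail_amp,
                                 f0 = NULL, block_len = 64L) {
  stopifnot(inherits(channels, "channel_data"))
  if (tau_max < 0 || trail_amp < 0)
    stop("parameter error: tau_max and trail_amp must be >= 0")
  if (tau_max == 0 || trail_amp == 0) return(channels)
  if (is.null(f0)) f0 <- channels$transducer$f0
  dt <- channels$dt
  nt <- dim(channels$rf)[1]
  tau_of <- function(s) tau_max * 1e-9 * s / nt   # linear ramp with depth
  klen <- max(8L, ceiling(6 * tau_max * 1e-9 / dt))
  tk <- (seq_len(klen) - 1) * dt
  out <- channels
  starts <- seq(1L, nt, by = block_len)
  for (tx in seq_len(dim(channels$rf)[3])) {
    acc <- matrix(0, nt + klen, dim(channels$rf)[2])
    for (s0 in starts) {
      s1 <- min(s0 + block_len - 1L, nt)
      tau <- tau_of((s0 + s1) / 2)
      tail_k <- trail_amp * exp(-tk / tau) * sin(2 * pi * f0 * tk)
      blk <- channels$rf[s0:s1, , tx, drop = FALSE]
      dim(blk) <- c(s1 - s0 + 1L, dim(channels$rf)[2])
      for (e in seq_len(ncol(blk))) {
        conv <- stats::convolve(blk[, e], rev(tail_k), type = "open")
        rows <- s0:(s1 + klen - 1L)
        acc[rows, e] <- acc[rows, e] + conv
      }
    }
    out$rf[, , tx] <- channels$rf[, , tx] + acc[seq_len(nt), ]
  }
  out$meta$tau_max_ns <- tau_max
  out$meta$trail_amp <- trail_amp
  out
}

#' Isolate, scale, and recombine trailing clutter
#'
#' Per channel: aligns the emission reference peak with the echo peak,
#' classifies samples after the emission's support as trailing clutter,
#' multiplies them by `scale`, and recombines.  `scale = 0` removes
#' trailing clutter; `scale = 2` doubles it; `scale = 1` is the identity.
#' Applicable to point-target (PSF) records with a detectable echo.
#'
#' @param channels a [channel_data()].
#' @param emission_ref pulse waveform vector sampled at the channel `dt`
#'   (e.g. `pulse_waveform(transducer, dt)$w`).
#' @param scale trailing-clutter scale factor (>= 0).
#' @param level fraction of the emission envelope peak below which the
#'   emission is considered over (support threshold).
#' @export
isolate_and_scale_trailing <- function(channels, emission_ref, scale,
                                       level = 0.01) {
  stopifnot(inherits(channels, "channel_data"))
  if (scale < 0) stop("parameter error: scale must be >= 0")
  if (scale == 1) return(channels)
  env_ref <- Mod(analytic_signal(emission_ref))
  pk_ref <- which.max(env_ref)
  over <- which(env_ref >= level * max(env_ref))
  support_after_peak <- max(over) - pk_ref
  out <- channels
  for (tx in seq_len(dim(channels$rf)[3])) {
    for (e in seq_len(dim(channels$rf)[2])) {
      x <- channels$rf[, e, tx]
      env <- Mod(analytic_signal(x))
      pk <- which.max(env)
      if (max(env) == 0) stop("detection error: no detectable echo peak")
      tail_start <- pk + support_after_peak + 1L
      if (tail_start <= length(x))
        x[tail_start:length(x)] <- scale * x[tail_start:length(x)]
      out$rf[, e, tx] <- x
    }
  }
  out$meta$trailing_scale <- scale
  out
}
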