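#' Adjacent-element arrival-time lags
#'
#' For each adjacent element pair, finds the lag maximizing the normalized
#' cross-correlation of their RF traces within a correlation window, refined
#' to sub-sample precision by parabolic interpolation of the correlation
#' peak.  Insensitive to per-channel amplitude scaling.
#'
#' @param channels a [channel_data()].
#' @param window integer `c(lo, hi)` sample bounds, or `NULL` to center a
#'   window of `periods` pulse periods on each element's envelope peak.
#' @param max_lag maximum |lag| searched (original samples).
#' @param periods window length in pulse periods when `window` is `NULL`.
#' @param upsample band-limited (FFT) upsampling factor applied to both
#'   traces before correlation; reduces the bias of the parabolic peak
#'   interpolation for small sub-sample shifts.
#' @param transmit transmit index.
#' @return data.frame with columns `pair`, `lag` (original samples,
#'   fractional), `rho` (peak correlation coefficient).
#' @export
interelement_lags <- function(channels, window = NULL, max_lag = 20L,
                              periods = 3, upsample = 8L, transmit = 1L) {
  stopifnot(inherits(channels, "channel_data"))
  rf <- channels$rf[, , transmit]
  nel <- ncol(rf)
  if (nel < 2) stop("need at least 2 elements")
  U <- max(1L, as.integer(upsample))
  rfu <- if (U > 1) apply(rf, 2, fft_upsample, U) else rf
  ntu <- nrow(rfu)
  half <- NULL
  if (is.null(window)) {
    half <- round(periods / (channels$transducer$f0 * channels$dt) / 2)
    env <- analytic_envelope(rf)
  }
  out <- data.frame(pair = seq_len(nel - 1), lag = NA_real_, rho = NA_real_)
  for (e in seq_len(nel - 1)) {
    w <- if (is.null(window)) {
      pk <- which.max(env[, e])
      c(max(1L, pk - half), min(nrow(rf), pk + half))
    } else window
    idx <- ((w[1] - 1L) * U + 1L):min(ntu, w[2] * U)
    x <- rfu[idx, e]
    if (stats::sd(x) == 0)
      stop("undefined-correlation error: zero-variance window")
    lags <- seq(-max_lag * U, max_lag * U)
    cc <- vapply(lags, function(n) {
      yi <- idx + n
      ok <- yi >= 1 & yi <= ntu
      if (sum(ok) < 8 * U) return(NA_real_)
      y <- rfu[yi[ok], e + 1]
      if (stats::sd(y) == 0) return(NA_real_)
      stats::cor(x[ok], y)
    }, 0)
    k <- which.max(cc)
    lag <- lags[k]
    # parabolic sub-sample refinement of the correlation peak
    if (k > 1 && k < length(cc) && !any(is.na(cc[(k - 1):(k + 1)]))) {
      y1 <- cc[k - 1]; y2 <- cc[k]; y3 <- cc[k + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) lag <- lag + 0.5 * (y1 - y3) / den
    }
    out$lag[e] <- lag / U
    out$rho[e] <- cc[k]
  }
  out
}

#' Arrival-time profile across the aperture
#'
#' Integrates adjacent-element lags into a per-element arrival-time profile
#' (cumulative sum of the pairwise lags times the sampling period) with the
#' mean removed, discarding bulk steering/offset.
#'
#' @param lags data.frame from [interelement_lags()] (or a numeric vector of
#'   pairwise lags in samples).
#' @param dt sampling period (s).
#' @return object of class `arrival_time_profile` with fields `delays`
#'   (s, length `n_elements`) and `dt`.
#' @export
arrival_time_profile <- function(lags, dt) {
  lv <- if (is.data.frame(lags)) lags$lag else as.numeric(lags)
  prof <- cumsum(c(0, lv)) * dt
  prof <- prof - mean(prof)
  structure(list(delays = prof, dt = dt), class = "arrival_time_profile")
}

#' RMS phase aberration
#'
#' Root-mean-square difference between an aberrated and a reference
#' arrival-time profile across the aperture, reported in nanoseconds — the
#' standard strength measure of phase aberration.
#'
#' @param profile_aberrated,profile_reference [arrival_time_profile()]s of
#'   equal length and sampling.
#' @return RMS aberration (ns).
#' @export
rms_aberration <- function(profile_aberrated, profile_reference) {
  a <- profile_aberrated$delays
  r <- profile_reference$delays
  if (length(a) != length(r))
    stop("incompatibility error: profiles differ in length")
  sqrt(mean((a - r)^2)) * 1e9
}

#' Reverberation curve
#'
#' Laterally averaged envelope magnitude versus depth: the mean linear
#' envelope across the lateral axis at each depth, converted to dB relative
#' to the image normalization.  (The linear envelope is averaged first and
#' converted to dB after.)
#'
#' @param bmode a [bmode_image()]; a log-compressed image is converted back
#'   to linear envelope before averaging.
#' @return data.frame with columns `depth` (m) and `level` (dB).
#' @export
reverberation_curve <- function(bmode) {
  stopifnot(inherits(bmode, "bmode_image"))
  lin <- if (bmode$is_log) 10^(bmode$image / 20) else if (is.complex(bmode$image)) Mod(bmode$image) else bmode$image
  lvl <- 20 * log10(pmax(rowMeans(lin), .Machine$double.xmin))
  data.frame(depth = bmode$depth, level = lvl)
}

# receive-delay (focus) the channels of one transmit; linear interpolation
receive_delayed <- function(channels, focus = NULL, c_bf = 1540,
                            transmit = 1L) {
  rf <- channels$rf[, , transmit]
  ev <- channels$events[[transmit]]
  if (is.null(focus)) focus <- ev$focus
  pos <- element_positions(channels$transducer, channels$meta$apex_depth,
                           channels$meta$x_mid)
  d <- sqrt((pos[, 1] - focus[1])^2 + (pos[, 2] - focus[2])^2)
  tau <- d / c_bf - min(d) / c_bf
  nt <- nrow(rf)
  t_axis <- (seq_len(nt) - 1) * channels$dt
  out <- matrix(0, nt, ncol(rf))
  for (e in seq_len(ncol(rf)))
    out[, e] <- stats::approx(t_axis, rf[, e], xout = t_axis + tau[e],
                              rule = 2)$y
  out
}

#' Spatial coherence curve of receive-focused channel data
#'
#' Receive-delays the channel data to the transmit focus, then computes the
#' mean zero-lag normalized correlation between all element pairs at each
#' inter-element distance (lag) `m = 0 .. K-1` within a temporal window
#' around the focal arrival.
#'
#' @param channels a [channel_data()].
#' @param window integer `c(lo, hi)` sample bounds, or `NULL` for a window
#'   of `periods` pulse periods centered on the focal two-way time.
#' @param max_lag largest lag computed (default `K - 1`).
#' @param periods window length (pulse periods) for the automatic window.
#' @param c_bf focusing speed (m/s).
#' @param transmit transmit index.
#' @param align receive-delay the channels to the transmit focus before
#'   correlating (the standard procedure); `FALSE` correlates the raw
#'   traces, e.g. for already-aligned or synthetic data.
#' @return object of class `coherence_curve`: data.frame `lag`, `rho`, with
#'   attribute `K`.
#' @export
coherence_curve <- function(channels, window = NULL, max_lag = NULL,
                            periods = 3, c_bf = 1540, transmit = 1L,
                            align = TRUE) {
  stopifnot(inherits(channels, "channel_data"))
  foc <- if (align)
    receive_delayed(channels, c_bf = c_bf, transmit = transmit)
  else channels$rf[, , transmit]
  K <- ncol(foc)
  if (is.null(max_lag)) max_lag <- K - 1L
  if (is.null(window)) {
    ev <- channels$events[[transmit]]
    pos <- element_positions(channels$transducer, channels$meta$apex_depth,
                             channels$meta$x_mid)
    d <- sqrt((pos[, 1] - ev$focus[1])^2 + (pos[, 2] - ev$focus[2])^2)
    t_echo <- max(ev$delays + d / c_bf) + min(d) / c_bf +
      3 * channels$transducer$n_cycles / (2.355 * channels$transducer$f0)
    ctr <- round(t_echo / channels$dt)
    half <- round(periods / (channels$transducer$f0 * channels$dt) / 2)
    window <- c(max(1L, ctr - half), min(nrow(foc), ctr + half))
  }
  if (window[1] < 1 || window[2] > nrow(foc))
    stop("range error: window outside record")
  seg <- foc[window[1]:window[2], , drop = FALSE]
  seg <- sweep(seg, 2, colMeans(seg))
  nrm <- sqrt(colSums(seg^2))
  rho <- vapply(0:max_lag, function(m) {
    i <- seq_len(K - m)
    num <- colSums(seg[, i, drop = FALSE] * seg[, i + m, drop = FALSE])
    mean(num / (nrm[i] * nrm[i + m]))
  }, 0)
  structure(data.frame(lag = 0:max_lag, rho = rho),
            K = K, class = c("coherence_curve", "data.frame"))
}

#' Lag-one coherence
#'
#' The normalized correlation between nearest-neighbor element signals — an
#' image-quality metric sensitive to acoustic and thermal noise; about
#' 0.95-0.96 for a clean focused speckle acquisition.
#'
#' @param curve a [coherence_curve()].
#' @return scalar `rho(1)`.
#' @export
lag_one_coherence <- function(curve) {
  if (!1 %in% curve$lag) stop("curve lacks lag 1 (need K >= 2)")
  curve$rho[curve$lag == 1]
}

#' Mean speckle brightness over a region of interest
#'
#' Mean dB value of a log-compressed image over an ROI, relative to the
#' image's declared normalization.
#'
#' @param bmode a log-compressed [bmode_image()].
#' @param roi logical mask matrix of the same shape as the image.
#' @return brightness (dB).
#' @export
speckle_brightness <- function(bmode, roi) {
  stopifnot(inherits(bmode, "bmode_image"))
  if (!bmode$is_log) stop("speckle brightness requires a log-compressed image")
  if (!any(roi)) stop("empty ROI")
  mean(bmode$image[roi])
}

#' Lesion contrast-to-noise ratio
#'
#' Contrast-to-noise ratio on log-compressed pixel values,
#' `|mu_bg - mu_lesion| / sqrt(sigma_bg^2 + sigma_lesion^2)`, with a
#' detectability flag that is `FALSE` (not detectable) below `nd_threshold`.
#'
#' @param bmode a log-compressed [bmode_image()].
#' @param lesion_mask,background_mask disjoint logical masks (each >= 100
#'   pixels).
#' @param nd_threshold CNR below which the lesion is flagged not detectable.
#' @return list with `cnr` and `detectable`.
#' @export
cnr <- function(bmode, lesion_mask, background_mask, nd_threshold = 0.1) {
  stopifnot(inherits(bmode, "bmode_image"))
  if (any(lesion_mask & background_mask)) stop("mask error: overlapping masks")
  if (sum(lesion_mask) < 100 || sum(background_mask) < 100)
    stop("mask error: each mask needs at least 100 pixels")
  if (!bmode$is_log) stop("CNR is computed on log-compressed pixels")
  mul <- mean(bmode$image[lesion_mask]); mub <- mean(bmode$image[background_mask])
  sl <- stats::sd(bmode$image[lesion_mask])
  sb <- stats::sd(bmode$image[background_mask])
  v <- abs(mub - mul) / sqrt(sb^2 + sl^2)
  list(cnr = v, detectable = v >= nd_threshold)
}
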