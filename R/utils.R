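## internal helpers

# evaluate expr with a temporary RNG seed, restoring prior RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

db <- function(x, ref = 1) 20 * log10(x / ref)

# separable Gaussian convolution with reflect padding; sigma in pixels
gaussian_blur <- function(mat, sigma) {
  if (sigma == 0) return(mat)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {  # along rows (first dim), reflect-padded
    n <- nrow(m)
    idx <- c(pmin(r:1 + 1L, n), 1:n, pmax(n - (1:r), 1L))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (s in seq_along(k))
      out <- out + k[s] * mp[(s - 1L) + 1:n, , drop = FALSE]
    out
  }
  t(blur1(t(blur1(mat))))
}

# smooth zero-mean lateral noise with a given correlation length (pixels),
# scaled so its peak magnitude equals `amplitude`
smooth_noise_1d <- function(n, corr_px, amplitude) {
  w <- stats::rnorm(n + 6L * ceiling(corr_px))
  h <- as.vector(gaussian_blur(matrix(w, ncol = 1), corr_px))
  h <- h[seq_len(n) + 3L * ceiling(corr_px)]
  h <- h - mean(h)
  m <- max(abs(h))
  if (m == 0) rep(0, n) else amplitude * h / m
}

# analytic signal of a real vector (Hilbert transform via FFT)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# band-limited upsampling by zero-padding the spectrum
fft_upsample <- function(x, U) {
  n <- length(x)
  X <- stats::fft(x)
  m <- n * U
  Y <- complex(m)
  h <- floor(n / 2)
  Y[1:(h + 1)] <- X[1:(h + 1)]
  Y[(m - (n - h - 2)):m] <- X[(h + 2):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# envelope via analytic signal along columns of a matrix
analytic_envelope <- function(m) {
  m <- as.matrix(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_len(ncol(m)))
    out[, j] <- Mod(analytic_signal(m[, j]))
  out
}
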