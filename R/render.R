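# Rendering and camera-noise primitives shared by all simulators.
#
# Coordinate convention: 0-based pixel indices, x = column, y = row,
# positions refer to pixel centres (matrix element [i, j] sits at
# x = j - 1, y = i - 1).

# Accumulate isotropic 2D Gaussian spots onto an image. Each spot is
# rendered over a +/- 4 sigma window; amp is the peak amplitude so the
# integrated intensity of one spot is 2*pi*sigma^2*amp (minus edge
# clipping).
render_spots <- function(height, width, x, y, amp, sigma) {
  img <- matrix(0, height, width)
  n <- length(x)
  if (n == 0L) return(img)
  if (length(amp) == 1L) amp <- rep(amp, n)
  if (length(sigma) == 1L) sigma <- rep(sigma, n)
  for (k in seq_len(n)) {
    r <- ceiling(4 * sigma[k])
    j0 <- max(1L, floor(x[k]) + 1L - r); j1 <- min(width, floor(x[k]) + 1L + r)
    i0 <- max(1L, floor(y[k]) + 1L - r); i1 <- min(height, floor(y[k]) + 1L + r)
    if (j0 > j1 || i0 > i1) next
    gx <- exp(-(((j0:j1) - 1 - x[k])^2) / (2 * sigma[k]^2))
    gy <- exp(-(((i0:i1) - 1 - y[k])^2) / (2 * sigma[k]^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amp[k] * (gy %o% gx)
  }
  img
}

# Poisson shot noise on the expected photon image plus additive Gaussian
# read noise, clamped at zero (camera counts are non-negative).
camera_noise <- function(expected, read_noise_sd = 2) {
  n <- length(expected)
  obs <- stats::rpois(n, lambda = pmax(expected, 0)) +
    stats::rnorm(n, sd = read_noise_sd)
  matrix(pmax(obs, 0), nrow = nrow(expected))
}

# Peak amplitude giving the requested SNR, defined as
# peak / sd(background) with background variance = Poisson(background)
# + read noise.
snr_amplitude <- function(snr, background, read_noise_sd) {
  snr * sqrt(background + read_noise_sd^2)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so simulations do not perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Reflect coordinates into [lo, hi] (keeps random walks inside the frame
# without absorbing at the border).
reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  lo + ifelse(v > span, 2 * span - v, v)
}
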