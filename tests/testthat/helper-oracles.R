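# Independent oracles used across the suite. These deliberately use the
# most literal formulation (double loops, explicit enumeration, textbook
# formulas) and never call the package code paths they check.

# O(n^2) nearest-neighbour scan with explicit loops
brute_nn_percent <- function(a, b, threshold_nm, pixel_size_nm) {
  if (nrow(a) == 0L) return(NA_real_)
  if (nrow(b) == 0L) return(0)
  n_within <- 0L
  for (i in seq_len(nrow(a))) {
    dmin <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2) * pixel_size_nm
      if (d < dmin) dmin <- d
    }
    if (dmin <= threshold_nm) n_within <- n_within + 1L
  }
  100 * n_within / nrow(a)
}

# exact two-sided Wilcoxon rank-sum p by complete enumeration (tie-free)
enum_wilcox_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  sums <- colSums(matrix(r[combs], nrow = n))
  p_le <- mean(sums <= w_obs); p_ge <- mean(sums >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# textbook equal-variance two-sample t
textbook_two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# textbook one-sample t
textbook_one_sample_t <- function(x, mu0) {
  t <- (mean(x) - mu0) / (sd(x) / sqrt(length(x)))
  list(t = t, p = 2 * pt(-abs(t), length(x) - 1))
}

# closed-form least squares via the normal equations
normal_eq_slope <- function(t, y) {
  n <- length(t)
  slope <- (n * sum(t * y) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)
  intercept <- mean(y) - slope * mean(t)
  c(slope = slope, intercept = intercept)
}

# literal double-loop dispersion evaluation
brute_dispersion_um <- function(image, mask, pixel_size_nm) {
  num_x <- 0; num_y <- 0; tot <- 0
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    if (!mask[i, j]) next
    tot <- tot + image[i, j]
    num_x <- num_x + image[i, j] * (j - 1)
    num_y <- num_y + image[i, j] * (i - 1)
  }
  cx <- num_x / tot; cy <- num_y / tot
  acc <- 0
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image))) {
    if (!mask[i, j]) next
    acc <- acc + image[i, j] * sqrt((j - 1 - cx)^2 + (i - 1 - cy)^2)
  }
  acc / tot * pixel_size_nm / 1000
}

# analytic two-state occupancy for the pulse-cohort mixture
# (entry rate ke, exit rate kx, equal cohorts activated at times t_act)
ctmc_occupancy <- function(t, t_act, ke, kx) {
  sapply(t, function(tt) {
    act <- t_act[t_act <= tt]
    if (!length(act)) return(0)
    peq <- if (ke + kx > 0) ke / (ke + kx) else 0
    mean(peq * (1 - exp(-(ke + kx) * (tt - act))))
  })
}

# small detection field rendered without the package's spot renderer
render_field <- function(h, w, x, y, amp, sigma) {
  img <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    img[i, j] <- sum(amp * exp(-(((j - 1) - x)^2 + ((i - 1) - y)^2) /
                                 (2 * sigma^2)))
  }
  img
}
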