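test_that("spot detection localises single and dense fields", {
  cfg <- analysis_config()
  expect_equal(nrow(detect_vesicles(matrix(0, 32, 32), cfg)), 0L)
  # single spot at (32.0, 48.0), SNR 10
  set.seed(5)
  img <- render_field(64, 80, 32, 48, 37.4, 1.5) + 10
  img <- matrix(rpois(length(img), img) + rnorm(length(img), sd = 2),
                nrow(img))
  img <- pmax(img, 0)
  det <- detect_vesicles(img, cfg)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 32), 0.5)
  expect_lt(abs(det$y - 48), 0.5)
  # 50 well-separated spots at SNR 5: recall and precision >= 0.9
  set.seed(6)
  n <- 50; h <- 256
  xs <- ys <- numeric(0)
  while (length(xs) < n) {
    cx <- runif(1, 8, h - 9); cy <- runif(1, 8, h - 9)
    if (!length(xs) || min((xs - cx)^2 + (ys - cy)^2) > 120) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  jj <- matrix(rep(0:(h - 1), each = h), h)   # x coordinate per pixel
  ii <- matrix(rep(0:(h - 1), h), h)          # y coordinate per pixel
  fld <- matrix(10, h, h)
  for (k in seq_len(n))
    fld <- fld + 18.7 * exp(-((jj - xs[k])^2 + (ii - ys[k])^2) / (2 * 1.5^2))
  set.seed(7)
  fld <- pmax(matrix(rpois(h * h, fld) + rnorm(h * h, sd = 2), h), 0)
  det2 <- detect_vesicles(fld, cfg)
  d2 <- outer(det2$y, ys, "-")^2 + outer(det2$x, xs, "-")^2
  recall <- mean(apply(d2, 2, min) < 4)
  precision <- mean(apply(d2, 1, min) < 4)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("exclusion removes centroids on and inside the mask", {
  det <- data.frame(x = c(5, 10.4, 20), y = c(5, 10.4, 20),
                    peak_intensity = 1:3, integrated_intensity = 1:3,
                    radius_px = 2)
  full <- matrix(TRUE, 32, 32)
  expect_equal(nrow(exclude_region(det, full)), 0L)
  none <- matrix(FALSE, 32, 32)
  expect_equal(exclude_region(det, none), det)
  # boundary pixel belongs to the mask: detection at its centre is excluded
  edge <- matrix(FALSE, 32, 32); edge[11, 11] <- TRUE  # pixel (x=10, y=10)
  kept <- exclude_region(det, edge)
  expect_equal(nrow(kept), 2L)
  expect_false(10.4 %in% kept$x && nrow(kept) == 3L)
})

test_that("greedy tracking links trajectories without identity switches", {
  cfg <- analysis_config()
  # one stationary spot over 20 frames
  det1 <- data.frame(frame = 1:20, x = 10 + rnorm(20, sd = 0.05),
                     y = 12 + rnorm(20, sd = 0.05))
  tr1 <- track_vesicles(det1, cfg)
  expect_equal(length(unique(tr1$track_id)), 1L)
  expect_equal(nrow(tr1), 20L)
  # two spots far apart are never merged
  det2 <- rbind(data.frame(frame = rep(1:10, 2),
                           x = rep(c(5, 50), each = 10),
                           y = rep(c(5, 50), each = 10)))
  tr2 <- track_vesicles(det2, cfg)
  expect_equal(length(unique(tr2$track_id)), 2L)
  # Brownian spots with step << spacing: purity >= 0.95
  set.seed(8)
  n <- 20; nf <- 30
  x0 <- seq(10, 200, by = 10); y0 <- rep(seq(20, 200, by = 45), 4)[1:n]
  X <- matrix(0, n, nf); Y <- matrix(0, n, nf)
  X[, 1] <- x0; Y[, 1] <- y0
  for (f in 2:nf) {
    X[, f] <- X[, f - 1] + rnorm(n, sd = 0.5)
    Y[, f] <- Y[, f - 1] + rnorm(n, sd = 0.5)
  }
  det3 <- data.frame(frame = rep(1:nf, each = n),
                     x = as.vector(X), y = as.vector(Y),
                     truth_id = rep(1:n, nf))
  tr3 <- track_vesicles(det3, cfg)
  purity <- mean(vapply(split(tr3$truth_id, tr3$track_id), function(ids)
    max(table(ids)) / length(ids), numeric(1)))
  expect_gte(purity, 0.95)
})

test_that("nearest-neighbour fraction matches the brute-force scan", {
  cfg <- analysis_config()
  px <- 160
  same <- data.frame(x = runif(10, 0, 50), y = runif(10, 0, 50))
  expect_equal(nn_fraction(same, same, cfg, px), 100)
  far_a <- data.frame(x = c(0, 1), y = c(0, 0))
  far_b <- data.frame(x = c(30, 40), y = c(30, 40))  # > 320 nm away
  expect_equal(nn_fraction(far_a, far_b, cfg, px), 0)
  expect_true(is.na(nn_fraction(far_a[0, ], far_b, cfg, px)))
  expect_equal(nn_fraction(far_a, far_b[0, ], cfg, px), 0)
  # exact tie at the threshold counts as within
  tie_a <- data.frame(x = 0, y = 0)
  tie_b <- data.frame(x = 2, y = 0)   # 2 px * 160 nm = 320 nm
  expect_equal(nn_fraction(tie_a, tie_b, cfg, px), 100)
  # 100 random configurations against the O(n^2) oracle
  set.seed(9)
  for (rep in 1:100) {
    na <- sample(1:40, 1); nb <- sample(0:40, 1)
    A <- data.frame(x = runif(na, 0, 60), y = runif(na, 0, 60))
    B <- data.frame(x = runif(max(nb, 1), 0, 60),
                    y = runif(max(nb, 1), 0, 60))[seq_len(nb), , drop = FALSE]
    expect_identical(nn_fraction(A, B, cfg, px),
                     brute_nn_percent(A, B, cfg$nn_threshold_nm, px))
  }
})

test_that("nn fraction is monotone in threshold and translation invariant", {
  set.seed(10)
  A <- data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100))
  B <- data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100))
  px <- 100
  thr <- c(100, 200, 320, 500, 1000)
  f <- vapply(thr, function(tt)
    nn_fraction(A, B, analysis_config(nn_threshold_nm = tt), px),
    numeric(1))
  expect_true(all(diff(f) >= 0))
  shift <- function(d, dx, dy) data.frame(x = d$x + dx, y = d$y + dy)
  expect_equal(nn_fraction(A, B, analysis_config(), px),
               nn_fraction(shift(A, 7.3, -2.1), shift(B, 7.3, -2.1),
                           analysis_config(), px))
})

test_that("randomised control reproduces the spatial-Poisson expectation", {
  cfg <- analysis_config()
  px <- 100; h <- 256
  cell <- matrix(TRUE, h, h)
  A <- data.frame(x = runif(100, 0, h - 1), y = runif(100, 0, h - 1))
  # B empty -> 0 in every iteration
  r0 <- randomized_nn_fraction(A, cell, A[0, ], cfg, px, n_iter = 5,
                               seed = 1)
  expect_true(all(r0$per_iteration == 0))
  # saturating B density -> 100
  dense <- expand.grid(x = seq(0, h - 1, by = 2), y = seq(0, h - 1, by = 2))
  r1 <- randomized_nn_fraction(A, cell, dense, cfg, px, n_iter = 3,
                               seed = 2)
  expect_equal(r1$mean_percent, 100)
  # reproducible given the seed
  r2a <- randomized_nn_fraction(A, cell, dense[1:50, ], cfg, px,
                                n_iter = 10, seed = 3)
  r2b <- randomized_nn_fraction(A, cell, dense[1:50, ], cfg, px,
                                n_iter = 10, seed = 3)
  expect_identical(r2a, r2b)
  # uniform B at density rho: mean approx 100 (1 - exp(-rho pi r^2)),
  # averaged over fresh B realisations to integrate out the B draw
  rho <- 1e-6                       # per nm^2
  area_nm2 <- (h * px)^2
  expected <- 100 * (1 - exp(-rho * pi * 320^2))
  set.seed(11)
  reps <- vapply(1:5, function(i) {
    nb <- rpois(1, rho * area_nm2)
    B <- data.frame(x = runif(nb, 0, h - 1), y = runif(nb, 0, h - 1))
    randomized_nn_fraction(A, cell, B, cfg, px, n_iter = 20,
                           seed = 100 + i)$mean_percent
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 3 * se + 1)
})

test_that("vesicle count trace counts spots outside the exclusion", {
  cfg <- analysis_config()
  blank <- time_lapse_movie(list(a = array(0, c(48, 48, 4))), 160, 0:3)
  expect_true(all(vesicle_count_trace(blank, "a", cfg = cfg)$values == 0))
  # 12 fixed spots per frame at SNR 10, none inside the exclusion circle
  set.seed(12)
  xs <- c(8, 20, 32, 44, 8, 20, 32, 44, 8, 20, 32, 44)
  ys <- c(8, 8, 8, 8, 24, 24, 24, 24, 40, 40, 40, 40)
  arr <- array(0, c(48, 48, 5))
  for (f in 1:5) {
    fr <- render_field(48, 48, xs, ys, 37.4, 1.3) + 10
    arr[, , f] <- pmax(matrix(rpois(48 * 48, fr) + rnorm(48 * 48, sd = 2),
                              48), 0)
  }
  mv <- time_lapse_movie(list(a = arr), 160, 0:4)
  counts <- vesicle_count_trace(mv, "a", cfg = cfg)$values
  expect_true(all(abs(counts - 12) <= 1))
  # exclusion covering every spot zeroes the counts
  all_roi <- roi_circle(24, 24, 40, role = "exclusion")
  expect_true(all(vesicle_count_trace(mv, "a", all_roi, cfg)$values == 0))
})
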