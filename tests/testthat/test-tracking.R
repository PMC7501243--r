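test_that("discoidal filter cancels constants, matches the hand kernel, and is linear", {
  const <- matrix(7, 11, 11)
  expect_equal(discoidal_filter(const, 1, 2), matrix(0, 11, 11))
  # unit impulse at the center; disk(1) = 5 pixels, annulus(1,2] = 8 pixels
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  f <- discoidal_filter(imp, 1, 2)
  expect_equal(f[6, 6], 1 / 5)          # impulse inside own disk
  expect_equal(f[6, 7], 1 / 5)          # distance 1: in the disk
  expect_equal(f[7, 7], -1 / 8)         # distance sqrt(2): annulus
  expect_equal(f[6, 8], -1 / 8)         # distance 2: annulus
  expect_equal(f[6, 9], 0)              # beyond the outer radius
  # linearity
  set.seed(1)
  i1 <- matrix(runif(121), 11, 11); i2 <- matrix(runif(121), 11, 11)
  expect_equal(discoidal_filter(2 * i1 + 3 * i2, 2, 5),
               2 * discoidal_filter(i1, 2, 5) + 3 * discoidal_filter(i2, 2, 5),
               tolerance = 1e-12)
  expect_error(discoidal_filter(const, 3, 2), "r_inner")
})

test_that("peak detection respects threshold, separation and tie rules", {
  img <- matrix(0, 21, 21)
  img[5, 5] <- 10; img[5, 15] <- 8
  pk <- detect_peaks(img, threshold = 1, min_separation = 3)
  expect_equal(nrow(pk), 2)
  expect_setequal(pk$x, c(4, 14))
  # two maxima 2 px apart with min_separation 3: only the brighter survives
  img2 <- matrix(0, 21, 21)
  img2[10, 10] <- 5; img2[10, 12] <- 7
  pk2 <- detect_peaks(img2, threshold = 1, min_separation = 3)
  expect_equal(nrow(pk2), 1)
  expect_equal(c(pk2$x, pk2$y), c(11, 9))
  # exact tie: smaller row, then smaller column wins
  img3 <- matrix(0, 21, 21)
  img3[10, 10] <- 5; img3[12, 10] <- 5
  pk3 <- detect_peaks(img3, threshold = 1, min_separation = 3)
  expect_equal(c(pk3$x, pk3$y), c(9, 9))
  expect_equal(nrow(detect_peaks(matrix(0, 9, 9), 1)), 0)
})

test_that("a noiseless sampled Gaussian is recovered to 1e-6", {
  patch <- sampled_gaussian_patch(15, 15, A = 100, B = 5, s = 1.3,
                                  x0 = 7.25, y0 = 6.75)
  fit <- fit_gaussian_2d(patch)
  expect_true(fit$ok)
  expect_equal(fit$x, 7.25, tolerance = 1e-6)
  expect_equal(fit$y, 6.75, tolerance = 1e-6)
  expect_equal(fit$A, 100, tolerance = 1e-6)
  expect_equal(fit$s, 1.3, tolerance = 1e-6)
  expect_equal(fit$B, 5, tolerance = 1e-6)
  expect_equal(fit$N, 2 * pi * 100 * 1.3^2, tolerance = 1e-5)
  # flat patch: no amplitude, fit-failure signal
  flat <- matrix(3, 9, 9)
  expect_false(fit_gaussian_2d(flat)$ok)
  expect_error(fit_gaussian_2d(matrix(0, 3, 3)), "5x5")
})

test_that("localization precision follows the photon/pixel/background formula", {
  # measured imaging point: ~6 nm limit (5.78 before rounding), um units
  sig <- localization_precision(50200, 1.57, 107, 0.78)
  expect_equal(sig * 1e3, 5.78, tolerance = 1e-3)
  expect_equal(round(sig * 1e3), 6)
  # closed-form limit b = 0, a -> 0: sigma -> s/sqrt(N)
  expect_equal(localization_precision(1e4, 1e-6, 0, 0.15),
               0.15 / sqrt(1e4), tolerance = 1e-4)
  # independent term-by-term evaluation
  N <- 1e4; a <- 0.1; b <- 10; s <- 0.15
  expect_equal(localization_precision(N, a, b, s),
               sqrt(s^2 / N + a^2 / (12 * N) + 8 * pi * s^4 * b^2 / (a^2 * N^2)))
  # monotonicity: decreasing in N, increasing in b
  Ns <- 10^seq(3, 6, length.out = 20)
  expect_true(all(diff(localization_precision(Ns, a, b, s)) < 0))
  bs <- seq(0, 100, length.out = 20)
  expect_true(all(diff(localization_precision(N, a, bs, s)) > 0))
  expect_error(localization_precision(-1, a, b, s), "N")
})

test_that("empirical localization error tracks the closed-form limit on rendered spots", {
  set.seed(42)
  run_mc <- function(N, b, s, reps) {
    err2 <- numeric(0)
    for (r in seq_len(reps)) {
      x0 <- 7 + runif(1, -0.5, 0.5); y0 <- 7 + runif(1, -0.5, 0.5)
      img <- render_video(data.frame(frame = 1, x = x0, y = y0), 1, 15, 15,
                          sigma_px = s, photons = N, background_mean = 50,
                          background_sd = b)[1, , ]
      fit <- fit_gaussian_2d(img, model = "integrated", background_sd = b)
      if (fit$ok) err2 <- c(err2, (fit$x - x0)^2, (fit$y - y0)^2)
    }
    sqrt(mean(err2))
  }
  for (N in c(1e3, 1e4, 1e5)) {
    emp <- run_mc(N, b = 10, s = 1.3, reps = 150)
    pred <- localization_precision(N, a = 1, b = 10, s = 1.3)
    expect_lt(abs(emp / pred - 1), 0.25)
  }
  # at the instrument's half-pixel-sampled operating point the closed form is
  # optimistic; the fit stays within a factor 1.6 of it
  emp <- run_mc(50200, b = 107, s = 0.78 / 1.57, reps = 150)
  pred <- localization_precision(50200, a = 1, b = 107, s = 0.78 / 1.57)
  expect_gt(emp / pred, 0.75)
  expect_lt(emp / pred, 1.6)
})

test_that("field-of-view arithmetic matches the sensor geometry", {
  fov <- estimate_fov(756, 581, 11, 100)
  expect_lt(abs(fov[["width_um"]] - 83), 1)
  expect_lt(abs(fov[["height_um"]] - 64), 1)
  expect_equal(unname(estimate_fov(640, 480, 1, 1)), c(640, 480))
  fov2 <- estimate_fov(2448, 2050, 3.45, 40)
  expect_lt(abs(fov2[["width_um"]] - 211), 1)
  expect_lt(abs(fov2[["height_um"]] - 177), 1.5)  # printed as 176 or 177
})

test_that("linking keeps identities for separated and for dense diffusing beads", {
  # one stationary bead over 100 frames
  det <- replicate(100, data.frame(x = 5, y = 5), simplify = FALSE)
  tr <- link_trajectories(det, radius = 1)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 100)
  # two beads always farther apart than the radius never swap
  det2 <- replicate(50, data.frame(x = c(0, 10), y = c(0, 0)), simplify = FALSE)
  tr2 <- link_trajectories(det2, radius = 2)
  expect_length(tr2, 2)
  expect_true(all(vapply(tr2, function(d) length(unique(d$x)) == 1, logical(1))))
  # 50 diffusing beads, step sd far below radius, spacing far above it
  set.seed(9)
  n_beads <- 50; n_frames <- 40
  x <- matrix(0, n_frames, n_beads); y <- matrix(0, n_frames, n_beads)
  x[1, ] <- seq(0, by = 8, length.out = n_beads); y[1, ] <- 0
  for (f in 2:n_frames) {
    x[f, ] <- x[f - 1, ] + rnorm(n_beads, 0, 0.05)
    y[f, ] <- y[f - 1, ] + rnorm(n_beads, 0, 0.05)
  }
  det3 <- lapply(seq_len(n_frames), function(f) data.frame(x = x[f, ], y = y[f, ]))
  tr3 <- link_trajectories(det3, radius = 1)
  expect_length(tr3, n_beads)
  for (d in tr3) {
    expect_equal(nrow(d), n_frames)
    bead <- which.min(abs(x[1, ] - d$x[1]))
    expect_equal(d$x, x[, bead], tolerance = 1e-12)  # zero identity swaps
  }
  # gaps: a missed detection bridges when max_gap allows it
  det4 <- replicate(9, data.frame(x = 1, y = 1), simplify = FALSE)
  det4[[5]] <- data.frame(x = numeric(0), y = numeric(0))
  tr4 <- link_trajectories(det4, radius = 1, max_gap = 1)
  expect_length(tr4, 1)
  expect_equal(nrow(tr4[[1]]), 8)
})

test_that("drift correction removes linear drift exactly and averages noise down", {
  frames <- 1:500
  drift <- 0.010 * frames  # 10 nm/s at 1 Hz, in um
  mk <- function(x0, y0, nx = 0, ny = 0) {
    data.frame(frame = frames, x = x0 + drift + nx, y = y0 - 0.5 * drift + ny)
  }
  tracks <- list(mk(0, 0), mk(10, 5), mk(20, -3))
  out <- correct_drift(tracks, stuck_idx = 1:3, window = 300, frame_rate = 1)
  for (d in out) {
    expect_lt(diff(range(d$x)), 1e-9)
    expect_lt(diff(range(d$y)), 1e-9)
  }
  # pairwise distances unchanged by the correction
  expect_equal(out[[2]]$x - out[[1]]$x, tracks[[2]]$x - tracks[[1]]$x,
               tolerance = 1e-9)
  # zero drift: output equals input
  still <- list(data.frame(frame = 1:50, x = rep(2, 50), y = rep(3, 50)))
  expect_equal(correct_drift(still, 1, frame_rate = 1)[[1]], still[[1]],
               tolerance = 1e-12, ignore_attr = TRUE)
  # white noise on 5 stuck beads: residual sd bounded by noise propagation
  set.seed(10)
  noisy <- lapply(1:5, function(i) mk(i * 4, 0, rnorm(500, 0, 0.020),
                                      rnorm(500, 0, 0.020)))
  outn <- correct_drift(noisy, 1:5, window = 300, frame_rate = 1)
  sds <- vapply(outn, function(d) stats::sd(d$x), numeric(1))
  expect_true(all(sds <= 0.020 * (1 + 1 / sqrt(5))))
  expect_error(correct_drift(noisy, integer(0)), "skip")
})

test_that("the full detection chain reproduces rendered ground truth", {
  set.seed(11)
  # 100 spots on a grid, rendered with modest noise
  grid <- expand.grid(gx = seq(8, 98, by = 10), gy = seq(8, 98, by = 10))
  pos <- data.frame(frame = 1, x = grid$gx + runif(100, -0.3, 0.3),
                    y = grid$gy + runif(100, -0.3, 0.3))
  stack <- render_video(pos, 1, 106, 106, sigma_px = 1.3, photons = 20000,
                        background_mean = 100, background_sd = 5)
  filt <- discoidal_filter(stack[1, , ], 2, 5)
  pk <- detect_peaks(filt, threshold = 200, min_separation = 5)
  expect_equal(nrow(pk), 100)
  # every detection within a pixel of a true spot
  d2 <- outer(pk$x, pos$x, "-")^2 + outer(pk$y, pos$y, "-")^2
  expect_true(all(sqrt(apply(d2, 1, min)) < 1.5))
})
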