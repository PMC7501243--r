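# Hand-built trajectories against a compact timeline exercise each
# classification stage; cohort-level behavior is covered in the acceptance
# suite.

mini_tl <- default_timeline(reaction_s = 120)

# trajectory skeleton sampled on the timeline's own grid
grid_times <- function(tl) {
  unlist(lapply(seq_len(nrow(tl)), function(i) {
    nf <- round((tl$t1[i] - tl$t0[i]) * tl$fps[i])
    tl$t0[i] + seq_len(nf) / tl$fps[i]
  }))
}

test_that("flow reversal locates the attachment point and flags mobility", {
  tl <- mini_tl
  t <- grid_times(tl)
  rev <- timeline_phase(tl, "reversal")
  x <- rep(10, length(t))
  in_rev <- t > rev$t0 & t <= rev$t1
  first_half <- in_rev & t <= (rev$t0 + rev$t1) / 2
  x[first_half] <- 14; x[in_rev & !first_half] <- 6
  traj <- data.frame(t_s = t, frame = seq_along(t) - 1L, x_um = x, y_um = 5)
  mob <- assess_mobility(traj, tl)
  expect_true(mob$mobile)
  expect_equal(mob$attachment[1], 10)
  expect_equal(mob$reversal_amplitude, 8)
  # stuck bead: amplitude far below the threshold
  set.seed(1)
  stuck <- data.frame(t_s = t, frame = seq_along(t) - 1L,
                      x_um = 10 + rnorm(length(t), 0, 0.01),
                      y_um = 5 + rnorm(length(t), 0, 0.01))
  expect_false(assess_mobility(stuck, tl)$mobile)
  no_rev <- protocol_timeline(data.frame(name = "reaction", t0 = 0, t1 = 10,
                                         flow = 2.5, turns0 = 0, turns1 = 0,
                                         fps = 4))
  expect_error(assess_mobility(traj, no_rev), "missing phase")
})

test_that("projected length is the planar distance to the attachment", {
  traj <- data.frame(t_s = 1:3, frame = 0:2, x_um = c(10, 13, 10),
                     y_um = c(5, 9, 5))
  l <- projected_length(traj, c(10, 5))
  expect_equal(l, c(0, 5, 0))  # 3-4-5 triangle
})

test_that("coiling-series compaction separates single, nicked and multi tethers", {
  tl <- mini_tl
  t <- grid_times(tl)
  turns <- turns_at(tl, t)
  base <- 6
  mk <- function(l_xy) data.frame(t_s = t, l = l_xy)
  # single tether at high force: compaction only when overwound
  l_single <- base - 0.03 * pmax(0, turns - 10)
  cs <- classify_coilability(t, l_single, tl)
  expect_true(cs$coilable); expect_true(cs$single_tether)
  # nicked: no response to turns at all
  cn <- classify_coilability(t, rep(base, length(t)), tl)
  expect_false(cn$coilable)
  # multiply tethered: compaction on both branches
  l_multi <- base - 0.03 * pmax(0, abs(turns) - 10)
  cm <- classify_coilability(t, l_multi, tl)
  expect_true(cm$coilable); expect_false(cm$single_tether)
})

test_that("the force window yields the injected force through the blurred solver", {
  tl <- mini_tl
  fw <- timeline_phase(tl, "force_window")
  nf <- round((fw$t1 - fw$t0) * fw$fps)
  t <- fw$t0 + seq_len(nf) / fw$fps
  l_um <- wlc_extension(0.2e-12) * 1e6
  # the 33 Hz samples are strongly correlated (tau ~ 0.19 s), so a single
  # 60 s window carries limited information; check the median over windows
  ests <- vapply(1:9, function(s) {
    y <- simulate_ou_segment(0.2, l_um, dt = 1 / fw$fps, n_steps = nf,
                             exposure = 10, seed = 50 + s)
    traj <- data.frame(t_s = t, frame = seq_along(t) - 1L, x_um = 10,
                       y_um = 5 + y * 1e6)
    measure_force(traj, tl)$force_pN
  }, numeric(1))
  expect_lt(abs(stats::median(ests) / 0.2 - 1), 0.10)
  y <- simulate_ou_segment(0.2, l_um, dt = 1 / fw$fps, n_steps = nf,
                           exposure = 10, seed = 55)
  traj <- data.frame(t_s = t, frame = seq_along(t) - 1L, x_um = 10,
                     y_um = 5 + y * 1e6)
  fm <- measure_force(traj, tl)
  expect_identical(measure_force(traj, tl), fm)  # deterministic
  short <- traj[1:50, ]
  expect_error(measure_force(short, tl), "samples")
})

test_that("turn-slope calibration is exact without noise and unbiased with it", {
  tl <- mini_tl
  t <- grid_times(tl)
  turns <- turns_at(tl, t)
  l <- 6 - 0.05 * pmax(0, turns - 5)   # 50 nm/turn beyond onset
  expect_equal(calibrate_turn_slope(t, l, tl), 50, tolerance = 1e-9)
  ests <- vapply(1:100, function(s) {
    set.seed(s)
    calibrate_turn_slope(t, l + rnorm(length(t), 0, 0.05), tl)
  }, numeric(1))
  expect_lt(abs(mean(ests) / 50 - 1), 0.05)
  expect_error(calibrate_turn_slope(t, rep(6, length(t)), tl), "compact")
})

test_that("sliding-window bursts convert slopes to cycles/s through the calibration", {
  tl <- mini_tl
  rxn <- timeline_phase(tl, "reaction")
  t <- grid_times(tl)
  # rise at 100 nm/s for 60 s, then compaction at -50 nm/s
  l <- rep(1, length(t))
  in_r <- t > rxn$t0 & t <= rxn$t1
  tt <- t[in_r] - rxn$t0
  l[in_r] <- ifelse(tt <= 60, 1 + 0.1 * tt, 7 - 0.05 * (tt - 60))
  b <- detect_bursts(t, l, turn_slope = 50, tl)
  expect_equal(nrow(b), 2)
  pos <- b[b$sign == "positive_relaxation", ]
  neg <- b[b$sign == "negative_introduction", ]
  expect_equal(pos$velocity_cps, 1.0, tolerance = 1e-6)
  expect_equal(neg$velocity_cps, 0.5, tolerance = 1e-6)
  # velocity invariant holds for every burst record
  expect_equal(abs(b$slope_nm_s), b$velocity_cps * 50 * 2, tolerance = 1e-9)
  expect_equal(pos$start_time, pos$t_start - rxn$t0)
  # flat reaction phase: no bursts
  set.seed(2)
  flat <- 3 + rnorm(length(t), 0, 0.03)
  expect_equal(nrow(detect_bursts(t, flat, 50, tl)), 0)
  # reaction shorter than the window errors out
  short_tl <- default_timeline(reaction_s = 10)
  t2 <- grid_times(short_tl)
  expect_error(detect_bursts(t2, rep(1, length(t2)), 50, short_tl), "window")
})

test_that("net length change tags alpha versus chi reactions", {
  tl <- mini_tl
  rxn <- timeline_phase(tl, "reaction")
  t <- grid_times(tl)
  in_r <- t > rxn$t0 & t <= rxn$t1
  tt <- t[in_r] - rxn$t0
  # alpha: relax upward then recoil below the pre-arrival baseline
  l_a <- rep(2, length(t))
  l_a[in_r] <- ifelse(tt < 30, 2 + 0.1 * tt,
                      ifelse(tt < 60, 5 - 0.15 * (tt - 30), 0.5))
  expect_equal(classify_reaction_mode(t, l_a, tl), "alpha")
  # chi: relax to full extension and stay
  l_c <- rep(2, length(t))
  l_c[in_r] <- ifelse(tt < 30, 2 + 0.1 * tt, 5)
  expect_equal(classify_reaction_mode(t, l_c, tl), "chi")
  # trace ending mid-burst stays untagged
  l_m <- rep(2, length(t))
  l_m[in_r] <- 2 + 0.05 * tt
  expect_warning(res <- classify_reaction_mode(t, l_m, tl), "mid-burst")
  expect_true(is.na(res))
})

test_that("break-rate arithmetic and the degenerate cases behave", {
  r <- compute_break_rates(2, 100, 2, 600)
  expect_equal(r$ratio, 6.0)
  expect_false(r$ratio_infinite)
  r0 <- compute_break_rates(0, 100, 0, 600)
  expect_equal(r0$burst_rate, 0)
  expect_true(r0$ratio_infinite)
  expect_true(is.na(r0$ratio))
  rI <- compute_break_rates(3, 100, 0, 600)
  expect_true(is.infinite(rI$ratio))
  expect_true(rI$ratio_infinite)
})

test_that("dose-response fits recover the one-site inhibition parameters", {
  conc <- c(0, 0.078, 0.156, 0.312, 1.25, 2.5, 5, 20)
  truth <- 0.1 + (1.2 - 0.1) / (1 + conc / 1)
  fit <- fit_dose_response(conc, truth)
  expect_equal(fit$IC50, 1, tolerance = 1e-6)
  expect_equal(fit$top, 1.2, tolerance = 1e-6)
  expect_equal(fit$bottom, 0.1, tolerance = 1e-6)
  # 5% multiplicative noise: median IC50 error within 20%
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    f <- fit_dose_response(conc, truth * (1 + rnorm(8, 0, 0.05)))
    abs(f$IC50 / 1 - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.20)
  expect_error(fit_dose_response(conc, rep(0.5, 8)), "constant")
  expect_error(fit_dose_response(c(0, 1, 2), c(1, 0.5, 0.2)), "4 distinct")
})

test_that("treadmilling cycle counts halve the rotation rate", {
  expect_equal(count_treadmill_cycles(8, 1), 4)
  expect_equal(count_treadmill_cycles(0, 100), 0)
  expect_equal(count_treadmill_cycles(c(2, 4, 8), 1800), c(1800, 3600, 7200))
})

test_that("thermal debiasing restores the underlying projected length", {
  tl <- mini_tl
  t <- grid_times(tl)
  set.seed(3)
  l_true <- seq(0.5, 3, length.out = length(t))
  dy <- rnorm(length(t), 0, 0.24)
  l_obs <- sqrt(l_true^2 + dy^2)
  deb <- debias_projected_length(t, l_obs, dy, tl)
  expect_lt(abs(mean(deb - l_true)), abs(mean(l_obs - l_true)))
  expect_lt(abs(mean(deb[l_true < 1] - l_true[l_true < 1])), 0.02)
})
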