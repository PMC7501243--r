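kB <- 1.380649e-23

test_that("OU segments reach the equipartition variance and are seed-deterministic", {
  # stationary variance kB*T*l/F at the gyrase operating point
  y <- simulate_ou_segment(0.2, 4.4, dt = 1, n_steps = 1e5, seed = 1)
  var_target <- kB * 296 * 4.4e-6 / 0.2e-12
  expect_equal(var_target, 8.99e-14, tolerance = 1e-3)
  expect_lt(abs(stats::var(y) / var_target - 1), 0.02)
  expect_identical(simulate_ou_segment(0.2, 4.4, dt = 1, n_steps = 100, seed = 7),
                   simulate_ou_segment(0.2, 4.4, dt = 1, n_steps = 100, seed = 7))
  expect_error(simulate_ou_segment(-1, 4.4), "positive")
})

test_that("within-exposure averaging attenuates the variance by the blur factor", {
  bead <- bead_model()
  for (alpha in c(0.1, 0.3, 1, 3)) {
    F_pN <- 0.5
    l_um <- wlc_extension(F_pN * 1e-12) * 1e6
    k <- F_pN * 1e-12 / (l_um * 1e-6)
    tau <- bead$gamma / k
    y <- simulate_ou_segment(F_pN, l_um, bead, dt = alpha * tau,
                             n_steps = 6e4, exposure = 50, seed = 100 + alpha * 10)
    var_inf <- kB * 296 / k
    expect_lt(abs(stats::var(y) / var_inf - blur_factor(alpha)),
              0.03 * blur_factor(alpha) + 0.01 * (alpha >= 3))
  }
})

test_that("hat curves are symmetric at low force and one-sided above the melt force", {
  m <- hat_curve_model()
  n <- seq(-150, 150, by = 5)
  low <- extension_vs_turns(n, 0.3, m)
  expect_equal(low, rev(low))                       # symmetric hat
  expect_equal(extension_vs_turns(100, 0.3, m),
               extension_vs_turns(-100, 0.3, m))
  high <- extension_vs_turns(n, 2, m)
  expect_equal(extension_vs_turns(-100, 2, m), extension_vs_turns(0, 2, m))
  expect_lt(extension_vs_turns(100, 2, m), extension_vs_turns(0, 2, m))
  # beyond the onset the compaction is exactly linear
  onset <- buckling_onset(2, m)
  nn <- ceiling(onset) + 10:40
  ext <- extension_vs_turns(nn, 2, m)
  expect_equal(diff(ext), rep(-m$slope_per_turn * 1e-3, length(nn) - 1),
               tolerance = 1e-9)
  # multiply-tethered response compacts on both branches regardless of force
  both <- extension_vs_turns(n, 2, m, both_branches = TRUE)
  expect_equal(both, rev(both))
})

test_that("supercoiling density bookkeeping uses the relaxed linking number", {
  expect_equal(supercoil_sigma(150), 0.075)
  expect_equal(supercoil_sigma(-150), -0.075)
  expect_equal(supercoil_sigma(150, Lk0 = 1000), 0.15)
})

test_that("the default timeline is contiguous and carries the coiling series", {
  tl <- default_timeline()
  expect_s3_class(tl, "protocol_timeline")
  expect_identical(tl$name, c("reversal", "coil_neg", "uncoil", "coil_pos",
                              "force_window", "partial_uncoil", "reaction"))
  expect_equal(tl$t0[-1], tl$t1[-nrow(tl)])
  # partial uncoil stops after 40 turns leaving +110
  pu <- timeline_phase(tl, "partial_uncoil")
  expect_equal(pu$turns0 - pu$turns1, 40)
  expect_equal(pu$turns1, 110)
  expect_equal(timeline_phase(tl, "force_window")$fps, 33)
  expect_error(timeline_phase(tl, "sds_wash"), "missing phase")
  expect_equal(turns_at(tl, (pu$t0 + pu$t1) / 2), 130)
})

test_that("simulated protocol traces encode the class-specific physics", {
  tl <- default_timeline()
  kin <- gyrase_kinetics(v_pos = 1.0, v_neg = 0.5, break_hazard_burst = 0,
                         break_hazard_background = 0)
  m <- hat_curve_model(slope_per_turn = 50)
  rec <- simulate_protocol_trace("single", tl, kin, m, force_pN = 0.35,
                                 noise_sd_um = 1e-4, seed = 21)
  expect_identical(rec$parameters$truth_class, "single")
  tr <- rec$trajectory
  expect_true(all(diff(tr$t_s) > 0))
  # gyrase-phase extension slope = v_pos * 2 * slope_per_turn = 100 nm/s
  att <- c(rec$parameters$truth_attach_x, rec$parameters$truth_attach_y)
  lxy <- projected_length(tr, att)
  rxn <- timeline_phase(tl, "reaction")
  t_arr <- rxn$t0 + 22; t_mid <- rxn$t0 + 50   # arrival in [20, 40] s
  sel <- tr$t_s > pmax(t_arr, rxn$t0 + 42) & tr$t_s < rxn$t0 + 52
  fit <- stats::lm(lxy[sel] ~ tr$t_s[sel])
  expect_equal(unname(stats::coef(fit)[2]) * 1e3, 100, tolerance = 10)
  # nicked molecules ignore turns entirely
  rec_n <- simulate_protocol_trace("nicked", tl, kin, m, force_pN = 0.35,
                                   noise_sd_um = 1e-4, seed = 22)
  lxy_n <- projected_length(rec_n$trajectory,
                            c(rec_n$parameters$truth_attach_x,
                              rec_n$parameters$truth_attach_y))
  coil <- timeline_phase(tl, "coil_pos")
  sel_c <- rec_n$trajectory$t_s > coil$t0 & rec_n$trajectory$t_s <= coil$t1
  expect_lt(diff(range(lxy_n[sel_c])), 0.6)  # thermal wiggle only, no hat
  # stuck beads barely move
  rec_s <- simulate_protocol_trace("stuck", tl, kin, m, seed = 23)
  expect_lt(stats::sd(rec_s$trajectory$x_um), 0.05)
})

test_that("cohorts have exact stratified counts and are byte-deterministic", {
  spec <- cohort_spec(n_molecules = 40,
                      fractions = c(stuck = 0.1, nicked = 0.2,
                                    multi = 0.2, single = 0.5),
                      seed = 33)
  design <- cohort_truth_design(spec)
  expect_equal(unname(table(design$class)[c("stuck", "nicked", "multi", "single")]),
               c(4, 8, 8, 20), ignore_attr = TRUE)
  tl <- default_timeline(reaction_s = 60)  # abbreviated for speed
  a1 <- simulate_cohort(spec, tl)
  a2 <- simulate_cohort(spec, tl)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_archive(a1, p1); write_archive(a2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  expect_equal(length(a1), 40L)
  expect_identical(unname(vapply(a1$records, function(r)
    r$parameters$truth_class, character(1))), design$class)
  expect_error(cohort_spec(10, fractions = c(stuck = 0.5, nicked = 0.2,
                                             multi = 0.2, single = 0.2)),
               "sum to 1")
})

test_that("rendered stacks are deterministic and refittable", {
  pos <- data.frame(frame = 1, x = 7.3, y = 6.6)
  s1 <- render_video(pos, 1, 15, 15, photons = 30000, background_sd = 5,
                     seed = 3)
  s2 <- render_video(pos, 1, 15, 15, photons = 30000, background_sd = 5,
                     seed = 3)
  expect_identical(s1, s2)
  # noiseless render: position recovered to 1e-3 px
  clean <- render_video(pos, 1, 15, 15, sigma_px = 1.3, photons = 30000,
                        background_mean = 0, background_sd = 0)
  fit <- fit_gaussian_2d(clean[1, , ])
  expect_equal(fit$x, 7.3, tolerance = 1e-3)
  expect_equal(fit$y, 6.6, tolerance = 1e-3)
  expect_warning(render_video(data.frame(frame = 1, x = -5, y = 2), 1, 15, 15),
                 "clipped")
  # TIFF round trip within 16-bit quantization; bytes stable under a seed
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(s1, path)
  back <- read_stack_tiff(path)
  expect_equal(dim(back), dim(s1))
  expect_lt(max(abs(back - pmax(pmin(s1, 65535), 0))), 1.01)
})
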