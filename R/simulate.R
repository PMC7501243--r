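# Synthetic-data generator: Ornstein-Uhlenbeck lateral bead fluctuations
# with camera motion blur, extension-versus-turns "hat" curves with
# force-dependent buckling asymmetry, full protocol traces (flow reversal,
# coiling series, high-frame-rate force window, partial uncoil, gyrase
# bursts, rare tether breaks), ground-truth-labeled cohorts, and rendered
# image stacks.

#' Experiment protocol timeline
#'
#' The piecewise schedule of an experiment: for each phase its name, start
#' and end time, flow rate, cumulative magnet turns at both ends (turns are
#' linear within a phase) and camera frame rate. Phases must be contiguous
#' and non-overlapping.
#'
#' @param phases Data frame with columns `name`, `t0`, `t1`, `flow`
#'   (ul/min), `turns0`, `turns1`, `fps`.
#' @return Object of class `protocol_timeline` (the validated data frame).
#' @export
protocol_timeline <- function(phases) {
  need <- c("name", "t0", "t1", "flow", "turns0", "turns1", "fps")
  stopifnot(is.data.frame(phases), all(need %in% names(phases)))
  if (any(phases$t1 <= phases$t0)) stop("protocol_timeline: need t1 > t0")
  if (nrow(phases) > 1 &&
      any(abs(phases$t0[-1] - phases$t1[-nrow(phases)]) > 1e-9)) {
    stop("protocol_timeline: phases must be contiguous and non-overlapping")
  }
  if (any(phases$fps <= 0)) stop("protocol_timeline: fps must be positive")
  structure(phases, class = c("protocol_timeline", "data.frame"))
}

#' Default classification protocol timeline
#'
#' Flow reversal (mobility check), a coiling series at elevated flow
#' (-150 turns, back to 0, +150 turns) for coilability and tether
#' multiplicity, a high-frame-rate (33 Hz) force window at reaction flow, a
#' partial uncoil of 40 turns leaving the DNA positively supercoiled
#' (+110 turns), and the reaction phase.
#'
#' @param reaction_flow Reaction-phase flow in ul/min (default 2.5).
#' @param coil_flow Coiling-series flow in ul/min (default 16, high force:
#'   above the ~1 pN melt force yet below the positive-buckling ceiling for
#'   essentially all beads).
#' @param reaction_s Reaction-phase duration in s.
#' @param force_window_s Duration of the 33 Hz force window in s.
#' @param fps_slow,fps_fast Frame rates (Hz) for standard phases and the
#'   force window.
#' @return A [protocol_timeline()].
#' @export
default_timeline <- function(reaction_flow = 2.5, coil_flow = 16,
                             reaction_s = 300, force_window_s = 60,
                             fps_slow = 4, fps_fast = 33) {
  coil_s <- 37.5  # 150 turns at 4 turns/s
  t <- cumsum(c(0, 20, coil_s, coil_s, coil_s, force_window_s, 10, reaction_s))
  protocol_timeline(data.frame(
    name = c("reversal", "coil_neg", "uncoil", "coil_pos", "force_window",
             "partial_uncoil", "reaction"),
    t0 = t[1:7], t1 = t[2:8],
    flow = c(reaction_flow, coil_flow, coil_flow, coil_flow, reaction_flow,
             reaction_flow, reaction_flow),
    turns0 = c(0, 0, -150, 0, 150, 150, 110),
    turns1 = c(0, -150, 0, 150, 150, 110, 110),
    fps = c(fps_slow, fps_slow, fps_slow, fps_slow, fps_fast, fps_slow,
            fps_slow)))
}

#' Coerce a stored timeline back into a `protocol_timeline`
#'
#' Accepts a `protocol_timeline`, a data frame, or the list-of-rows /
#' list-of-columns forms that JSON or YAML round trips produce (e.g. the
#' `timeline` entry of archive metadata).
#'
#' @param x Timeline in any of the supported representations.
#' @return A [protocol_timeline()].
#' @export
as_protocol_timeline <- function(x) {
  if (inherits(x, "protocol_timeline")) return(x)
  if (is.data.frame(x)) return(protocol_timeline(x))
  if (is.list(x) && length(x) > 0) {
    if (!is.null(names(x)) && all(c("name", "t0", "t1") %in% names(x))) {
      df <- data.frame(name = unlist(x$name), t0 = unlist(x$t0),
                       t1 = unlist(x$t1), flow = unlist(x$flow),
                       turns0 = unlist(x$turns0), turns1 = unlist(x$turns1),
                       fps = unlist(x$fps), stringsAsFactors = FALSE)
      return(protocol_timeline(df))
    }
    rows <- lapply(x, function(r) {
      data.frame(name = r$name, t0 = r$t0, t1 = r$t1, flow = r$flow,
                 turns0 = r$turns0, turns1 = r$turns1, fps = r$fps,
                 stringsAsFactors = FALSE)
    })
    return(protocol_timeline(do.call(rbind, rows)))
  }
  stop("as_protocol_timeline: unsupported timeline representation")
}

#' Look up a phase of a timeline by name
#' @param tl A `protocol_timeline`.
#' @param name Phase name.
#' @param required Error if the phase is absent (default TRUE).
#' @return One-row data frame, or NULL when absent and not required.
#' @export
timeline_phase <- function(tl, name, required = TRUE) {
  i <- which(tl$name == name)
  if (length(i) == 0) {
    if (required) stop(sprintf("timeline is missing phase '%s'", name))
    return(NULL)
  }
  tl[i[1], ]
}

#' Cumulative magnet turns at given times
#' @param tl A `protocol_timeline`.
#' @param t Times in s.
#' @return Turns, linearly interpolated within phases.
#' @export
turns_at <- function(tl, t) {
  out <- rep(NA_real_, length(t))
  for (i in seq_len(nrow(tl))) {
    in_ph <- t >= tl$t0[i] & t <= tl$t1[i]
    frac <- (t[in_ph] - tl$t0[i]) / (tl$t1[i] - tl$t0[i])
    out[in_ph] <- tl$turns0[i] + frac * (tl$turns1[i] - tl$turns0[i])
  }
  out
}

#' Supercoiling density for a turn count
#'
#' `sigma = n / Lk0` with the relaxed linking number `Lk0 = 2000` by
#' default (150 turns then corresponds to sigma = 0.075).
#'
#' @param n Signed turns.
#' @param Lk0 Relaxed linking number.
#' @export
supercoil_sigma <- function(n, Lk0 = 2000) n / Lk0

#' Hat-curve model for extension versus turns
#'
#' Phenomenological model of plectonemic compaction: extension is flat up to
#' a force-dependent buckling onset, then falls linearly at
#' `slope_per_turn`. Below `melt_above` the response is symmetric in the
#' sign of the turns; at or above it the underwound branch is flat (local
#' melting absorbs negative turns). The onset is linear in force through
#' the anchor "buckling at `anchor_turns` turns at `anchor_force` pN".
#'
#' @param slope_per_turn Compaction slope beyond buckling in nm/turn
#'   (default 30).
#' @param melt_above Force (pN) at and above which negative turns cause no
#'   compaction (default 1).
#' @param anchor_turns,anchor_force Positive-buckling anchor (150 turns at
#'   6.5 pN).
#' @param min_extension_um Floor on the projected length (um) once fully
#'   compacted.
#' @return Object of class `hat_curve_model`.
#' @export
hat_curve_model <- function(slope_per_turn = 30, melt_above = 1,
                            anchor_turns = 150, anchor_force = 6.5,
                            min_extension_um = 0.05) {
  stopifnot(slope_per_turn > 0, melt_above > 0)
  structure(list(slope_per_turn = slope_per_turn, melt_above = melt_above,
                 anchor_turns = anchor_turns, anchor_force = anchor_force,
                 min_extension_um = min_extension_um),
            class = "hat_curve_model")
}

#' Buckling onset in turns at a given force
#' @param F_pN Force in pN.
#' @param model A [hat_curve_model()].
#' @return Onset turns (>= 1).
#' @export
buckling_onset <- function(F_pN, model = hat_curve_model()) {
  pmax(1, model$anchor_turns * F_pN / model$anchor_force)
}

#' Extension versus turns (hat curve)
#'
#' @param n Signed turns (vectorized).
#' @param F_pN Applied force in pN.
#' @param model A [hat_curve_model()].
#' @param p A [wlc_params()] object (sets the zero-turn extension).
#' @param both_branches Force compaction on both branches regardless of the
#'   melt force (multiply-tethered beads behave this way).
#' @return Projected length in um.
#' @export
extension_vs_turns <- function(n, F_pN, model = hat_curve_model(),
                               p = wlc_params(), both_branches = FALSE) {
  ext <- wlc_extension(F_pN * 1e-12, p) * 1e6
  onset <- buckling_onset(F_pN, model)
  over <- pmax(0, abs(n) - onset)
  comp <- model$slope_per_turn * 1e-3 * over
  if (!both_branches && F_pN >= model$melt_above) comp[n < 0] <- 0
  pmax(ext - comp, model$min_extension_um)
}

#' Gyrase kinetics for simulated reactions
#'
#' @param v_pos Positive supercoil relaxation velocity in cycles/s
#'   (default 1.26).
#' @param v_neg Negative supercoil introduction velocity in cycles/s
#'   (default 0.65).
#' @param pause_s Pause between relaxation and introduction in s.
#' @param arrival_range_s Range (s after reaction start) from which the
#'   gyrase arrival time is drawn uniformly.
#' @param break_hazard_burst Tether-break hazard during activity bursts
#'   (1/s).
#' @param break_hazard_background Break hazard outside bursts within the
#'   reaction phase (1/s).
#' @param neg_turns_final Turns at which negative introduction stalls
#'   (alpha mode).
#' @param mode_force_threshold Force (pN) separating alpha (below) from chi
#'   (at or above).
#' @return Object of class `gyrase_kinetics`.
#' @export
gyrase_kinetics <- function(v_pos = 1.26, v_neg = 0.65, pause_s = 10,
                            arrival_range_s = c(20, 40),
                            break_hazard_burst = 3e-5,
                            break_hazard_background = 1e-5,
                            neg_turns_final = -150,
                            mode_force_threshold = 0.5) {
  stopifnot(v_pos >= 0, v_neg >= 0, pause_s >= 0,
            break_hazard_burst >= 0, break_hazard_background >= 0)
  structure(list(v_pos = v_pos, v_neg = v_neg, pause_s = pause_s,
                 arrival_range_s = arrival_range_s,
                 break_hazard_burst = break_hazard_burst,
                 break_hazard_background = break_hazard_background,
                 neg_turns_final = neg_turns_final,
                 mode_force_threshold = mode_force_threshold),
            class = "gyrase_kinetics")
}

#' Simulate an Ornstein-Uhlenbeck bead-fluctuation segment
#'
#' Exact discretization of the OU process with spring constant `k = F/l`,
#' relaxation time `tau = gamma/k` and stationary variance `kB*T*l/F`:
#' `y[i+1] = y[i]*exp(-dt/tau) + xi*sqrt(var_inf*(1 - exp(-2*dt/tau)))`.
#' When `exposure > 1`, each camera sample is the mean of `exposure`
#' equally spaced substeps spanning the frame interval, emulating motion
#' blur from within-exposure averaging; choose `exposure` large enough that
#' the substep is below `tau/10` for faithful blur statistics.
#'
#' @param F_pN Force in pN.
#' @param l_um Extension in um.
#' @param bead A [bead_model()].
#' @param temperature_K Temperature in K.
#' @param dt Camera frame interval in s.
#' @param n_steps Number of camera samples.
#' @param exposure Substeps averaged per camera sample (1 = no blur).
#' @param seed Optional seed for reproducibility.
#' @return Numeric vector of `n_steps` lateral positions in m.
#' @export
simulate_ou_segment <- function(F_pN, l_um, bead = bead_model(),
                                temperature_K = 296, dt = 1/33,
                                n_steps = 1000, exposure = 1, seed = NULL) {
  if (F_pN <= 0 || l_um <= 0) {
    stop("simulate_ou_segment: force and length must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  F <- F_pN * 1e-12
  l <- l_um * 1e-6
  k <- F / l
  tau <- bead$gamma / k
  var_inf <- .kB * temperature_K / k
  m <- as.integer(exposure)
  dt_sub <- dt / m
  a <- exp(-dt_sub / tau)
  sd_step <- sqrt(var_inf * (1 - a^2))
  n_tot <- n_steps * m
  eps <- stats::rnorm(n_tot, 0, sd_step)
  y0 <- stats::rnorm(1, 0, sqrt(var_inf))
  y <- as.numeric(stats::filter(eps, a, method = "recursive", init = y0))
  if (m > 1) y <- colMeans(matrix(y, nrow = m))
  y
}

# force experienced in a phase: the molecule's reaction-flow force scaled
# linearly with flow (force rises linearly with flow rate in FMT)
phase_force <- function(force_pN, flow, reaction_flow) {
  force_pN * flow / reaction_flow
}

#' Simulate one molecule through the full protocol
#'
#' Produces the complete trace for one tether of a given class: flow
#' reversal excursions around the attachment point, the coiling-series
#' response (single tethers compact only when overwound at high force,
#' nicked molecules ignore turns, multiply-tethered beads compact on both
#' branches), the 33 Hz force window with blurred OU fluctuations, the
#' partial uncoil, and the gyrase phase (relaxation burst at `v_pos`
#' cycles/s, pause, negative introduction at `v_neg` cycles/s for alpha
#' mode), with optional rare tether breaks from the configured hazards.
#' Ground-truth labels are stored as record parameters prefixed `truth_`.
#'
#' @param class One of "stuck", "nicked", "multi", "single".
#' @param tl A [protocol_timeline()].
#' @param kinetics A [gyrase_kinetics()].
#' @param model A [hat_curve_model()].
#' @param p A [wlc_params()].
#' @param bead A [bead_model()].
#' @param force_pN Reaction-flow force for this molecule (pN).
#' @param noise_sd_um Tracking (localization) noise sd on x in um.
#' @param attachment Attachment point `c(x, y)` in um.
#' @param uid Record uid (generated when NULL).
#' @param seed Optional per-molecule seed.
#' @param blur_substeps Substeps per frame in the force window.
#' @return A `mol_record` with truth parameters.
#' @export
simulate_protocol_trace <- function(class = "single", tl = default_timeline(),
                                    kinetics = gyrase_kinetics(),
                                    model = hat_curve_model(),
                                    p = wlc_params(), bead = bead_model(),
                                    force_pN = 0.35, noise_sd_um = 0.05,
                                    attachment = c(10, 10), uid = NULL,
                                    seed = NULL, blur_substeps = 8) {
  stopifnot(class %in% c("stuck", "nicked", "multi", "single"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(uid)) uid <- fmt_uuid(1)
  reaction_flow <- timeline_phase(tl, "reaction")$flow
  mode <- if (force_pN < kinetics$mode_force_threshold) "alpha" else "chi"

  # gyrase schedule (single tethers only)
  rxn <- timeline_phase(tl, "reaction")
  t_arr <- rxn$t0 + stats::runif(1, kinetics$arrival_range_s[1],
                                 kinetics$arrival_range_s[2])
  n0 <- rxn$turns0
  t_relax_end <- t_arr + abs(n0) / max(2 * kinetics$v_pos, 1e-9)
  t_pause_end <- t_relax_end + kinetics$pause_s
  n_final <- if (mode == "alpha") kinetics$neg_turns_final else 0
  t_neg_end <- t_pause_end + abs(n_final) / max(2 * kinetics$v_neg, 1e-9)
  bursts_true <- if (class == "single") {
    rbind(
      data.frame(sign = "positive_relaxation", t_start = t_arr,
                 t_end = min(t_relax_end, rxn$t1)),
      if (mode == "alpha" && t_pause_end < rxn$t1) {
        data.frame(sign = "negative_introduction", t_start = t_pause_end,
                   t_end = min(t_neg_end, rxn$t1))
      })
  } else NULL

  # effective turns felt by the molecule during the reaction
  reaction_turns <- function(t) {
    n <- rep(n0, length(t))
    relax <- t >= t_arr & t < t_relax_end
    n[relax] <- n0 - sign(n0) * 2 * kinetics$v_pos * (t[relax] - t_arr)
    n[t >= t_relax_end] <- 0
    if (mode == "alpha") {
      neg <- t >= t_pause_end & t < t_neg_end
      n[neg] <- -2 * kinetics$v_neg * (t[neg] - t_pause_end)
      n[t >= t_neg_end] <- n_final
    }
    n
  }

  # tether break time (single class only): piecewise-constant hazard over
  # the reaction phase, elevated inside true activity windows
  t_break <- Inf
  if (class == "single" &&
      (kinetics$break_hazard_burst > 0 || kinetics$break_hazard_background > 0)) {
    edges <- sort(unique(c(rxn$t0, rxn$t1,
                           pmax(rxn$t0, pmin(rxn$t1, c(bursts_true$t_start,
                                                       bursts_true$t_end))))))
    u <- stats::rexp(1)
    acc <- 0
    for (i in seq_len(length(edges) - 1)) {
      mid <- (edges[i] + edges[i + 1]) / 2
      in_burst <- !is.null(bursts_true) &&
        any(mid >= bursts_true$t_start & mid <= bursts_true$t_end)
      h <- if (in_burst) kinetics$break_hazard_burst else kinetics$break_hazard_background
      seg <- edges[i + 1] - edges[i]
      if (acc + h * seg >= u) {
        t_break <- edges[i] + (u - acc) / h
        break
      }
      acc <- acc + h * seg
    }
  }

  frames <- list()
  frame0 <- 0L
  for (i in seq_len(nrow(tl))) {
    ph <- tl[i, ]
    nf <- round((ph$t1 - ph$t0) * ph$fps)
    t <- ph$t0 + seq_len(nf) / ph$fps
    F_ph <- phase_force(force_pN, ph$flow, reaction_flow)
    if (class == "stuck") {
      x <- attachment[1] + stats::rnorm(nf, 0, 0.02)
      y <- attachment[2] + stats::rnorm(nf, 0, 0.02)
    } else {
      n_t <- ph$turns0 + (t - ph$t0) / (ph$t1 - ph$t0) * (ph$turns1 - ph$turns0)
      if (ph$name == "reaction" && class == "single") n_t <- reaction_turns(t)
      l_xy <- switch(class,
        nicked = rep(wlc_extension(F_ph * 1e-12, p) * 1e6, nf),
        multi = extension_vs_turns(n_t, F_ph, model, p, both_branches = TRUE),
        single = extension_vs_turns(n_t, F_ph, model, p))
      if (class == "multi" && ph$name == "reaction") {
        l_xy <- rep(l_xy[1], nf)  # no gyrase response once multiply tethered
      }
      dir <- rep(1, nf)
      if (ph$name == "reversal") dir[t > (ph$t0 + ph$t1) / 2] <- -1
      l_ext <- wlc_extension(F_ph * 1e-12, p) * 1e6
      if (ph$name == "force_window") {
        y_fluct <- simulate_ou_segment(F_ph, l_ext, bead = bead,
                                       temperature_K = p$T, dt = 1 / ph$fps,
                                       n_steps = nf, exposure = blur_substeps)
      } else {
        var_inf <- .kB * p$T * l_ext * 1e-6 / (F_ph * 1e-12)
        y_fluct <- stats::rnorm(nf, 0, sqrt(var_inf))
      }
      x <- attachment[1] + dir * l_xy + stats::rnorm(nf, 0, noise_sd_um)
      y <- attachment[2] + y_fluct * 1e6
    }
    frames[[i]] <- data.frame(t_s = t, frame = frame0 + seq_len(nf) - 1L,
                              x_um = x, y_um = y)
    frame0 <- frame0 + nf
  }
  traj <- do.call(rbind, frames)
  if (is.finite(t_break)) {
    keep <- traj$t_s <= t_break
    post <- which(!keep)
    if (length(post) > 0) {
      spike <- traj[post[1], ]
      spike$x_um <- attachment[1] + p$l0 * 1e6 * 1.15
      spike$y_um <- attachment[2]
      traj <- rbind(traj[keep, ], spike)
    }
  }
  rownames(traj) <- NULL
  params <- list(truth_class = class,
                 truth_force_pN = force_pN,
                 truth_mode = if (class == "single") mode else NA,
                 truth_v_pos = if (class == "single") kinetics$v_pos else NA_real_,
                 truth_v_neg = if (class == "single" && mode == "alpha")
                   kinetics$v_neg else NA_real_,
                 truth_t_break = if (is.finite(t_break)) t_break else NA_real_,
                 truth_slope_per_turn = model$slope_per_turn,
                 truth_attach_x = attachment[1],
                 truth_attach_y = attachment[2])
  rec <- mol_record(uid = uid, trajectory = traj, parameters = params,
                    log = sprintf("simulated protocol trace (class %s)", class))
  attr(rec, "bursts_true") <- bursts_true
  rec
}

#' Cohort specification for synthetic populations
#'
#' @param n_molecules Cohort size.
#' @param fractions Named fractions for classes stuck/nicked/multi/single;
#'   must sum to 1. Counts are stratified (largest-remainder rounding), so
#'   they are exact.
#' @param force_meanlog,force_sdlog Lognormal parameters of the per-molecule
#'   reaction-flow force (pN); defaults log(0.35) and 0.3, reflecting
#'   bead-to-bead variation in size and magnetic content.
#' @param kinetics A [gyrase_kinetics()].
#' @param model A [hat_curve_model()].
#' @param noise_sd_um Tracking noise sd (um).
#' @param seed Master seed fixing all randomness.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_molecules = 100,
                        fractions = c(stuck = 0.1, nicked = 0.2,
                                      multi = 0.2, single = 0.5),
                        force_meanlog = log(0.35), force_sdlog = 0.3,
                        kinetics = gyrase_kinetics(),
                        model = hat_curve_model(),
                        noise_sd_um = 0.05, seed = 1) {
  stopifnot(n_molecules >= 1)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("cohort_spec: class fractions must sum to 1")
  }
  if (any(fractions < 0)) stop("cohort_spec: fractions must be non-negative")
  structure(list(n_molecules = as.integer(n_molecules), fractions = fractions,
                 force_meanlog = force_meanlog, force_sdlog = force_sdlog,
                 kinetics = kinetics, model = model,
                 noise_sd_um = noise_sd_um, seed = as.integer(seed)),
            class = "cohort_spec")
}

# exact stratified class counts by largest remainder
stratified_counts <- function(fractions, n) {
  raw <- fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  as.integer(cnt)
}

#' Draw the per-molecule ground-truth design of a cohort
#'
#' Deterministic under the cohort seed: classes (stratified counts), uids,
#' per-record RNG streams, forces and attachment points.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `uid`, `class`, `force_pN`, `seed`,
#'   `attach_x`, `attach_y`.
#' @export
cohort_truth_design <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_molecules
  cnt <- stratified_counts(spec$fractions, n)
  classes <- rep(names(spec$fractions), times = cnt)
  uids <- fmt_uuid(n)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  forces <- stats::rlnorm(n, spec$force_meanlog, spec$force_sdlog)
  data.frame(uid = uids, class = classes, force_pN = forces, seed = seeds,
             attach_x = stats::runif(n, 20, 80),
             attach_y = stats::runif(n, 20, 80),
             stringsAsFactors = FALSE)
}

#' Simulate a ground-truth-labeled cohort
#'
#' @param spec A [cohort_spec()].
#' @param tl A [protocol_timeline()].
#' @param p A [wlc_params()].
#' @param bead A [bead_model()].
#' @return A `mol_archive`; ground truth is stored both as record
#'   parameters (`truth_*`) and as a data frame in `metadata$truth`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), tl = default_timeline(),
                            p = wlc_params(), bead = bead_model()) {
  design <- cohort_truth_design(spec)
  arch <- new_archive(metadata = list(
    timeline = as.data.frame(tl), seed = spec$seed,
    truth = design[, c("uid", "class", "force_pN")]))
  for (i in seq_len(nrow(design))) {
    rec <- simulate_protocol_trace(
      class = design$class[i], tl = tl, kinetics = spec$kinetics,
      model = spec$model, p = p, bead = bead,
      force_pN = design$force_pN[i], noise_sd_um = spec$noise_sd_um,
      attachment = c(design$attach_x[i], design$attach_y[i]),
      uid = design$uid[i], seed = design$seed[i])
    attr(rec, "bursts_true") <- NULL
    arch <- add_record(arch, rec)
  }
  arch
}

#' Render bead positions into a synthetic image stack
#'
#' Each bead is drawn as a pixel-integrated 2-D Gaussian carrying `photons`
#' photons with Poisson shot noise, on top of a Gaussian background with
#' mean `background_mean` and standard deviation `background_sd`.
#'
#' @param positions Data frame with columns `frame` (1-based), `x`, `y`
#'   (0-based pixel-center coordinates).
#' @param n_frames,nrow_px,ncol_px Stack geometry.
#' @param sigma_px Spot standard deviation in pixels.
#' @param photons Photons per bead per frame.
#' @param background_mean,background_sd Background statistics (counts).
#' @param seed Optional seed; a fixed seed yields identical stacks.
#' @return 3-D array `[frame, row, col]` of counts.
#' @export
render_video <- function(positions, n_frames, nrow_px, ncol_px,
                         sigma_px = 1.3, photons = 5000,
                         background_mean = 100, background_sd = 10,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- array(0, dim = c(n_frames, nrow_px, ncol_px))
  cols <- 0:(ncol_px - 1)
  rows <- 0:(nrow_px - 1)
  for (f in seq_len(n_frames)) {
    img <- matrix(0, nrow_px, ncol_px)
    sub <- positions[positions$frame == f, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      x0 <- sub$x[k]; y0 <- sub$y[k]
      if (x0 < -0.5 || x0 > ncol_px - 0.5 || y0 < -0.5 || y0 > nrow_px - 0.5) {
        warning(sprintf("render_video: bead at (%.1f, %.1f) outside frame %d; clipped",
                        x0, y0, f))
      }
      fx <- stats::pnorm(cols + 0.5, x0, sigma_px) -
        stats::pnorm(cols - 0.5, x0, sigma_px)
      fy <- stats::pnorm(rows + 0.5, y0, sigma_px) -
        stats::pnorm(rows - 0.5, y0, sigma_px)
      img <- img + photons * outer(fy, fx)
    }
    if (background_sd > 0 || background_mean > 0) {
      signal <- matrix(stats::rpois(length(img), pmax(img, 0)),
                       nrow_px, ncol_px)
      bg <- matrix(stats::rnorm(length(img), background_mean, background_sd),
                   nrow_px, ncol_px)
      img <- signal + bg
    }
    out[f, , ] <- img
  }
  out
}

#' Write an image stack to a multi-page 16-bit TIFF
#' @param stack 3-D array `[frame, row, col]` of counts.
#' @param path Output path.
#' @param scale Counts mapped to the 16-bit full scale (default 65535).
#' @export
write_stack_tiff <- function(stack, path, scale = 65535) {
  pages <- lapply(seq_len(dim(stack)[1]), function(f) {
    pmin(pmax(stack[f, , ] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#' @param path TIFF path.
#' @param scale Counts at 16-bit full scale.
#' @return 3-D array `[frame, row, col]`.
#' @export
read_stack_tiff <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) out[f, , ] <- pages[[f]] * scale
  out
}
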