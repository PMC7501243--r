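# Automated molecule classification: mobility/attachment from flow
# reversal, coilability and tether multiplicity from the coiling series,
# per-molecule force from the 33 Hz window, nm/turn calibration, sliding
# window burst detection in enzymatic cycles/s, alpha/chi net-length
# tagging, rare tether-break statistics with bootstrap errors, and
# dose-response (IC50) fitting.

#' Classification thresholds
#'
#' Named defaults for the thresholds the pipeline uses. All lengths in um,
#' times in s.
#'
#' @param min_amplitude Minimum flow-reversal amplitude for a mobile bead.
#' @param msd_min Minimum mean-squared displacement (um^2) over the trace.
#' @param compaction_frac Minimum fractional length loss in the positive
#'   coiling phase for a coilable molecule.
#' @param multi_slope_frac Maximum |negative-phase slope| relative to the
#'   positive-phase slope for a single tether.
#' @param w_pos,w_neg Sliding-window lengths (s) for positive-relaxation and
#'   negative-introduction burst search.
#' @param slope_sig Burst slope significance in multiples of the local
#'   slope-noise sd.
#' @param min_turn_slope_nm Minimum nm/turn for a calibratable molecule.
#' @param plateau_pre_s,plateau_post_s Plateau windows (s) for the alpha/chi
#'   net-length comparison.
#' @param min_force_samples Minimum samples in the force window.
#' @param debias_thermal Subtract the per-phase thermal broadening from the
#'   projected length before slope analysis (see
#'   [debias_projected_length()]).
#' @return Named list of thresholds.
#' @export
classify_config <- function(min_amplitude = 0.5, msd_min = 0.01,
                            compaction_frac = 0.25, multi_slope_frac = 0.25,
                            w_pos = 12.5, w_neg = 25, slope_sig = 3,
                            min_turn_slope_nm = 5, plateau_pre_s = 15,
                            plateau_post_s = 30, min_force_samples = 100,
                            debias_thermal = TRUE) {
  as.list(environment())
}

phase_rows <- function(traj, ph) {
  traj[traj$t_s > ph$t0 & traj$t_s <= ph$t1, , drop = FALSE]
}

#' Assess bead mobility and locate the attachment point
#'
#' The attachment site is the midpoint of the two extreme x positions
#' during the flow-reversal phase; a bead is mobile when the reversal
#' amplitude reaches `min_amplitude` and its overall mean-squared
#' displacement exceeds the stuck-bead baseline.
#'
#' @param traj Trajectory data frame (`t_s`, `x_um`, `y_um`) or a
#'   `mol_record`.
#' @param tl A [protocol_timeline()] containing a `reversal` phase.
#' @param min_amplitude Minimum reversal amplitude in um.
#' @param msd_min Stuck-bead MSD baseline in um^2.
#' @return List with `mobile`, `attachment` (`c(x, y)` um),
#'   `reversal_amplitude` (um).
#' @export
assess_mobility <- function(traj, tl, min_amplitude = 0.5, msd_min = 0.01) {
  if (inherits(traj, "mol_record")) traj <- traj$trajectory
  ph <- timeline_phase(tl, "reversal")
  rev <- phase_rows(traj, ph)
  if (nrow(rev) < 2) stop("assess_mobility: no samples in the reversal phase")
  x_hi <- max(rev$x_um); x_lo <- min(rev$x_um)
  amplitude <- x_hi - x_lo
  attachment <- c((x_hi + x_lo) / 2, stats::median(rev$y_um))
  msd <- mean((traj$x_um - mean(traj$x_um))^2 +
                (traj$y_um - mean(traj$y_um))^2)
  list(mobile = amplitude >= min_amplitude && msd > msd_min,
       attachment = attachment, reversal_amplitude = amplitude)
}

#' Projected tether length over time
#'
#' Planar Euclidean distance from the attachment point to the bead.
#'
#' @param traj Trajectory data frame or `mol_record`.
#' @param attachment `c(x, y)` in um.
#' @return Numeric vector of l_xy in um, one per trajectory row.
#' @export
projected_length <- function(traj, attachment) {
  if (inherits(traj, "mol_record")) traj <- traj$trajectory
  sqrt((traj$x_um - attachment[1])^2 + (traj$y_um - attachment[2])^2)
}

# median of the first / last `frac` of a vector (>= 3 samples)
edge_median <- function(v, frac = 0.1, tail = FALSE) {
  k <- max(3L, round(length(v) * frac))
  if (tail) stats::median(utils::tail(v, k)) else stats::median(utils::head(v, k))
}

#' Classify coilability and tether multiplicity from the coiling series
#'
#' Fractional compaction is measured over each high-force coiling phase.
#' Properly formed single tethers compact only when overwound; nicked
#' molecules ignore turns entirely; multiply-tethered beads compact on both
#' branches. A molecule is coilable when the positive-phase compaction
#' reaches `compaction_frac`, and singly tethered when the magnitude of the
#' negative-phase slope stays below `multi_slope_frac` times the
#' positive-phase slope.
#'
#' @param t Times (s) of the `l_xy` samples.
#' @param l_xy Projected length series (um).
#' @param tl A [protocol_timeline()] with `coil_neg` and `coil_pos` phases.
#' @param compaction_frac,multi_slope_frac Thresholds (see
#'   [classify_config()]).
#' @return List with `coilable`, `single_tether`, `slope_pos`, `slope_neg`
#'   (um/turn magnitudes), `compaction_pos`, `compaction_neg`.
#' @export
classify_coilability <- function(t, l_xy, tl, compaction_frac = 0.25,
                                 multi_slope_frac = 0.25) {
  measure <- function(name) {
    ph <- timeline_phase(tl, name)
    sel <- t > ph$t0 & t <= ph$t1
    if (sum(sel) < 6) stop(sprintf("classify_coilability: too few samples in %s", name))
    v <- l_xy[sel]
    l_start <- edge_median(v)
    l_end <- edge_median(v, tail = TRUE)
    dn <- abs(ph$turns1 - ph$turns0)
    list(compaction = (l_start - l_end) / max(l_start, 1e-9),
         slope = abs(l_start - l_end) / dn)
  }
  neg <- measure("coil_neg")
  pos <- measure("coil_pos")
  coilable <- pos$compaction >= compaction_frac
  single <- coilable && neg$slope <= multi_slope_frac * pos$slope
  list(coilable = coilable, single_tether = single,
       slope_pos = pos$slope, slope_neg = neg$slope,
       compaction_pos = pos$compaction, compaction_neg = neg$compaction)
}

#' Per-molecule force from the high-frame-rate window
#'
#' Variance of bead motion perpendicular to flow within the 33 Hz force
#' window, passed to the blur-corrected equipartition/WLC solver with the
#' camera integration time `W = 1/frame_rate`.
#'
#' @param traj Trajectory data frame or `mol_record`.
#' @param tl A [protocol_timeline()] with a `force_window` phase.
#' @param p A [wlc_params()].
#' @param bead A [bead_model()].
#' @param min_samples Minimum samples required in the window.
#' @return List with `force_pN`, `length_um` and the full solver `solution`.
#' @export
measure_force <- function(traj, tl, p = wlc_params(), bead = bead_model(),
                          min_samples = 100) {
  if (inherits(traj, "mol_record")) traj <- traj$trajectory
  ph <- timeline_phase(tl, "force_window")
  win <- phase_rows(traj, ph)
  if (nrow(win) < min_samples) {
    stop(sprintf("measure_force: force window has %d < %d samples",
                 nrow(win), min_samples))
  }
  var_y <- stats::var(win$y_um * 1e-6)
  sol <- solve_force_length_blurred(var_y, W = 1 / ph$fps, bead = bead, p = p)
  list(force_pN = sol$F * 1e12, length_um = sol$l * 1e6, solution = sol)
}

#' Calibrate the length change per magnet turn
#'
#' Slope of projected length versus cumulative turns during magnet
#' rotations conducted at the experimental flow rate (the partial-uncoil
#' step of the default protocol), in nm/turn. This calibration converts
#' burst slopes (nm/s) into enzymatic cycles/s.
#'
#' @param t Times (s) of the `l_xy` samples.
#' @param l_xy Projected length series (um).
#' @param tl A [protocol_timeline()].
#' @param phase Name of the rotation phase (default `"partial_uncoil"`).
#' @param min_slope_nm Minimum credible slope; below it the molecule is not
#'   compacting and cannot be calibrated.
#' @return Positive slope in nm/turn.
#' @export
calibrate_turn_slope <- function(t, l_xy, tl, phase = "partial_uncoil",
                                 min_slope_nm = 5) {
  ph <- timeline_phase(tl, phase)
  sel <- t > ph$t0 & t <= ph$t1
  if (sum(sel) < 4) stop("calibrate_turn_slope: too few samples in rotation phase")
  turns <- turns_at(tl, t[sel])
  fit <- ols_line(turns, l_xy[sel])
  slope_nm <- abs(fit$slope) * 1e3
  if (!is.finite(slope_nm) || slope_nm < min_slope_nm) {
    stop(sprintf(paste0("calibrate_turn_slope: molecule does not compact ",
                        "(%.2f nm/turn < %.2f); cannot calibrate"),
                 slope_nm, min_slope_nm))
  }
  slope_nm
}

# analytic sd of an OLS slope over nw evenly spaced samples with white
# point noise of sd sigma
slope_noise_sd <- function(sigma, nw, dt) {
  sigma * sqrt(12 / (dt^2 * nw * (nw^2 - 1)))
}

# Expected maximum (in sd units) of the rolling-slope noise field over m
# overlapping windows of nw samples. Calibrated against Monte-Carlo maxima
# of OLS slopes of white noise (accurate to ~0.12 sd for m/nw in 1.5-6);
# used to debias peak sliding-window slopes, which are order statistics.
max_slope_bias_coeff <- function(m, nw) {
  if (m <= 1) return(0)
  sqrt(2 * log(1 + 3 * m / nw))
}

#' Subtract thermal broadening from a projected-length series
#'
#' The projected length `sqrt(dx^2 + dy^2)` is inflated by the lateral
#' thermal fluctuations of the bead (by about `var_y / (2 l)`), which
#' compresses apparent length changes at short extensions. Using the
#' per-phase variance of the orthogonal coordinate,
#' `l = sqrt(max(l_xy^2 - var_y, floor^2))` removes this bias (in
#' expectation, `E[l_xy^2] = l^2 + var_x + var_y`, with the orthogonal term
#' dominating).
#'
#' @param t Times (s) of the samples.
#' @param l_xy Raw projected length (um).
#' @param y Orthogonal-to-flow coordinate (um), same length.
#' @param tl A [protocol_timeline()] (the variance is estimated per phase,
#'   where the force and hence the fluctuation amplitude is constant).
#' @param floor_um Lower bound of the debiased length.
#' @return Debiased projected-length series (um).
#' @export
debias_projected_length <- function(t, l_xy, y, tl, floor_um = 0.02) {
  out <- l_xy
  for (i in seq_len(nrow(tl))) {
    sel <- t > tl$t0[i] & t <= tl$t1[i]
    if (sum(sel) < 8) next
    var_y <- stats::var(y[sel])
    out[sel] <- sqrt(pmax(l_xy[sel]^2 - var_y, floor_um^2))
  }
  out
}

#' Detect gyrase activity bursts with sliding windows
#'
#' Within the reaction phase, a window of `w_pos` seconds slides over the
#' region before the trace maximum searching for the highest slope
#' (positive supercoil relaxation) and a window of `w_neg` seconds over the
#' region after it searching for the lowest slope (negative supercoil
#' introduction). Peak slopes are converted to enzymatic velocities as
#' `|slope| / turn_slope / 2` cycles/s (each gyrase cycle changes the
#' linking number by -2). A burst is only reported when its peak slope
#' exceeds `slope_sig` times the local slope-noise sd; its extent is the
#' contiguous run of significant same-sign windows around the peak.
#'
#' @param t Times (s).
#' @param l_xy Projected length (um).
#' @param turn_slope Calibration in nm/turn (> 0).
#' @param tl A [protocol_timeline()] with a `reaction` phase.
#' @param w_pos,w_neg Window lengths in s.
#' @param slope_sig Significance multiple of the slope-noise sd.
#' @return Data frame with columns `sign`, `t_start`, `t_end` (absolute s),
#'   `slope_nm_s`, `velocity_cps`, `start_time` (s after reaction start);
#'   zero rows when no burst is significant.
#' @export
detect_bursts <- function(t, l_xy, turn_slope, tl, w_pos = 12.5, w_neg = 25,
                          slope_sig = 3) {
  stopifnot(turn_slope > 0)
  ph <- timeline_phase(tl, "reaction")
  sel <- t > ph$t0 & t <= ph$t1
  tr <- t[sel]; lr <- l_xy[sel]
  n <- length(tr)
  if (n < 4) stop("detect_bursts: too few reaction-phase samples")
  dt <- stats::median(diff(tr))
  fps <- 1 / dt
  nw_pos <- round(w_pos * fps)
  nw_neg <- round(w_neg * fps)
  if (n <= max(nw_pos, nw_neg)) {
    stop("detect_bursts: reaction phase shorter than the sliding window")
  }
  sigma_pt <- point_noise_sd(lr)
  # trace maximum located on a lightly smoothed copy (2 s rolling mean)
  ks <- max(1L, round(2 * fps))
  sm <- as.numeric(stats::filter(lr, rep(1 / ks, ks), sides = 2))
  sm[is.na(sm)] <- lr[is.na(sm)]
  i_max <- which.max(sm)
  empty <- data.frame(sign = character(), t_start = numeric(),
                      t_end = numeric(), slope_nm_s = numeric(),
                      velocity_cps = numeric(), start_time = numeric())
  # change-point segmentation of the reaction trace: burst extents come
  # from segment boundaries, which are unbiased at the ramp/plateau kinks
  # (sliding-window extents overshoot by up to half a window per edge)
  segs <- NULL
  burst_extent <- function(t_peak_lo, t_peak_hi, peak_slope, thr, positive) {
    if (is.null(segs)) segs <<- segment_trace(tr, lr, confidence = 0.99,
                                              min_pts = 8)
    floor_slope <- max(thr, abs(peak_slope) / 2)
    active <- if (positive) segs$slope > floor_slope else segs$slope < -floor_slope
    hit <- active & segs$t_end >= t_peak_lo & segs$t_start <= t_peak_hi
    if (!any(hit)) return(c(t_peak_lo, t_peak_hi))
    # grow the contiguous chain of active segments around the hit
    i0 <- min(which(hit)); i1 <- max(which(hit))
    while (i0 > 1 && active[i0 - 1]) i0 <- i0 - 1
    while (i1 < nrow(segs) && active[i1 + 1]) i1 <- i1 + 1
    c(segs$t_start[i0], segs$t_end[i1])
  }
  one_burst <- function(nw, region_last, region_first, positive) {
    if (positive) {
      hi <- region_last - nw + 1  # windows fully before the maximum
      if (hi < 1) return(NULL)
      idx <- seq_len(hi)
    } else {
      lo <- region_first
      if (lo > n - nw + 1) return(NULL)
      idx <- lo:(n - nw + 1)
    }
    slopes <- rolling_slope(tr, lr, nw)[idx]
    sd_sl <- slope_noise_sd(sigma_pt, nw, dt)
    thr <- slope_sig * sd_sl
    # detection gate: the peak is the maximum over length(idx) correlated
    # windows, so it must clear the expected pure-noise maximum by
    # slope_sig noise sds, not just slope_sig sds
    gate <- thr + max_slope_bias_coeff(length(idx), nw) * sd_sl
    if (positive) {
      k <- which.max(slopes)
      if (slopes[k] <= gate) return(NULL)
      sig <- slopes > max(thr, slopes[k] / 2)
    } else {
      k <- which.min(slopes)
      if (slopes[k] >= -gate) return(NULL)
      sig <- slopes < min(-thr, slopes[k] / 2)
    }
    # contiguous significant run around the peak window
    lo_k <- k; while (lo_k > 1 && sig[lo_k - 1]) lo_k <- lo_k - 1
    hi_k <- k; while (hi_k < length(sig) && sig[hi_k + 1]) hi_k <- hi_k + 1
    ext <- burst_extent(tr[idx[lo_k]], tr[idx[hi_k] + nw - 1], slopes[k],
                        thr, positive)
    # the peak of m noisy window slopes is an order statistic; subtract its
    # expected extreme-value excess (zero for noiseless input)
    m_run <- hi_k - lo_k + 1
    excess <- max_slope_bias_coeff(m_run, nw) * slope_noise_sd(sigma_pt, nw, dt)
    slope_um_s <- if (positive) {
      max(slopes[k] - excess, thr)
    } else {
      min(slopes[k] + excess, -thr)
    }
    data.frame(sign = if (positive) "positive_relaxation" else "negative_introduction",
               t_start = ext[1], t_end = ext[2],
               slope_nm_s = slope_um_s * 1e3,
               velocity_cps = abs(slope_um_s) * 1e3 / turn_slope / 2,
               start_time = ext[1] - ph$t0)
  }
  out <- rbind(one_burst(nw_pos, region_last = i_max, positive = TRUE),
               one_burst(nw_neg, region_first = i_max, positive = FALSE))
  if (is.null(out)) empty else out
}

#' Tag the reaction mode from the net length change
#'
#' Compares plateau medians of the projected length before gyrase arrival
#' and after all supercoiling activity. A negative net change means the
#' DNA ended negatively supercoiled (alpha mode); a positive change means
#' it was only relaxed (chi mode, high force prevents negative
#' introduction).
#'
#' @param t Times (s).
#' @param l_xy Projected length (um).
#' @param tl A [protocol_timeline()].
#' @param pre_s Pre-arrival plateau window after reaction start (s).
#' @param post_s Final plateau window before the trace end (s).
#' @param slope_sig Plateau stationarity threshold (multiples of the
#'   slope-noise sd over the final window).
#' @return `"alpha"`, `"chi"`, or `NA` (with a warning) when the trace ends
#'   mid-burst and the final plateau is not reached.
#' @export
classify_reaction_mode <- function(t, l_xy, tl, pre_s = 15, post_s = 30,
                                   slope_sig = 3) {
  ph <- timeline_phase(tl, "reaction")
  sel <- t > ph$t0 & t <= ph$t1
  tr <- t[sel]; lr <- l_xy[sel]
  if (length(tr) < 8) stop("classify_reaction_mode: too few reaction samples")
  pre <- lr[tr <= ph$t0 + pre_s]
  post_sel <- tr > max(tr) - post_s
  post <- lr[post_sel]
  if (length(pre) < 3 || length(post) < 3) {
    warning("classify_reaction_mode: plateaus not measurable; molecule untagged")
    return(NA_character_)
  }
  # final plateau must be stationary, otherwise the trace ended mid-burst;
  # the noise level is taken from the plateau window itself (fully
  # compacted tethers fluctuate more than the trace average)
  tp <- tr[post_sel]
  fit <- ols_line(tp, post)
  dt <- stats::median(diff(tr))
  sd_pt <- max(point_noise_sd(post), point_noise_sd(lr))
  thr <- slope_sig * slope_noise_sd(sd_pt, length(post), dt)
  if (abs(fit$slope) > max(thr, 1e-3)) {
    warning("classify_reaction_mode: trace ends mid-burst; molecule untagged")
    return(NA_character_)
  }
  if (stats::median(post) - stats::median(pre) < 0) "alpha" else "chi"
}

#' Break-rate arithmetic
#'
#' Breaks per unit time inside versus outside burst windows, and their
#' ratio. Exposed separately so the estimator can be checked directly.
#'
#' @param n_burst,n_background Break counts inside / outside bursts.
#' @param burst_time,background_time Total exposure times (s).
#' @return List with `burst_rate`, `background_rate`, `ratio`,
#'   `ratio_infinite` flag.
#' @export
compute_break_rates <- function(n_burst, burst_time, n_background,
                                background_time) {
  burst_rate <- if (burst_time > 0) n_burst / burst_time else 0
  background_rate <- if (background_time > 0) n_background / background_time else 0
  if (background_rate == 0) {
    list(burst_rate = burst_rate, background_rate = 0,
         ratio = if (burst_rate > 0) Inf else NA_real_, ratio_infinite = TRUE)
  } else {
    list(burst_rate = burst_rate, background_rate = background_rate,
         ratio = burst_rate / background_rate, ratio_infinite = FALSE)
  }
}

interval_overlap <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0))
}

#' Detect tether breaks and compare burst versus background break rates
#'
#' A break is an irreversible tether loss: the track terminates before the
#' end of the observation while at least `persist_frac` of concurrent
#' tracks persist, or the projected length spikes beyond the contour
#' length. Break rates are computed per unit time inside and outside the
#' detected burst windows of each molecule ("burst-time normalization"),
#' with the standard deviation of the ratio from `n_boot` bootstrap
#' resamples over molecules.
#'
#' @param summaries Data frame with one row per molecule: `uid`, `t_last`
#'   (last trajectory time, s), `spike` (logical: projected length exceeded
#'   the contour at the end), and optionally `active_at_end` (logical: the
#'   trace had a significant slope when it ended; such a break truncated
#'   the burst it occurred in and is attributed to burst time even when the
#'   shortened burst itself is no longer reconstructable).
#' @param bursts Named list (by uid) of burst tables from [detect_bursts()]
#'   (absolute `t_start`, `t_end`); missing/NULL entries mean no bursts.
#' @param tl A [protocol_timeline()] (defines the reaction observation
#'   window).
#' @param persist_frac Required fraction of concurrent surviving tracks.
#' @param n_boot Bootstrap cycles for the s.d. of the ratio (default 30).
#' @return List with `events` (data frame `uid`, `t_break`, `during_burst`),
#'   `burst_rate`, `background_rate`, `ratio`, `ratio_infinite`, `sd`
#'   (bootstrap), `burst_time`, `background_time`.
#' @export
detect_breaks <- function(summaries, bursts, tl, persist_frac = 0.9,
                          n_boot = 30) {
  ph <- timeline_phase(tl, "reaction")
  t_end_exp <- max(tl$t1)
  n <- nrow(summaries)
  dt_margin <- 2 / ph$fps
  early <- summaries$t_last < t_end_exp - dt_margin
  # persistence rule: fraction of tracks still alive at the break time
  alive_at <- vapply(summaries$t_last, function(tb) {
    mean(summaries$t_last >= tb - dt_margin) }, numeric(1))
  is_break <- early & (summaries$spike | alive_at >= persist_frac)
  per_mol <- lapply(seq_len(n), function(i) {
    obs_end <- min(summaries$t_last[i], ph$t1)
    obs <- max(0, obs_end - ph$t0)
    bu <- bursts[[summaries$uid[i]]]
    bt <- if (is.null(bu) || nrow(bu) == 0) 0 else
      sum(interval_overlap(bu$t_start, bu$t_end, ph$t0, obs_end))
    brk <- is_break[i] && summaries$t_last[i] > ph$t0
    during <- FALSE
    if (brk && !is.null(bu) && nrow(bu) > 0) {
      # burst edges are quantized to the window grid; allow one frame slack
      during <- any(summaries$t_last[i] >= bu$t_start - dt_margin &
                      summaries$t_last[i] <= bu$t_end + dt_margin)
    }
    if (brk && !during && isTRUE(summaries$active_at_end[i])) {
      during <- TRUE  # burst truncated by the break itself
    }
    c(obs = obs, burst_time = bt, brk = as.numeric(brk),
      during = as.numeric(during))
  })
  m <- do.call(rbind, per_mol)
  tally <- function(idx) {
    sub <- m[idx, , drop = FALSE]
    n_in <- sum(sub[, "brk"] * sub[, "during"])
    n_out <- sum(sub[, "brk"] * (1 - sub[, "during"]))
    compute_break_rates(n_in, sum(sub[, "burst_time"]), n_out,
                        sum(sub[, "obs"]) - sum(sub[, "burst_time"]))
  }
  full <- tally(seq_len(n))
  boots <- replicate(n_boot, {
    tally(sample.int(n, n, replace = TRUE))$ratio
  })
  sd_boot <- stats::sd(boots[is.finite(boots)])
  events <- data.frame(uid = summaries$uid[is_break],
                       t_break = summaries$t_last[is_break],
                       during_burst = m[is_break, "during"] == 1)
  rownames(events) <- NULL
  c(list(events = events, sd = sd_boot,
         burst_time = sum(m[, "burst_time"]),
         background_time = sum(m[, "obs"]) - sum(m[, "burst_time"])),
    full)
}

#' Fit the one-site inhibitor dose-response curve
#'
#' `Y = Bottom + (Top - Bottom) / (1 + X / IC50)` fitted by
#' Levenberg-Marquardt least squares; zero concentration is the `Y = Top`
#' limit. The 95% CI of the IC50 comes from the parameter covariance.
#'
#' @param conc Concentrations (uM), at least 4 distinct values.
#' @param response Responses (e.g. median burst velocities, cycles/s).
#' @return List with `IC50`, `top`, `bottom`, `CI95` (length 2), `fit` (the
#'   `nls` object).
#' @export
fit_dose_response <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  if (length(unique(conc)) < 4) {
    stop("fit_dose_response: need at least 4 distinct concentrations")
  }
  if (stats::sd(response) == 0) {
    stop("fit_dose_response: constant response; IC50 not identifiable")
  }
  top0 <- max(response); bot0 <- min(response)
  mid <- (top0 + bot0) / 2
  pos <- conc > 0
  ic0 <- conc[pos][which.min(abs(response[pos] - mid))]
  if (length(ic0) == 0 || ic0 <= 0) ic0 <- stats::median(conc[pos])
  df <- data.frame(x = conc, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ bottom + (top - bottom) / (1 + x / ic50),
                      data = df,
                      start = list(top = top0, bottom = bot0, ic50 = ic0),
                      lower = c(-Inf, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf("fit_dose_response: fit failed (%s)",
                                     conditionMessage(e))))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))["ic50"],
                 error = function(e) NA_real_)
  dfree <- length(conc) - 3
  q <- stats::qt(0.975, dfree)
  ci <- if (is.finite(se)) est["ic50"] + c(-1, 1) * q * se else c(NA_real_, NA_real_)
  list(IC50 = unname(est["ic50"]), top = unname(est["top"]),
       bottom = unname(est["bottom"]), CI95 = unname(ci), fit = fit)
}

#' Expected treadmilling cycle count
#'
#' With the magnet rotating at `rotation_rate` turns/s and gyrase removing
#' supercoils as they form, each enzymatic cycle absorbs 2 turns, so the
#' cycle count over an active period is `rotation_rate / 2 * active_time`.
#'
#' @param rotation_rate Magnet rotation rate in turns/s (>= 0, vectorized).
#' @param active_time Active duration in s.
#' @return Expected number of enzymatic cycles.
#' @export
count_treadmill_cycles <- function(rotation_rate, active_time) {
  stopifnot(all(rotation_rate >= 0), all(active_time >= 0))
  rotation_rate / 2 * active_time
}

#' Classify one molecule through the full pipeline
#'
#' Runs mobility -> coilability/multiplicity -> force -> turn-slope
#' calibration -> burst detection -> alpha/chi tagging on a single record,
#' tolerating molecules that fail early stages (downstream fields are NA).
#'
#' @param rec A `mol_record`.
#' @param tl A [protocol_timeline()].
#' @param cfg A [classify_config()].
#' @param p A [wlc_params()].
#' @param bead A [bead_model()].
#' @return List with `classification` (one-row data frame) and `bursts`
#'   (data frame, possibly empty).
#' @export
classify_molecule <- function(rec, tl, cfg = classify_config(),
                              p = wlc_params(), bead = bead_model()) {
  traj <- rec$trajectory
  mob <- assess_mobility(traj, tl, cfg$min_amplitude, cfg$msd_min)
  out <- data.frame(uid = rec$uid, mobile = mob$mobile,
                    coilable = FALSE, single = FALSE, accepted = FALSE,
                    force_pN = NA_real_, length_um = NA_real_,
                    turn_slope_nm_per_turn = NA_real_,
                    mode = NA_character_,
                    reversal_amplitude = mob$reversal_amplitude,
                    attach_x = mob$attachment[1], attach_y = mob$attachment[2],
                    t_last = max(traj$t_s), spike = FALSE,
                    active_at_end = FALSE,
                    stringsAsFactors = FALSE)
  bursts <- NULL
  if (mob$mobile) {
    l_xy <- projected_length(traj, mob$attachment)
    contour_um <- p$l0 * 1e6
    out$spike <- any(l_xy > contour_um * 1.05)
    good <- l_xy <= contour_um * 1.05
    tg <- traj$t_s[good]; lg <- l_xy[good]
    if (isTRUE(cfg$debias_thermal)) {
      lg <- debias_projected_length(tg, lg, traj$y_um[good], tl)
    }
    if (out$spike) out$t_last <- max(tg)  # last frame with the tether intact
    coil <- tryCatch(classify_coilability(tg, lg, tl, cfg$compaction_frac,
                                          cfg$multi_slope_frac),
                     error = function(e) NULL)
    if (!is.null(coil)) {
      out$coilable <- coil$coilable
      out$single <- coil$single_tether
    }
    out$accepted <- out$mobile && out$coilable && out$single
    if (out$accepted) {
      fm <- tryCatch(measure_force(traj, tl, p, bead, cfg$min_force_samples),
                     error = function(e) NULL)
      if (!is.null(fm)) {
        out$force_pN <- fm$force_pN
        out$length_um <- fm$length_um
      }
      ts <- tryCatch(calibrate_turn_slope(tg, lg, tl,
                                          min_slope_nm = cfg$min_turn_slope_nm),
                     error = function(e) NULL)
      if (!is.null(ts)) {
        out$turn_slope_nm_per_turn <- ts
        bursts <- tryCatch(detect_bursts(tg, lg, ts, tl, cfg$w_pos, cfg$w_neg,
                                         cfg$slope_sig),
                           error = function(e) NULL)
      }
      out$mode <- tryCatch(
        suppressWarnings(classify_reaction_mode(tg, lg, tl, cfg$plateau_pre_s,
                                                cfg$plateau_post_s,
                                                cfg$slope_sig)),
        error = function(e) NA_character_)
      # was the tether actively changing length when the track ended?
      # (a break that truncates a burst leaves too little of it to
      # reconstruct, so the break/burst attribution uses this local test)
      rx <- timeline_phase(tl, "reaction", required = FALSE)
      if (!is.null(rx) && out$t_last > rx$t0) {
        sel <- tg > max(rx$t0, out$t_last - cfg$w_pos) & tg <= out$t_last
        if (sum(sel) >= 6) {
          fit_end <- ols_line(tg[sel], lg[sel])
          dt_end <- stats::median(diff(tg[sel]))
          rsel <- tg > rx$t0 & tg <= min(rx$t1, out$t_last)
          thr_end <- cfg$slope_sig *
            slope_noise_sd(point_noise_sd(lg[rsel]), sum(sel), dt_end)
          out$active_at_end <- is.finite(fit_end$slope) &&
            abs(fit_end$slope) > max(thr_end, 1e-3)
        }
      }
    }
  }
  if (is.null(bursts)) {
    bursts <- data.frame(sign = character(), t_start = numeric(),
                         t_end = numeric(), slope_nm_s = numeric(),
                         velocity_cps = numeric(), start_time = numeric())
  }
  list(classification = out, bursts = bursts)
}
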