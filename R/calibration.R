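# Force calibration from lateral bead fluctuations: equipartition +
# worm-like-chain mechanics, camera motion-blur correction, tether geometry
# and laminar-flow drag. All internal units are SI (m, N, s, K); the
# convenience accessors at the bottom convert to pN/um for interactive use.

#' Boltzmann constant (J/K)
#' @keywords internal
.kB <- 1.380649e-23

#' Worm-like-chain parameters
#'
#' Container for the polymer parameters of the tether. Defaults describe a
#' 21 kb double-stranded DNA construct: persistence length 46 nm, contour
#' length 6.8 um, room temperature 296 K.
#'
#' @param persistence_nm Persistence length P in nm.
#' @param contour_um Contour length l0 in um.
#' @param temperature_K Absolute temperature in K.
#' @return An object of class `wlc_params` with fields `P`, `l0`, `T` (SI).
#' @export
wlc_params <- function(persistence_nm = 46, contour_um = 6.8,
                       temperature_K = 296) {
  P <- persistence_nm * 1e-9
  l0 <- contour_um * 1e-6
  stopifnot(P > 0, l0 > 0, P < l0, temperature_K > 0)
  structure(list(P = P, l0 = l0, T = temperature_K), class = "wlc_params")
}

#' Bead and fluid model for hydrodynamic drag
#'
#' @param radius_um Bead radius R in um (default 0.5, i.e. a 1 um bead).
#' @param viscosity_Pa_s Dynamic viscosity eta in Pa s (default water,
#'   8.9e-4).
#' @return An object of class `bead_model` with fields `R`, `eta` and the
#'   Stokes friction factor `gamma = 6*pi*eta*R` (SI).
#' @export
bead_model <- function(radius_um = 0.5, viscosity_Pa_s = 8.9e-4) {
  R <- radius_um * 1e-6
  stopifnot(R > 0, viscosity_Pa_s > 0)
  structure(list(R = R, eta = viscosity_Pa_s, gamma = 6 * pi * viscosity_Pa_s * R),
            class = "bead_model")
}

#' Flow-cell lane geometry
#'
#' @param width_mm Lane width w in mm.
#' @param height_um Lane height h in um.
#' @param flow_ul_min Volumetric flow Q in ul/min.
#' @return Object of class `flow_cell` with fields `w`, `h`, `Q` (SI) and
#'   the peak (centerline) velocity `v_max = 3*Q/(2*w*h)`.
#' @export
flow_cell <- function(width_mm = 3, height_um = 100, flow_ul_min = 2.5) {
  w <- width_mm * 1e-3
  h <- height_um * 1e-6
  Q <- ul_min_to_m3s(flow_ul_min)
  stopifnot(w > 0, h > 0, Q > 0)
  structure(list(w = w, h = h, Q = Q, v_max = 3 * Q / (2 * w * h)),
            class = "flow_cell")
}

#' Convert a volumetric flow from ul/min to m^3/s
#' @param flow_ul_min Flow in microliters per minute.
#' @return Flow in m^3/s.
#' @export
ul_min_to_m3s <- function(flow_ul_min) flow_ul_min * 1e-9 / 60

#' Worm-like-chain interpolation force
#'
#' Marko-Siggia interpolation: `F*P/(kB*T) = 1/4*(1 - l/l0)^-2 - 1/4 + l/l0`.
#' The interpolation carries a known 5-7% error at mid extension, which is
#' accepted here; no higher-order correction terms are applied.
#'
#' @param l Extension in m (vectorized), `0 <= l < l0`.
#' @param p A [wlc_params()] object.
#' @return Force in N.
#' @export
wlc_force <- function(l, p = wlc_params()) {
  if (any(l < 0) || any(l >= p$l0)) {
    stop("wlc_force: extension must satisfy 0 <= l < contour length")
  }
  x <- l / p$l0
  .kB * p$T / p$P * (0.25 * (1 - x)^-2 - 0.25 + x)
}

#' Worm-like-chain extension at a given force
#'
#' Numerical inverse of [wlc_force()] by bracketed root finding on
#' `(0, l0)`.
#'
#' @param F Force in N (scalar or vector), `F >= 0`.
#' @param p A [wlc_params()] object.
#' @return Extension in m.
#' @export
wlc_extension <- function(F, p = wlc_params()) {
  vapply(F, function(f) {
    stopifnot(f >= 0)
    if (f == 0) return(0)
    eps <- 1e-12
    stats::uniroot(function(l) wlc_force(l, p) - f,
                   lower = eps, upper = p$l0 - eps,
                   tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
}

#' Equipartition force from lateral fluctuations
#'
#' `F = kB*T*l / <dy^2>`, where `<dy^2>` is the variance of bead position
#' along the axis orthogonal to the force (for FMT, perpendicular to flow).
#'
#' @param var_y Positional variance in m^2.
#' @param l Tether extension in m.
#' @param temperature_K Temperature in K.
#' @return Force in N.
#' @export
equipartition_force <- function(var_y, l, temperature_K = 296) {
  if (any(var_y <= 0) || any(l <= 0) || temperature_K <= 0) {
    stop("equipartition_force: var_y, l and temperature must be positive")
  }
  .kB * temperature_K * l / var_y
}

#' Solve simultaneously for force and extension (no blur correction)
#'
#' In FMT only the projected length is observable, so force and extension
#' are obtained by solving the equipartition relation and the worm-like
#' chain force law simultaneously for `(F, l)` given the measured lateral
#' variance. A unique root exists on `(0, l0)` whenever the variance is
#' below the zero-force limit `2*P*l0/3`.
#'
#' @param var_y Measured lateral variance in m^2.
#' @param p A [wlc_params()] object.
#' @return A `force_length_solution` list with fields `F` (N), `l` (m),
#'   `alpha` (0), `S` (1), `var_corrected` (= `var_y`), `tau` (s, requires a
#'   bead model downstream so reported as NA here).
#' @export
solve_force_length <- function(var_y, p = wlc_params()) {
  stopifnot(var_y > 0)
  g <- function(l) wlc_force(l, p) - .kB * p$T * l / var_y
  eps <- 1e-12
  lo <- eps
  hi <- p$l0 - eps
  if (g(lo) >= 0 || g(hi) <= 0) {
    stop(sprintf("solve_force_length: no root bracketed in (0, l0) for var_y = %g m^2",
                 var_y))
  }
  l <- stats::uniroot(g, lower = lo, upper = hi,
                      tol = .Machine$double.eps^0.9, maxiter = 200)$root
  # polish with a couple of Newton steps on g for residual < 1e-9 relative
  for (i in 1:3) {
    dl <- max(1e-15, abs(l) * 1e-8)
    deriv <- (g(l + dl) - g(l - dl)) / (2 * dl)
    if (is.finite(deriv) && deriv != 0) {
      step <- g(l) / deriv
      l_new <- l - step
      if (l_new > 0 && l_new < p$l0) l <- l_new
    }
  }
  F <- .kB * p$T * l / var_y
  structure(list(F = F, l = l, alpha = 0, S = 1,
                 var_corrected = var_y, tau = NA_real_),
            class = "force_length_solution")
}

#' Motion-blur correction factor
#'
#' `S(alpha) = 2/alpha - 2/alpha^2 * (1 - exp(-alpha))` where `alpha` is the
#' ratio of the camera integration time W to the trap relaxation time
#' `tau = gamma/k`. Averaging the bead position over the exposure attenuates
#' the measured variance by the factor S. For `alpha < 1e-4` the Taylor
#' series `1 - alpha/3 + alpha^2/12` is used to avoid cancellation.
#'
#' @param alpha Ratio W/tau, `>= 0` (vectorized).
#' @return S in `(0, 1]`, with `S(0) = 1`.
#' @export
blur_factor <- function(alpha) {
  if (any(alpha < 0)) stop("blur_factor: alpha must be >= 0")
  out <- numeric(length(alpha))
  small <- alpha < 1e-4
  a <- alpha[small]
  out[small] <- 1 - a / 3 + a^2 / 12
  a <- alpha[!small]
  out[!small] <- 2 / a - 2 / a^2 * (1 - exp(-a))
  out
}

#' Solve for force and extension with motion-blur correction
#'
#' Self-consistent fixed point of the blur-corrected equipartition/WLC
#' system: `alpha = F*W/(l*gamma)`, `S = blur_factor(alpha)`,
#' `var_corrected = var_y / S`, `(F, l) = solve_force_length(var_corrected)`.
#' Because `S <= 1`, the corrected variance is never smaller than the
#' measured one and the corrected force never exceeds the uncorrected
#' estimate (motion blur otherwise inflates the apparent stiffness).
#'
#' @param var_y Measured lateral variance in m^2.
#' @param W Camera integration (exposure) time in s; `W = 0` reduces to
#'   [solve_force_length()].
#' @param bead A [bead_model()] object.
#' @param p A [wlc_params()] object.
#' @param tol Relative convergence tolerance on F.
#' @param max_iter Maximum fixed-point iterations.
#' @return A `force_length_solution` list with fields `F`, `l`, `alpha`,
#'   `S`, `var_corrected`, `tau`.
#' @export
solve_force_length_blurred <- function(var_y, W, bead = bead_model(),
                                       p = wlc_params(), tol = 1e-9,
                                       max_iter = 200) {
  stopifnot(var_y > 0, W >= 0)
  sol <- solve_force_length(var_y, p)
  if (W == 0) {
    sol$tau <- bead$gamma * sol$l / sol$F
    return(sol)
  }
  F_prev <- sol$F
  for (i in seq_len(max_iter)) {
    alpha <- sol$F * W / (sol$l * bead$gamma)
    S <- blur_factor(alpha)
    var_c <- var_y / S
    sol <- solve_force_length(var_c, p)
    if (abs(sol$F - F_prev) <= tol * abs(F_prev)) {
      k <- sol$F / sol$l
      out <- structure(list(F = sol$F, l = sol$l, alpha = alpha, S = S,
                            var_corrected = var_c,
                            tau = bead$gamma / k),
                       class = "force_length_solution")
      return(out)
    }
    F_prev <- sol$F
  }
  stop(sprintf(paste0("solve_force_length_blurred: no convergence in %d ",
                      "iterations (var_y = %g, W = %g, last F = %g N)"),
               max_iter, var_y, W, F_prev))
}

#' Tether angle and bead height from projected length
#'
#' `theta = acos(l_xy / l)` and `z = l * sin(theta)`, where `l_xy` is the
#' projected (in-plane) length and `l` the end-to-end extension.
#'
#' @param l_xy Projected length in m, `0 <= l_xy <= l`.
#' @param l Extension in m, `> 0`.
#' @return List with `theta` (rad), `z` (m), `l_xy` (m).
#' @export
bead_geometry <- function(l_xy, l) {
  if (any(l <= 0)) stop("bead_geometry: l must be positive")
  if (any(l_xy < 0) || any(l_xy > l)) {
    stop("bead_geometry: l_xy must lie in [0, l]")
  }
  theta <- acos(l_xy / l)
  list(theta = theta, z = l * sin(theta), l_xy = l_xy)
}

#' Drag force on a bead in laminar channel flow
#'
#' Stokes drag `F_d = 6*pi*eta*R*v` with the parabolic laminar profile
#' `v(z) = 2*v_max*(z/h)*(1 - z/h)` and `v_max = 3*Q/(2*w*h)`.
#'
#' @param z Height of the bead above the surface in m, in `[0, h]`.
#' @param cell A [flow_cell()] object.
#' @param bead A [bead_model()] object.
#' @return Drag force in N (zero at both walls, maximal at `z = h/2`).
#' @export
drag_force <- function(z, cell = flow_cell(), bead = bead_model()) {
  if (any(z < 0) || any(z > cell$h)) {
    stop("drag_force: z must lie within [0, h]")
  }
  v <- 2 * cell$v_max * (z / cell$h) * (1 - z / cell$h)
  bead$gamma * v
}

#' @rdname solve_force_length_blurred
#' @param sol A `force_length_solution`.
#' @return `as_pn_um()`: the solution with force in pN and lengths in um,
#'   for display.
#' @export
as_pn_um <- function(sol) {
  list(force_pN = sol$F * 1e12, length_um = sol$l * 1e6,
       alpha = sol$alpha, S = sol$S,
       var_corrected_um2 = sol$var_corrected * 1e12,
       tau_s = sol$tau)
}
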