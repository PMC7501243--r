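---
title: "Models and methods behind fmtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fmtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtkit)
```

`fmtkit` analyzes flow-magnetic-tweezers (FMT) experiments: surface-tethered
DNA molecules hold magnetic beads in a laminar flow, a magnet stack sets the
vertical force and twists the DNA, and tether-length changes are read out as
lateral bead displacements. This vignette explains the models the package
implements, the parameters that matter, the numerical choices, what the
synthetic-data generator does and does not emulate, and the estimator
corrections that were required to make the pipeline quantitatively unbiased.

## Force calibration

For a bead on a tether of extension $l$ at force $F$, equipartition gives
$\langle \delta y^2\rangle = k_B T\, l / F$ for the positional variance
along the axis orthogonal to the force (perpendicular to flow). In FMT only
the projected length is observable, so `solve_force_length()` solves this
jointly with the Marko–Siggia worm-like-chain interpolation

$$\frac{F P}{k_B T} = \frac14\Bigl(1 - \frac{l}{l_0}\Bigr)^{-2} - \frac14 + \frac{l}{l_0},$$

with persistence length $P = 46$ nm, contour length $l_0 = 6.8\ \mu$m
(a ~21 kb construct) and $T = 296$ K as defaults. The interpolation carries
a known 5–7% error at mid extension; it is used deliberately, and no
higher-order correction is applied. A unique root exists on $(0, l_0)$
whenever the measured variance is below the zero-force limit $2 P l_0 / 3$;
the root is bracketed with `uniroot` at machine tolerance and polished by
Newton steps to a relative residual below $10^{-9}$.

**Motion blur.** A camera that integrates over an exposure $W$ attenuates
the measured variance by
$S(\alpha) = 2/\alpha - 2/\alpha^2\,(1 - e^{-\alpha})$ with
$\alpha = W/\tau$, $\tau = \gamma/k$, $k = F/l$,
$\gamma = 6\pi\eta R$. Since $S$ depends on the unknown $(F, l)$,
`solve_force_length_blurred()` iterates
$\alpha \to S \to \langle\delta y^2\rangle_c = \langle\delta y^2\rangle/S
\to (F, l)$ to a fixed point ($10^{-9}$ relative on $F$; convergence is
monotone in practice, no damping required). For $\alpha < 10^{-4}$ the
Taylor series $1 - \alpha/3 + \alpha^2/12$ avoids cancellation. $W$ is
taken to be the frame interval $1/\text{fps}$ by default and is
configurable; at the default gyrase operating point (0.2 pN, 33 Hz)
$\alpha \approx 0.16$ and the correction lowers the force estimate by
about 5%.

**Geometry and drag.** From projected length and solved extension,
$\theta = \cos^{-1}(l_{xy}/l)$ and $z = l\sin\theta$. The laminar-channel
drag is $F_d = 6\pi\eta R\, v(z)$ with
$v(z) = 2 v_{\max}(z/h)(1 - z/h)$ and $v_{\max} = 3Q/(2wh)$. Note that this
profile, implemented as stated, peaks at $v_{\max}/2$ at mid-height; it
reproduces the 0.07 pN drag at $z = 2.1\ \mu$m, $Q = 4.2\times10^{-11}$
m$^3$/s that anchors the low-flow operating condition.

## Localization

Peaks are amplified by a discoidal averaging filter (mean over a disk of
radius `r_inner` minus mean over the annulus to `r_outer`; defaults 2 and
5 px, truncated — not padded — at image borders), detected by threshold plus
greedy local-maximum selection (ties: smaller row, then column), and
refined by least-squares fits of
$I = B + A e^{-((x-x_0)^2+(y-y_0)^2)/2s^2}$ with photons $N = 2\pi A s^2$.
Detections are linked frame-to-frame by mutual-nearest greedy assignment
within a search radius; drift is removed using stuck beads with a running
local-linear smoother (exact on linear drift, including at the series
edges).

The closed-form precision limit
$\sigma = \sqrt{s^2/N + a^2/12N + 8\pi s^4 b^2/(a^2 N^2)}$ evaluates to
5.78 nm (≈6 nm) at the instrument's measured point
($N = 50{,}200$, $a = 1.57\ \mu$m, $b = 107$, $s = 0.78\ \mu$m). Monte-Carlo
fits of rendered spots (pixel-integrated Gaussian, Poisson shot noise,
Gaussian background) match this formula within 25% for adequately sampled
spots ($s \approx 1.3$ px) when the fit uses the pixel-integrated model
with variance weights $1/(b^2+\mu)$ (`fit_gaussian_2d(model =
"integrated", background_sd = b)`). At half-pixel sampling
($s/a \approx 0.5$, the instrument's own regime) the empirical error is
~1.35× the formula: the $a^2/12N$ pixelation term understates the loss from
coarse sampling there, and the formula should be read as an optimistic
bound.

## Change points

`fit_single_changepoint()` minimizes the total SSE of two independent OLS
lines over every admissible split (at least `min_pts = 3` points per side),
by exhaustive scan in $O(n)$ using prefix sums on centered data; ties take
the earliest split. The reported $t^\ast$ is the intersection of the two
fitted lines when it falls between the bracketing samples (exact on clean
kinks), otherwise their midpoint. Significance is an F-test of the
two-line versus one-line model ($\mathrm{df} = 2,\ n-4$), **Bonferroni
corrected** by the number of candidate splits: the scan selects the best of
many correlated tests, and without the correction two thirds of pure-noise
lines are declared split. Kinetic change-point methods in this field variously gate splits by F-test
or by information criterion; the multiplicity-corrected F-test is this
package's choice.
`segment_trace()` splits recursively at confidence 0.99 and then merges
adjacent segments whose union shows no significant change point — binary
splitting can land an early cut inside a longer true segment, and the merge
pass heals exactly that artifact.

## The classification pipeline

The pipeline consumes a protocol timeline (flow reversal; −150-turn /
+150-turn coiling series at elevated flow; 33 Hz force window; partial
uncoil of 40 turns leaving +110; reaction phase) and applies, per molecule:

1. **Mobility**: the attachment point is the midpoint of the extreme x
   positions during flow reversal; mobile requires amplitude ≥ 0.5 µm and
   MSD above a stuck baseline (0.01 µm²).
2. **Projected length**: Euclidean distance to the attachment. Because
   thermal fluctuations inflate $\sqrt{dx^2+dy^2}$ by
   $\approx \sigma_y^2/2l$, the pipeline subtracts the per-phase variance
   of the orthogonal coordinate
   ($l = \sqrt{\max(l_{xy}^2 - \widehat{\sigma_y^2}, \text{floor})}$).
   Without this debiasing the nm/turn calibration is compressed by ~2.4%,
   which propagates directly into the velocities.
3. **Coilability / multiplicity**: fractional compaction per coiling phase
   (edge medians); coilable requires ≥ 0.25 in the positive phase; singly
   tethered requires the negative-phase slope below 0.25× the positive one.
   The coiling flow (16 µl/min default) is chosen so the coiling force sits
   between the ~1 pN melt force (below which both branches compact and
   multiplicity is undecidable) and the positive-buckling ceiling (above
   which 150 turns no longer compact a tether).
4. **Force**: variance of y in the 33 Hz window through the blur-corrected
   solver. At 0.2 pN the OU correlation time (~0.19 s) leaves only ~160
   effective samples per 60 s window, so single-window estimates carry
   ~10% scatter; cohort-level rank correlation with truth exceeds 0.95.
5. **Turn slope**: OLS of projected length against cumulative turns during
   the partial uncoil (rotations at reaction flow), in nm/turn.
6. **Bursts**: a 12.5 s window slides over the region before the trace
   maximum (highest slope = positive supercoil relaxation), a 25 s window
   after it (lowest slope = negative supercoil introduction). Velocity is
   $|\text{slope}| / \text{turn slope} / 2$ cycles/s (ΔLk = −2 per cycle).
   Two statistical facts shape the implementation: the peak of $m$
   overlapping noisy windows is an order statistic, so (i) the detection
   gate is 3σ *above* the expected pure-noise maximum
   $c(m, n_w)\,\sigma_{\text{slope}}$ with
   $c = \sqrt{2\ln(1 + 3m/n_w)}$ (Monte-Carlo calibrated to ~0.12 sd), and
   (ii) the same expected excess is subtracted from the reported peak
   slope. Both corrections vanish on noiseless input. Burst *extents* come
   from the change-point segmentation (boundaries unbiased at kinks;
   window-based extents overshoot by up to half a window per free edge),
   which matters because extents set the exposure time in the break-rate
   estimator.
7. **α/χ tagging**: sign of (final plateau − pre-arrival plateau) of the
   projected length; plateau medians over 30 s (final) and 15 s
   (pre-arrival; kept short of the earliest simulated enzyme arrivals at
   20 s). A trace whose final window still has a significant slope ended
   mid-burst and stays untagged.
8. **Breaks**: a break is a track that ends early while ≥90% of tracks
   persist, or a projected-length spike beyond the contour length. Rates
   are breaks per unit time inside versus outside the detected burst
   intervals; the ratio's s.d. comes from 30 bootstrap cycles over
   molecules. A break that lands inside a burst truncates it — often below
   the window length — so a break is also attributed to burst time when the
   final window before the loss has a significant slope.

Thresholds live in `classify_config()` and are deliberately few: 0.25
(compaction), 0.25 (multi-tether slope fraction), 0.5 µm (mobility), 3σ
(slope significance).

## The synthetic-data generator

`simulate_cohort()` defines the study conditions the tests assert:

- classes stuck / nicked / multi / single at fractions 0.1/0.2/0.2/0.5
  (stratified, exact counts);
- per-molecule reaction-flow force lognormal(meanlog log 0.35 pN,
  sdlog 0.3) for bead-to-bead variation; forces scale linearly with flow
  across phases;
- hat curves with compaction slope 30 nm/turn, melt force 1 pN, and a
  buckling onset linear in force through "150 turns at 6.5 pN". The
  30 nm/turn default keeps the ±150-turn series inside the contour length
  at the working force, so the partial-uncoil calibration stays in the
  linear regime; only velocity *ratios* (cycles/s) are asserted anywhere,
  so tests are insensitive to this choice;
- gyrase kinetics: positive relaxation 1.26 cycles/s, pause 10 s, negative
  introduction 0.65 cycles/s down to −150 turns for α-mode molecules
  (reaction force < 0.5 pN) and relaxation only for χ; arrival uniform in
  20–40 s after the reaction starts;
- exact-discretization OU fluctuations orthogonal to flow (blurred by
  averaging 8 substeps per frame in the 33 Hz window), 50 nm white
  tracking noise on the flow axis, 150-turn supercoiling density
  σ = 0.075 (relaxed linking number 2000);
- rare breaks as inhomogeneous Poisson events, hazard 3×10⁻⁵ s⁻¹ during
  true activity and 1×10⁻⁵ s⁻¹ otherwise (~0.6% of molecules; the 3×
  hazard ratio is the quantity the estimator must recover);
- rendered stacks: pixel-integrated Gaussian spots, Poisson shot noise,
  Gaussian background.

What the generator does **not** emulate: thermal fluctuations along the
flow axis (suppressed to a fixed tracking noise), mechanical drift,
illumination flicker or focus loss, bead clusters, plectoneme hopping, or
torque-dependent enzyme kinetics. Passing tests therefore demonstrate that
the estimators are unbiased under the stated noise model at the stated
sizes — not that every instrumental pathology is handled.

Problem sizes used by the validation suite: cohorts of 1,000 molecules for
classification accuracy (≥95% per class) and velocity recovery (median
within 5%), 10,000 molecules for the break-rate ratio (within the
bootstrap s.d. of 3), 10⁵-sample OU segments for solver recovery (within
5%), and up to 10⁴-point series for change-point/brute-force equality.

## Archive format

Archives persist as one JSON document (`schema: "fmtkit-archive/1"`) with
one record per physical line and a uid → byte-offset index before the
closing brace; `read_record()` reads the file tail plus a single line, so
record access cost does not grow with archive size. Numbers are serialized
with 17 significant digits, which round-trips IEEE doubles bit-exactly.
Record mutations append log entries; merging requires disjoint uid sets and
keys metadata per source so merged datasets partition exactly. A binary
(Smile) encoding and concurrent writers are out of scope.

## Known limitations

- The burst-velocity extreme-value debias assumes an approximately
  constant true slope across the competing windows; strongly curved bursts
  would be over-corrected by up to the calibration error (~0.1σ).
- The break-rate estimator retains a small low bias (~10% at the default
  hazards) from breaks within ~1 s of burst onset, which are
  indistinguishable from background by the trailing-slope test.
- Force estimates below ~0.1 pN push the equipartition variance toward its
  zero-force ceiling $2Pl_0/3$ and degrade quickly.
- The WLC interpolation's mid-extension error (5–7%) is inherited by
  design.
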