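---
title: "Model-based kinematics of post-stroke planar reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based kinematics of post-stroke planar reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachkin)
```

## The generative model

reachkin models planar point-to-point reaching movements — the standard
robot-assisted assessment task in which a subject moves a handle from the
center of a workspace to one of eight targets on a 14 cm circle and back,
16 movements per full *turn* — as compositions of discrete **submovements**.
The tangential speed of a movement is a constrained sum of Gaussian bells,

$$ v_T(t) = \sum_{i=1}^{nPK} A_i \,
   e^{-\left(\frac{t - t_i}{\sqrt{2}\,\sigma_i}\right)^2},
   \qquad 0 \le t \le t_{dur}, $$

subject to the average-speed constraint
$\frac{1}{t_{dur}}\int_0^{t_{dur}} v_T = MV$ and to
$E[\sigma_i] = \langle\sigma\rangle$. Peak times are uniform on
$[0, t_{dur}]$ with a minimum spacing of $2\langle\sigma\rangle$ so that
submovements do not collapse onto each other. The submovement picture is the
core scientific commitment: in hemiparetic subjects a reach is fragmented
into many short corrective submovements, and recovery manifests as *blending*
— fewer, wider, more overlapping bells — which is exactly what the model's
parameters count and scale.

The movement is then lifted to the plane in the frame of the *theoretical
path* (the straight start-to-target line): a longitudinal profile $v_L$ and a
transversal profile $v_N$ are again Gaussian sums, with a configurable number
of their peaks (`cont_l`, `cont_n`) locked to tangential peak times and the
rest placed randomly under the same spacing rule. Their amplitudes jointly
minimize

$$ \alpha\,\bigl|MV_L - \overline{v_L}\bigr| +
   \beta\,\bigl|MV_N - \overline{|v_N|}\bigr|, \qquad
   \alpha = 0.8,\ \beta = 0.2, $$

so longitudinal compliance is prioritized. $MV_L$ is not free: it is the
path length over the duration, $D / t_{dur}$. Integrating $(v_L, v_N)$ and
rotating into the workspace yields the simulated trajectory.

Ten **model-based parameters** drive this machinery (`npk`,
`mean_sigma`, `t_dur`, `mv`, `mv_n`, `cont_l`, `cont_n`, `ratio_amp_l`,
`ratio_amp_n`, `ratio_npk`), and the same ten are extracted from any
trajectory by `extract_model_params()`. Fourteen held-out **evaluation
parameters** (`extract_evaluation_params()`) — per-polarity peak counts and
amplitudes, mean deviation from the theoretical path, submovement overlap,
and contributing-amplitude ratios — validate simulations without being used
to build them.

```{r example, eval = FALSE}
geo <- task_geometry()                       # 8 targets, 14 cm
spec <- tangential_spec(npk = 3, mean_sigma = 0.06, t_dur = 2, mv = 0.08)
plan <- planar_spec(mv_n = 0.01, cont_l = 3, cont_n = 1,
                    ratio_amp_l = 0.9, ratio_amp_n = 0.3, ratio_npk = 1)
tr <- simulate_movement(spec, plan, geo, target = 2)
extract_model_params(tr, ln_frame_for(geo, 2, "outward"))
```

## Parameters that matter

* `mean_sigma` (s): submovement duration scale. Defaults in the synthetic
  cohorts range 0.05–0.15 s, the scale at which multi-peaked pathological
  profiles are visibly fragmented at 2–6 s movement durations.
* `sampling_hz` (default 200): simulation grid. Chosen so that the shortest
  submovements (≈ 50 ms σ) are sampled by tens of points; the grid always
  ends exactly at `t_dur` so quadrature-based constraints and extraction
  agree on the duration.
* `alpha`, `beta` (0.8 / 0.2): objective weights of the planar stage.
* `threshold_frac` (0.1): a speed peak counts only if it exceeds 10 % of the
  profile's maximum; applied separately to positive and negative parts of
  signed profiles. Raising it can only reduce the count (a tested
  invariant).
* Contributing-peak windows: a longitudinal/transversal peak "contributes"
  when it lies within a window as wide as σ centered on a tangential peak.
  The window width is ambiguous between the per-peak fitted σ and the
  movement's ⟨σ⟩; the per-peak σ is the default (locally adaptive, reduces
  to ⟨σ⟩ when fits are uniform) and both are exposed via `cont_window`.
* Two-link arm: `l1 = 0.282` m, `l2 = 0.36` m (forearm + hand-to-handle +
  handle radius), 50th-percentile adult male anthropometry; the shoulder
  sits 0.45 m proximal to the circle center along −y so the whole task
  circle is comfortably inside the reachable annulus.

## Numerical choices

* **Tangential amplitudes.** The mean-speed constraint is linear in the
  amplitudes, so the fit scales the equal-contribution initialization
  $A_i = MV\, t_{dur} / (nPK\,\sigma_i\sqrt{2\pi})$ onto the constraint
  hyperplane: the objective is zero to rounding and positivity holds by
  construction. A bounded quasi-Newton pass is kept as a safeguard; a dense
  grid search is the independent oracle in the tests.
* **Planar amplitudes.** Nelder–Mead with three re-jittered restarts
  (tolerance 1e-6) from the amplitude-ratio initialization (alternating
  signs transversally). Because the longitudinal term is also linear, the
  initial point and the final solution are both rescaled exactly onto the
  longitudinal target — a strict improvement of the objective that realizes
  the intended $\alpha$-dominance.
* **σ estimation.** Each detected peak is fitted by nonlinear least squares
  over a window of ±4 half-width-based σ, clipped at midpoints to
  neighbouring peaks; failures fall back to the half-width at the Gaussian
  $e^{-1/2}$ level. This windowing is robust to measurement noise, unlike
  valley-to-valley windows which collapse when noise creates spurious local
  minima.
* **Degenerate profiles.** A constant-speed profile has a maximum but no
  strict interior local maximum; the global maximum is counted as its single
  peak. An all-zero profile has no peaks. Signed profiles with an empty
  polarity class report that class's amplitude as missing (`NA`), never 0.
* **σ sampling.** The generative constraint is only $E[\sigma] =
  \langle\sigma\rangle$; draws are uniform on
  $[(1-w), (1+w)]\langle\sigma\rangle$ (w = 0.3) and rescaled so the sample
  mean is exact, bounding σ away from zero. L/N submovements re-sample their
  σ with the same ⟨σ⟩ rather than reusing tangential values.
* **Endpoint closure.** No hard constraint forces $x_L(t_{dur}) = D$; the
  target is reached approximately through $MV_L = D/t_{dur}$, as the
  objective contains only average-speed terms.
* **MV_N.** For an oscillatory transversal profile a signed mean is ≈ 0, so
  `mv_n` targets (and extraction reports) the mean of $|v_N|$.
* **Two-link inversion.** $k$ is analytically non-negative on the reachable
  annulus and exactly zero on its boundary; rounding noise is clamped
  relative to the leading term. The forward map uses absolute link
  orientations, the convention under which the printed inverse is an exact
  inverse (verified to 1e-9 m on 1,000 random points).

## What the synthetic cohorts emulate — and what they do not

`cohort_config()` ships three presets. `"impaired"` (nPK 3–8, durations
2–6 s, MV 0.03–0.08 m/s, strong transversal activity) and `"recovered"`
(nPK 1–3, 1–2.5 s, 0.08–0.15 m/s, weak transversal activity) bracket the
kinematic regimes reported for early and late robot-assisted rehabilitation;
the exact ranges are this package's configuration defaults, chosen as
plausible study conditions, not published values. `"well_separated"` is the
identifiability regime used by the parameter-recovery harness: peaks spaced
at ≥ 4⟨σ⟩, full longitudinal coupling, tiny transversal components, and the
generating MV tied to $D/t_{dur}$. That last choice is deliberate: the
trajectory is reconstructed from $(v_L, v_N)$ alone, whose speed scale is
pinned to $D/t_{dur}$, so an independently drawn MV would be unrecoverable
by *any* extractor — in real data MV and $MV_L$ come from the same movement
and are automatically consistent. For the same reason the sensitivity scan
reports the MV effect at the tangential stage (`mean_mv_tangential`), where
the parameter acts.

Passing recovery tests on these cohorts shows that extraction inverts the
generative model under identifiable conditions. It does not show robustness
to sensor noise beyond the smoothing option, to assisted (force-field)
movements, to segmentation errors in continuous recordings, or to joint
dependence between parameters — pools are sampled independently, which is a
known simplification.

Problem sizes used by the test-suite and the acceptance script — 500 random
tangential specs, a 200-movement recovery cohort, 32-movement similarity
cohorts, 20 seeded factor panels of n = 500, and 50 time-course fits per
family at 30 sessions — were chosen so each estimate's Monte-Carlo error is
well below the margin it is compared against.

## Recovery factors

`run_factor_analysis()` standardizes the parameter panel and runs
maximum-likelihood factor analysis with promax rotation (`stats::factanal` +
`stats::promax`). Retention is fully quantitative: the smallest k whose
cumulative explained variance reaches 70 % with every factor individually
above 5 %; with an oblique rotation the per-factor shares (squared loadings
over the number of variables) are approximate and reported as such. Loadings
above 0.6 in absolute value assign a parameter to a factor; parameters
reaching the threshold on no factor are "shared". Factor scores averaged per
session are fitted by a straight line, an exponential decay, and a
double-exponential decay (multi-start nonlinear least squares, τ starts at
1, 5 and 15 sessions), selected by
$BIC = n\ln(RSS/n) + k\ln n$ — the Gaussian-residual form, with k the number
of fitted parameters (2, 3, 5). Exact fits are guarded against $\ln 0$; the
two time constants of the double exponential are reported sorted.

## Known limitations

* The two-link arm reduces the shoulder to one planar degree of freedom;
  shoulder-angle comparisons inherit that approximation.
* The model simulates unassisted movements only; severely impaired subjects
  who need robot assistance are outside its regime.
* Real trajectories are not individually reconstructed — the model aims at
  distributional similarity, which is what the E_RS / E_I metrics measure.
* The CONT window, the polarity convention of `ratio_npk` (both polarities
  summed), and the E_RS pairing scheme (all pairs within direction,
  reference = real) are documented conventions where the field's definitions
  are loose; each is either configurable or recorded in the report objects.
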