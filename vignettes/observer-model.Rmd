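---
title: "A noisy-observer model of color-material trade-off in object selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A noisy-observer model of color-material trade-off in object selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

On each trial of the selection task an observer sees a fixed target object
and two test objects that differ from it in color and/or material
(glossiness), and picks the test more similar to the target. Stimuli are
labelled by integer nominal levels on a 7 x 7 design grid, color and
material each running -3..+3, with the target at (0, 0).

The model represents every stimulus as a bivariate Gaussian in a latent
two-dimensional perceptual space. Two conventions fix the units of that
space: the target's mean position is the origin, and the noise standard
deviation is 1 on each dimension. On a trial, the target and both tests
are drawn independently from their distributions, and the observer picks
the test whose draw lies closer to the target's draw under a weighted
metric. With color-material weight $w \in [0,1]$, color differences are
scaled by $w$ and material differences by $1-w$ before combination,
either Euclidean,

$$d = \sqrt{(w\,\Delta C)^2 + ((1-w)\,\Delta M)^2},$$

or city-block,

$$d = w\,|\Delta C| + (1-w)\,|\Delta M|.$$

Mean positions are linked to nominal levels by a *positional mapping*.
Four variants are fitted: polynomials through the origin of degree 1-3
(linear/quadratic/cubic, 1-3 coefficients per dimension) and a full
variant with one free position per non-target level (6 per dimension).
No affine term is included, so level 0 always maps to position 0.
Crossing 4 mappings with 2 metrics gives 8 model variants; the full
variant has 13 free parameters (weight + 6 + 6).

Two constraints keep solutions interpretable and inside the precomputed
probability tables: positions must increase strictly with nominal level,
with adjacent positions at least 0.25 apart (a quarter of the noise SD),
and every position must lie in [-20, 20].

Model assumptions worth keeping in mind: the perceptual space is exactly
two-dimensional; the color and material coordinates of a stimulus depend
only on its own nominal level on that dimension (independence); noise is
additive, Gaussian, independent across dimensions and stimuli, and does
not grow with distance from the target.

## Choice probabilities: Monte-Carlo tables and interpolation

The probability that test 1 is chosen has no closed form (the two
distances share the target draw and the metric is nonlinear), so it is
precomputed by forward simulation on a 5-D grid over
$(w, p_{1C}, p_{1M}, p_{2C}, p_{2M})$: 10 weight values linearly spaced
in [0, 1], 20 position values linearly spaced in [-20, 20] on each
position axis, 3000 simulated trials per cell. Separate tables are built
for the two metrics. Off-grid values come from separable local cubic
(4-point Lagrange) interpolation, which is exact at grid nodes.

Numerical choices:

* **Shared-draw complement symmetry.** Each cell's trials score both
  presentation orders from the same noise draws and the cell stores the
  average of the two orientation estimates, so
  $P(p_1,p_2) + P(p_2,p_1) = 1$ holds exactly in the stored table rather
  than only in expectation.
* **Symmetry orbits.** The generative model is exactly invariant under
  sign flips of either dimension's positions and complements under
  swapping the two tests. On the (symmetric) standard grids, only one
  representative cell per symmetry orbit is simulated, from its own RNG
  stream derived from `(seed, cell index)`; the orbit's other cells are
  filled by the corresponding transform. Cells fixed by a complementing
  transform have true probability exactly 1/2 and are stored as such.
  This makes the full 10 x 20^4 table buildable in about a minute per
  metric on one CPU.
* **Likelihood clipping.** Interpolated probabilities are clipped to
  $[10^{-4}, 1-10^{-4}]$ before log-likelihood use; cubic interpolation
  can overshoot [0, 1] slightly, and an unclipped zero would destroy a
  fit.
* **Interpolation error.** The choice-probability surface varies on the
  scale of the unit noise SD, while the position grid step is ~2.1, so
  the surface is under-resolved where it transitions steeply. At grid
  nodes the only error is binomial (SD about 0.009 at 3000 trials/cell);
  between nodes in steep regions the interpolation error can reach a few
  hundredths and in the worst corners of the box about 0.1. This is a
  property of the gridded-table method at its standard resolution, and
  it is shared by any implementation using these grid settings. The test
  suite compares interpolated values against fresh high-N direct
  simulations; see the acceptance notes below.
* A reduced `"test"` preset (position step 4, 1000 trials/cell) builds
  in seconds and backs the structural and logic tests, where exact
  probability values do not matter.

```{r}
library(cmtradeoff)
tab <- build_lookup_table("euclidean", preset = "full", seed = 1)
interpolate_choice_probability(tab, w = 0.5, p1 = c(1, 0), p2 = c(0, 1))
```

## Fitting

`fit_model()` maximizes the interpolated likelihood of a trial table for
one variant/metric. Trials collapse to unique ordered test pairs with
choice counts, so one objective evaluation costs a few hundred
interpolations. Parameters are transformed so the constraints become
unconstrained coordinates: the weight is fitted on the logit scale
(avoiding boundary stalls for observers near 0 or 1), polynomial leading
coefficients on the log scale, and the full variant fits log-spacings
between adjacent positions floored at the minimum spacing, which makes
monotonicity structural. Residual violations (non-monotone polynomials,
out-of-bounds positions) are excluded by a penalty during the search;
returned solutions always satisfy the constraints, and the public
`negative_log_likelihood()` refuses invalid solutions outright.

The search is Nelder-Mead from multiple starts: a coarse grid over
weights 0.1..0.9 crossed with linear slopes in [0.5, 6] (the range the
adaptive procedure spans), 10 starts by default, with optional warm
starts. Multi-start matters because the likelihood surface carries a
pronounced weight/position trade-off ridge (below). Convergence uses a
relative objective tolerance derived from `fit_config(tolerance=)`
(default 1e-6) and an iteration cap of 600 per free parameter by
default; the heavy pipelines cap at 1500 iterations, which changes the
optimum by ~0.01 log-likelihood units on 2160-trial fits.

If every trial pairs a stimulus with an identical copy of itself the
likelihood is flat; the fit returns `w = 0.5`, minimum-spacing
positions, and a `non_identifiable` flag instead of an arbitrary
optimum.

## Model selection

`select_model()` runs the preregistered-style ladder: a single 8-fold
partition is reused across all 8 variants. Fold assignment permutes
trials within sub-block-source strata (seeded by trial content, so the
plan is invariant to row order) and deals round-robin, keeping fold
sizes within one trial and balancing adaptive and random trial sources
across folds. Within each metric the ladder starts at the full variant
and keeps a more complex variant only if its per-fold held-out
log-likelihoods beat the next simpler variant's in a one-tailed paired
t-test at 0.05; otherwise it descends full to cubic to quadratic to
linear. The metric winner is whichever ladder winner has the higher
mean held-out log-likelihood (ties prefer Euclidean, the arbitrary
default used to drive the adaptive procedure), with a two-tailed paired
p-value reported against the multiple-comparison level 0.05/12.
Zero-variance fold differences take the t-test's limiting behaviour: a
constant nonzero difference is significant in its sign's favour, a zero
difference is not.

Fold fits start from a reduced start set plus a warm start at the same
spec's full-data fit. The warm start mirrors the published bootstrap
initialization ("both the standard start range and the full-data
solution") and keeps the 64-fit ladder fast; since the ladder compares
variants on the same folds, any small optimism it introduces is shared
by all variants.

## Adaptive trial placement

The QUEST+ engine maintains a posterior over a 7-parameter grid: the
cubic/Euclidean variant with linear coefficients 0.5..6 (5 levels),
quadratic and cubic coefficients -0.3..0.3 (4 levels each) per
dimension, and weights 0.05..0.95 (5 levels) — 32000 raw combinations,
of which 6480 satisfy the monotonicity/spacing/bounds constraints. The
prior is uniform over the valid combinations (the procedure's standard
default; no other prior is published). Each trial presents the candidate
pair minimizing expected posterior entropy; with per-combination choice
likelihoods $L$ precomputed for all 1176 pairs, the expected information
gain reduces to two matrix-vector products per pair using the identity
$\mathrm{gain} = H(\bar p) + \sum_i \pi_i\,[L_i\log L_i +
(1-L_i)\log(1-L_i)]$, so a full-range selection costs ~15 ms. Posterior
updates floor the per-trial likelihood at 1e-6 so an interpolated
probability near 0 or 1 can never zero the posterior irrecoverably; ties
in expected gain resolve to the lowest pair index for deterministic
replay. The likelihood matrix depends only on (grid, table) and can be
cached on disk keyed by a content hash.

## Session simulation

`simulate_session()` reproduces the experimental design: 8 blocks of
270 trials, each block made of 9 sub-blocks of 30 trials — six adaptive
sub-blocks over the full range, one restricted to levels within ±2, one
within ±1, and one whose pairs are drawn uniformly without replacement
within the block (with replacement across blocks). Trials run in groups
of 9, one per sub-block in random order. Each adaptive sub-block keeps
its own posterior, and posteriors persist across blocks by default
(`reset_between_blocks` exposes the alternative; whether the original
procedure reset between sessions is not stated, and persisting
maximizes the information the adaptive streams accumulate). Responses
are generated by passing fresh noisy draws through the observer's
decision rule — the generative model itself — not by thresholding
lookup probabilities, so the simulator is independent of the
approximation layer it is used to test.

What the generator emulates: the trial economy, adaptive placement, and
stochastic responding of the published design, for any valid generating
observer. What it does not emulate: criterion drift within or across
sessions, lapses and motor errors, learning, stimulus-level rendering
artefacts, or color-material interactions — all features of real
observers that the model family itself excludes. Passing recovery tests
therefore shows that the analysis pipeline inverts the model faithfully
at realistic trial counts, not that human data satisfy the model.

## Post-fit analyses

* `bootstrap_weights()` resamples trials with replacement (N of N,
  ignoring block structure, matching the published procedure), refits
  the chosen spec from the default starts plus the full-data solution,
  and reports the central 68% interval of the bootstrapped weights (the
  Gaussian-equivalent of 1 SEM).
* `tradeoff_functions()` computes, for each material level of a *color
  match* (a test sharing the target's color) against each color level of
  a *material match*, the predicted probability the color match is
  chosen. At (0, 0) vs (0, 0) this is exactly one half; curves rise
  towards 1 as the material match's color offset grows.
* `slope_ratio()` summarizes a solution's positional geometry by the
  least-squares slope of position against nominal level per dimension,
  returning color slope over material slope.
* `recovery_study()` chains simulate, select, fit (and optionally
  bootstrap) per generating observer.

## Limits to identifiability, and what the tests assert

The weight and the positional spacings trade off along a ridge: raising
$w$ while compressing color positions (equivalently expanding material
positions) changes predicted choice probabilities only through the
noise contributed by the non-varied dimension, a second-order effect.
Within a bootstrap family the correlation between the fitted weight and
the color-material slope ratio is strongly negative — the package's
tests reproduce this sign — and the practical consequence is that the
maximum-likelihood weight from a 2160-trial session has substantial
spread when the generating weight is extreme and the generating
spacings are no larger than the noise SD. Mid-range weights are well
determined; extreme weights with unit-slope generating positions are
determined only up to roughly the tolerance band of the recovery
analyses. The recovery test therefore asserts a tight error bound at
$w = 0.5$, and rank-order preservation with wider bands at $w = 0.2$
and $w = 0.8$; the full-scale three-observer recovery is run end-to-end
at its printed scale in the acceptance suite. For the same reason the
adaptive procedure's advantage is asserted where it actually operates:
QUEST+ concentrates the posterior over its discrete parameter grid much
faster than random placement (posterior entropy after matched trial
counts), but it does not materially tighten the continuous ML weight
estimate relative to random placement at these study conditions.

Problem sizes used by the automated checks (chosen to exercise the full
method while keeping a laptop-scale run): structural and logic tests use
the reduced table preset; accuracy-sensitive tests (fitting, recovery,
trade-off, bootstrap) use the full 10 x 20^4 tables built once per run;
the recovery property uses 2160-trial sessions with 12 replicates per
generating weight; bootstrap tests use 20-25
iterations on 800-1000-trial datasets; the acceptance recovery runs the
complete three-observer protocol at full scale (8 blocks x 270 trials
each, full model-selection ladder).

## Known limitations

* Interpolated choice probabilities inherit the table's Monte-Carlo
  noise and, in steep regions, a cubic-interpolation bias of up to a few
  hundredths (see above); both are properties of the standard grid
  resolution.
* The weight is reported from the selected model; because the two
  metrics' best models can imply noticeably different weights while
  fitting almost equally well, metric selection noise contributes to
  recovery spread.
* The simulator and fits assume the model family exactly; none of the
  real-data caveats above are modelled.
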