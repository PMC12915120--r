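---
title: "Inferring per-cell depth and whole-cell radius from a single 2D section"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring per-cell depth and whole-cell radius from a single 2D section}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldepth)
```

## The problem and the model

A standard H&E section is several microns thick, so the nuclei a 2D
segmentation detects actually sit at different depths. Cells squeeze
against their neighbors but do not interpenetrate; their size is tied to
their nucleus. `celldepth` turns those two facts into a reconstruction: for
each detected nucleus $i$ with fixed 2D centroid $(x_i, y_i)$ and nuclear
radius $r^{nuc}_i$, it infers a depth $z_i$ and a whole-cell radius $R_i$,
modelling each cell as a sphere centered at $c_i = (x_i, y_i, z_i)$.

Feasibility is encoded as three hinge penalties:

* **radius band** — $R_i$ must lie in $[\alpha r^{nuc}_i, \beta r^{nuc}_i]$;
  cells are plausibly 1.5 to 2.5 times their nuclear radius by default
  ($P_R = \sum_i \max(0, \alpha r^{nuc}_i - R_i) + \max(0, R_i - \beta r^{nuc}_i)$);
* **depth box** — $z_i \in [z_{min}, z_{max}]$, the admissible depth range
  of the section
  ($P_Z = \sum_i \max(0, z_{min} - z_i) + \max(0, z_i - z_{max})$);
* **non-interpenetration** — adjacent cells $j \in N_i$ keep a minimal 3D
  center distance equal to the sum of their *nuclear* radii (nuclei are
  treated as incompressible, cytoplasm may deform):
  $P_O = \sum_i \sum_{j \in N_i} \max(0, (r^{nuc}_i + r^{nuc}_j) - \lVert c_i - c_j \rVert)$.

The loss is the weighted sum $L = \lambda_R P_R + \lambda_Z P_Z +
\lambda_O P_O$; $L = 0$ exactly on the feasible set. $N_i$ is a
fixed-radius neighbor set at threshold $\tau = 2 \max_i R_i$: any pair that
could violate the separation lies within $\tau$, so pruning leaves the
penalty unchanged while keeping evaluation local. With symmetric neighbor
sets each violating pair is counted once per ordered pair; we keep that
double count as the definition (it only rescales $\lambda_O$).

## Parameters

| parameter | meaning | default |
|---|---|---|
| $\alpha$, $\beta$ | cell/nucleus radius ratio band (dimensionless) | 1.5, 2.5 |
| $z_{min}$, $z_{max}$ | depth box (same length unit as radii) | 0, 50 |
| $\lambda_R$, $\lambda_Z$, $\lambda_O$ | penalty weights | $5\times10^4$, $1\times10^4$, $1\times10^6$ |
| $w$ | inertia, linear from start to end | 0.9 → 0.4 |
| $c_1$ | cognitive coefficient, linear | 2.5 → 1.0 |
| $c_2$ | social coefficient, linear | 1.0 → 2.6 |
| $n_{swarm}$ | particles | 50 |
| $T$ | iterations | 120 |

All lengths share one unit. The package works in pixels; a
microns-per-pixel scale (typically 0.25 µm/px at 40×) can be applied when
reading a mask (`nucleiFromMask(..., pixelSize = )`), after which radii and
the depth box are both in microns. The depth box default of 50 is wider
than a physical 5–10 µm section thickness; it should be read as the
admissible reconstruction depth range rather than the cut thickness, and it
is configurable. $z_{min}$ defaults to 0, consistent with the uniform
$z$ initialization.

## Optimization

Each particle encodes $(z_1..z_N, R_1..R_N)$. Initialization draws
$z_i \sim U(z_{min}, z_{max})$ and
$R_i \sim U(\alpha r^{nuc}_i, \beta r^{nuc}_i)$ with zero velocities;
nucleus pairs closer in-plane than the sum of their nuclear radii would
collide at equal depth, so their $z$ values are re-drawn (up to 50 times
per particle) until 3D-separated. Velocities follow the standard inertia +
cognitive + social update with fresh per-coordinate $U(0,1)$ multipliers;
the scheduled coefficients interpolate linearly over $[0, T-1]$, shifting
from individual exploration to collective convergence.

Numerical choices where the scheme is genuinely open:

* **Projection** onto the feasible box is per-coordinate clipping — the
  simplest idempotent projection. After the first step every particle
  satisfies the radius band and depth box exactly; only the overlap term
  requires search.
* **Velocity at the boundary** is zeroed on the clipped coordinates, which
  avoids oscillatory sticking, and clamped to half of each coordinate's box
  width to prevent divergence.
* **Ties**: personal and swarm bests are replaced only on *strict*
  improvement, so the best-loss trace is non-increasing by construction and
  runs are deterministic under a fixed seed.
* **Neighbor sets** are rebuilt every iteration from each particle's own
  current geometry (τ depends on the current maximum radius); per-iteration
  rebuilding is the conservative choice.
* **Early exit**: once the swarm best reaches $L = 0$ no strict improvement
  is possible and the run stops, padding the trace to $T$ rows.

An optional **genetic perturbation** (off by default) replaces the worst
quartile every 20 iterations by uniform crossover of two random
personal-best vectors plus Gaussian mutation (sd = 5% of the box width),
projected back onto the box. The swarm best is stored separately and can
only improve. The operator is a deliberately simple diversification
mechanism; the hybridization itself is exposed as a flag because its exact
operators are an open design choice.

## What the model can and cannot identify

Two structural limits are worth stating plainly, because they shape every
downstream result:

* **Depth reflection.** All penalties depend on relative depths only, so a
  global flip $z \mapsto z_{max} - z$ leaves the loss unchanged.
  `recoveryScore()` therefore reports the depth RMSE as the minimum over
  both orientations.
* **Radii are box-identified only.** The overlap term measures separations
  against *nuclear* radii, and the neighbor threshold
  $\tau = 2\max_i R_i$ always exceeds any violating pair's distance, so
  the loss is flat in every $R_i$ within its band. The optimizer returns
  radii drawn from the admissible band, not radii pinned by data. The
  validation statistics below are what carry information about radius
  distributions; a per-cell radius should not be over-interpreted.

## Validation statistics

The nuclear-to-cytoplasmic (N/C) ratio is operationalized as
$r^{nuc}_i / R_i$, which lies in $[1/\beta, 1/\alpha] = [0.4, 2/3]$ for any
feasible reconstruction. Per patch we summarize its distribution by the
median and by a Shannon entropy computed from a histogram with 20 equal
bins *fixed* on $[1/\beta, 1/\alpha]$ (values outside are clipped into the
edge bins). The fixed range makes entropies comparable across patches —
necessary when entropy is later used to split cohorts — and natural
logarithms bound $H$ by $\ln 20$. Binning choice is a free parameter; a
kernel estimate would serve equally, but fixed binning keeps the statistic
exactly reproducible.

The null model assigns $R_i \sim U(\alpha r^{nuc}_i, \beta r^{nuc}_i)$ with
no optimization. `validateAgainstRandom()` compares per-patch summaries of
a reconstruction against pooled summaries of `nReps` null draws with the
two-sample Kolmogorov–Smirnov test ($D$ = ECDF supremum distance;
asymptotic p at effective size $n_a n_b/(n_a+n_b)$, with the
theta-function form of the Kolmogorov distribution at small arguments for
numerical stability). Exact brute-force ECDF enumeration backs the
implementation in the test suite for samples up to 50.

## The synthetic generator

`generateTissue()` builds ground truth the reconstruction can be scored
against: nuclear radii LogNormal($\log 4$, 0.35) truncated to [2, 10] px
(right-skewed like real nuclei), cell/nucleus ratios Normal(2.0, 0.25)
truncated to $[\alpha, \beta]$ — within a patch, cells keep a cohesive N/C
ratio; a uniform option matches the null band instead — and sequential
uniform placement in a 200 × 200 × 50 slab with rejection of any candidate
closer to an accepted cell than the sum of nuclear radii. Fifty cells in a
200-px field matches the cell density of real 40× tumor patches (hundreds
of cells per 1000 × 1000 px). The accepted packing satisfies every
constraint exactly, so its loss is zero by construction; a density guard
(total nuclear cross-section below 40% of the field) keeps rejection
sampling terminating.

What the generator does *not* emulate: H&E color and texture, sectioning
artifacts (folds, tears), non-spherical cells, adhesion or tension forces,
and extracellular matrix. Tests passing on synthetic tissues therefore
demonstrate the optimizer's contracts (feasibility, recovery, statistical
separation from the null) — not robustness to real-slide segmentation
noise.

Problem sizes used by the test suite and the acceptance script — 50-cell
fields, swarms of 30–50, 60–120 iterations, cohorts of 30 patches, 10–20
replicate seeds — are desk-scale choices that keep the full suite in the
minutes range while exercising every contract at the sizes the method is
normally run per patch.

## Outputs and patch construction

Reconstructions export as ASCII PLY (one icosphere per cell; 2 subdivision
levels, 162 vertices / 320 faces per sphere), load in standard mesh
viewers, and round-trip centers and radii to $10^{-5}$. Projection to the
section plane supports two readings of a "projected cell region": the
orthographic **shadow** (radius $R_i$; the default, since it yields one
region per cell) and the **cross-section** at $Z = 0$ (radius
$\sqrt{R_i^2 - z_i^2}$, only for cells the plane cuts — with depths spread
over $[0, 50]$ most cells are not cut, which is why shadow is the
default). Patch datasets for downstream classifiers come in the three
standard flavors — sliding 60 × 60 grid, nucleus-centered windows, and
cell-region windows with pixels outside the projected disk zeroed (black,
not mean-filled) — each labelled by whether its defining point falls in an
annotation mask.

## A worked example

```{r example}
tis <- generateTissue(nCells = 50, seed = 1)
fit <- optimizeCells(observations(tis), swarmConfig(seed = 2))
penaltyBreakdown(fit)
recoveryScore(truthCells(tis), cellEstimates(fit))[c("rmseZ", "violations")]
```

A loss of zero means the reconstruction is fully feasible: all radius
bands, the depth box and every pairwise separation hold. The depth RMSE is
reported up to the reflection symmetry discussed above.

## Known limitations

* Cells are spheres; elongated or lobed cells are out of scope.
* The depth coordinate is identified only through pairwise interactions;
  isolated cells get an arbitrary feasible depth.
* Whole-cell radii are informative only at the distribution level (see the
  identifiability discussion).
* The generator's feasibility-by-construction sidesteps segmentation
  errors; none of the statistics here quantify robustness to missed or
  merged nuclei.
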