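---
title: "Testing differential cell-type co-localization across groups of images"
author: "coloctest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential cell-type co-localization across groups of images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multiplexed tissue-imaging technologies (imaging mass cytometry, CODEX,
cyclic immunofluorescence and relatives) produce, after segmentation and
cell-type classification, a table of cell centroids with type labels for
each image. A recurring question is not whether two cell types co-localize
within one image, but whether the *degree* of co-localization **changes
between groups of images** — disease stage versus control, treated versus
untreated — when each subject contributes one or several images and images
differ wildly in how many cells they contain. `coloctest` addresses exactly
that inference problem, in three steps:

1. **Summarize** co-localization of every ordered cell-type pair in every
   image by a single score derived from the cross-type Ripley K function.
2. **Model the score's noise** as a function of the pairwise cell counts,
   and convert the fitted variance surface into per-image precision
   weights.
3. **Test** each pair for a condition effect with a weighted linear model,
   or a weighted random-intercept mixed-effects model when subjects have
   multiple images, with Satterthwaite degrees of freedom.

## The co-localization score

Each image is treated as a marked point pattern in a rectangular window
$W$. For an ordered pair of types $(i, j)$, the empirical cross K function

$$\hat K_{ij}(r) = \frac{|W|}{n_i n_j} \sum_{a \in i}\sum_{b \in j}
  \mathbf{1}[d_{ab} \le r]\, e(a, b)$$

estimates the scaled expected number of type-$j$ cells within distance $r$
of a typical type-$i$ cell; under independence of the two patterns
$K_{ij}(r) = \pi r^2$. For a self-pair ($i = j$) the sum excludes
zero-distance self matches and the normalizer is $n(n-1)$, the standard
univariate convention — self-pairs are meaningful (they measure clustering
of a type with itself) and are always included in the analysis. $e(a,b)$
is an edge-correction weight compensating for pairs lost beyond the window
boundary. Three corrections are implemented for rectangular windows:

* `none` — $e \equiv 1$; negatively biased near the boundary;
* `translation` — $e = |W| / |W \cap W_{a-b}|$, the reciprocal shrinking
  overlap of the window with its translate; the package default because it
  is exact, cheap, and standard for rectangles;
* `isotropic` — the reciprocal fraction of the circle centred on the
  $i$-cell through the $j$-cell that lies inside the window, computed from
  a closed-form corner-overlap formula that is exact for every radius.

The correction in use is echoed in every result object. On the
variance-stabilized L scale, $\hat L(r) = \sqrt{\hat K(r)/\pi}$, the
complete-spatial-randomness reference is the identity line $L(r) = r$, and
the co-localization score of a pair in an image is the summed departure

$$u = \sum_{r'} \left[\hat L_{ij}(r') - r'\right]$$

over a discrete radius grid, by default $r' = 10, 20, \dots, 100$
coordinate units. Positive $u$ means attraction, negative $u$ avoidance.
The grid is a plain sum (not trapezoid-weighted), is fully configurable,
and a single-radius grid — where $u = \hat L(r_0) - r_0$ — is legal.
Coordinates are continuous and unit-agnostic; the radii must simply share
the units of the coordinates. Radii should bracket the biological
interaction distances of interest: large radii summarize broad structure
but dilute short-range signal, so when the relevant distance is unknown a
range of radii is the robust choice.

Scores are undefined (`NA`, never an error) when a type has no cells in an
image — or a single cell, for a self-pair. Undefined scores survive to the
inference stage, which drops them per pair with a logged count.

## Count-dependent variance weights

The sampling noise of $u$ grows steeply as cell counts fall: with few
cells, a handful of chance neighbour pairs moves $\hat K$ a lot. Treating
all images equally therefore wastes information. `fit_variance_surface()`
models the squared score as a surface of the two counts under a **monotone
non-increasing constraint** in each count, and `compute_weights()` uses
its reciprocal as per-observation precision weights, normalized to mean 1
(both downstream models are invariant to a global weight rescale, which is
asserted in the test suite).

Numerical design of the fit:

* the response is $\log(u^2 + \delta)$ (with $\delta$ a tiny fraction of
  the mean squared score) regressed on an additive basis of decreasing
  saturating ramps over $\log n_i$ and $\log n_j$ with non-negative
  coefficients — a non-negative least-squares problem solved by the
  Lawson–Hanson algorithm. Any non-negative coefficient vector yields a
  monotone non-increasing, piecewise-log-linear surface, so monotonicity
  holds by construction and is additionally asserted on a probe grid after
  every fit;
* fitting on the log scale matters: $u^2$ is heavy-tailed
  (chi-squared-like), and a linear-scale least-squares fit lets the
  high-count corner of the surface collapse towards zero, producing a few
  enormous weights that *increase* the variance of weighted estimates. On
  the log scale errors are roughly symmetric; the fitted surface is then
  rescaled by one global factor so its mean matches the mean of $u^2$
  (the log-scale fit alone estimates the geometric rather than arithmetic
  mean);
* extrapolation beyond the observed count range is flat, automatically,
  because the ramp basis saturates at the boundary knots;
* predictions are floored at
  $\max(10^{-3} \times \text{median fitted value}, 10^{-10})$ so weights
  stay finite;
* the surface is fitted to the scores of **all** cell-type pairs
  concurrently by default (`pooling = "all_pairs"`): the count–noise
  relationship is shared across pairs and per-pair data is often scarce.
  `pooling = "per_pair"` is available when pairs are believed to differ.

One caveat is inherited by design: $u^2$ conflates the score's variance
with its squared mean, so systematically strong co-localization at low
counts is partly read as noise. Relatedly, if cell number is confounded
with the condition effect itself, down-weighting low-count images can
obscure real differences; no mitigation is attempted, and users with such
designs should compare weighted and unweighted results.

## The inference models

For each ordered pair, with $u_{sj}$ the score of subject $s$'s image $j$,
condition $x_s$ and optional covariates $W$:

* **Linear model** (one image per subject, or subject structure ignored):
  $u_s = \alpha + \beta x_s + \Gamma W + \varepsilon_s$, fitted by
  weighted least squares; two-sided t-test on $\beta$ with residual
  degrees of freedom.
* **Mixed-effects model** (default whenever a subject grouping is present
  and any subject has more than one image):
  $u_{sj} = \alpha_s + \beta x_s + \Gamma W + \varepsilon_{sj}$ with a
  subject random intercept $\alpha_s$, fitted by REML (lme4). The
  p-value for $\beta$ uses the Satterthwaite effective degrees of freedom
  (lmerTest), which interpolate between the between-subject and
  between-image information; in the balanced intercept-dominated limit
  they recover the exact between-subject degrees of freedom $m - 2$, a
  closed form the test suite checks to 0.1.

Weights enter both models as precision weights — a row's residual variance
is $\sigma^2 / w$. A categorical condition with more than two levels is
treatment-coded against a configurable reference level, one result row per
contrast; a continuous condition gives a single slope. Boundary fits
(zero random-intercept variance) are valid results and are flagged, not
errors. A pair with fewer usable rows than fixed-effect columns plus two
is reported untestable (`NA` p-value) rather than failing the run.

Raw p-values are reported by default; Benjamini–Hochberg adjustment across
the tested pairs is available (`p_adjust = "BH"`) and recommended when
many cell types are screened. Results render as a signed significance
heatmap, $\mathrm{sign}(\beta)\cdot(-\log_{10} p)$, rows the "from" type
and columns the "to" type.

The choice between the linear and the mixed model is not cosmetic: when an
apparent group effect is driven by a minority of subjects, the linear
model — which treats every image as independent — can report strong
significance that the mixed model, correctly charging the evidence to the
number of subjects, does not. The test suite constructs exactly this
scenario and asserts the discordance.

## The simulator

`simulate_study()` generates complete two-type studies used for power and
calibration benchmarking, with defaults that define the package's
reference study:

| parameter | default | meaning |
|---|---|---|
| `window` | 1000 × 1000 units | image extent |
| `n_subjects` | 40 (two groups of 20) | subjects |
| `images_per_subject` | 3 | repeated images |
| `cell_counts` | {20, 40, …, 400} | expected count menu, per type |
| `sigma` | 40 units | mean co-localization disc radius |
| `delta` | `sigma/3` | group-2 disc-radius shift ("difference" regime) |
| `count_multiplier` | 1 | scales the whole menu (density sweeps) |
| `density_grid` | 128 × 128 | disc-kernel evaluation grid |
| `count_draw` | `"per_image"` | when the menu is re-drawn |

Per image, type A is a homogeneous Poisson process with expected count
drawn uniformly from the menu; the A pattern's disc-kernel density (a
uniform kernel whose radius is the subject's Poisson($\sigma$) or
Poisson($\sigma + \delta$) draw — shared by all of a subject's images,
which is what induces the subject-level correlation the mixed model
targets) is normalized to integrate to one and scaled by an independent
count draw to form the intensity of an inhomogeneous Poisson process for
type B (per-pixel Poisson counts, uniform placement within pixels;
64 vs 256 grids are statistically indistinguishable in the downstream
benchmark). A zero disc-radius draw is redrawn; an empty A pattern makes
B homogeneous. Everything is bit-reproducible from one seed, and
`run_benchmark()` derives replicate seeds from a master seed by a fixed
counter scheme (`master + i` for null replicate $i$, `master + 500000 + i`
for difference replicate $i$).

### What the simulator does and does not emulate

The generator reproduces the features the method targets — subject-shared
co-localization scale, repeated images, severe count heterogeneity — but
not segmentation error, marker noise, more than two cell types, irregular
(non-rectangular) tissue windows, or spatial correlation between a
subject's images beyond the shared disc radius. Passing benchmarks
therefore demonstrate statistical behaviour under the stated generative
model, not performance on any particular real dataset.

One structural property of this generative model deserves emphasis,
because it dominates the benchmark. Conditional on the A pattern, the
expected excess of the cross K function is

$$E[\hat K_{AB}(r)] - \pi r^2 \;=\; \frac{|W|}{n_A}\,
  \frac{\min(r, R)^2}{R^2},$$

the share of a single parent disc in the total B intensity — so the
*mean* of $u$, not just its variance, scales like $1/n_A$ (the package
verifies this closed form against simulation). With `count_draw =
"per_image"` the A-count varies 20-fold between images of one study, so
scores carry large count-driven mean heterogeneity that neither precision
weights (which rescale rows, not centre them) nor the random intercept
(which acts at subject level) can absorb; it lands in the residual and
caps the achievable power of *any* analysis in this framework. Weighting
still helps — the weighted analysis consistently beats the unweighted one
on shared seeds — but both operate far from the no-heterogeneity ceiling:
at the defaults the null/difference ROC AUC is roughly 0.63 weighted
versus 0.58 unweighted, while with `count_draw = "per_study"` (every image
of a study sharing one expected count per type) discrimination is nearly
perfect (AUC ≈ 0.99) and weighting has nothing left to correct. Both
regimes are exposed so users can study the transition; the per-image
regime is the default precisely because it is the hard case the weighting
scheme exists for.

```{r benchmark-example}
library(coloctest)
bench <- run_benchmark(sim_config(), n_null = 100, n_diff = 100,
                       weights = c("fitted", "none"), master_seed = 1)
summarize_benchmark(bench)   # AUC, FPR and TPR at alpha = 0.05, per mode
autoplot(bench)              # ROC curves
plot_rejection_rates(bench)  # calibration / power bars
```

False and true positive rates are the proportions of null and difference
replicates with $p$ strictly below the threshold, with exact
Clopper–Pearson intervals; the ROC AUC is computed by the rank
(Mann–Whitney) formulation with ties counted one half — identical to
integrating the empirical ROC, but trivially oracle-testable by
exhaustive pair counting.

## Numerical and scale choices in the test suite

Monte-Carlo checks in the package's tests use deliberately chosen problem
sizes: the benchmark acceptance checks run three paired sets of 100 null +
100 difference replicates at the default design (the three null sets,
300 replicates, also feed the type-I-error calibration); oracle
equivalence of the K estimator is asserted on 50 patterns of up to 100
points against an independently coded double loop (with the isotropic
weight recomputed by angle-interval intersection) at $10^{-10}$ relative
tolerance; CSR calibration averages 200 images of 400 + 400 cells — at
lower counts the square-root transform's small-sample (Jensen) bias,
of order $|W| \pi r^2 / (8\sqrt{\pi} K^{3/2} n_i n_j)$, would be
comparable to the Monte-Carlo band at the smallest radius; and
mixed-model coverage uses 500 replicates of the random-intercept
generative model. Determinism is asserted bit-for-bit, from single studies
up through the CLI benchmark path.

## Known limitations

* Rectangular windows only; masks and holes are not modelled, and the
  bounding-box default window slightly inflates the area for sparse
  images — supply explicit windows when they are known.
* The score targets pairwise co-localization at the chosen radii; no
  nearest-neighbour, touching-cell or inhomogeneous-K variants.
* The variance surface depends only on the two counts; other noise
  drivers (image area, staining batch) are not modelled, though they can
  enter the mean model as covariates.
* Random intercepts only: no random slopes or crossed designs.
* p-value calibration of the mixed model rests on approximate normality
  of the scores within pairs; with extreme count heterogeneity the scores
  are heavy-tailed and the Satterthwaite approximation is only
  approximate (the type-I error check in the acceptance suite guards the
  default design).
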