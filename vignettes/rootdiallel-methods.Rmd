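---
title: "Methods: root silhouette phenotyping and diallel analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: root silhouette phenotyping and diallel analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootdiallel)
```

This vignette is the package's own account of its methods: the models
and procedures implemented, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical conventions that make results
reproducible to the bit.

## Box-counting fractal estimation

A binary silhouette is tiled with grids of square boxes of side $L$
pixels, anchored at the image origin, and the number $N_L$ of boxes
containing at least one foreground pixel is counted per scale. Under
approximate self-similarity the counts follow the power law
$$\log N_L = \log K - D \log L,$$
and ordinary least squares of $\log N_L$ on $\log L$ (natural
logarithms) yields the **fractal dimension** FD $= D$ (minus the slope)
and the **fractal abundance** FA $= \log K$ (the intercept). For planar
silhouettes FD runs from 1 (a single unbranched root) to 2 (a
space-filling, highly branched system); FA indexes the extent of
soil-space exploration.

Conventions, each of them testable:

* **Scale ladder.** Default $L \in \{1, 2, 4, \ldots, 512\}$ — ten
  scales spanning $\log_{10} 512 \approx 2.7$ orders of magnitude. The
  ladder is configurable; every size must divide the canvas side.
* **Padding.** Images are padded with background (bottom/right) to the
  next power-of-two square before counting, so the full ladder always
  applies and the grid stays origin-anchored.
* **No grid-offset averaging.** Plain box counting with a fixed grid;
  combined with the padding rule this makes counts integer-reproducible.
* **Dual abundance scales.** FA is reported as the natural log
  ($\ln 85{,}265 = 11.35$, for example) *and* as $K = e^{\mathrm{FA}}$,
  because both scales occur in practice; emitting both avoids any
  ambiguity about which was meant.
* **Local dimensions.** The negated slope between each pair of
  consecutive scales (nine values on the default ladder) is attached as
  a diagnostic of where on the ladder the power law actually holds. The
  global fit's $r^2$ feeds the outlier filter below. No goodness-of-fit
  test of the power-law hypothesis itself is attempted: with ten points
  per image the behaviour of such tests is not established, so the
  package reports diagnostics instead of a verdict.

The machinery is validated against closed forms: the line fixture gives
FD $= 1$ and the filled fixture FD $= 2$ to better than $10^{-6}$ (their
counts are exact powers, so the regression is exact), the discrete
Sierpinski gasket gives FD within 0.05 of $\log 3 / \log 2 \approx
1.585$, and counts on arbitrary masks equal a brute-force double-loop
oracle.

## Architecture traits from side views

**Stalk diameter (SD).** The stalk is the contiguous band of foreground
rows at the top of a side view before the root cone flares. The
reference width is the median per-row foreground extent over the top 5%
of foreground rows (`band_frac = 0.05`); the band ends at the first row
wider than `flare_factor` (default 1.5) times that reference, and SD is
the mean width over the band. The 1.5 multiple is lax enough to bridge
pixel-level wobble of a straight stem and strict enough to stop at any
genuine cone flare; both knobs are exposed.

**Root angle (RA).** The root region is everything below the stalk
band. Straight envelope lines are fitted by least squares through the
per-row extreme (leftmost/rightmost) foreground columns, and RA is the
angle between the two lines in degrees — the full apex angle of the
root cone. Two refinements matter in practice:

* The fit stops at the first row reaching 90% of the region's maximum
  width. Below the tips of the outermost roots the silhouette plateaus
  or narrows again, and those rows carry no information about the cone.
* A robust variant (5th/95th-percentile columns per row) is available
  by argument for noisy images; the default uses the extremes, which is
  exact on clean silhouettes.

On analytically constructed wedges the procedure recovers the apex
angle within 2°; on rendered synthetic root systems the four-view mean
recovers twice the generating cone half-angle within 5° on average,
with a small negative bias (~3–4°) that is inherent to projecting a 3-D
cone of finitely many roots: a root's apparent angle is foreshortened
by the cosine of its azimuth relative to the viewing plane.

**Aggregation.** RA and SD are arithmetic means over the valid side
views (four perspectives reduce single-projection bias); FD and FA are
taken from the underside view alone, since fractal estimates from
different perspectives of the same sample are very strongly correlated
and side views contain the stem. Per-view values are retained for
diagnostics.

**Outlier filtering.** Image-processing failures are screened per view:
a view is dropped when its box-count fit has $r^2 < 0.95$ or when a
trait deviates more than 4 MAD from its plot median; a plot becomes
missing (never zero-filled) only when all views fail; every removal is
logged with its reason. The specific rule ($r^2$ cutoff, 4 MAD) is this
package's own convention — outlier screening of this kind is standard
for imaging pipelines, but no canonical rule exists, so the thresholds
are explicit arguments and the removal log makes the rule auditable.

**Binarization.** Luminance grayscale conversion (Rec. 601 weights),
optional background-frame subtraction (absolute difference), then a
global threshold with a strictly-greater convention: a pixel exactly at
the threshold is background. The strictness direction is arbitrary but
must be fixed; it is documented and tested.

## The generation-block diallel model

For plot-mean trait value $Y_{ijklm}$:
$$Y = \mu + e_i + r_{ij} + b_k + [a_l\beta + a_m\beta] +
[g_l\gamma + g_m\gamma + s_{lm}\delta] + eb_{ik} + rb_{ijk} + d_{ilm} +
c_n + ec_{in} + \varepsilon$$
with environments $e_i$, replications nested in environments $r_{ij}$,
entry-class (generation block: parents, F1s, checks) effects $b_k$,
additive line effects per se $a_l$, general combining abilities $g_l$,
specific combining abilities $s_{lm}$, check effects $c_n$, and the
environment interactions with class ($eb$), replication-by-class
($rb$), additive effects ($d$, "line × environment") and checks
($ec$). Design coefficients: $\beta = 1$ on a parent's own plot,
$\beta = 0.5$ per parent on a cross plot, $\gamma = \delta = 1$ on
cross plots, and all genetic coefficients zero on check plots. Because
the parents are a selected set, every genetic parameter is a fixed
effect and estimation is ordinary least squares — no REML, no BLUP.

Estimability comes from sum-to-zero restrictions on every effect
family. For SCA the restriction is that each line's cross effects sum
to zero; the free subspace is computed once as the null space of the
12×66 line-by-cross incidence matrix (via SVD), giving $p(p-3)/2 = 54$
free columns for $p = 12$, alongside 11 additive and 11 GCA columns.
Fitted free coefficients are mapped back through the same bases, so
reported effects always satisfy the restrictions exactly. With
zero-noise simulated data every effect family and contrast is recovered
at machine precision — the parameterization of the simulator and of the
estimator are written independently and meet only at this test.

* **Type III tests** are full-versus-reduced model comparisons that
  drop exactly one term's sum-to-zero columns, which under this coding
  tests each term adjusted for all others. Null simulations confirm
  calibration (mean F ≈ 1, uniform p-values).
* **Contrasts.** The entry-class effects partition into mid-parent
  heterosis (F1 block mean − parent block mean) and the F1-vs-checks
  difference; the environment difference is reported alongside.
  Standard errors come from the fit covariance
  $\hat\sigma^2 (X^\top X)^{-1}$.
* **Missing plots** are dropped per trait (row deletion), giving an
  unbalanced design; rank deficiency is handled by pivoted QR with
  non-estimable coefficients flagged, and unbalanced estimates agree
  with a pseudoinverse normal-equations oracle.
* **Adaptive FDR.** Q-values use an adaptive linear step-up: a
  first-stage pass at level $\alpha/(1+\alpha)$ (default
  $\alpha = 0.05$) estimates the number of true nulls $m_0 = m - R_1$
  (floored at 1, so a single p-value maps to itself), and step-up
  q-values are rescaled by $m_0/m$. This is the canonical "adaptive"
  variant of the linear step-up procedure; it never exceeds the plain
  adjustment. Significance stars render at $q \le$ 0.001/0.01/0.05/0.1.
* **Repeatability.** Because the entries are selected rather than
  sampled, entry-mean broad-sense repeatability is reported instead of
  heritability: $R = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/n_E +
  \sigma^2_\varepsilon/(n_E n_R))$ with method-of-moments components
  from the two-way ANOVA expected mean squares and negative estimates
  truncated at zero. The exact plug-in is this package's convention
  (flagged as such in outputs), chosen because it is the standard
  entry-mean formula.

## Multivariate summaries

Pearson correlations are computed pairwise-complete within entry class
(matching the unbalanced design), with t-approximation p-values.
Maturity adjustment regresses each trait on days to silking and keeps
the re-centred residuals — the simplest defensible reading of
"adjusted for maturity"; the fitted slope and its SE are returned so
the adjustment is inspectable. Traits are Z-scored before PCA and
clustering. PCA is an eigendecomposition of the correlation matrix
(eigenvalues sum to the trait count; the sign convention makes each
component's largest-magnitude loading positive; rank deficiency yields
zero eigenvalues rather than an error). Clustering is agglomerative on
Euclidean distances with Ward linkage — chosen for compact,
even-sized groups, and configurable, since no linkage choice is
canonical for phenotype dendrograms; entries are sorted by id before
clustering so the partition is independent of input order.

## The synthetic-data generator

The generator exists so that every downstream stage has ground truth.

**Fractal fixtures** (`render_known_fractal`) are deterministic rasters
of known dimension: a full-width one-pixel line (dimension 1), a filled
canvas (dimension 2), and the discrete Sierpinski gasket
($\log 3/\log 2$), built by quadrant subdivision — equivalently, cell
$(r, c)$ survives iff `bitwAnd(r, c) == 0` on the level-bit prefix — so
its grid-aligned box counts are exactly $3^{\text{level}-j}$ at scale
$2^j$ and the fitted dimension is exact.

**Root systems** (`grow_root_system`) are simple stochastic recursive
branching processes, not biomechanical models: a vertical stem at the
canvas centre; whorls of shoot-borne roots from compact nodes at
13–18% of canvas depth (maize forms about six compact underground
node whorls); and recursive laterals. Choices worth knowing:

* Whorl roots emerge essentially at the cone surface (polar angle
  $\theta = $ half-angle $\times$ Beta(40, 1.2)), with evenly spaced,
  jittered azimuths. The cone angle is *defined* by the outermost
  shoot-borne roots, so concentrating them at the surface is what makes
  "the generating half-angle" and "the measured cone angle" the same
  quantity; interior mass comes from laterals.
* Each root or lateral is one straight capsule segment; laterals of
  order $o+1$ arise at up to `lateral_sites` (default 4) points per
  order-$o$ segment with probability `branch_prob`, length scaled by
  `length_decay` per order; orders beyond `max_order` never branch.
  With `branch_prob = 0` the model is exactly the stem plus
  `n_nodes × roots_per_node` unbranched segments.
* Lateral endpoints are clamped radially to the cone surface: roots
  grow downward-outward but stay inside the cone, keeping the
  silhouette's envelope crisp.
* Defaults scale with the canvas (stem 8% of side, segment length 35%)
  so the same geometry renders at 512 px (matching the 1–512 box
  ladder) or smaller test canvases.
* Rasterization is anti-aliasing-free: a pixel is foreground iff its
  centre lies within a segment's capsule, so box counts are
  integer-reproducible. Side views are orthographic projections at
  0/90/180/270° about the stem axis; the underside view projects along
  the vertical axis.
* All randomness flows through one explicit seed per call and the
  global RNG stream is restored afterwards.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: soil and washing artefacts (including
random tissue loss during cleaning, which the imaging protocol is known
to incur but whose magnitude is unknowable without real data),
root curvature and gravitropic bending, brace-vs-crown distinctions,
camera noise, illumination gradients, and occlusion by adhering soil.
Tests on simulator output validate the *estimation machinery*, not the
biology.

**Diallel phenotypes** (`simulate_diallel_dataset`) draw one record per
environment × replication × entry from the same linear predictor the
estimator fits, with Gaussian residual noise. Effect maps that violate
the sum-to-zero restrictions are rejected, keeping the truth
identifiable. The trait presets (`root_trait_sim_spec`) emulate a
two-year, three-replicate trial of 12 parents, 66 crosses and 6 checks
with magnitudes on the scale reported for such material — e.g. for FD a
mean of 1.78, heterosis 0.038, environment difference −0.074 and
residual SD 0.022; for RA a mean of 70°, heterosis 14.5° and residual
SD 7° — so simulated tables look like plausible field output while the
truth stays known. Line effect vectors are drawn per seed (centred, and
SCA vectors projected onto the constraint subspace) rather than fixed,
so Monte-Carlo studies average over effect configurations.

## Numerical conventions and problem sizes

* Box counts are integers; curves are validated to be non-increasing
  with $1 \le N_L \le (S/L)^2$.
* The degenerate all-equal-counts curve with fewer than three scales is
  an error, as is an empty silhouette anywhere in the pipeline.
* Pipeline CSVs carry a provenance header (package version, stage,
  configuration hash excluding the output path, seed); re-running a
  configuration reproduces byte-identical tables.
* The test suite sizes its simulations to validate without waste:
  silhouette ensembles use 36–50 samples at 256 px; null calibration of
  the F tests uses an 8-parent design with 300 noise replicates;
  parameter recovery uses the full 12-parent design over 200 seeds.
  These sizes give Monte-Carlo errors comfortably inside the asserted
  tolerances.

## Known limitations

* RA carries the small projection-geometry bias discussed above; it is
  a property of cone projection, not of the fitting code.
* The Type III machinery assumes the sum-to-zero parameterization built
  by `build_design`; arbitrary external design matrices are not
  supported.
* Repeatability uses the average cell count for $n_R$ under mild
  unbalance; severely unbalanced designs deserve a dedicated
  variance-component fit instead.
* The generator's cone-clamped laterals mean silhouette width carries
  little information beyond the cone angle; real root systems violate
  this in interesting ways the simulator cannot reveal.
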