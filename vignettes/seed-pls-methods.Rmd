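---
title: "Seed PLS structural covariance: model, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed PLS structural covariance: model, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedpls)
```

## The model

Structural covariance treats inter-subject correlation between the
gray-matter volume of a seed region and that of every other voxel as a
network-level quantity. `seedpls` implements the *seed PLS* form of this
analysis for a longitudinal two-group design: all scans (both groups, all
three time points) enter one analysis, and group × timepoint cells are kept
separate on the rows of the correlation structure rather than pooled.

Let $x_{i v}$ be the TIV-scaled value of voxel $v$ in scan $i$ and
$s_{i r}$ the mean TIV-scaled value of seed region $r$ (left/right ×
anterior/posterior hippocampus). For each design cell $c$ the Pearson
correlation $R_{(c,r),v} = \mathrm{corr}_c(s_{\cdot r}, x_{\cdot v})$ is
computed across the cell's subjects, and the blocks are stacked into a
$(6 \cdot 4) \times V$ matrix $R$ in fixed order (control TP1..TP3, then
training TP1..TP3; seeds ordered left aHC, left pHC, right aHC, right
pHC). The SVD $R = \sum_k u_k \sigma_k v_k^\top$ defines the latent
variables: unit-norm voxel saliences $v_k$, unit-norm design/seed weights
$u_k$, and singular values $\sigma_k$, with covariance fraction
$\sigma_k^2 / \sum_j \sigma_j^2$ (the share of $\lVert R\rVert_F^2$, which
is what "percent of cross-correlation variance" means here). A scan's
brain score on LV $k$ is the dot product $\sum_v x_{iv} v_{kv}$.

Assumptions worth stating: correlations (not covariances) are used, which
neutralizes voxel-wise variance differences and bounds every entry in
$[-1, 1]$; Pearson correlation presumes roughly linear seed–voxel
relations; and at least 3 subjects per cell are required (fewer is an
error). A seed or voxel with zero variance within a cell contributes a
correlation of 0, with a warning — a convention, chosen so that degenerate
columns do not poison the decomposition.

## Inference

**Permutation test of the LVs.** The null of no seed–voxel association is
simulated by permuting the assignment of seed-value rows to image rows
uniformly at random across all scans; images keep their cell labels, so
cell sizes and the voxel blocks are preserved (this also makes the test
fast: the standardized image blocks are computed once). Singular values
are recomputed per permutation and compared rank-for-rank,
$p_k = (1 + \#\{\sigma'_k \ge \sigma_k\}) / (1 + n_{perm})$. The add-one
form avoids $p = 0$; with $n_{perm} = 0$ the p-values are reported as
absent rather than zero. The rank-matched comparison is what makes a
"LV1 and LV3 significant, LV2 not" outcome expressible. Whether the
original PLS toolbox permuted within or across groups is not documented
anywhere we could verify; permuting across all scans is the scheme
implemented, and it is configurable in the sense that the permutation
operates on the seed table, so alternative schemes can be built on the
exported primitives.

**Bootstrap reliability.** Subjects (not scans) are the resampling units,
drawn with replacement independently within each group; a subject's three
scans move together, preserving the longitudinal dependence, and each
group × timepoint cell keeps its size. Per draw the stack and its SVD are
recomputed. Because the SVD is defined only up to sign (and, under near-
degeneracy, order) of its components, each draw's saliences are aligned to
the original by the orthogonal Procrustes rotation $Q$ minimizing
$\lVert V_b Q - V_{ref}\rVert_F$ (computed from the SVD of
$V_b^\top V_{ref}$; reflections allowed). If the overlap matrix is
rank-deficient the alignment falls back to per-column sign matching,
recorded in an attribute. Without alignment, sign flips corrupt the
bootstrap SD and the BSR with it.

The BSR numerator is the *unscaled* salience $\sigma_k v_k$, so the ratio
is invariant to the unit-norm convention; the denominator is the SD of the
aligned, scaled bootstrap saliences. An SE below $10^{-10}$ of the per-LV
salience scale is treated as numerically zero (a degenerate bootstrap, as
happens with noiseless data where every draw reproduces the same
correlations up to floating-point rounding): those voxels get a signed
infinite sentinel and a flag, never a silent drop and never a spuriously
huge finite BSR. The default threshold |BSR| > 3.8 corresponds to a
two-tailed standard-normal tail probability of about $10^{-4}$.

Per (cell, seed, LV), the correlation between resampled seed values and
resampled brain scores is recomputed each draw and summarized by 2.5/97.5
percentile bounds — the percentile method, chosen because only "95%
bootstrapped confidence intervals" is specified by convention and the
percentile form is the least parametric.

## ROI volumetry

TIV scaling divides every voxel by the subject's total intracranial volume
(mm³), yielding proportional regional volume. The hippocampus mask is
split along the MNI y-axis: anterior = $y \in [-18, -2]$, posterior =
$y \in [-42, -24]$, both closed — "spanned from ... to ..." reads as
inclusive — with the gap between them excluded (a 2 mm coronal slice
trimmed from each adjacent end around the uncal apex). Hemisphere is the
sign of the mm x-coordinate: $x < 0$ left, $x > 0$ right, and voxels at
exactly $x = 0$ belong to neither (real hippocampus masks contain no
midline voxels; synthetic grids might). Each subregion mean is the plain
arithmetic mean of in-mask voxels; an empty subregion is an error, because
a seed would be undefined.

## Cluster reports

Suprathreshold BSR voxels are grouped into connected components, positive
and negative separately. Default connectivity is the 26-neighborhood (the
SPM convention); 6 and 18 are available, and corner-touching voxels merge
under 26 but not 6 — a property the tests verify against an independent
reachability oracle. The default minimum extent is 50 voxels: the smallest
cluster one would report in a table whose smallest entry is 51 voxels,
an inference from reported tables rather than a documented choice, and
fully configurable. Peaks are the maximum-|BSR| voxel, ties broken by
lexicographic voxel index so output is independent of discovery order;
records are sorted by peak y descending (anterior → posterior).

## Group statistics

Baseline comparisons use the pooled-variance two-sample t (df = n₁+n₂−2)
— which reproduces printed demographic p-values exactly, Welch would not —
accepting either raw vectors or (n, mean, sd) summaries so that published
table rows can be re-tested. Gender uses Pearson χ² without continuity
correction. The longitudinal analysis is a mixed-design repeated-measures
ANCOVA: time within, group between, age/gender/education as covariates of
no interest, Type III sums of squares, fitted via `car::Anova()` on a
multivariate linear model. The between factor is sum-coded and covariates
are centered, so within-subject effects are evaluated at the covariate
means — the SPSS GLM construction, which includes covariate × time terms.
Greenhouse–Geisser epsilons are computed and reported but the uncorrected
tests are returned, sphericity handling being otherwise unspecified.
Post-hoc paired t-tests report the mean difference; zero-variance
differences are flagged rather than silently producing infinities.
Benjamini–Hochberg adjustment is applied jointly to the family of baseline
outcome tests. (Note that BH-adjusted values are not a fixed point of the
adjustment: re-running BH on its own output changes non-tied values; only
order-equivariance and the saturated tied case are invariant.)

## The synthetic-data generator

`synthetic_config()` / `generate_dataset()` emulate the inputs of a
longitudinal VBM study: 30 subjects per group scanned at three time
points (the randomized allocation of the emulated design), on a
24 × 28 × 24 grid of 2 mm voxels positioned to cover both hemispheres and
the hippocampal y-range; TIV drawn once per subject from
N(1.55 × 10⁶, (1.25 × 10⁵)²) mm³ and constant across time points; ages
near 23 ± 1.4 years, education near 16.6 ± 1.2 years, random gender —
all matching the demographic scale of the emulated cohort.

A planted pattern couples the four seed ROIs to a disjoint support-voxel
set through a per-scan latent score $z \sim N(0, \sigma_z^2)$: each seed
ROI voxel receives $z \cdot \ell(r, c) \cdot g(c)$ and each support voxel
$z \cdot w(v) \cdot g(c)$, where $\ell$ is the (possibly per-cell) seed
loading, $w$ the signed support weight and $g$ the cell gain. Support
sets must be disjoint from seed ROIs so the planted seed–voxel covariance
is genuine rather than tautological. I.i.d. Gaussian voxel noise is added;
the latent-Gaussian-plus-noise form is the minimal generative model
matching the Pearson-correlation machinery, since the emulated study
worked with real data and specifies none. The image is generated in
TIV-proportional units and multiplied by the subject's TIV, so TIV
scaling recovers the planted linear structure exactly — that is what makes
the noiseless correlation-of-exactly-one contract testable. The default
noise SD is $\sqrt{3}$, giving a per-voxel seed–voxel correlation of 0.5
for the default unit pattern (`noise_sd_for_correlation()` computes the
general conversion); planted effect sizes are free parameters chosen for
testability, as no effect sizes for covariance patterns are reported
anywhere to copy.

`decouple_cell()` zeroes one seed's loading in one cell, emulating a seed
whose coupling to a pattern is absent at one time point only — the ground
truth against which the bootstrap CI behaviour ("covers zero exactly
where decoupled") is validated.

What the generator does *not* emulate: cortical anatomy, spatial
autocorrelation from smoothing, scanner artifacts, motion, registration
error, or non-Gaussian volume distributions. Passing tests therefore
demonstrate correctness of the estimator and its inference under the
stated generative model, not robustness to real-data pathologies.

## Numerical choices

- Sign convention: each salience vector is flipped so its largest-magnitude
  entry is positive, with the design weights flipped jointly; output is
  deterministic across platforms.
- Zero-variance seeds/voxels within a cell: correlation 0 with a warning.
- Singular values in the permutation loop come from the eigenvalues of
  $R R^\top$ (24 × 24), which is exact and much faster than a full SVD.
- Bootstrap SE below $10^{-10}$ of the salience scale ⇒ flagged sentinel.
- Degenerate paired/pooled tests (zero variance) return t = 0, p = 1 when
  the effect is also zero, and a flagged non-finite statistic otherwise.
- Mm coordinates follow the NIfTI affine (RAS+), with 0-based voxel
  indices in the affine convention and 1-based indices in R arrays.

## Validation problem sizes

The test suite validates each stage against independent oracles
(hand-computed Pearson/t/χ²/BH values, exhaustive 4! permutation
enumeration, Frobenius/SVD identities, a reachability oracle for connected
components, an explicit least-squares projection oracle for the ANCOVA,
and brute-force recomputation of the bootstrap with frozen draws). The
end-to-end suites use: 50 replicate datasets at full study scale
(30/group, 24 × 28 × 24 at 2 mm, 200 permutations) for planted-pattern
recovery; 200 pure-noise replicates at reduced size (10/group,
12 × 14 × 12 at 4 mm, 50 permutations, 40 bootstrap draws) for null
calibration of permutation p-values and BSR maps; and one study-scale
dataset with 100 bootstrap draws for the decoupling signature. These sizes
were chosen so the whole validation runs in minutes on a laptop while
keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

- Only the seed-PLS variant is implemented; task/behavioral PLS,
  mean-centered contrast PLS and split-half reliability are out of scope.
- Cluster-extent inference (random field theory, TFCE) is not provided;
  the cluster table is descriptive.
- The mixed ANCOVA requires complete, balanced time points per subject;
  subjects with missing scans must be excluded upstream.
- Anatomical labeling of clusters requires a user-supplied lookup; no
  atlas is bundled.
- With very small cells (3–5 subjects) the percentile bootstrap CIs are
  coarse and the permutation p floor, $1/(1+n_{perm})$, limits attainable
  significance.
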