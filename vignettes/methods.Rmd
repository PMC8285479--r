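---
title: "Methods: quantifying glucocorticoid-induced tumor cell dormancy"
author: "gcDormancy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying glucocorticoid-induced tumor cell dormancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcDormancy)
```

# Scope

Glucocorticoids acting through the glucocorticoid receptor (GR) can switch
lung cancer cells into a reversible, drug-tolerant dormant state driven by
induction of the CDK inhibitor p57 (*CDKN1C*). Establishing that phenotype
quantitatively takes a heterogeneous toolkit: a differential-viability drug
screen, transcriptomic activity scoring of tumor cohorts, linkage of a
distal enhancer's chromatin accessibility to its target gene, comparison of
viewpoint-anchored chromatin contacts, label-free proteomics with
missing-value imputation, and single-nucleus immunofluorescence
quantification. This package implements each procedure as a tested,
reusable component, together with synthetic-data generators that emulate
every input with known ground truth. This vignette records the models, the
parameters that matter, and the design decisions taken where the
procedures left genuine freedom.

# Plate-screen scoring

**Model.** A 384-well plate (16 rows x 24 columns) carries compounds plus
positive (killed) and negative (vehicle) control wells, which alternate by
row parity down columns 2 and 23. Raw viability signal is normalised per
plate by normalised percentage inhibition (NPI): with positive-control
mean $\bar v_{pos}$ and negative-control mean $\bar v_{neg}$,

$$v' = \frac{v - \bar v_{pos}}{\bar v_{neg} - \bar v_{pos}},$$

anchoring the kill floor at 0 and untreated growth at 1. NPI is invariant
to per-plate affine rescaling of the raw signal. Per compound and
concentration, the differential survival value is the treated-arm mean
minus the vehicle-arm mean over replicate wells; the replicate values
enter a two-sided t-test, and p-values are Benjamini-Hochberg adjusted
within a concentration. A compound is *sensitized* when
$P_{adj} < 0.05$ and the differential is below $-0.3$, and *tolerant*
under the symmetric positive rule (the published effect-size cut is
stated only for sensitization; symmetry is this package's default, and
the cut is a parameter). Follow-up selection takes compounds with mean
vehicle viability strictly below 0.7 at 5 µM.

**Pooled versus Welch variance.** The t-test variant is selectable
(`var_equal`). The default pools the arm variances. At screen-scale
replicate counts (three wells per arm) the Welch test is materially
conservative: its true type-I error at nominal 0.05, measured over
2 x 10^5 null draws, is 0.034, so a screen scored with Welch cannot be
calibrated at the nominal level — the package's own null-calibration
property (raw $p < 0.05$ fraction equal to 0.05 within binomial error)
fails structurally. The pooled test attains 0.049 and is exact under the
generator's equal-variance noise. Welch remains available for unequal
arm variances at larger replicate counts.

**Degenerate replicates.** When both arms have zero variance the p-value
is defined as 1 for equal means and 0 otherwise; non-finite wells are
dropped with a warning rather than imputed.

**Simulator.** `simulatePlates()` draws each compound's true fractional
viability from a configurable distribution (default uniform on
[0.4, 1.1]), adds an additive treated-arm viability shift for compounds
named in `interaction_set` (the planted tolerance/sensitization ground
truth), and renders raw signal as `baseline * viability + noise`, with
controls drawn around the kill floor and baseline. Defaults: baseline
1000 counts, kill floor 50, well noise sd 10 (0.05 on the normalised
scale is obtained with `well_noise_sd = 0.05 * 950`), two concentrations
(1 and 5 µM), three replicate plates per arm. The ground-truth table is a
sidecar; analysis functions never read it.

# Signature activity scoring

**Model.** For a gene signature $S$ (in the motivating study, 253 genes
associated with GR activation) the per-sample activity score is the mean
over $g \in S$ of the gene's across-sample z-score,
$z_{gs} = (x_{gs} - \bar x_g)/\mathrm{sd}_g$. The sample sd ($n-1$
denominator) is used; "sum" aggregation is available. Z-scoring per gene
makes the score invariant to per-gene affine rescaling; genes absent from
the matrix are skipped with a logged count, and zero-variance genes are
excluded with a warning. Scores are always computed within the supplied
matrix — any cohort filtering must happen before scoring.

**Stratification.** The "25% split" is read as comparing extreme
quartiles: the top `floor(n/4)` samples are labelled high, the bottom
`floor(n/4)` low, the middle excluded; tertile stratification gives three
equal-count groups. Ties break by stable sample order, and an all-tied
score vector is refused rather than split arbitrarily.

**Group comparison.** The two-sided Wilcoxon rank-sum test, exact by
enumeration when both groups have at most 8 untied observations,
otherwise the normal approximation with continuity correction and
mid-ranks. Enumeration over every achievable U at $n_1 = n_2 = 8$ puts
the worst-case gap between the approximate and exact p at 0.0109, which
is the bound the tests assert.

# Enhancer-gene linkage

**Model.** The association between a candidate enhancer's accessibility
and a target gene's expression across tumor samples is Spearman's rank
correlation (mid-rank ties; Pearson selectable). Three complementary
checks establish that a linkage is real and specific:

1. **Background null** — the same correlation is computed for every
   background enhancer in the locus (306 in the motivating analysis) and
   the candidate is placed in that empirical distribution as a tie-aware
   mid-quantile, $q = (\#\{\rho_{bg} < \rho\} + \tfrac12\#\{\rho_{bg} =
   \rho\})/N$. Constant background enhancers are dropped with a logged
   count. The background set is user input: locus definitions derive from
   external accessibility catalogues and are not recomputed here.
2. **Neighbor specificity** — the candidate's accessibility is correlated
   with each neighboring gene's expression; a specific enhancer-target
   link leaves those near zero.
3. **Conditioned correlation curve** — samples are removed in increasing
   fractions $f \in \{0, 0.1, \ldots, 0.8\}$ (a decile grid; the source
   analysis says only "step-wise") from the bottom of a conditioning
   gene's expression (the receptor gene), and the correlation is
   recomputed on the retained samples. A linkage that requires receptor
   expression produces a rising curve; $f = 0$ reproduces the
   unconditioned correlation exactly. Ties in the conditioning variable
   break by stable sample order; the curve truncates with a warning if
   fewer than 4 samples would remain.

**Simulator.** `simulateCohort()` draws a latent per-sample activity
(standard normal) that loads on the signature genes, an independent
receptor expression, and a shared component coupling candidate
accessibility to target expression with strength `linkage_effect`
$= \lambda$; with unit noise the population correlation is
$\lambda^2/(\lambda^2 + 1)$, and the default $\lambda = \sqrt{1.5}$
gives 0.6, matching the strength of the motivating association. The
`gate = "top-half"` option restricts the coupling to samples above the
median receptor expression, creating the conditioned-curve signal.
Background enhancers and neighbor genes are pure noise, so at
`linkage_effect = 0` the candidate is exchangeable with its background
and the empirical quantile is uniform.

# 4C region comparison

**Model.** A `FourCProfile` holds one viewpoint's normalised contact
signal over an ordered, non-overlapping fragment grid shared by two
conditions (normalisation itself, e.g. by a dedicated 4C caller, is out
of scope; this component consumes its output). Regions are specified in
printed 1-based inclusive coordinates ("chr11: 2773921-2812270" spans
38,350 positions); BED input/output converts to and from 0-based
half-open at the file boundary. A fragment belongs to a region when its
midpoint lies inside it (inclusive at both ends) — unambiguous for
fragments straddling a boundary.

Within a region, replicate signals are averaged per condition and the
per-fragment paired differences enter a two-sided Wilcoxon signed-rank
test: exact with at most 20 non-zero untied differences (six uniformly
positive differences give $2/2^6 = 0.03125$), normal approximation with
continuity correction beyond that; zero differences are dropped and an
all-zero region returns p = 1 with zero effect. The paired form is the
default because both conditions share the fragment grid; the unpaired
rank-sum variant is available. Because the test uses only signs and
ranks, a common multiplicative rescaling of both conditions leaves the
p-value unchanged.

**Simulator.** `simulateFourC()` builds a sorted fragment grid with
log-normal baseline signal, multiplies condition 2 by the declared effect
inside each effect region, and applies multiplicative log-normal
replicate noise (`dispersion` is the log-sd; 0 reproduces the declared
effects exactly).

# LFQ proteomics post-processing

**Filtering.** Two published valid-value rules are implemented: keep
proteins with at least a fraction of observed values overall (the 66%
rule used for IP experiments), or with at least a count per group
("two valid values out of three in both conditions"; an "in at least one
group" variant is selectable). The filter is idempotent and never
increases the row count.

**Imputation.** Missing values are replaced per sample column by draws
from a downshifted normal: with observed column mean $\mu$ and sd
$\sigma$, imputed values follow
$N(\mu - 1.8\sigma, (0.3\sigma)^2)$ — the standard width-0.3 /
downshift-1.8 rule, reflecting the low-abundance origin of
missing-not-at-random (MNAR) dropout. Imputation is per column,
deterministic given a seed, and refuses columns with fewer than three
observed values or zero sd. The pre-imputation missingness mask is kept
on the object so downstream calls can still see the observation pattern.

**Differential and enrichment calling.** Per protein, a two-sided Welch
t-test between the two groups; a call requires $p \le 0.05$ and a log2
difference of at least 1.5 in magnitude with matching sign. The
"$[x/y] \ge 1.5$" threshold is read on the log2 scale (the symmetric
negative bound implies it); the ratio-scale reading is selectable.
Proteins fully observed in one group and fully missing in the other
bypass testing and are flagged on/off. IP-enrichment calling declares a
protein an interactor when its log2 enrichment over the control
pull-down and $-\log_{10} p$ clear both cuts; presets carry the
published rules (2.5 enrichment with $-\log p > 2$; 1.5 with
$-\log p > 1.3$). An optional per-protein IgG-mean subtraction supports
IgG-corrected pooled comparisons (read here as subtraction; a flag
disables it). Welch is retained in this module — unlike the screen, the
calibration requirement here is one-sided (the null p distribution must
not be anticonservative at the 5% tail), which the conservative Welch
test satisfies, and group variances after MNAR dropout plus imputation
are genuinely unequal.

**What recall means under MNAR.** The caller's power guarantee (log2
shifts of 2 at noise sd 0.3, 3 vs 3, recalled at $\ge$ 95%) is a
property of the test-and-threshold rule and is measured on fully
observed rows. MNAR dropout can censor a differential protein in both
groups; no post-hoc imputation recovers information that was never
measured, and such rows impute to similar downshifted values in both
groups. One-sided censoring, by contrast, surfaces as the on/off flag.
The tests assert both behaviours separately.

**Simulator.** `simulateLFQ()` draws per-protein baselines
($N(26, 2.5^2)$ log2 units), injects alternating up/down shifts into the
first `n_diff` proteins, and censors entries with probability
$\min(1, 2r(1 - \Phi((x - m)/s)))$ — decreasing in intensity, with
expected overall rate $r$.

# Immunofluorescence quantification

The single-nucleus pipeline mirrors a standard automated-microscopy
macro, parameterised in physical units so results track across
magnifications:

1. **Rolling-ball background subtraction** (40 µm radius): the
   background is the grayscale opening with a ball structuring element —
   erosion $\min_q f(p+q) - h(q)$ then dilation with the ball height
   profile $h$ — subtracted and clipped at zero. For large radii the
   image is shrunk by block minimum, the ball rolled on the shrunk
   image with replicate padding (so gradients reconstruct cleanly at the
   borders), and the background bilinearly re-enlarged, never exceeding
   the image. A flat image subtracts to exactly zero; objects much
   smaller than the ball survive with their contrast.
2. **Median filter** (1.5 µm disk radius, minimum one pixel; in-bounds
   footprint at borders).
3. **Local mean thresholding** (8 µm window): foreground pixels exceed
   the local disk mean by $k = 4$ background standard deviations.
   The offset is *added* — nuclei are bright on a subtracted background;
   the opposite sign would mark most of the image foreground. The
   background sd is estimated from pixels at or below the image's 90th
   percentile as the one-sided quantile spread $q_{0.84} - q_{0.50}$:
   consistent for a normal sd, but immune to the lower tail that
   rolling-ball subtraction clips to zero. (A lower-half sd, the obvious
   estimator, collapses to near zero on corrected images for exactly
   that reason.)
4. **Distance-transform watershed** to separate touching nuclei
   (disabling it merges contacting pairs into one label), hole filling
   beforehand, then a minimum-area filter (default 20 µm², disable with
   0) to suppress watershed slivers and noise specks, and contiguous
   relabelling 1..K. An empty foreground yields an empty label map, not
   an error.
5. **Marker measurement and positivity.** The mean marker intensity is
   measured inside each nucleus; a nucleus is positive when its mean is
   *strictly* above a threshold calibrated from untreated control
   samples — by default the 99th percentile of control per-nucleus means
   (mean + 3 sd is offered). The summary statistic is the protein
   expression index: the number of positive nuclei times the mean marker
   intensity of the positive nuclei (zero when none are positive).
   Averaging over positive rather than all cells is a choice; three
   positives with means 10/20/30 give 3 x 20 = 60. Edge-touching nuclei
   are retained.

**Simulator.** `simulateImage()` renders disk nuclei with cosine-tapered
edges (taper 1 µm) over a low-frequency additive gradient plus Gaussian
noise, with a configurable fraction of nuclei placed in touching pairs
overlapping 10-20% of the mean radius — enough to merge under naive
thresholding but separable by watershed. The marker channel paints each
nucleus at a constant mean per its (deterministically assigned)
positivity class plus noise. Ground truth (label map, centres, radii,
positivity, marker means) is emitted alongside and never consumed by the
pipeline. Because the taper is a fixed physical width, the mean rendered
intensity of a nucleus depends on its radius; position-independence
checks therefore compare the same rendered scene with and without a
background gradient rather than comparing nuclei of different radii.

# Orchestration and formats

`runStage()` runs each stage from a validated configuration (unknown
parameter keys are rejected), writes its outputs and a manifest with
input/output MD5 checksums, parameters, seed and package version; the
same configuration and seed reproduce outputs byte-identically. Formats:
long-format TSV plates; gene x sample and enhancer x sample TSV matrices
(blank cells = missing); BED (0-based half-open on disk, converted at
the boundary — in memory all intervals are `GRanges`, 1-based
inclusive); region tables in printed coordinates; long TSV 4C profiles;
two-page 16-bit TIFF micrographs with a JSON sidecar carrying the pixel
size. A thin command-line wrapper over `runStage()` ships in
`inst/scripts/gcdormancy.R`; the package functions are the primary
interface.

# Problem sizes used in the checks

The packaged tests and the acceptance script exercise: screens of
1056 compounds (null calibration) and 300 spike-in compounds (recall);
cohorts of 200 samples with 253 signature genes and 306 background
enhancers (100 seeds for linkage specificity, 500 smaller-cohort seeds
for null uniformity); 40-fragment 4C profiles; 10^4 imputed values per
column; 50-seed proteomics recall; and 50-100 synthetic micrographs of
256 x 256 px at 0.6 µm/px with 30 nuclei each. These sizes give the
Monte-Carlo assertions comfortable margins while keeping a full run in
minutes on one core.

# What the synthetic data do and do not show

The generators reproduce the *structure* each procedure assumes:
control-anchored plates with additive interaction effects, a latent
activity coupling signature genes and gating an enhancer linkage,
region-localised multiplicative contact changes, intensity-dependent
dropout, and touching nuclei over uneven background. They do not
reproduce plate-position artefacts beyond control noise, cohort
confounding or batch structure, restriction-site biology, correlated
protein complexes, or realistic chromatin texture in images. Passing
tests therefore certify the implementations and their statistical
calibration under the stated models — not performance on any particular
experimental dataset.

# Known limitations

- NPI control-mean noise is shared by all compounds on a plate, mildly
  overdispersing null p-value fractions relative to binomial sampling;
  with 16 control wells per role this stays well within the calibrated
  bands but would grow with fewer controls.
- Downshifted-normal imputation deliberately fabricates low values;
  rows dominated by imputed entries in both groups are uninformative
  (see the MNAR discussion above).
- The watershed uses a fixed tolerance of 1 px on the distance map;
  heavily overlapping nuclei (beyond ~20% of radius) may still merge.
- The rolling ball's shrink factor trades exactness for speed at large
  radii; the unshrunk path is exact against brute-force opening and is
  used whenever the radius is at most 16 px.
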