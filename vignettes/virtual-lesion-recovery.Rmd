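---
title: "Predicting motor recovery from virtual-lesion connectomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting motor recovery from virtual-lesion connectomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Upper-limb recovery after stroke is commonly quantified by the Fugl-Meyer
assessment (FMA, 0-66 points) measured around two weeks and again three
months after the event, summarised as the recovery score

$$\mathrm{recovery} = 100\,\frac{\mathrm{FMA}_{3m} - \mathrm{FMA}_{2w}}{66 - \mathrm{FMA}_{2w}},$$

the percentage of the maximal possible improvement actually achieved. Most
patients recover roughly 70% of their initial impairment (the proportional
recovery rule); a substantial minority ("non-fitters") barely improve.
Predicting who will recover matters for triage and rehabilitation planning.

The classical predictors are focal: initial impairment, lesion volume, and
the fractional-anisotropy asymmetry of the two cortico-spinal tracts,
$(\mathrm{FA}_H - \mathrm{FA}_L)/(\mathrm{FA}_H + \mathrm{FA}_L)$. The idea
implemented here is that a focal lesion also disrupts connections between
regions far from the lesion (diaschisis), so *network-level* damage carries
additional predictive information — and that this damage can be estimated
without any patient diffusion imaging by embedding the patient's binary
lesion mask into healthy subjects' tractograms ("virtual lesioning"): every
healthy streamline whose rasterized trace intersects the lesion is deleted,
and the surviving streamlines are aggregated into a region-by-region
connectome with weights $w_{ij} = c_{ij}/(V_i + V_j)$ (streamline count over
summed region volumes). Graph measures of these lesioned connectomes,
averaged over the healthy subjects, become features in a regularized linear
prediction of the recovery score.

## Pipeline stages and their parameters

**Rasterization and transection.** A streamline is a polyline in continuous
voxel coordinates (voxel $(0,0,0)$ spans $[0,1)^3$). "Passing through" is
decided by supersampling each segment at steps of at most 0.5 voxel and
flooring: vertex-only checks would miss fast-crossing segments, so the
supersampled trace is a deliberately conservative transection detector.
Endpoints map to the region of their containing voxel, with a Chebyshev
radial rescue (default radius 2 voxels) for endpoints that land in
background; streamlines with an unassignable endpoint, or with both
endpoints in one region, are excluded from the connectome but tracked, so
`n_streamlines_used + n_excluded` always equals the input count.

**Density-matched binarization.** Half of the measures are defined on binary
graphs. A fixed edge-count threshold would be arbitrary, so the binary
density is matched to the *weighted density* of the weighted matrix, defined
here as the max-normalized mean weight
$\sum_{i<j}(w_{ij}/w_{\max}) / \binom{N}{2}$. This definition reduces to the
ordinary binary density on 0/1 matrices and always yields a target in
$(0,1)$ on non-degenerate matrices. The $k$ largest-weight edges are kept
($k$ = rounded target times $\binom{N}{2}$), ties at the cutoff broken by
lexicographic $(i,j)$ order; zero-weight pairs never become edges.

**The measure suite.** Eleven binary measures (density; median degree; mean
and median Watts-Strogatz clustering; mean flow coefficient; transitivity;
Louvain modularity; mean and median eigenvector centrality; mean and median
unnormalized betweenness) and seven weighted measures (algebraic
connectivity, i.e. the second-smallest eigenvalue of $D - W$; mean and
median eigenvector centrality of $W$; weighted Louvain modularity; weighted
global efficiency with edge lengths $w_{\max}/w_{ij}$ and unreachable pairs
contributing zero; mean participation coefficient
$1 - \sum_m (s_{im}/s_i)^2$ over the Louvain modules; quasi-idempotence, the
Pearson correlation between the node strengths of $W/w_{\max}$ and of its
square). Node-level measures are summarised by mean and/or median, exactly
one global value per listed measure. Degenerate conventions are explicit:
clustering and flow are 0 for degree < 2, participation is 0 for isolated
nodes, an empty graph has density 0, all node summaries 0 and modularity 0,
and quasi-idempotence is reported missing when a strength vector has zero
variance (its correlation is undefined); missing values are excluded
pairwise when averaging over healthy subjects.

Two definitions deserve a note because the literature states them loosely.
The *flow coefficient* of a node is implemented as the fraction of its
neighbour pairs that are *not* directly connected — the pairs whose shortest
interconnection is the two-step path through the node (the complement of
local clustering; 0 for degree < 2). A reading under which every neighbour
pair counts as a realized two-path is degenerate on undirected simple graphs
(identically 1 for degree ≥ 2) and is therefore rejected; the implemented
definition reproduces the canonical star example (centre 1, leaves 0).
*Quasi-idempotence* is implemented as the strength correlation between the
max-normalized matrix and its square, indexing how well two-step
connectivity preserves the strength structure.

**Community detection.** Louvain is stochastic, which would make modularity
and participation irreproducible. All Louvain calls run a fixed number of
restarts (default 10) under a seeded RNG, keeping the best-modularity
partition; the caller's RNG state is saved and restored, so the measures are
pure functions of (matrix, gamma, seed). On well-separated module structure
the restarts converge to the same optimum, which is what the
permutation-invariance tests exercise.

**Prediction.** Five nested feature sets are assembled: {age, initial FMA};
+ lesion volume; + CST asymmetry (the clinical benchmark); + all 18
connectivity measures; and the last without CST asymmetry. Everything
downstream lives inside a leave-one-subject-out loop: per fold, features are
standardized on the training patients only (population SD, divisor $n$;
zero-variance columns are dropped and logged), collinear features are
eliminated by iteratively removing the highest-VIF feature until all VIFs
fall below the operating threshold, the ridge penalty is chosen by an inner
leave-one-out grid search on the training fold (ties to the smaller
penalty), and the held-out patient is predicted. The ridge solves
$(Z^\top Z + N\lambda I)\beta = Z^\top y_c$ — the stationarity condition of
$(1/N)\lVert y - Z\beta\rVert^2 + \lambda\lVert\beta\rVert^2$ with the
intercept handled by centring the target on its training mean.

The VIF-eligible pool is the connectivity measures plus lesion volume; age,
initial FMA and CST asymmetry are protected. This mirrors the observation
that among the benchmarks only lesion volume is informationally redundant
with the network measures. The operating VIF threshold defaults to 23 and is
a configuration value: `vif_sweep()` exposes the accuracy-versus-threshold
curve (thresholds 5-200), but the pipeline never auto-selects the threshold
from that outer curve, because the curve is computed on the same predictions
it would be selecting for and would quietly leak test information. The
penalty grid is logarithmic, $10^{-3}$ to $10^3$ in 25 points — wide enough
that the inner search is never pinned at an edge in practice.

Accuracy is reported with the prediction-anchored
$R^2 = 1 - \sum(Y - Y')^2 / \sum(Y - \bar{Y'})^2$, whose denominator is
centred on the mean *prediction*; the conventional variant is available
behind a flag but is never the default. Fitter/non-fitter labels use the
strict 30% threshold; a boundary score of exactly 30 is a non-fitter.

**Classification cross-check.** The two-group labelling is also computed by
agglomerative clustering of patients against the proportional recovery model
(expected recovery $0.7\,(66-\mathrm{FMA}_{2w})$ points versus actual
recovered points). Two candidate spaces were considered. Spearman distance
between two-dimensional patient points is degenerate (any two distinct
points correlate exactly ±1). Euclidean distance on the standardized
$(\mathrm{expected}, \mathrm{actual})$ plane turned out to be structurally
wrong as a default: the fitter/non-fitter boundary is a *ratio* (the 30%
recovery threshold corresponds to the line
$\mathrm{actual} \approx 0.43\,\mathrm{expected}$ through the origin), so
the two groups form elongated stripes that average linkage splits by
baseline severity rather than recovery pattern — on separated synthetic
cohorts its agreement with the threshold rule was as low as 57%. The default
therefore clusters the standardized one-dimensional recovery ratio
$\mathrm{actual}/\mathrm{expected}$ (Euclidean, average linkage), in which
separated groups have a genuine gap and agreement with the 30% rule is exact;
the plane variant remains available via `coords = "plane"`. The cluster with
the higher mean ratio is labelled fitter. Undefined classification ratios
(zero denominators) are reported missing, never as 0.

**Uncertainty.** Bootstrap confidence intervals for $R^2$ draw 10000
subsamples of 32 predictions *without* replacement (a 32-of-$n$ subsampling
scheme; with-replacement resampling is available behind a flag) and report
the empirical 2.5/97.5 percentiles. Rank-sum tests report the Mann-Whitney
$U$, a tie-corrected normal $z$, and a p-value that is exact (full
enumeration of group assignments) whenever $\binom{n}{n_1} \le 20000$.
Spearman p-values use the $t$ approximation and Bonferroni correction.

## What the synthetic cohort emulates

The phantom module generates the study conditions end to end. Its defaults —
a 24×24×16 grid split into 36 box parcels (18 per hemisphere), 60 healthy
subjects sharing one 5000-streamline template up to Gaussian vertex jitter
(SD 0.3 voxel), and 40 patients — are a scaled-down stand-in for a
360-region atlas with $10^7$-streamline tractograms, small enough that the
default study runs in minutes on one CPU (the exhaustive oracle tests use
even smaller graphs, up to six nodes).

Streamline region pairs follow preferential attachment with probability
proportional to $(\mathrm{degree}+1)^{h}$ ($h$ = 1 by default), so hubs
exist and lesions hitting them cause disproportionate efficiency loss; at
$h = 0$ endpoint regions are uniform, which the tests verify by a chi-square
check. Lesions are nested ellipsoids: with the centre fixed by the seed, the
semi-axes scale linearly with severity ($\sqrt 3 \cdot$ grid at severity 1,
so severity 1 covers the whole grid and severity 0 is empty), giving exact
voxel-superset nesting across severities. Sixty percent of patient lesions
are centred on a designated cortico-spinal corridor (emulating
middle-cerebral-artery territory strokes), the rest at random locations, so
CST damage is not a deterministic function of lesion size.

Recovery is planted linearly:
$\mathrm{recovery} = \beta_0 + \beta_1\,\mathrm{FMA}_{2w} +
\beta_2\,\mathrm{asym} + \beta_3\,d + \varepsilon$, clipped to $[0,100]$,
with $\varepsilon \sim N(0, \mathrm{noise\_sd}^2)$ the *only* stochastic
term given the lesion, and $d$ the relative drop in mean weighted global
efficiency across the healthy connectomes caused by the patient's mask (a
dimensionless 0-1 damage index; using the relative drop keeps $\beta_3$ on
the same footing as the asymmetry coefficient). The default betas
$(5, 1.0, -60, -60)$ were chosen once so that each planted driver
contributes a comparable share of the recovery variance and the clipping at
0 produces a realistic non-fitter floor group; initial FMA decreases with
severity into the 0-55 inclusion range, age is drawn but carries no planted
effect, and the ipsilesional CST FA is attenuated proportionally to the
fraction of corridor streamlines the lesion transects. Three-month FMA is
the rounded integer consequence of the planted recovery, so the observed
recovery score inherits a quantization error of up to
$100/(66-\mathrm{FMA}_{2w})$ points per FMA point — one reason the planted
model is not recovered with $R^2 = 1$ even at zero noise.

What the phantom does *not* emulate: anatomically realistic atlas geometry
or tract shapes, diffusion signal and tractography errors, inter-subject
anatomical (rather than jitter) variability, measurement error in the FMA
beyond rounding, and any nonlinearity in recovery beyond the $[0,100]$
clip. Passing tests therefore demonstrate that the pipeline recovers the
relationships it assumes, on data shaped like its assumptions — not
clinical validity on real cohorts.

## Numerical choices and degenerate inputs

* Ridge at $\lambda = 0$ on collinear features raises an informative error
  rather than silently pseudo-inverting.
* VIF of duplicated columns is $+\infty$ (auxiliary $R^2$ within $10^{-10}$
  of 1); a single feature has VIF 1 by convention; with more features than
  rows the auxiliary regressions are ridge-stabilized ($10^{-8}$).
* VIF elimination ties break by reverse column order, so later-added
  connectivity features are removed before benchmarks; if the threshold is
  unreachable with non-protected features the protected set is returned
  with a warning.
* Zero-variance prediction targets in a fold abort loudly; all-equal
  patients in the clustering labeller warn and return a single class.
* Algebraic connectivity is clamped at 0 from below (eigenvalue tolerance
  $10^{-9}$); disconnected graphs return exactly 0.
* `run_pipeline` collects per-fold warnings (e.g. dropped zero-variance
  columns at fixture scale) into the report's structured log instead of
  emitting them mid-run.

## Known limitations

* Whether the original analysis protected the benchmark features from VIF
  elimination, and its exact flow-coefficient and quasi-idempotence
  formulas, are interpretation choices documented above, not certainties.
* The weighted-density definition (max-normalized mean weight) is one of
  several possible; all downstream binarization inherits it.
* Volumes are in voxel units by default; units cancel after per-fold
  standardization, so only reported lesion volumes are affected by
  `voxel_size`.
* Lesion masks are assumed already registered to the parcellation's space;
  no normalization or registration is performed.
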