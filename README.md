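# strokenet

Virtual-lesion connectomics and prediction of post-stroke upper-limb motor
recovery.

After a middle-cerebral-artery stroke, some patients recover most of their
arm function within three months while others barely improve. `strokenet`
implements an analysis pipeline for predicting that recovery from a binary
lesion mask alone, without patient-specific diffusion imaging:

1. **Virtual lesioning** — the patient's lesion mask is intersected with a
   set of healthy streamline tractograms; every streamline passing through
   the lesioned voxels is deleted, giving one "virtually lesioned"
   connectome per healthy subject. Connectome edges are volume-normalized
   streamline counts: `w_ij = c_ij / (V_i + V_j)`.
2. **Graph measures** — 11 binary and 7 weighted connectivity measures
   (density, median degree, clustering, flow coefficient, transitivity,
   Louvain modularity, eigenvector and betweenness centrality, algebraic
   connectivity, weighted global efficiency, participation coefficient,
   quasi-idempotence) are computed per lesioned connectome and averaged
   across the healthy subjects. Binary graphs come from density-matched
   binarization: the threshold is chosen so that the binary density equals
   the weighted density `sum(w_ij / w_max) / (N(N-1)/2)` of the weighted
   matrix.
3. **Prediction** — the measures are combined with clinical benchmark
   features (age, initial Fugl-Meyer assessment, lesion volume,
   cortico-spinal tract FA asymmetry `(FA_H - FA_L)/(FA_H + FA_L)`) into five
   nested feature sets and fed to a ridge regression
   `min_b (1/N)||y - Xb||^2 + lambda ||b||^2` under leave-one-subject-out
   cross-validation, with in-fold standardization, iterative VIF feature
   elimination (sets 4-5) and an inner leave-one-out grid search for
   `lambda`. The target is the FMA recovery score
   `100 (FMA_3m - FMA_2w) / (66 - FMA_2w)`. Accuracy is the
   prediction-anchored coefficient of determination
   `R^2 = 1 - sum((Y - Y')^2) / sum((Y - mean(Y'))^2)`.
4. **Evaluation** — patients are labelled fitters/non-fitters of the 70%
   proportional-recovery rule (30% recovery threshold, cross-checked by
   two-group hierarchical clustering), and each feature set is scored by
   specificity/sensitivity/PPV/NPV, bootstrap R^2 confidence intervals,
   Spearman correlations with Bonferroni correction, Wilcoxon rank-sum
   tests and a feature dendrogram.

Because clinical lesion masks and healthy tractograms are not shipped, the
package includes a first-class synthetic module (`generate_phantom`,
`generate_lesion`, `generate_cohort`) that builds phantom brains, hub-bearing
tractograms, nested ellipsoidal lesions and cohorts with a planted linear
recovery model, so the entire pipeline is testable end to end.

## Worked example

```r
library(strokenet)

cfg <- pipeline_config(
  phantom = phantom_config(grid_shape = c(16, 16, 16), n_regions = 12,
                           n_healthy = 8, n_streamlines = 500,
                           n_patients = 12, seed = 1),
  sets = c(1, 3, 4), bootstrap_draws = 300, n_permutations = 2, seed = 42
)
report <- run_pipeline(cfg)
print(report)
```

```
<pipeline_report>
  Set 1: R2 = 0.671 [0.549, 0.745], spec 0.88 sens 0.50 ppv 0.67 npv 0.78
  Set 3: R2 = 0.678 [0.598, 0.755], spec 1.00 sens 0.50 ppv 1.00 npv 0.80
  Set 4: R2 = 0.939 [0.917, 0.959], spec 1.00 sens 1.00 ppv 1.00 npv 1.00
  permuted-target control: mean R2 = -0.500 over 2 runs
  fitters: 4 / 12 patients
```

Reading: demographics plus initial impairment alone (Set 1) explain about
two-thirds of the variance in this planted cohort; adding lesion volume and
CST asymmetry (Set 3, the clinical benchmark) changes little at this tiny
scale, while adding the averaged virtual-lesion connectivity measures
(Set 4) lifts the leave-one-out R^2 to 0.94 and labels every patient's
recovery class correctly. The permuted-target control shows the pipeline
finds no signal once the recovery scores are shuffled. Per-fold feature
selections, ridge weights and penalties are in
`report$predictions[["4"]]`.

A command-line wrapper over the same pipeline lives in
`inst/cli/strokenet.R` (`Rscript strokenet.R --config config.yaml --outdir
results`); `read_pipeline_config()` documents the YAML keys.

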