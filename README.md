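# phenotree

Tree-structured phenomapping of broad-QRS electrocardiograms.

A QRS complex wider than 120 ms marks abnormal ventricular
depolarization. Clinical practice reads it as one of three labels — left
bundle-branch block (LBBB), right bundle-branch block (RBBB) or
nonspecific intraventricular conduction delay (NSIVCD) — but those labels
hide a continuum of morphologies with different disease risk and
different odds of responding to cardiac resynchronization therapy (CRT).
phenotree models that continuum end to end:

1. **Median beats** are distilled from rhythm strips (zero-phase
   0.5–100 Hz band-pass, 60 Hz notch, resampling to 400 Hz, R-peak
   alignment, per-sample median over the 8 independent leads I, II,
   V1–V6), with broad-QRS selection (QRS > 120 ms, no pacing/CIED/CHB).
2. A convolutional **variational autoencoder** compresses each beat to a
   51-dimensional latent vector (deterministic posterior-mean encoding).
3. **DDRTree** (reversed graph embedding, implemented from scratch)
   jointly learns a 2-D embedding `Z`, centroids `Y`, a spanning-tree
   backbone `B` and soft assignments `R` by exact alternating
   minimization of

   ```
   ||X − W Z||² + λ Σ_{(i,j)∈B} ||y_i − y_j||²
               + γ [ Σ_ik R_ik ||z_i − y_k||² + σ Σ_ik R_ik log R_ik ]
   ```

   The backbone is decomposed into sub-branches, merged into phenogroups
   (size-weighted Ward cost restricted to tree-adjacent pairs; default 6
   groups), and each sample receives a pseudotime — its geodesic distance
   from the tree center along the backbone.
4. **External cohorts** are projected onto the frozen tree: XGBoost
   regressors predict the two coordinates from the latent features,
   predictions snap to the nearest point on any backbone segment, and a
   cross-validated k-NN assigns phenogroups. The tree is never refit.
5. **Statistical overlays**: logistic/linear models for prevalent
   outcomes, Cox models for fatal and Fine–Gray subdistribution-hazard
   models for nonfatal outcomes (death competing), per-sample risk
   surfaces, Global Moran's I on the tree, elastic-net explainability of
   phenogroups, bootstrapped C-index model comparison, and CRT-response
   models (LVEF +10 points absolute; LVESD/LVESV −15% relative).

Clinical broad-QRS cohorts are access-restricted, so the package includes
a synthetic generator (`generate_cohort()`) producing 8-lead median beats
with class-specific QRS morphology, linked survival outcomes with a
competing death risk, prevalent-disease flags and pre/post-CRT echo
pairs. A single latent `severity` is the planted risk axis the pipeline
is asked to rediscover.

## Worked example

```r
library(phenotree)

co   <- generate_cohort(400, seed = 7, waveforms = "median")
vae  <- train_vae(co$records[1:320],
                  vae_config(latent_dim = 16, n_blocks = 4, epochs = 10,
                             batch_size = 32, seed = 8))
z    <- encode(vae, co$records)
median(reconstruction_correlation(vae, co$records[321:400]))
#> held-out reconstruction r: 0.947

tree <- fit_ddrtree(z, ddrtree_params(K = 40), seed = 9)
tree <- compute_pseudotime(merge_branches(assign_branches(tree), n_groups = 3))
tree
#> <tree_model> N = 400, K = 40, converged, 3 phenogroups
head(tree_samples(tree, ids = co$outcomes$id), 4)
#>   id        dim1   dim2 centroid branch phenogroup pseudotime_global
#> 1 rec00001 -2.40  2.57         4      8          3              4.78
#> 2 rec00002  3.86  0.332       16      5          2              3.40
#> 3 rec00003  4.15 -0.234        6      6          2              3.70
#> 4 rec00004  4.35 -0.316       19      6          2              3.88
```

Each row is one ECG: its position on the two tree dimensions, its
sub-branch and merged phenogroup, and its pseudotime (distance from the
tree core; larger = more extreme morphology). Overlay models read
directly off this table, e.g. a Fine–Gray model of incident disease
against the tree dimensions with death as the competing event:

```r
tab <- tree_samples(tree, ids = co$outcomes$id)
fit_adjusted_model(cbind(tab, co$outcomes[, -1]),
                   predictors = c("dim1", "dim2"),
                   covariates = c("age", "sex"), kind = "fine_gray")
#>      term exp_estimate    ci_low  ci_high          p
#> 1    dim1    0.9744283 0.9355235 1.014951 0.21272227
#> 2    dim2    0.9637703 0.8620014 1.077554 0.51690281
#> 3     age    0.9997320 0.9854798 1.014190 0.97080810
#> 4 sexmale    1.4482561 1.0773634 1.946832 0.01414017

mor <- morans_i(co$outcomes$qrs_ms, cbind(tab$dim1, tab$dim2), seed = 10)
#> Moran's I for QRS duration over the tree: 0.524 (null mean -0.0025, p = 0.001)
```

Exponentiated estimates are subdistribution hazard ratios with 95%
Wald intervals; the Moran statistic says QRS duration clusters strongly
on the tree (permutation p = 0.001), as a meaningful embedding should
show. `run_pipeline(pipeline_config())` chains all stages — generation,
preprocessing, VAE, tree, projection of an external cohort, outcome
overlays and CRT models — from one (optionally YAML) config and writes
tables plus a JSON run manifest.

## The methods vignette

`vignettes/phenomapping-methods.Rmd` documents the models and every
numerical choice: the synthetic generator's study conditions, the
envelope-based QRS measurement, the VAE architecture and training, the
DDRTree update equations and their closed forms, branch merging,
pseudotime, the projection contract, all overlay models and the known
limitations.
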