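# brainsfc

Structure–function coupling analysis of brain networks via graph signal
processing, with a fully synthetic validation cohort.

## The problem

Resting-state activity is shaped, but not dictated, by anatomy. Given a
subject's structural connectome (streamline counts between atlas
parcels, normalized by the parcels' gray-matter volumes) and their
regional BOLD time series, this package quantifies *how much* each
region's activity rides on the anatomical backbone:

1. Build the weighted adjacency `A[i,j] = counts[i,j] / (GMV_i + GMV_j)`
   and its symmetric normalized Laplacian `L = I − D^{−1/2} A D^{−1/2}`.
2. Eigendecompose `L U = U Λ`: the eigenvectors are *connectome
   harmonics*, the eigenvalues their graph frequencies.
3. Graph-Fourier-transform the BOLD matrix (`X̂ = Uᵀ X`), find the
   cutoff harmonic `C` that splits the average spectral energy density
   into halves, and project onto the two bands: a *coupled* component
   `X^C` (smooth over the connectome) and a *decoupled* component `X^D`.
4. Per region, the **structural decoupling index**
   `SDI_i = log2(‖X^D_i‖₂ / ‖X^C_i‖₂)` — negative means coupled to
   structure, positive means decoupled — plus coupled/decoupled
   functional-connectivity matrices (c-FC, d-FC) from within-component
   Pearson correlations, Fisher z-transformed.
5. Inference across a two-group cohort: covariate-adjusted permutation
   t-tests on regional SDI (5,000 label permutations, two-tailed,
   p < 0.05, BH-FDR column included), a 2×2 mixed ANOVA
   (component × group) per connectivity edge with Bonferroni FWE at
   p < 0.01 and simple effects, and residualized Spearman correlation
   between d-FC edges and a behavioral measure (total flight hours)
   after one-pass outlier removal.

Because real imaging inputs are large and external, the package ships a
synthetic-cohort generator whose statistical structure matches what the
analysis assumes — community-structured connectomes, band-limited
signals with a planted unimodal/transmodal coupling gradient, planted
group decoupling shifts, and a behavior-linked connectivity edge — with
the *realized* ground truth re-measured through the exact analysis
filters. Every stage is tested against it. The intended user is anyone
who wants a transparent, seed-reproducible SDI pipeline operating on
plain-text region-level matrices (exported from any tractography/fMRI
preprocessing workflow), or a test bed for coupling-analysis methodology.

## Worked example

The `analysis/` scripts run the full study on a simulated cohort
(40 subjects, 246 regions, 255 volumes, planted decoupling shift of
1 log2 unit in five regions, behavior effect 0.6 at edge 31–120):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_coupling_pipeline.R
Rscript analysis/03_recovery_summary.R
Rscript analysis/04_calibration_check.R
```

One run printed:

```
planted effect (realized, ground truth): target-region SDI 0.415 in pilots vs 0.078 in controls
coupling gradient (realized): unimodal -0.187 / transmodal 0.277 / subcortical 0.050
spectral cutoff C = 130 of 246 harmonics (group scope)
regions with SDI group difference at p < 0.05: 12 of 246 (12 pilot-higher)
edges with FWE-significant interaction at p < 0.01: 0 of 30135
d-FC(31,120) vs flight hours: rho = 0.525 (rho^2 = 0.275), p = 0.01751, n = 20
targets detected: 3 of 5
non-target significant regions: 9 (uncorrected p < 0.05 over 241 regions; ~12.1 expected by chance)
```

Reading this: the generator planted decoupling in five target regions;
the realized (leak-corrected) group difference there is ≈0.34 log2
units. The pipeline recovers the planted coupling hierarchy (unimodal
negative, transmodal positive SDI), flags the three targets whose
realized effects were large in this draw, finds roughly the chance
number of non-target regions at the uncorrected threshold, and recovers
the planted positive d-FC–flight-hours association. Across 50 seeded
replicates (see the acceptance test-suite block) at least 4 of 5 targets
are detected in ≥80% of runs.

Programmatic use mirrors the scripts:

```r
library(brainsfc)
cfg <- sfc_config(n_subjects_per_group = 20, decoupling_shift = 1,
                  target_regions = c(20, 60, 110, 160, 230), seed = 1)
cohort <- generate_cohort(cfg)                      # or load_cohort(dir)
an  <- analyze_cohort(cohort, cutoff_scope = "group")
sdi <- sdi_group_test(an$sdi, an$manifest, n_perm = 5000, seed = 1)
```

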