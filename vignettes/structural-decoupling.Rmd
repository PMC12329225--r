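---
title: "Measuring structure-function coupling with connectome harmonics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring structure-function coupling with connectome harmonics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`brainsfc` treats regional brain activity as a signal on a graph whose
nodes are atlas parcels and whose edge weights are structural
connectivity (SC): streamline counts from probabilistic tractography,
normalized by the summed gray-matter volumes (GMV) of the two endpoint
parcels,

$$A_{ij} = \frac{\text{counts}_{ij}}{\text{GMV}_i + \text{GMV}_j},
\qquad A_{ii} = 0 .$$

The symmetric normalized Laplacian $L = I - D^{-1/2} A D^{-1/2}$ (with
$D$ the diagonal strength matrix) is eigendecomposed, $L U = U \Lambda$.
The eigenvectors $u_k$ are the *connectome harmonics* and the ascending
eigenvalues $\lambda_k \in [0, 2]$ play the role of graph frequencies:
low-$\lambda$ harmonics vary smoothly along strong structural
connections, high-$\lambda$ harmonics vary against them.

A regions $\times$ timepoints BOLD matrix $X$ is projected into this
basis by the graph Fourier transform $\hat{X} = U^\top X$ and split at a
cutoff harmonic $C$ into complementary band projections

$$X^{C} = U_{\mathrm{low}} U_{\mathrm{low}}^\top X \quad\text{(coupled)},
\qquad
X^{D} = U_{\mathrm{high}} U_{\mathrm{high}}^\top X \quad\text{(decoupled)} .$$

$C$ is chosen so the cumulative average spectral energy density (mean
squared GFT coefficient per harmonic) reaches half of the total; harmonic
$C$ itself belongs to the low band. Per region, the structural
decoupling index is

$$\mathrm{SDI}_i = \log_2
  \frac{\lVert X^{D}_{i\cdot} \rVert_2}{\lVert X^{C}_{i\cdot} \rVert_2},$$

with the norm taken over the full retained time series, so each region
gets one number: negative = activity rides on structure (coupled),
positive = activity independent of it (decoupled). Pearson correlation
among regions *within* each component gives the coupled (c-FC) and
decoupled (d-FC) connectivity matrices; both are Fisher z-transformed
(with $r$ clipped at $\pm(1 - 10^{-12})$) before any statistics.

## Conventions and numerical choices

Several details are under-determined by the formulas above; the package
fixes them once:

* **Count symmetrization.** Probabilistic tractography returns
  asymmetric seed-to-target counts; they are symmetrized by the
  arithmetic mean before GMV normalization.
* **Cutoff tie rule.** $C$ is the *smallest* index whose cumulative
  density reaches half the total, and it belongs to the low band. The
  realized low-band energy share is recorded (it exceeds 0.5 whenever
  the cumulative sum jumps past the midpoint).
* **Eigen determinism.** Each eigenvector's largest-magnitude entry is
  made positive (first index wins ties); numerically degenerate
  eigenvalue groups are ordered by the sign-fixed vectors'
  lexicographic order. All downstream quantities are projector-based
  and therefore invariant to these conventions — randomized sign-flip
  tests assert this.
* **Degenerate bands.** A region whose coupled (or decoupled) component
  has zero norm relative to its total gets an `NA` SDI with a
  `coupled_zero`/`decoupled_zero` flag rather than $\pm\infty$; flagged
  regions are excluded from group tests and the exclusion is logged.
* **Isolated nodes** make $D^{-1/2}$ undefined and always indicate
  broken input, so they raise an error naming the region instead of
  being silently regularized. No SC thresholding is applied by default
  (`sc_threshold` exists but is off).
* **Energy accounting** uses plain squared GFT coefficients, all
  harmonics included — no windowing, no exclusion of the first
  (constant-like) harmonic.

## Cutoff scope

`analyze_cohort()` supports two scopes for the energy-halving cutoff.
With `cutoff_scope = "subject"` every subject's own density determines
their own $C$, keeping each subject self-contained. With
`cutoff_scope = "group"` densities are pooled first and a single $C$ is
shared.

For *group comparisons* the package's analyses use the group scope, and
this is a substantive choice, not a stylistic one: a condition that
raises decoupled-band energy in one group also shifts that group's
per-subject cutoffs upward, which lowers every region's SDI in that
group and can cancel exactly the effect being tested. A shared cutoff
keeps the band definition identical across groups so the comparison is
of signal content, not of band placement. Subject scope remains the
default for single-subject exploration.

## The synthetic cohort generator

The package is validated end-to-end on synthetic cohorts because the
generative truth is then known exactly. The generator emulates the
statistical structure the analysis assumes, at the study's native scale:
a 246-region parcellation (210 cortical, split evenly over hemispheres;
36 subcortical), 255 acquired volumes of which the first 5 are
discarded, and two groups of 20 subjects by default.

* **Connectomes** follow a community (block) model: Poisson streamline
  counts with mean 20 within and 10 between 6 contiguous communities,
  symmetrized draws, connectivity enforced by deterministic unit-edge
  repair. The modest 2:1 contrast is deliberate: it yields clearly
  modular graphs while keeping the Laplacian bulk spectrum
  non-degenerate, so harmonics — and hence per-region band projectors —
  are stable across subjects. (Strong contrast clusters the spectrum,
  makes eigenspaces rotate freely between draws, and inflates
  between-subject SDI variance several-fold.)
* **GMV** is log-normal with median 2500 mm^3 (log-sd 0.4), the scale of
  fine-parcellation cortical parcels.
* **Signals** are built directly in each subject's own harmonic basis:
  $X = P_{\mathrm{low}} E_c + \Gamma\, (P_{\mathrm{high}} E_d)$ with
  independent white-noise matrices $E_c, E_d$, band projectors at the
  nominal cutoff $\lfloor N/2 \rfloor$, and a diagonal per-region gain
  $\Gamma$ on the decoupled band. The gain encodes a coupling gradient
  ($2^{-0.5}$ for unimodal, $2^{+0.5}$ for transmodal parcels), so the
  canonical hierarchy — sensory regions coupled, association regions
  decoupled — is recoverable, plus a planted group offset
  $2^{\text{decoupling\_shift}}$ in designated target regions for
  pilots only.
* **Realized, not nominal, ground truth.** Row-scaling a band-limited
  component leaks across bands, so nominal gains overstate what is
  plantable. The generator therefore re-runs the exact analysis filters
  at the nominal cutoff on the retained volumes and returns that
  *realized* SDI as the reference; tests assert the two code paths agree
  to $10^{-10}$. The realized per-region effect varies with each
  cohort's graphs (projector weights differ by region), and recovery
  simulations are judged against what was realizably planted.
* **Behavior.** Pilot flight hours are log-uniform over 350-19,000
  (a range spanning orders of magnitude). A shared latent time series in
  the decoupled band of the two `behavior_edge` regions, with loading
  proportional to normalized log hours (peak `behavior_effect`), makes
  realized d-FC at that edge co-vary monotonically with hours — Spearman
  correlation is invariant to the monotone transform, which the tests
  assert.
* **Covariates** (age, education, TIV, mean framewise displacement) are
  drawn from one distribution for both groups, i.e. matched by
  construction, mirroring a matched-control design.

What the generator does *not* emulate: hemodynamic autocorrelation,
1/f spectra, motion artifacts, spatial smoothness of parcel signals, or
distance-dependent connectome weights. Passing tests therefore certify
the pipeline's algebra, calibration, and recovery behavior under the
stated generative law — not performance on real MRI-derived matrices.

## Inference layer

* **Regional SDI.** Covariates are regressed out once on the pooled
  design (OLS; rank deficiency is an error naming the collinear
  columns); a pooled-variance two-sample t is computed on residuals and
  its null built by permuting group labels (default 5,000 draws, fixed
  seed, shared across regions). The p-value uses the +1 correction,
  $p = (1 + \#\{|t_\pi| \ge |t_{\mathrm{obs}}|\})/(n_{\mathrm{perm}}+1)$,
  so it is valid and never zero. Results are reported uncorrected at
  $p < 0.05$ with an accompanying Benjamini-Hochberg FDR column.
* **Edge ANOVA.** Per edge, a 2 $\times$ 2 mixed design (component
  within, group between) on covariate-residualized z-values. With a
  two-level within factor the interaction test is algebraically a
  pooled two-sample t-test on difference scores (d-FC z minus c-FC z),
  $F = t^2$ on $(1, n-2)$ df; the implementation is cross-checked
  against `aov()` with an `Error(subject)` stratum. Family-wise error
  is Bonferroni by default (max-F permutation available), threshold
  $p < 0.01$; significant edges get per-component simple-effect
  t-tests.
* **Behavior.** Pilots only: the edge's d-FC z is residualized on the
  covariates, outliers at $|z| > 3$ standardized residuals removed once
  (non-iterative, count reported), then Spearman's $\rho$ against total
  flight hours, with $\rho^2$ reported alongside.

## Simulation scales

Calibration and recovery runs use sizes chosen to make Monte-Carlo error
small relative to the quantities checked: type-I error of the
permutation test from 500 null cohorts (20 regions, 20 subjects/group,
1,000 permutations each); ANOVA family-wise error from 250 null cohorts
of the same shape; regional recovery from 50 cohorts at the full
246-region scale (planted shift 1 in 5 regions); behavior recovery from
100 cohorts with 40 pilots at 60 regions. The test suite runs the same
checks at 250/200 null cohorts.

## Known limitations

* The generator's white-noise bands make time points exchangeable;
  temporal autocorrelation in real BOLD would widen the sampling
  distribution of correlation-based quantities.
* Residualize-then-permute is a Freedman-Lane-style simplification;
  exchangeability holds only approximately when covariates correlate
  with group, though matched covariates make this benign here.
* Bonferroni over tens of thousands of correlated edges is
  conservative; the max-F option trades exactness of the bound for
  power.
* With per-subject cutoff scope, group differences in band energy move
  the cutoff itself; use group scope for any between-group contrast
  (see above).
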