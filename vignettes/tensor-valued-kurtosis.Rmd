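---
title: "Separating anisotropic and isotropic diffusional kurtosis with tensor-valued encoding: models, phantoms and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating anisotropic and isotropic diffusional kurtosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvdmri)
```

## The measurement and the model

Conventional diffusion MRI encodes diffusion along a single direction per
shot (linear tensor encoding, LTE, b-tensor shape $b_\Delta = 1$).
Spherical tensor encoding (STE, $b_\Delta = 0$) sensitizes the signal to
diffusion in all directions simultaneously. Acquiring both shapes makes it
possible to split the total diffusional kurtosis $MK$ — a single number in
LTE-only DKI — into two components with different microstructural
meanings: anisotropic kurtosis $MK_A$, driven by elongated microscopic
structures regardless of how coherently they are oriented, and isotropic
kurtosis $MK_I$, driven by voxel-internal heterogeneity of isotropic
diffusivities (e.g. variation in cell density).

`fit_qti()` fits, per voxel, the powder-averaged (directionally averaged)
signal cumulant model

$$\log S(b, b_\Delta) = \log S_0 - b\,\mathrm{MD}
 + \frac{b^2 \mathrm{MD}^2}{6}\left(MK_I + b_\Delta^2\, MK_A\right),$$

where $b$ is in ms/µm² (1 ms/µm² = 1000 s/mm²) and MD in µm²/ms. $MK_A$
and $MK_I$ are constrained to $[-1, 4]$ as an outlier guard; a voxel whose
solution sits on the constraint is flagged (`fit_flags = 1`). For
comparison the package also fits conventional DTI (`fit_dti()`, log-linear
tensor fit on LTE shells with $b \le 1$ ms/µm², eigenvalues clipped at 0
before FA) and DKI (`fit_dki()`, weighted linear least squares of the full
diffusion + kurtosis tensor expansion on all LTE data, with $MK$ the mean
directional apparent kurtosis over a fixed 60-direction set).

Assumptions worth stating explicitly: diffusion in each micro-environment
is Gaussian (no exchange, no time dependence), the powder average is taken
over a finite direction set, and the cumulant expansion is truncated at
$b^2$. Each of these is examined quantitatively below.

## The default protocol

`default_protocol()` returns the built-in acquisition: four LTE shells at
$b =$ 0.1, 0.7, 1.4 and 2.0 ms/µm² with 6, 6, 12 and 16 directions, plus
four STE shells at the same b-values with 6, 6, 12 and 16 repeats — 80
measurements in 8 shells, at 2.3 mm isotropic voxels. The direction sets
are deterministic: the classic icosahedral 6-direction scheme, and
purpose-optimized 12- and 16-direction sets whose even moments match the
uniform sphere through degree 6 as closely as the point counts allow
(frame-potential residuals $1.3\times10^{-7}$ and below $10^{-14}$). This
matters because the powder cumulant fit implicitly equates the finite
shell average with the rotational average; with Fibonacci-spiral sets the
direction-sampling bias at the top shell is of order $10^{-3}$ in log
signal — the same size as the model's truncation bias, with which it can
spuriously cancel or add. The published direction sets of the acquisitions
this protocol emulates are not public; any well-spread deterministic set
is acceptable here, and ours is chosen for quadrature accuracy.

## The synthetic cohort generator

No patient data ship with the package. `sample_cohort()` generates phantom
subjects that emulate the *structure* of a surgical meningioma cohort —
not the biology of any specific patient group:

* labels: consistency (soft / variable / firm / unknown), WHO grade
  (I / II) and histological type (1–7), arranged in strata
  (`demo_strata()`, `full_strata()` with a 30-subject case mix: 7 firm /
  5 variable / 4 soft / 14 unknown, 22 grade I / 8 grade II);
* geometry: an ellipsoidal brain support and an ellipsoidal tumor with
  randomized center and semi-axes, and a peritumoral rim built
  morphologically (`make_rim_roi()`: 26-connectivity dilation up to
  2 voxels = 4.6 mm, clipped to brain, tumor excluded);
* microstructure: per voxel, a two-component Gaussian mixture whose
  isotropic diffusivities are $\mathrm{MD}(1 \pm \delta)$ (log-normal MD
  jitter) and whose per-component anisotropy is proportional to the
  component diffusivity with the proportionality clipped so radial
  diffusivities stay non-negative — a clipped-normal effective anisotropy.
  The mapping from targets $(\mathrm{MD}, MK_I, MK_A)$ to components is
  exact where feasible; ground truth is always recomputed from the actual
  (possibly clipped) components via `mixture_moments()`, so truth maps are
  exact by construction;
* orientations: per-voxel random axes with configurable dispersion
  (aligned, Watson-like six-fold cone, or uniform twelve-fold), so FA and
  $MK_A$ can be decoupled — microscopically anisotropic tissue with
  incoherent orientations has low FA but high $MK_A$;
* noise: Rician, $\sqrt{(S+\epsilon_1)^2+\epsilon_2^2}$ with
  $\epsilon \sim N(0, (S_0/\mathrm{SNR})^2)$, one independent complex draw
  per measurement; default SNR 30;
* planted effects: group differences are specified as subject-level
  standardized shifts (`d` units of the between-subject SD). The defaults
  reproduce the qualitative orderings this pipeline is designed to detect:
  firm consistency → lower $MK_A$ (hence lower $MK$) tail, variable
  consistency → lower MD, psammomatous type (7) → higher $MK_A$ and
  $MK_I$ medians. The grade effect is a *scale* effect: grade II subjects
  get a larger voxel-level $MK_I$ jitter in the rim (0.20 vs 0.08),
  emulating a high-grade peritumoral "$MK_I$ ring". Baseline tissue
  values (tumor MD 1.1 µm²/ms, $MK_A$ 0.6, $MK_I$ 0.4; brain MD 0.8,
  $MK_A$ 0.8, $MK_I$ 0.2) are plausible synthetic choices, not literature
  measurements; no quantitative tissue parameters for meningioma subtypes
  were available to copy.

Effects are planted at the (group, parameter) level rather than per
distribution characteristic: a location shift moves all percentiles and a
scale effect moves the standard deviation, which is how group structure
plausibly enters real histograms.

What the generator does *not* emulate: anatomy, partial volume with CSF
or skull, susceptibility and eddy-current artifacts, concomitant-gradient
bias, diffusion time dependence, and intrinsic (non-mixture)
compartmental kurtosis. Passing tests therefore demonstrate correctness
of the estimation and statistics chain under the stated forward model,
not robustness to those confounds.

Reproducibility: a master seed spawns per-subject tissue substreams and
per-run noise substreams (`substream_seed`), so identical configurations
give bit-identical cohorts, signals and result tables.

## Numerical choices in the fits

* The cumulant model is fitted by ordinary least squares on the
  log-signal, the scale on which the model is linear in
  $(\log S_0, \mathrm{MD}, MK_I \mathrm{MD}^2, MK_A \mathrm{MD}^2)$.
  The unconstrained optimum is a single linear solve; only voxels whose
  solution violates the box are refined with L-BFGS-B from the clipped
  linear start (objective tolerance `factr = 10`), so the procedure is
  deterministic and fast. A signal-domain residual convention is exposed
  (`residual = "signal"`); on exact rotational powder averages the two
  conventions agree to three decimals in all parameters, so the choice is
  not consequential here.
* Voxels with any non-positive shell mean are flagged (`fit_flags = 2`)
  and excluded from feature extraction, as are non-converged voxels (3).
* Smoothing (`smooth_volume()`, default σ = 1.6 mm, i.e. 0.696 voxels at
  2.3 mm) is applied to the DWI data before averaging and fitting, as a
  separable truncated-at-4σ Gaussian with row-renormalized kernels, so
  constant volumes are preserved exactly, including at volume edges.
* Percentiles use linear interpolation between order statistics
  (`quantile` type 7) and standard deviations the $n-1$ denominator —
  the most common conventions, fixed here for bit-reproducibility.
* The Mann–Whitney U is computed from midranks; p-values are exact (full
  enumeration) when $n_1+n_2 \le 12$ without ties, else the normal
  approximation with tie and continuity correction. Degenerate all-equal
  data give $p = 1$.
* AUC is the rank statistic $U/(n_1 n_2)$ with half-weight ties; the
  score direction (e.g. "lower $MK_{A,10}$ indicates firm") is a declared
  input, never auto-selected, to avoid optimistic bias. Bootstrap CIs are
  percentile intervals over pair resamples (default $n = 5000$),
  redrawing resamples that lose a class. The optimal cut-point maximizes
  Youden's J over midpoints between adjacent distinct scores plus the two
  boundary thresholds (predict-none / predict-all), ties broken toward
  the lower threshold.
* Characteristic ranking averages $|d|$ (Cohen's d with pooled SD) over
  parameters and contrasts; signed averaging is available but the default
  is magnitude, since the sign depends on arbitrary group orientation.
  Ties in the ranking break by the fixed order p10 < p25 < p50 < p75 <
  p90 < std.
* No multiple-comparison correction is applied by default (the
  exploratory convention of the analyses this package re-implements); any
  `p.adjust` method can be requested.

## Accuracy limits, measured

Two genuine limits of the second-order powder model are worth numbers.
Both were measured against exact rotational powder averages (numerical
integration), eliminating direction-sampling effects:

* **Truncation bias.** For the extreme single-tensor case
  $(d_\parallel, d_\perp) = (2.0, 0.2)$ µm²/ms (analytic $MK_A = 1.35$),
  fitting the quarter-scaled protocol ($b_{\max} = 0.5$) recovers
  $MK_A = 1.278$ — a −5.3% bias that is identical under log-domain,
  weighted and signal-domain residuals. The third cumulant of an ADC
  distribution spanning 0.2–2.0 µm²/ms is simply not negligible at
  $b_{\max} d_\parallel = 1$. The bias scales as $b^2$: halving $b$
  roughly halves the worst-case kurtosis error across generated cohorts
  (tested). MD is recovered to better than 0.5% throughout, and the
  isotropic two-component case ($MK_I = 0.75$) to −1.8% at quarter scale.
* **Additivity.** On orientationally isotropic voxels the LTE-only DKI
  $MK$ and the tensor-valued $MK_A + MK_I$ agree within 0.05 on the
  full-scale protocol — both estimators share the truncation bias, which
  therefore cancels in the comparison.

A related power limit: with $n = 8$ vs 8 subjects and a planted
subject-level effect of $d = 1.5$, the two-sided U test at $\alpha=0.05$
has ≈ 74% power (its $t$-test counterpart has 80%); simulation-based
checks of the comparison grid should expect that number, not 80%.

## Problem sizes

The test-suite and acceptance-script runs use deliberately small
instances chosen to exercise every code path: 16³–24³ voxel grids,
cohorts of 12–30 subjects, 100-replicate power/type-I simulations on
truth-map features, 1000-voxel Rician recovery panels, and bootstrap
depths of 500–5000. These sizes are the package's own defaults for a
desk-scale, fully reproducible study; all of them are configuration
fields, and scale up without code changes.

## Known limitations

* The rim ROI is a morphological ring, a reproducible stand-in for
  manual peritumoral delineation; meninges exclusion is modeled only as
  exclusion of non-brain support.
* The grade effect (rim $MK_I$ heterogeneity) survives the full
  simulate–fit–test pipeline only in attenuated form at SNR 30, because
  voxel-level fit noise adds to both groups' rim spread — the fitted
  effect size (≈ 0.7 at $n=30$) is noticeably smaller than its truth-map
  counterpart. This mirrors the weak grade discriminability the method
  shows on real data and is left as an honest property of the pipeline.
* `fit_qti` applies no Rician noise-floor correction; at SNR 30 the
  resulting median biases are below 2% in MD and 0.02 in the kurtosis
  components (measured in the acceptance script), but at substantially
  lower SNR the noise floor will bias kurtosis upward.
* S0 maps are fitted jointly with the diffusion parameters from the
  powder signal, not estimated from separate $b=0$ acquisitions (the
  protocol has none).
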