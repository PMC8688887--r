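# tvdmri

Tensor-valued diffusion MRI analysis in R: simulation of linear + spherical
b-tensor encoded acquisitions, separation of anisotropic and isotropic
diffusional kurtosis, ROI histogram features, and nonparametric group
statistics with bootstrap ROC analysis.

## The problem

Conventional diffusion MRI conflates microscopic anisotropy with
orientation dispersion: a voxel full of elongated cells pointing every
which way and a voxel with no elongated cells at all can both show low
fractional anisotropy (FA). Acquiring two b-tensor shapes — linear (LTE,
one direction per shot) and spherical (STE, all directions at once) —
breaks that degeneracy. Fitting the powder-averaged signal with

    log S(b, b_Δ) = log S0 − b·MD + b²·MD²·(MK_I + b_Δ²·MK_A) / 6

splits the total mean kurtosis MK of diffusion kurtosis imaging into an
anisotropic component MK_A (elongated microscopic structures, whatever
their orientation coherence) and an isotropic component MK_I (intra-voxel
heterogeneity of isotropic diffusivities). In tumor imaging — the use case
this package is built around, with meningioma consistency, grade and type
as the motivating labels — MK_A and MK_I carry complementary information
that MK alone cannot: histogram characteristics of these maps inside a
whole-tumor ROI and in a ≤2-voxel peritumoral rim are compared between
patient groups with rank-sum tests, Cohen's d, and ROC analysis.

The package is aimed at methods researchers who want a fully reproducible,
end-to-end desk-scale replica of such a study: a synthetic cohort
generator stands in for patient data (none ship with the package), and
every stage — acquisition scheme, forward simulation with Rician noise,
smoothing, model fits, ROI features, statistics — is an exported, tested
function.

## Worked example

A single voxel: two Gaussian tissue components, forward-simulated on the
built-in 80-measurement LTE+STE protocol, then re-estimated:

```r
library(tvdmri)
comp <- tissue_components(
  tissue_component(d_par = 2.0, d_perp = 0.2, fraction = 0.5),
  tissue_component(d_par = 1.4, d_perp = 1.4, fraction = 0.5))
round(mixture_moments(comp), 3)
#>    md  mk_i  mk_a
#> 1.100 0.223 0.357

scheme <- default_protocol()
signal <- synthesize_signal(comp, scheme, s0 = 100)
vol <- dwi_volume(array(signal, c(1, 1, 1, 80)), voxel_size = 2.3, scheme)
maps <- fit_qti(powder_average(vol))
```

which prints `S0 = 100.0, MD = 1.098, MK_I = 0.207, MK_A = 0.431`: MD is
recovered to 0.2%, and the kurtosis split lands close to the analytic
moments, with the residual deviation being the second-order cumulant
truncation at b = 2 ms/µm² (quantified in the vignette).

A full simulated study — 30 phantom subjects whose case mix mirrors a
surgical meningioma cohort, simulate → smooth → fit → features → stats:

```r
res <- run_study(make_demo_config("full", seed = 1), out_dir = "study")
for (nm in names(res$headline)) { h <- res$headline[[nm]]
  cat(sprintf("%-45s AUC %.2f [%.2f, %.2f]  p = %.3f\n",
              nm, h$auc, h$ci[1], h$ci[2], h$p)) }
#> consistency_firm.mk_a__p10__whole_tumor       AUC 0.90 [0.70, 1.00]  p = 0.008
#> consistency_firm.mk__p10__whole_tumor         AUC 0.81 [0.56, 1.00]  p = 0.044
#> consistency_variable.md__p10__whole_tumor     AUC 1.00 [1.00, 1.00]  p = 0.002
#> grade_II.mk_i__std__rim                       AUC 0.69 [0.45, 0.91]  p = 0.116
#> type_7.mk_a__p50__whole_tumor                 AUC 0.95 [0.86, 1.00]  p = 0.002
```

Reading: firm-consistency phantoms are separated from the pooled
soft/variable ones by the 10th percentile of MK_A (lower = firm) with AUC
0.90; variable consistency by a lower MD 10th percentile; the psammomatous
type (7) by a higher MK_A median; and the grade II rim-heterogeneity
effect survives the noisy pipeline only in attenuated form (AUC 0.69) —
deliberately, since that is how weakly the rim sign discriminates in
practice. `res$tests` holds the full 11-contrast × 36-characteristic × 2-ROI
grid (one row per test), `res$ranking` the effect-size ranking of the six
distribution characteristics, and `study/` the CSV/JSON outputs plus a run
manifest.

A thin command-line wrapper with `simulate`, `fit`, `features`, `stats`,
`run-all` and `demo` subcommands lives at `inst/cli/tvdmri.R`.

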