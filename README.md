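# placseg

Compartment-resolved analysis of dual-contrast (T2\* + diffusion-weighted)
placental MRI, for researchers studying placental oxygenation in vivo.

Whole-placenta T2\* averages mix maternal blood, fetal vessels and villous
tissue, which blunts and can reverse gestational-age trends. `placseg`
instead works voxel by voxel:

1. **Parametric maps** — mono-exponential T2\* relaxometry
   (`S(TE) = S0·e^(−TE/T2*)`) and diffusion-tensor fitting
   (`S(b,g) = S0·e^(−b·gᵀDg)`), both by two-pass weighted log-linear least
   squares, yielding per-voxel ADC, FA, AD, RD and T2\*.
2. **Fuzzy segmentation** — an unsupervised K = 3 Gaussian-mixture model
   (EM on z-scored features, full covariances) assigns each voxel posterior
   probabilities of belonging to the intervillous space (IVS), placental
   vessels (PV) or placental tissue (PT). Components are named by their
   signatures: highest FA → PV; of the rest, higher T2\* → IVS.
3. **Lesion detection** — a voxel whose typicality (upper-tail χ²₅
   probability of its squared Mahalanobis distance) is below 0.05 for
   *every* physiological component is atypical for all of them and joins
   the lesion cluster (PL); the PL volume fraction quantifies placental
   abnormality.
4. **Depth layers** — a normalized chorionic→basal coordinate
   `d_c/(d_c + d_b)` from exact Euclidean distance transforms, cut into
   five layers (B, chorionic … F, basal) for layer-wise trend analysis.
5. **Cohort statistics** — per-compartment T2\*-vs-GA regressions with 95%
   confidence bands, GA-binned Mann–Whitney comparisons (exact p for small
   samples), lesion-burden group tests, and fetal-brain/placenta T2\*
   correlations ranked by R².

Because clinical placental MRI is rarely shareable, the package ships a
**digital phantom**: cotyledon-structured placental geometry, compartment
feature distributions, planted lesions, GA-dependent cohort trends,
Rician noise — with every generative parameter recorded as ground truth,
so each module is validated against a known answer.

## Worked example

```r
library(placseg)

des <- cohort_design(n_subjects = 10, lesion_prevalence = 0.2,
                     geometry = phantom_geometry(dim = c(32, 32, 12)))
co  <- generate_cohort(des, seed = 7)
res <- analyze_cohort(co, seed = 7)

print(res$model)
#> <Gaussian mixture: K = 3, n features = 5, loglik = 136373.77, converged>
#>                           ADC    FA    AD    RD  T2star
#> component 1 (w = 0.350) 2.817 0.231 3.476 2.488 109.128
#> component 2 (w = 0.448) 1.422 0.240 1.741 1.263  55.185
#> component 3 (w = 0.202) 1.737 0.472 2.502 1.355  81.291

res$stats$trends$IVS
#> slope -1.503 +/- 0.307, intercept 150.7, R^2 = 0.799, P = 0.00274 (n = 8)
res$stats$trends$PT
#> slope 0.3151 +/- 0.123, intercept 46.43, R^2 = 0.524, P = 0.0423 (n = 8)

res$stats$pl$group_test
#> Mann-Whitney U = 16.0, P = 0.04444 (exact)

res$stats$brain$summary
#>   compartment      slope r_squared      p_value
#> 1         IVS  0.8061097 0.9553451 1.107240e-06
#> 2          PV  0.5982156 0.9205428 1.126375e-05
#> 3       total  0.7609976 0.5734409 1.119716e-02
#> 4          PT -1.5428015 0.2068265 1.866466e-01
```

Reading the output: the three mixture components are recognizably IVS
(high T2\*, high diffusivity), PT (low T2\*, low diffusivity) and PV (high
FA). IVS T2\* falls with gestational age (here −1.5 ms/week, the planted
trend) while tissue stays roughly flat; subjects with planted lesions
carry a significantly higher PL fraction than healthy subjects
(mean 0.259 vs 0.024 here); and fetal-brain T2\* correlates best with IVS
T2\* — the coupling the cohort generator planted.

`vignettes/placseg-methods.Rmd` documents the models, parameter defaults,
numerical choices and the phantom's scope and limitations.

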