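# pollenflow

Analysis of fluorescent-dye pollinator-movement experiments in fragmented
plant populations, built around the field system of two parapatric *Silene
nutans* ecotypes (calcicolous `Ca` and silicicolous `Si`) in southern
Belgium. Fluorescent powdered dye applied to anthers acts as a pollen
analogue; the particle counts recovered on recipient stigmas tell you how
far pollinators carry pollen, whether deposition is spatially structured,
and whether the two ecotypes share pollinators or are isolated from them.

The package is for pollination ecologists and conservation biologists who
have (or simulate) dye-deposition data and want the full analysis chain:

* **Dispersal kernel** — the 2-D exponential-power family

  f(α, β; r) = β exp(−(r/α)^β) / (2π α² Γ(2/β)),

  with extent α (m) and shape β (β < 1 leptokurtic, β > 1 thin-tailed),
  fitted to per-recipient mean dye counts by chi-squared minimization with a
  free proportionality constant, and the mean transfer distance

  δ_k = α Γ(3/β) / Γ(2/β).

  Degenerate fits (parameter pinned at a bound, or no detectable distance
  decay) are flagged rather than reported silently.
* **Spatial structure** — Moran's *I* under row-standardized
  inverse-distance weights with permutation tests (999 permutations),
  Bonferroni screening, distance-binned correlograms, and Goodman–Kruskal
  Γ distance-decay statistics.
* **Hurdle count regression** — maximum-likelihood two-part models (logit
  hurdle crossing + zero-truncated Poisson/negative-binomial counts) with
  offsets, Wald and likelihood-ratio tests, randomized-quantile residuals
  and residual spatial checks; the three standard transfer analyses
  (among-population differences, intra- vs inter-ecotypic, directionality)
  are packaged as `run_transfer_analyses()`.
* **Community statistics** — correlation-matrix PCA and Bray–Curtis
  PERMANOVA of seed-predator abundances, Mann–Whitney *U* comparisons of
  camera-derived visitation, chi-square tests of germination and chlorosis.
* **Synthetic data** — `sim_config()` + `simulate_*()` generate landscapes,
  kernel-driven dye deposition with excess zeros and overdispersion,
  ecotype-structured predator communities, visitation and germination
  samples with known ground truth for recovery and calibration experiments.

The study's printed summary tables (seed-predator abundances, camera
recordings, fitted kernel parameters) ship as plain-text fixtures; see
`load_predator_counts()`, `load_camera_records()`,
`load_kernel_parameters()`.

## Worked example

```r
library(pollenflow)

# mean transfer distance from fitted kernel parameters (Rav_Si: alpha = 28.9,
# beta = 0.83)
kp <- load_kernel_parameters()
rav <- kp[kp$population_id == "Rav_Si", ]
mean_dispersal_distance(rav$alpha, rav$beta)
#> delta_k = 87.4 m

# seed-predator communities: ordination and ecotype effect
pred <- load_predator_counts()
pca_correlation(pred)
#> Correlation-matrix PCA
#>   % variance per axis: 51.8, 20.6, 19.4, 7.8, 0.4
#>   PC1+PC2: 72.4%
permanova(pred, n_perm = 999, seed = 1)
#> PERMANOVA (bray distance, 999 permutations, sequential SS)
#>      term df sum_of_squares pseudo_F p_perm
#>   ecotype  1         0.5725     3.15  0.006
#>      year  1         0.1907     1.05  0.390
#>  Residual 10         1.8171       NA     NA
#>     Total 12         2.5803       NA     NA

# simulate one population with known kernel and refit it
cfg <- sim_config(n_populations = 1, ecotypes = "Si",
                  centers = matrix(c(0, 0), 1), radii = 200,
                  plants_per_population = 300, alpha = 30, beta = 0.8,
                  seed = 1)
plants <- simulate_landscape(cfg)
dye <- simulate_dye_deposition(plants, cfg)
transfers <- build_transfer_table(plants, dye, simulated_source_map(cfg))
fit_kernel(transfers)
#> Exponential-power dispersal kernel fit (chisq objective, n = 300)
#>   alpha = 28.04 m, beta = 0.7583, scale c = 1.89e+05
#>   mean transfer distance delta_k = 108.3 m
#>   objective = 339.689, converged = TRUE, boundary_flag = FALSE
```

The PCA says the first two axes carry 72.4% of the community variance — the
silicicolous populations host a richer seed-predator fauna — and the
PERMANOVA confirms ecotype (pseudo-F = 3.15, p = 0.006) but not year
explains the variation. The refit of the simulated population recovers the
generating kernel (α = 30 → 28.0, β = 0.8 → 0.76); δ_k is estimated less
precisely than the parameters because it integrates the kernel's tail.

A full pipeline run from a manifest (input CSVs, dye-color → source map,
options) is `run_manifest()`; `validate_pipeline()` re-checks the package's
core numerical invariants.

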