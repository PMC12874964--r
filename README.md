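# paridis

Ensemble species distribution modelling, niche-overlap statistics, and plastid
mini-barcode design for the medicinal herbs *Paris polyphylla* var.
*chinensis* and var. *yunnanensis* — implemented as a desk-scale,
fully testable R package in which every analysis stage can run against
synthetic data with planted ground truth.

## The scientific problem

Two closely related medicinal herbs are harvested from the wild and
increasingly cultivated. Three questions drive the workflow:

1. **Where can each variety grow, and how much does human pressure cost?**
   Presence-only occurrence records and gridded environmental layers feed an
   ensemble of distribution models. Single models (GLM, GAM, CTA, ANN, RF,
   GBM, SRE) are trained on presences versus randomly drawn pseudo-absences
   (75/25 stratified splits), and only runs with TSS > 0.8 and ROC > 0.9 enter
   the committee whose averaged prediction is the suitability map. Human
   impact is quantified by modelling with and without the human-footprint
   layer and comparing the two maps with Schoener's overlap
   `D = 1 − ½ Σ|z₁ − z₂|` on normalized suitability surfaces; `1 − D` is the
   impact index.

2. **Do the two varieties occupy equivalent niches, and how do ranges shift?**
   Occurrences are projected into a PCA of the background environment,
   kernel-density occupancy surfaces are corrected by availability, and niche
   equivalency is tested by pooling and re-partitioning the records
   (`p_greater = (1 + #{null ≤ D_obs}) / (n_iter + 1)`). Suitability maps are
   graded into five classes, binarized at 0.6, and compared across scenarios:
   contraction/retention/expansion areas, area-weighted centroid shifts, and
   the all-scenario intersection (long-term stable area).

3. **How do you tell the varieties apart as seedlings?** In aligned plastid
   genomes, diagnostic columns (each variety fixed for a different base, or a
   fixed indel) are enumerated, 200-bp mini-barcode candidates are designed
   around them with conserved 20-bp flanks, and query sequences are classified
   by aligning to each candidate window and voting over the diagnostic sites.

## Worked example: SDM on a synthetic landscape

```r
library(paridis)

specs <- dplyr::bind_rows(
  layer_spec("t_range", mean = 30, sd = 5,   range = 3),
  layer_spec("precip",  mean = 1000, sd = 250, range = 3),
  layer_spec("hfi",     mean = 20, sd = 8,   range = 2)
)
stack <- generate_env_stack(specs, dims = c(60, 60), origin = c(100, 30),
  cell_size = 0.1, seed = 1)

# a precipitation-specialist virtual species
sim <- simulate_virtual_species(stack,
  coefficients = c(precip = 12 / 250),
  intercept = -12 / 250 * (1000 + 1.5 * 250),
  n_presence = 150, seed = 2)

occ <- spatial_thin(load_and_clean(sim$occurrences), resolution_km = 10, seed = 3)
thinning_log(occ)$n_cells_occupied
#> [1] 116

pa <- sample_pseudo_absences(stack, occ, n = 300, n_sets = 2, seed = 4)
runs <- run_single_models(stack, occ, pa,
  algorithms = c("GLM", "CTA", "RF", "GBM"), n_rep = 2, seed = 5)
ens <- select_and_ensemble(runs, stack, tss_min = 0.8, roc_min = 0.9)
ens
#> <ensemble_result> committee of 16 runs (GLM, CTA, RF, GBM), rule = mean
glance(ens)
#> # A tibble: 1 × 5
#>   n_members n_algorithms mean_tss mean_roc_auc rule
#>       <int>        <int>    <dbl>        <dbl> <chr>
#> 1        16            4    0.875        0.950 mean

data <- extract_values(stack, dplyr::bind_rows(occ,
  dplyr::mutate(pa[pa$pa_set == 1, c("lon", "lat")], species = "bg")))
variable_importance(ens, data, n_perm = 5, seed = 6)
#> # A tibble: 3 × 3
#>   variable raw_importance importance_pct
#>   <chr>             <dbl>          <dbl>
#> 1 precip          1.03            99.4
#> 2 t_range         0.00358          0.345
#> 3 hfi             0.00250          0.240

classify_and_area(ens$suitability)$areas
#> # A tibble: 5 × 2
#>   class         km2
#>   <fct>       <dbl>
#> 1 none      348111.
#> 2 low         9733.
#> 3 medium      4873.
#> 4 high       11684.
#> 5 ultrahigh  22910.
```

The permutation importance correctly identifies the planted driver (`precip`)
of the virtual species.

## Worked example: diagnostic sites and mini-barcodes

```r
aln <- simulate_alignment(n_a = 8, n_b = 12, length = 2000,
  n_diagnostic_snps = 5, n_diagnostic_indels = 1,
  within_group_poly_rate = 0.01, seed = 11)

sites <- find_diagnostic_sites(aln)
sites
#> # A tibble: 6 × 4
#>   column kind  state_a state_b
#>    <int> <chr> <chr>   <chr>
#> 1     15 SNP   G       T
#> 2    109 SNP   A       T
#> 3    764 SNP   T       A
#> 4   1431 SNP   C       T
#> 5   1509 indel C       -
#> 6   1599 SNP   T       C

cands <- design_candidates(aln, sites, target_len = 200, flank_len = 20)
classify_sample(paste(aln$mat[1, ], collapse = ""), cands, aln, sites)$call
#> [1] "A"
```

All six planted diagnostics are recovered (the generator attaches the planted
truth as `attr(aln, "truth")`), and a held-out sequence classifies to its true
group.

## The full pipeline

```r
cfg <- default_config(seed = 1, out_dir = "out")
state <- run_pipeline(cfg)   # simulate → prep → sdm → niche → dynamics → barcode
```

Artifacts (CSV/TSV tables, ASCII grids, FASTA, JSON reports) land in
`out/` together with `manifest.json` (md5 per artifact; identical config +
seed ⇒ identical hashes) and `pipeline.log`. A command-line wrapper is
installed at `inst/scripts/run_pipeline.R`.

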