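make_sdm_fixture <- function(seed = 41, n_presence = 120) {
  st <- test_stack(seed = seed)
  sim <- easy_species(st, "precip", 1000, 250, n_presence = n_presence,
    seed = seed + 1)
  occ <- spatial_thin(load_and_clean(sim$occurrences), 10, seed = seed + 2)
  pa <- sample_pseudo_absences(st, occ, n = 200, n_sets = 2, seed = seed + 3)
  list(stack = st, sim = sim, occ = occ, pa = pa)
}

test_that("pseudo-absences avoid presence cells and respect counts", {
  fx <- make_sdm_fixture()
  expect_equal(nrow(fx$pa), 2 * 200)
  expect_setequal(unique(fx$pa$pa_set), 1:2)
  # no pseudo-absence falls in a presence cell (both live on cell centres)
  pres <- paste(round(fx$occ$lon, 6), round(fx$occ$lat, 6))
  bg <- paste(round(fx$pa$lon, 6), round(fx$pa$lat, 6))
  expect_length(intersect(pres, bg), 0)
  # deterministic in the seed
  pa2 <- sample_pseudo_absences(fx$stack, fx$occ, n = 200, n_sets = 2,
    seed = 41 + 3)
  expect_equal(fx$pa, pa2)
})

test_that("run_single_models produces one evaluated run per cell of the design", {
  fx <- make_sdm_fixture()
  runs <- suppressWarnings(run_single_models(
    fx$stack, fx$occ, fx$pa,
    algorithms = c("GLM", "CTA", "RF"), n_rep = 2, seed = 11
  ))
  expect_equal(nrow(runs), 3 * 2 * 2) # algorithms x pa sets x replicates
  expect_true(all(runs$roc_auc >= 0 & runs$roc_auc <= 1))
  expect_true(all(runs$tss >= -1 & runs$tss <= 1))
  expect_true(all(c("GLM", "CTA", "RF") %in% runs$algorithm))
})

test_that("every algorithm predicts probabilities in [0, 1]", {
  fx <- make_sdm_fixture(seed = 43)
  runs <- suppressWarnings(run_single_models(
    fx$stack, fx$occ, fx$pa,
    algorithms = sdm_algorithms(), n_rep = 1, seed = 12
  ))
  newdata <- as_tibble(fx$stack, drop_na = TRUE)
  for (i in seq_len(nrow(runs))) {
    p <- predict(runs$fit[[i]], newdata)
    expect_true(all(p >= 0 & p <= 1),
      info = paste("algorithm", runs$algorithm[i]))
  }
})

test_that("committee selection applies strict thresholds and averages members", {
  fx <- make_sdm_fixture(seed = 44)
  runs <- suppressWarnings(run_single_models(
    fx$stack, fx$occ, fx$pa,
    algorithms = c("GLM", "RF", "GBM"), n_rep = 2, seed = 13
  ))
  ens <- select_and_ensemble(runs, fx$stack, tss_min = 0.8, roc_min = 0.9)
  comm <- tidy(ens)
  expect_gt(nrow(comm), 0)
  expect_true(all(comm$tss > 0.8 & comm$roc_auc > 0.9))
  s <- ens$suitability$layers$suitability
  expect_true(all(s[!is.na(s)] >= 0 & s[!is.na(s)] <= 1))
  # impossible thresholds give an informative error, not an empty object
  # tss is capped at 1, so a strict threshold of 1 is unsatisfiable
  expect_error(
    select_and_ensemble(runs, fx$stack, tss_min = 1, roc_min = 1),
    "empty committee"
  )
})

test_that("variable importance is a normalized percentage ranking", {
  fx <- make_sdm_fixture(seed = 45)
  runs <- suppressWarnings(run_single_models(
    fx$stack, fx$occ, fx$pa,
    algorithms = c("GLM", "RF"), n_rep = 2, seed = 14
  ))
  ens <- select_and_ensemble(runs, fx$stack, tss_min = 0.8, roc_min = 0.9)
  data <- extract_values(fx$stack, dplyr::bind_rows(
    fx$occ,
    dplyr::mutate(fx$pa[fx$pa$pa_set == 1, c("lon", "lat")], species = "bg")
  ))
  imp <- variable_importance(ens, data, n_perm = 5, seed = 15)
  expect_equal(sum(imp$importance_pct), 100)
  expect_true(all(imp$raw_importance >= 0))
  # the driving variable dominates for this easy species
  expect_equal(imp$variable[1], "precip")
})
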