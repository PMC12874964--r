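test_that("generate_env_stack honours dimensions, moments and bounds", {
  specs <- dplyr::bind_rows(
    layer_spec("a", mean = 10, sd = 2, range = 3),
    layer_spec("b", mean = 500, sd = 100, range = 3),
    layer_spec("hfi", mean = 25, sd = 10, range = 2)
  )
  st <- generate_env_stack(specs, dims = c(40, 50), origin = c(100, 30),
    cell_size = 0.05, seed = 3)
  expect_identical(dim(st), c(40L, 50L))
  expect_named(st$layers, c("a", "b", "hfi"))
  expect_equal(mean(st$layers$a), 10, tolerance = 1e-6)
  expect_equal(stats::sd(as.vector(st$layers$b)), 100, tolerance = 1e-6)
  expect_true(all(st$layers$hfi >= 0 & st$layers$hfi <= 50))
})

test_that("generate_env_stack imposes the requested inter-layer correlation", {
  specs <- dplyr::bind_rows(
    layer_spec("x", mean = 0, sd = 1, range = 4),
    layer_spec("y", mean = 0, sd = 1, range = 4)
  )
  corr <- matrix(c(1, 0.9, 0.9, 1), 2)
  st <- generate_env_stack(specs, dims = c(30, 30), target_corr = corr, seed = 11)
  r <- stats::cor(as.vector(st$layers$x), as.vector(st$layers$y))
  expect_lt(abs(r - 0.9), 0.05)
})

test_that("generate_env_stack is a pure function of its seed", {
  specs <- dplyr::bind_rows(layer_spec("a", 0, 1, 3), layer_spec("b", 5, 2, 3))
  s1 <- generate_env_stack(specs, dims = c(25, 25), seed = 7)
  s2 <- generate_env_stack(specs, dims = c(25, 25), seed = 7)
  s3 <- generate_env_stack(specs, dims = c(25, 25), seed = 8)
  expect_identical(s1$layers, s2$layers)
  expect_false(identical(s1$layers, s3$layers))
})

test_that("simulate_virtual_species samples where the species is suitable", {
  st <- test_stack(seed = 5)
  sim <- easy_species(st, "precip", 1000, 250, n_presence = 200, seed = 9)
  occ <- sim$occurrences
  expect_equal(nrow(occ), 200)
  expect_named(occ, c("species", "lon", "lat"))
  # every point lies inside the stack extent
  cells <- extract_values(st, occ)
  expect_equal(nrow(cells), 200)
  # presences concentrate in the favourable tail of the driving layer
  expect_gt(mean(cells$precip), 1000 + 250) # >= 1 sd above the landscape mean
  # truth surface is a proper probability field
  truth <- sim$species$truth$layers[[1]]
  expect_true(all(truth >= 0 & truth <= 1))
})

test_that("simulate_alignment plants recoverable diagnostics and honest truth", {
  aln <- simulate_alignment(
    n_a = 6, n_b = 8, length = 1200,
    n_diagnostic_snps = 4, n_diagnostic_indels = 2,
    within_group_poly_rate = 0.005, seed = 31
  )
  expect_identical(dim(aln), c(14L, 1200L))
  truth <- attr(aln, "truth")
  expect_equal(nrow(truth), 6)
  expect_setequal(unique(truth$kind), c("SNP", "indel"))
  rows_a <- aln$groups == "A"
  for (i in seq_len(nrow(truth))) {
    col <- truth$column[i]
    # group A is fixed for state_a, group B for state_b at each planted column
    expect_true(all(aln$mat[rows_a, col] %in% c(truth$state_a[i], "N")))
    expect_true(all(aln$mat[!rows_a, col] %in% c(truth$state_b[i], "N")))
    expect_false(truth$state_a[i] == truth$state_b[i])
  }
})

test_that("perturb_scenario applies the per-layer affine change", {
  st <- test_stack(seed = 2, with_hfi = FALSE)
  delta <- scenario_delta(shift = c(t_range = 2), scale = c(precip = 0.9))
  fut <- perturb_scenario(st, delta)
  expect_equal(fut$layers$t_range, st$layers$t_range + 2)
  expect_equal(fut$layers$precip, st$layers$precip * 0.9)
})
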