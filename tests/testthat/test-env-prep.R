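test_that("extract_values reads the layer value of the containing cell", {
  st <- test_stack(seed = 21, with_hfi = FALSE)
  # pick three known cells and build points at their centres
  cc <- cell_centers(st)
  pts <- cc[c(1, 50, 400), ]
  occ <- tibble::tibble(species = "x", lon = pts$lon, lat = pts$lat)
  vals <- extract_values(st, occ)
  expect_equal(
    vals$precip,
    st$layers$precip[cbind(pts$row, pts$col)]
  )
  # a point outside the extent errors
  bad <- tibble::tibble(species = "x", lon = 500, lat = 0)
  expect_error(extract_values(st, bad), "extent")
})

test_that("collinearity_filter leaves no retained pair above the threshold", {
  set.seed(22)
  n <- 300
  base <- rnorm(n)
  tb <- tibble::tibble(
    v1 = base,
    v2 = base + rnorm(n, sd = 0.1), # |r| ~ 0.99 with v1
    v3 = rnorm(n),
    v4 = -base + rnorm(n, sd = 0.2) # strongly negative with v1
  )
  res <- collinearity_filter(tb, threshold = 0.7)
  cm <- stats::cor(tb[res$retained])
  off <- abs(cm[upper.tri(cm)])
  expect_true(all(off <= 0.7))
  expect_setequal(c(res$retained, res$dropped$variable), names(tb))
})

test_that("collinearity_filter protects priority variables", {
  set.seed(23)
  base <- rnorm(200)
  tb <- tibble::tibble(a = base, b = base + rnorm(200, sd = 0.05))
  res <- collinearity_filter(tb, threshold = 0.7, priority = "b")
  expect_true("b" %in% res$retained)
  expect_false("a" %in% res$retained)
})

test_that("whittaker_biome classifies reference points", {
  expect_equal(whittaker_biome(-12, 15), "tundra")
  # far outside any polygon
  expect_equal(whittaker_biome(40, 1000), "unclassified")
})

test_that("compare_env_groups reproduces wilcox.test p-values", {
  set.seed(24)
  ta <- tibble::tibble(v1 = rnorm(40), v2 = rnorm(40))
  tb <- tibble::tibble(v1 = rnorm(40, 1), v2 = rnorm(40))
  res <- compare_env_groups(ta, tb, vars = c("v1", "v2"))
  for (v in c("v1", "v2")) {
    ref <- stats::wilcox.test(ta[[v]], tb[[v]], exact = FALSE)
    expect_equal(res$p_value[res$variable == v], ref$p.value, tolerance = 1e-12)
  }
})
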