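make_env_tables <- function(seed = 61, n_bg = 1500, shift2 = 0) {
  set.seed(seed)
  bg <- tibble::tibble(v1 = rnorm(n_bg), v2 = rnorm(n_bg), v3 = rnorm(n_bg))
  g1 <- tibble::tibble(v1 = rnorm(40, 1), v2 = rnorm(40, -0.5), v3 = rnorm(40))
  g2 <- tibble::tibble(
    v1 = rnorm(40, 1 + shift2), v2 = rnorm(40, -0.5 + shift2), v3 = rnorm(40)
  )
  list(bg = bg, g1 = g1, g2 = g2)
}

test_that("pca_env matches a direct prcomp on the correlation matrix", {
  tb <- make_env_tables()$bg
  space <- pca_env(tb)
  ref <- stats::prcomp(tb, center = TRUE, scale. = TRUE)
  # explained variance fractions agree (sign conventions may differ)
  expect_equal(
    space$explained,
    ref$sdev^2 / sum(ref$sdev^2),
    tolerance = 1e-12
  )
  sc <- project_env(space, tb)
  expect_equal(abs(stats::cor(sc$PC1, ref$x[, 1])), 1, tolerance = 1e-12)
})

test_that("occupancy surfaces are normalized probability fields", {
  e <- make_env_tables(seed = 62)
  space <- pca_env(e$bg)
  g <- build_niche_grid(space, e$g1, e$bg, R = 60)
  expect_equal(sum(g$z), 1, tolerance = 1e-12)
  expect_true(all(g$z >= 0))
  expect_identical(dim(g$z), c(60L, 60L))
})

test_that("schoener_d is symmetric and detects self-identity", {
  e <- make_env_tables(seed = 63)
  space <- pca_env(e$bg)
  g1 <- build_niche_grid(space, e$g1, e$bg, R = 50)
  g2 <- build_niche_grid(space, e$g2, e$bg, R = 50)
  expect_equal(schoener_d(g1, g1), 1, tolerance = 1e-12)
  expect_equal(schoener_d(g1, g2), schoener_d(g2, g1), tolerance = 1e-12)
  expect_equal(schoener_d(g1, g2), oracle_schoener_d(g1$z, g2$z),
    tolerance = 1e-12)
  # mismatched lattices are rejected
  g3 <- build_niche_grid(space, e$g1, e$bg, R = 40)
  expect_error(schoener_d(g1, g3), "lattice")
})

test_that("equivalency test returns valid, seed-deterministic p-values", {
  e <- make_env_tables(seed = 64, shift2 = 2)
  a <- equivalency_test(e$g1, e$g2, e$bg, n_iter = 99, R = 50, seed = 5)
  b <- equivalency_test(e$g1, e$g2, e$bg, n_iter = 99, R = 50, seed = 5)
  expect_equal(a$D, b$D)
  expect_equal(a$null_D, b$null_D)
  expect_true(a$p_greater > 0 && a$p_greater <= 1)
  expect_true(a$p_lower > 0 && a$p_lower <= 1)
  # strongly shifted groups: observed D below essentially all null values
  expect_lt(a$D, stats::quantile(a$null_D, 0.05))
  expect_lte(a$p_greater, 0.05)
  g <- glance(a)
  expect_named(g, c("D", "p_greater", "p_lower", "n_iter", "significant_overlap"))
  expect_equal(nrow(tidy(a)), 99)
})

test_that("impact_overlap is 1 on identical maps and drops under perturbation", {
  st <- test_stack(seed = 65, with_hfi = FALSE)
  p <- st$layers$precip
  suit <- env_stack(
    list(suitability = stats::plogis((p - mean(p)) / stats::sd(p))),
    origin = st$origin, cell_size = st$cell_size
  )
  same <- impact_overlap(suit, suit)
  expect_equal(same$D, 1, tolerance = 1e-12)
  expect_equal(same$impact, 0, tolerance = 1e-12)
  expect_true(same$significant_overlap)
  # a strong local perturbation lowers D below 1
  m <- suit$layers$suitability
  m[1:10, 1:10] <- 0
  other <- env_stack(list(suitability = m), origin = st$origin,
    cell_size = st$cell_size)
  less <- impact_overlap(suit, other)
  expect_lt(less$D, 1)
  expect_gt(less$impact, 0)
})
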