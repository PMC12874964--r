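test_that("load_and_clean drops malformed, duplicate and out-of-range rows", {
  raw <- tibble::tibble(
    species = c("x", "x", "x", "x", "x", "x"),
    lon = c(100.5, 100.5, NA, 250, 101.2, 101.2),
    lat = c(30.1, 30.1, 30.2, 30.3, -95, 29.9)
  )
  clean <- load_and_clean(raw)
  # duplicate collapsed, NA dropped, lon 250 and lat -95 out of range
  expect_equal(nrow(clean), 2)
  expect_setequal(clean$lon, c(100.5, 101.2))
  log <- cleaning_log(clean)
  expect_true(is.data.frame(log) || is.list(log))
})

test_that("load_and_clean clips to an extent when given one", {
  raw <- tibble::tibble(
    species = "x", lon = c(100.1, 105.0), lat = c(30.1, 30.1)
  )
  clean <- load_and_clean(raw, extent = c(100, 101, 29, 31))
  expect_equal(nrow(clean), 1)
  expect_equal(clean$lon, 100.1)
})

test_that("spatial thinning keeps exactly one record per occupied cell", {
  set.seed(14)
  occ <- tibble::tibble(
    species = "x",
    lon = 100 + runif(400, 0, 0.5),
    lat = 30 + runif(400, 0, 0.5)
  )
  thin <- spatial_thin(occ, resolution_km = 10, seed = 2)
  log <- thinning_log(thin)
  expect_equal(nrow(thin), log$n_cells_occupied)
  expect_lt(nrow(thin), nrow(occ))
  # survivors are a subset of the input records
  expect_true(all(paste(thin$lon, thin$lat) %in% paste(occ$lon, occ$lat)))
})

test_that("spatial thinning is idempotent", {
  set.seed(15)
  occ <- tibble::tibble(
    species = "x",
    lon = 100 + runif(300, 0, 0.4),
    lat = 30 + runif(300, 0, 0.4)
  )
  once <- spatial_thin(occ, resolution_km = 10, seed = 3)
  twice <- spatial_thin(once, resolution_km = 10, seed = 99)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(
    dplyr::arrange(tibble::as_tibble(once), lon, lat),
    dplyr::arrange(tibble::as_tibble(twice), lon, lat),
    ignore_attr = TRUE
  )
})

test_that("spatial thinning is deterministic in its seed", {
  set.seed(16)
  occ <- tibble::tibble(
    species = "x", lon = 100 + runif(200, 0, 0.3), lat = 30 + runif(200, 0, 0.3)
  )
  a <- spatial_thin(occ, resolution_km = 10, seed = 5)
  b <- spatial_thin(occ, resolution_km = 10, seed = 5)
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
})
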