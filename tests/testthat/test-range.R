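suit_fixture <- function(seed = 71, dims = c(25, 25)) {
  set.seed(seed)
  m <- matrix(runif(prod(dims)), dims[1], dims[2])
  env_stack(list(suitability = m), origin = c(100, 30), cell_size = 0.1)
}

test_that("cell areas follow the spherical cosine rule", {
  st <- suit_fixture()
  area <- cell_area_km2(st)
  lat_row3 <- 30 - (3 - 0.5) * 0.1
  expect_equal(
    area[3, 1],
    (0.1 * 111.32)^2 * cos(lat_row3 * pi / 180),
    tolerance = 1e-12
  )
  # equal along a row, decreasing toward the pole-side rows? here origin is the
  # top (north) edge, so area must increase from row 1 (higher lat) downward
  expect_true(all(diff(area[, 1]) > 0))
  expect_true(all(area[5, ] == area[5, 1]))
})

test_that("five-grade classification partitions the landscape exactly", {
  st <- suit_fixture(seed = 72)
  cl <- classify_and_area(st)
  expect_equal(
    as.character(cl$areas$class),
    c("none", "low", "medium", "high", "ultrahigh")
  )
  # areas across grades sum to total landscape area
  expect_equal(sum(cl$areas$km2), sum(cell_area_km2(st)), tolerance = 1e-9)
  # boundary conventions: right-open edges, top closed
  tiny <- env_stack(
    list(suitability = matrix(c(0, 0.2, 0.4, 0.6, 0.8, 1), 2, 3)),
    origin = c(0, 0), cell_size = 0.1
  )
  cl2 <- classify_and_area(tiny)
  codes <- cl2$graded$layers$grade
  expect_equal(as.vector(codes), c(0, 1, 2, 3, 4, 4))
})

test_that("binarize_and_change partitions both periods consistently", {
  t1 <- suit_fixture(seed = 73)
  t2 <- suit_fixture(seed = 74)
  ch <- binarize_and_change(t1, t2, threshold = 0.6, strict = TRUE)
  km2 <- stats::setNames(ch$areas$km2, as.character(ch$areas$state))
  area <- cell_area_km2(t1)
  t1_area <- sum(area[t1$layers$suitability > 0.6])
  t2_area <- sum(area[t2$layers$suitability > 0.6])
  expect_equal(km2[["contraction"]] + km2[["retention"]], t1_area, tolerance = 1e-9)
  expect_equal(km2[["retention"]] + km2[["expansion"]], t2_area, tolerance = 1e-9)
  expect_equal(ch$retention_rate, km2[["retention"]] / t1_area, tolerance = 1e-12)
  g <- glance(ch)
  expect_equal(g$t1_km2, t1_area, tolerance = 1e-9)
  # strict vs non-strict differ exactly at cells equal to the threshold
  m <- matrix(c(0.6, 0.7, 0.5, 0.6), 2, 2)
  st_eq <- env_stack(list(suitability = m), origin = c(0, 0), cell_size = 0.1)
  strict <- binarize_and_change(st_eq, st_eq, threshold = 0.6, strict = TRUE)
  loose <- binarize_and_change(st_eq, st_eq, threshold = 0.6, strict = FALSE)
  expect_equal(sum(strict$state$layers$state == 2), 1)
  expect_equal(sum(loose$state$layers$state == 2), 3)
})

test_that("centroid shift is zero between identical ranges and positive otherwise", {
  t1 <- suit_fixture(seed = 75)
  b1 <- env_stack(
    list(suitable = (t1$layers$suitability > 0.6) + 0),
    origin = t1$origin, cell_size = t1$cell_size
  )
  same <- centroid_shift(list(a = b1, b = b1))
  expect_equal(same$shifts$distance_km, 0, tolerance = 1e-9)
  # shift the suitable mask one column east: centroid moves ~ one cell east
  m2 <- cbind(b1$layers$suitable[, 25], b1$layers$suitable[, 1:24])
  b2 <- env_stack(list(suitable = m2), origin = t1$origin, cell_size = t1$cell_size)
  moved <- centroid_shift(list(a = b1, b = b2))
  expect_gt(moved$shifts$distance_km, 0)
})

test_that("long-term intersection is contained in every input", {
  t1 <- suit_fixture(seed = 76)
  maps <- lapply(1:3, function(i) {
    set.seed(76 + i)
    env_stack(
      list(suitable = matrix(rbinom(625, 1, 0.5), 25, 25)),
      origin = c(100, 30), cell_size = 0.1
    )
  })
  names(maps) <- c("p1", "p2", "p3")
  lt <- longterm_intersection(maps)
  joint <- lt$intersection$layers[[1]]
  for (m in maps) {
    expect_true(all(joint <= m$layers$suitable))
  }
  expect_equal(lt$km2, sum(cell_area_km2(t1)[joint == 1]), tolerance = 1e-9)
})
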