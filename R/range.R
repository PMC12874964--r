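suit_matrix <- function(x) {
  if (inherits(x, "env_stack")) x$layers[[1]] else as.matrix(x)
}

suit_geometry <- function(x) {
  stopifnot(inherits(x, "env_stack"))
  list(origin = x$origin, cell_size = x$cell_size)
}

#' Grade a suitability map into five equal-interval classes and measure areas
#'
#' Classifies suitability in `[0, 1]` into `none` (0-0.2), `low` (0.2-0.4),
#' `medium` (0.4-0.6), `high` (0.6-0.8) and `ultrahigh` (0.8-1): intervals are
#' left-closed right-open, with the top class closed at 1. Per-class areas use
#' the spherical cell-area approximation of [cell_area_km2()].
#'
#' @param suitability a one-layer [env_stack()] with values in `[0, 1]`.
#' @param breaks interior class breaks, strictly increasing within (0, 1).
#' @return a list: `graded` (one-layer `env_stack` of class codes 0-4),
#'   `classes` (code-to-label legend) and `areas` (tibble `class`, `km2`).
#' @export
classify_and_area <- function(suitability, breaks = c(0.2, 0.4, 0.6, 0.8)) {
  m <- suit_matrix(suitability)
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop("suitability outside [0, 1]", call. = FALSE)
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0) || any(breaks >= 1)) {
    stop("breaks must be strictly increasing within (0, 1)", call. = FALSE)
  }
  labels <- c("none", "low", "medium", "high", "ultrahigh")[seq_len(length(breaks) + 1)]
  edges <- c(0, breaks, 1 + 1e-12) # right-open everywhere; top class closed at 1
  code <- matrix(
    as.integer(cut(as.vector(m), edges, right = FALSE, labels = FALSE)) - 1L,
    nrow(m), ncol(m)
  )
  area <- cell_area_km2(suitability)
  areas <- tibble::tibble(
    class = factor(labels, levels = labels),
    km2 = vapply(seq_along(labels) - 1L, function(k) {
      sum(area[!is.na(code) & code == k])
    }, numeric(1))
  )
  g <- suit_geometry(suitability)
  list(
    graded = env_stack(list(grade = code + 0),
      origin = g$origin, cell_size = g$cell_size,
      label = paste0("graded-", suitability$label)
    ),
    classes = stats::setNames(labels, seq_along(labels) - 1L),
    areas = areas
  )
}

binary_map <- function(suitability, threshold = 0.6, strict = TRUE) {
  m <- suit_matrix(suitability)
  if (strict) (m > threshold) + 0 else (m >= threshold) + 0
}

#' Binary range change between two periods
#'
#' Cells are "suitable" when their suitability exceeds `threshold`
#' (strictly by default; `strict = FALSE` uses `>=` — both conventions appear
#' in applied work, so the choice is explicit and recorded in the output).
#' Each cell is then `absent`, `contraction` (suitable only at t1),
#' `retention` (both) or `expansion` (only at t2); the retention rate is
#' area(retention) / area(t1 suitable).
#'
#' @param suit_t1,suit_t2 one-layer [env_stack()]s on the same grid (values in
#'   `[0, 1]`), or already-binary 0/1 stacks with `binary = TRUE`.
#' @param threshold suitability threshold (default 0.6).
#' @param strict strict inequality (default `TRUE`).
#' @param binary treat inputs as already-binarized 0/1 maps.
#' @return a `change_map`: per-cell state stack (codes 0-3), state legend,
#'   per-state areas (km2), retention rate and settings.
#' @export
binarize_and_change <- function(suit_t1, suit_t2, threshold = 0.6, strict = TRUE,
                                binary = FALSE) {
  stopifnot_same_grid(suit_t1, suit_t2)
  b1 <- if (binary) suit_matrix(suit_t1) else binary_map(suit_t1, threshold, strict)
  b2 <- if (binary) suit_matrix(suit_t2) else binary_map(suit_t2, threshold, strict)
  area <- cell_area_km2(suit_t1)
  shared <- !is.na(b1) & !is.na(b2)
  state <- matrix(NA_real_, nrow(b1), ncol(b1))
  state[shared] <- 0 # absent
  state[shared & b1 == 1 & b2 == 0] <- 1 # contraction
  state[shared & b1 == 1 & b2 == 1] <- 2 # retention
  state[shared & b1 == 0 & b2 == 1] <- 3 # expansion
  labels <- c("absent", "contraction", "retention", "expansion")
  # km2 must be computed before tibble() so `state` is the cell matrix,
  # not the factor column defined one argument earlier.
  km2 <- vapply(0:3, function(k) sum(area[shared & state == k]), numeric(1))
  areas <- tibble::tibble(
    state = factor(labels, levels = labels),
    km2 = km2
  )
  t1_area <- sum(areas$km2[areas$state %in% c("contraction", "retention")])
  if (t1_area <= 0) {
    stop("t1 suitable set is empty: retention rate undefined", call. = FALSE)
  }
  g <- suit_geometry(suit_t1)
  structure(
    list(
      state = env_stack(list(state = state),
        origin = g$origin,
        cell_size = g$cell_size, label = "range-change"
      ),
      states = stats::setNames(labels, 0:3),
      areas = areas,
      retention_rate = areas$km2[areas$state == "retention"] / t1_area,
      threshold = threshold, strict = strict
    ),
    class = "change_map"
  )
}

#' @export
print.change_map <- function(x, ...) {
  cat(sprintf(
    "<change_map> retention rate %.3f (threshold %s %.2f)\n",
    x$retention_rate, if (x$strict) ">" else ">=", x$threshold
  ))
  print(x$areas)
  invisible(x)
}

#' Per-state areas of a change map
#'
#' @param x a `change_map`.
#' @param ... unused.
#' @return the per-state area tibble.
#' @export
tidy.change_map <- function(x, ...) x$areas

#' One-row change-map summary
#'
#' @param x a `change_map`.
#' @param ... unused.
#' @return tibble with retention rate, t1/t2 suitable areas, threshold.
#' @export
glance.change_map <- function(x, ...) {
  km2 <- stats::setNames(x$areas$km2, as.character(x$areas$state))
  tibble::tibble(
    retention_rate = x$retention_rate,
    t1_km2 = km2[["contraction"]] + km2[["retention"]],
    t2_km2 = km2[["retention"]] + km2[["expansion"]],
    threshold = x$threshold, strict = x$strict
  )
}

#' @export
autoplot.change_map <- function(object, ...) {
  df <- as_tibble.env_stack(object$state)
  df$state <- factor(object$states[as.character(df$state)],
    levels = unname(object$states)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(
        absent = "grey95", contraction = "#d7301f",
        retention = "#2b8cbe", expansion = "#41ab5d"
      ),
      na.value = "white"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' Distribution centroids and migration vectors of binary maps
#'
#' The centroid of each labelled binary map is the cell-area-weighted mean of
#' its suitable cell centres; successive maps yield migration vectors with
#' haversine distance (km) and initial bearing from north (degrees).
#'
#' @param binary_maps named list of one-layer 0/1 [env_stack()]s (names label
#'   the periods/scenarios, in order).
#' @return a list: `centroids` (tibble `label, lon, lat`) and `shifts`
#'   (tibble `from, to, distance_km, bearing_deg`).
#' @export
centroid_shift <- function(binary_maps) {
  stopifnot(length(binary_maps) >= 1)
  labels <- names(binary_maps) %||% paste0("map", seq_along(binary_maps))
  centroids <- purrr::map2_dfr(binary_maps, labels, function(bm, lab) {
    m <- suit_matrix(bm)
    suitable <- !is.na(m) & m == 1
    if (!any(suitable)) stop("map '", lab, "' has no suitable cell", call. = FALSE)
    w <- cell_area_km2(bm)[suitable]
    cc <- cell_centers(bm)
    idx <- which(as.vector(suitable))
    tibble::tibble(
      label = lab,
      lon = sum(cc$lon[idx] * w) / sum(w),
      lat = sum(cc$lat[idx] * w) / sum(w)
    )
  })
  shifts <- if (nrow(centroids) > 1) {
    purrr::map_dfr(seq_len(nrow(centroids) - 1), function(i) {
      p1 <- c(centroids$lon[i], centroids$lat[i])
      p2 <- c(centroids$lon[i + 1], centroids$lat[i + 1])
      tibble::tibble(
        from = centroids$label[i],
        to = centroids$label[i + 1],
        distance_km = geosphere::distHaversine(p1, p2) / 1000,
        bearing_deg = (geosphere::bearing(p1, p2) + 360) %% 360
      )
    })
  } else {
    tibble::tibble(
      from = character(), to = character(),
      distance_km = numeric(), bearing_deg = numeric()
    )
  }
  list(centroids = centroids, shifts = shifts)
}

#' Long-term suitable area: all-period intersection of binary maps
#'
#' A cell is long-term suitable iff it is suitable in every input map (the
#' rule used to delineate century-scale cultivation regions across current
#' and future scenarios). When a second species' map list is supplied, the
#' per-species intersections and their conjunction (the joint long-term area
#' for both species) are all returned.
#'
#' @param binary_maps list of one-layer 0/1 [env_stack()]s on one grid.
#' @param species_maps optional second list for a second species.
#' @return a list: `intersection` (0/1 `env_stack`), `km2`; and when
#'   `species_maps` is given, `intersection_b`, `km2_b`, `joint`, `joint_km2`.
#' @export
longterm_intersection <- function(binary_maps, species_maps = NULL) {
  if (!length(binary_maps)) stop("empty map list", call. = FALSE)
  intersect_list <- function(maps) {
    for (m in maps[-1]) stopifnot_same_grid(maps[[1]], m)
    mats <- lapply(maps, suit_matrix)
    out <- Reduce(function(a, b) {
      r <- a * b
      r[is.na(a) | is.na(b)] <- NA
      r
    }, mats)
    out
  }
  g <- suit_geometry(binary_maps[[1]])
  area <- cell_area_km2(binary_maps[[1]])
  wrap <- function(m, label) {
    env_stack(list(suitable = m), origin = g$origin, cell_size = g$cell_size, label = label)
  }
  inter_a <- intersect_list(binary_maps)
  out <- list(
    intersection = wrap(inter_a, "longterm"),
    km2 = sum(area[!is.na(inter_a) & inter_a == 1])
  )
  if (!is.null(species_maps)) {
    stopifnot_same_grid(binary_maps[[1]], species_maps[[1]])
    inter_b <- intersect_list(species_maps)
    joint <- inter_a * inter_b
    joint[is.na(inter_a) | is.na(inter_b)] <- NA
    out$intersection_b <- wrap(inter_b, "longterm-b")
    out$km2_b <- sum(area[!is.na(inter_b) & inter_b == 1])
    out$joint <- wrap(joint, "longterm-joint")
    out$joint_km2 <- sum(area[!is.na(joint) & joint == 1])
  }
  out
}
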