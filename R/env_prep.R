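#' Extract layer values at occurrence points
#'
#' Looks up the value of every stack layer at the grid cell containing each
#' record. Records falling on nodata cells are dropped and counted in the
#' `"extraction_log"` attribute; records outside the stack extent are an error.
#'
#' @param stack an [env_stack()].
#' @param occ tibble with `lon`, `lat` (and usually `species`) columns.
#' @return a tibble: the input columns plus one column per layer.
#' @export
extract_values <- function(stack, occ) {
  rc <- point_to_cell(stack, occ$lon, occ$lat)
  if (anyNA(rc$row)) {
    stop(sum(is.na(rc$row)), " point(s) outside the stack extent", call. = FALSE)
  }
  out <- tibble::as_tibble(occ)
  for (nm in layer_names(stack)) {
    out[[nm]] <- stack$layers[[nm]][cbind(rc$row, rc$col)]
  }
  complete <- stats::complete.cases(out[layer_names(stack)])
  dropped <- sum(!complete)
  out <- out[complete, , drop = FALSE]
  attr(out, "extraction_log") <- list(n_input = nrow(occ), n_dropped_nodata = dropped)
  out
}

#' Screen collinear environmental variables
#'
#' Computes pairwise Pearson correlations over the table rows and greedily
#' removes variables until no retained pair exceeds the threshold, mirroring
#' the conventional pre-modelling screen that deletes correlation pairs with
#' `|r| > 0.7`. At each step the worst offending pair is found and the member
#' with the larger mean absolute correlation to all other remaining variables
#' is dropped; a `priority` ranking, when given, protects earlier-listed
#' variables (the lower-priority member of the pair is dropped instead).
#'
#' @param table data frame of extracted values; non-numeric columns and
#'   `lon`/`lat` are ignored.
#' @param threshold correlation magnitude above which a pair is collinear.
#' @param priority optional character vector ranking variables from most to
#'   least important.
#' @param vars optional explicit set of candidate variable columns.
#' @return a list with `retained` (character vector), `dropped` (tibble of
#'   variable, step), and `cor_matrix` (full correlation matrix of candidates).
#' @export
collinearity_filter <- function(table, threshold = 0.7, priority = NULL, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(table)[vapply(table, is.numeric, logical(1))]
    vars <- setdiff(vars, c("lon", "lat"))
  }
  if (length(vars) < 2L) stop("need at least 2 candidate variables", call. = FALSE)
  if (nrow(table) < 3L) stop("need at least 3 rows", call. = FALSE)
  cm <- stats::cor(as.matrix(table[vars]))
  keep <- vars
  dropped <- character(0)
  repeat {
    sub <- abs(cm[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) <= threshold) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    if (!is.null(priority) && any(pair %in% priority)) {
      rank <- match(pair, priority)
      rank[is.na(rank)] <- length(priority) + 1L
      victim <- pair[which.max(rank)]
    } else {
      mean_abs <- vapply(pair, function(v) {
        others <- setdiff(keep, v)
        mean(abs(cm[v, others]))
      }, numeric(1))
      victim <- pair[which.max(mean_abs)]
    }
    dropped <- c(dropped, victim)
    keep <- setdiff(keep, victim)
    if (length(keep) < 2L) break
  }
  list(
    retained = keep,
    dropped = tibble::tibble(variable = dropped, step = seq_along(dropped)),
    cor_matrix = cm
  )
}

#' Whittaker biome polygon set
#'
#' A simplified, versioned digitization of the classic Whittaker biome diagram
#' in (mean annual temperature, mean annual precipitation) space: nine simple
#' polygons tiling the climate envelope. Units are degrees Celsius and
#' centimetres per year. The polygon order is the documented tie-break order
#' for boundary points in [whittaker_biome()].
#'
#' @return a tibble with columns `biome`, `order`, `mat`, `map` (polygon
#'   vertices in drawing order).
#' @export
whittaker_polygons <- function() {
  poly <- function(biome, order, mat, map) {
    tibble::tibble(biome = biome, order = order, mat = mat, map = map)
  }
  dplyr::bind_rows(
    poly("tundra", 1, c(-16, -4, -4, -16), c(0, 0, 30, 30)),
    poly("boreal forest", 2, c(-4, 4, 4, -4), c(10, 15, 150, 130)),
    poly(
      "temperate grassland/desert", 3,
      c(-4, 22, 22, 4, -4), c(0, 0, 15, 15, 10)
    ),
    poly(
      "woodland/shrubland", 4,
      c(4, 22, 22, 4), c(15, 15, 60, 90)
    ),
    poly(
      "temperate seasonal forest", 5,
      c(4, 22, 22, 4), c(90, 60, 180, 200)
    ),
    poly(
      "temperate rain forest", 6,
      c(4, 22, 22, 4), c(200, 180, 350, 300)
    ),
    poly("subtropical desert", 7, c(22, 30, 30, 22), c(0, 0, 50, 50)),
    poly(
      "tropical seasonal forest/savanna", 8,
      c(22, 30, 30, 22), c(50, 50, 250, 230)
    ),
    poly(
      "tropical rain forest", 9,
      c(22, 30, 30, 22), c(230, 250, 450, 450)
    )
  )
}

#' Assign Whittaker biomes from annual climate normals
#'
#' Point-in-polygon assignment against [whittaker_polygons()] (or a
#' user-supplied polygon set with the same columns). Points on a shared
#' boundary take the first matching polygon in `order`; points outside every
#' polygon are `"unclassified"`.
#'
#' @param mat_C mean annual temperature, degrees Celsius (vectorized).
#' @param map_cm mean annual precipitation, centimetres per year (vectorized).
#' @param polygons polygon tibble, defaulting to [whittaker_polygons()].
#' @return character vector of biome labels.
#' @export
whittaker_biome <- function(mat_C, map_cm, polygons = whittaker_polygons()) {
  pts <- cbind(mat_C, map_cm)
  out <- rep("unclassified", nrow(pts))
  ordered <- polygons |>
    dplyr::distinct(.data$biome, .data$order) |>
    dplyr::arrange(.data$order)
  for (i in rev(seq_len(nrow(ordered)))) { # reverse so earlier polygons overwrite
    b <- ordered$biome[i]
    v <- polygons[polygons$biome == b, ]
    inside <- point_in_polygon(pts[, 1], pts[, 2], v$mat, v$map)
    out[inside] <- b
  }
  out
}

# Even-odd ray casting with on-boundary points counted inside.
point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary test: point on segment (i, j)
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    within <- pmin(xi, xj) - 1e-12 <= x & x <= pmax(xi, xj) + 1e-12 &
      pmin(yi, yj) - 1e-12 <= y & y <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Compare two species' environments variable by variable
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per shared numeric
#' variable, with significance stars as used in comparative environment
#' figures: `ns` (p >= 0.05), `*` (< 0.05), `**` (< 0.01), `***` (< 0.001),
#' `****` (< 0.0001).
#'
#' @param table_a,table_b extracted-value tables sharing variable columns.
#' @param vars variables to test; defaults to the shared numeric columns
#'   excluding `lon`/`lat`.
#' @return a tibble: `variable`, `statistic` (Mann-Whitney U for group A),
#'   `p_value`, `stars`.
#' @export
compare_env_groups <- function(table_a, table_b, vars = NULL) {
  if (is.null(vars)) {
    num <- function(t) names(t)[vapply(t, is.numeric, logical(1))]
    vars <- setdiff(intersect(num(table_a), num(table_b)), c("lon", "lat"))
  }
  if (!length(vars)) stop("no shared numeric variables", call. = FALSE)
  if (nrow(table_a) < 3L || nrow(table_b) < 3L) stop("each group needs n >= 3", call. = FALSE)
  purrr::map_dfr(vars, function(v) {
    wt <- suppressWarnings(stats::wilcox.test(table_a[[v]], table_b[[v]], exact = FALSE))
    p <- wt$p.value
    stars <- dplyr::case_when(
      p < 1e-4 ~ "****",
      p < 1e-3 ~ "***",
      p < 1e-2 ~ "**",
      p < 0.05 ~ "*",
      TRUE ~ "ns"
    )
    tibble::tibble(
      variable = v, statistic = unname(wt$statistic),
      p_value = p, stars = stars
    )
  })
}
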