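#' Load and clean occurrence records
#'
#' Reads a `species, lon, lat` CSV, drops rows with unparseable or
#' out-of-range coordinates, drops exact duplicate `(species, lon, lat)`
#' triples, and optionally clips to a bounding box. Drop counts are attached
#' as the `"cleaning_log"` attribute and available via [cleaning_log()].
#'
#' @param path CSV file with columns `species`, `lon`, `lat` (extra columns
#'   are carried through), or a data frame with those columns.
#' @param extent optional bounding box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return a tibble of clean records with attribute `cleaning_log`.
#' @export
load_and_clean <- function(path, extent = NULL) {
  raw <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  req <- c("species", "lon", "lat")
  if (!all(req %in% names(raw))) {
    stop(
      "missing required column(s): ",
      paste(setdiff(req, names(raw)), collapse = ", "),
      call. = FALSE
    )
  }
  n0 <- nrow(raw)
  raw$lon <- suppressWarnings(as.numeric(raw$lon))
  raw$lat <- suppressWarnings(as.numeric(raw$lat))
  parseable <- !is.na(raw$lon) & !is.na(raw$lat) & !is.na(raw$species)
  in_range <- parseable & raw$lon >= -180 & raw$lon <= 180 & raw$lat >= -90 & raw$lat <= 90
  kept <- raw[in_range, , drop = FALSE]
  n_bad <- n0 - nrow(kept)
  n_before_dup <- nrow(kept)
  kept <- dplyr::distinct(kept, .data$species, .data$lon, .data$lat, .keep_all = TRUE)
  n_dup <- n_before_dup - nrow(kept)
  n_extent <- 0L
  if (!is.null(extent)) {
    inside <- kept$lon >= extent[1] & kept$lon <= extent[2] &
      kept$lat >= extent[3] & kept$lat <= extent[4]
    n_extent <- sum(!inside)
    kept <- kept[inside, , drop = FALSE]
  }
  if (nrow(kept) == 0L) stop("no records survive cleaning", call. = FALSE)
  attr(kept, "cleaning_log") <- list(
    n_input = n0,
    n_dropped_bad_coords = n_bad,
    n_dropped_duplicates = n_dup,
    n_dropped_outside_extent = n_extent,
    n_retained = nrow(kept)
  )
  kept
}

#' @rdname load_and_clean
#' @param occ a tibble returned by [load_and_clean()] or [spatial_thin()].
#' @export
cleaning_log <- function(occ) attr(occ, "cleaning_log")

# Deterministic thinning lattice: anchored at (-180, -90); latitude rows of
# height resolution_km/111.32 degrees, and a longitude cell width computed at
# each row's centre latitude (1 deg lon = 111.32 * cos(lat) km). Because the
# lattice depends only on resolution_km, thinning is exactly idempotent.
thin_cell_ids <- function(lon, lat, resolution_km) {
  dlat <- resolution_km / 111.32
  row <- floor((lat + 90) / dlat)
  row_center_lat <- (row + 0.5) * dlat - 90
  dlon <- resolution_km / (111.32 * pmax(cos(row_center_lat * pi / 180), 1e-6))
  col <- floor((lon + 180) / dlon)
  paste(row, col, sep = ":")
}

#' Spatially rarefy occurrence records on a km lattice
#'
#' At most one record survives per cell of a `resolution_km` grid (the
#' rarefaction the source datasets undergo at 10 km before modelling); the
#' survivor is drawn uniformly at random within each cell under `seed`, and
#' input order is preserved among survivors. A report (cells occupied, records
#' removed, lattice convention) is attached as the `"thinning_log"` attribute.
#'
#' @param occ tibble with `lon`, `lat` columns (and usually `species`).
#' @param resolution_km thinning resolution in kilometres (default 10).
#' @param seed RNG seed for survivor choice.
#' @return a thinned tibble, a subset of the input rows.
#' @export
spatial_thin <- function(occ, resolution_km = 10, seed = 1) {
  stopifnot(resolution_km > 0)
  if (nrow(occ) == 0L) stop("empty occurrence set", call. = FALSE)
  cells <- thin_cell_ids(occ$lon, occ$lat, resolution_km)
  keep <- with_seed(seed, {
    idx <- seq_len(nrow(occ))
    survivors <- vapply(
      split(idx, cells),
      function(members) if (length(members) == 1L) members else sample(members, 1L),
      integer(1)
    )
    sort(survivors)
  })
  out <- occ[keep, , drop = FALSE]
  attr(out, "thinning_log") <- list(
    resolution_km = resolution_km,
    lattice = "global origin (-180,-90); 1 deg lat = 111.32 km; lon width at row-centre latitude",
    n_input = nrow(occ),
    n_cells_occupied = length(unique(cells)),
    n_removed = nrow(occ) - length(keep),
    seed = seed
  )
  out
}

#' @rdname spatial_thin
#' @export
thinning_log <- function(occ) attr(occ, "thinning_log")
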