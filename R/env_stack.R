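#' Aligned environmental layer stack
#'
#' An `env_stack` holds one or more gridded environmental layers (bioclim-style
#' variables, elevation, a Human Footprint Index, model suitability surfaces,
#' binary range maps ...) that share the same extent, resolution and missing-data
#' mask. Each layer is an `nrow x ncol` numeric matrix whose first row is the
#' northernmost row; cell `(i, j)` has its centre at
#' `lon = origin[1] + (j - 0.5) * cell_size`, `lat = origin[2] - (i - 0.5) * cell_size`.
#' Missing cells are `NA`.
#'
#' @param layers named list of numeric matrices, all the same dimension.
#' @param origin numeric length-2, (lon, lat) of the grid's upper-left corner.
#' @param cell_size cell edge length in degrees.
#' @param label optional free-text label (e.g. a scenario name).
#'
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers, origin = c(0, 0), cell_size = 1, label = "current") {
  if (!is.list(layers) || length(layers) == 0L) {
    stop("`layers` must be a non-empty named list of matrices", call. = FALSE)
  }
  if (is.null(names(layers)) || anyDuplicated(names(layers)) || any(names(layers) == "")) {
    stop("every layer must have a unique non-empty name", call. = FALSE)
  }
  layers <- lapply(layers, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all layers must share dimensions", call. = FALSE)
  }
  for (m in layers) {
    if (all(is.na(m))) stop("a layer is entirely nodata", call. = FALSE)
  }
  if ("hfi" %in% names(layers)) {
    h <- layers[["hfi"]]
    if (any(h < 0 | h > 50, na.rm = TRUE)) {
      stop("HFI layer must lie in [0, 50]", call. = FALSE)
    }
  }
  structure(
    list(
      layers = layers,
      origin = as.numeric(origin),
      cell_size = as.numeric(cell_size),
      label = label
    ),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf(
    "<env_stack '%s'> %d layer(s) on a %d x %d grid, %.4g deg cells, origin (%.4g, %.4g)\n",
    x$label, length(x$layers), d[1], d[2], x$cell_size, x$origin[1], x$origin[2]
  ))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.env_stack <- function(x) dim(x$layers[[1]])

layer_names <- function(stack) names(stack$layers)

#' Cell-centre coordinates of an env_stack
#'
#' @param stack an [env_stack()].
#' @return a tibble with `cell` (column-major index), `row`, `col`, `lon`, `lat`.
#' @export
cell_centers <- function(stack) {
  d <- dim(stack)
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  tibble::tibble(
    cell = seq_len(d[1] * d[2]),
    row = grid$row,
    col = grid$col,
    lon = stack$origin[1] + (grid$col - 0.5) * stack$cell_size,
    lat = stack$origin[2] - (grid$row - 0.5) * stack$cell_size
  )
}

#' Tabular view of an env_stack
#'
#' One row per grid cell with cell-centre coordinates and one column per layer.
#'
#' @param x an [env_stack()].
#' @param ... unused.
#' @param drop_na drop cells that are nodata in any layer (default `FALSE`).
#' @return a tibble.
#' @export
as_tibble.env_stack <- function(x, ..., drop_na = FALSE) {
  out <- cell_centers(x)
  for (nm in names(x$layers)) out[[nm]] <- as.vector(x$layers[[nm]])
  if (drop_na) out <- tidyr::drop_na(out, dplyr::all_of(names(x$layers)))
  out
}

# row/col lookup for points; returns NA row/col for out-of-extent points
point_to_cell <- function(stack, lon, lat) {
  d <- dim(stack)
  col <- floor((lon - stack$origin[1]) / stack$cell_size) + 1L
  row <- floor((stack$origin[2] - lat) / stack$cell_size) + 1L
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

same_grid <- function(a, b) {
  identical(dim(a), dim(b)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("grids do not share extent/resolution", call. = FALSE)
  invisible(TRUE)
}

#' Area of each grid cell in square kilometres
#'
#' Spherical approximation: a cell of edge `c` degrees centred at latitude
#' `phi` covers `(c * 111.32)^2 * cos(phi)` square km. Returned as a matrix
#' matching the stack's grid.
#'
#' @param stack an [env_stack()].
#' @return numeric matrix of per-cell areas (km^2).
#' @export
cell_area_km2 <- function(stack) {
  d <- dim(stack)
  lat <- stack$origin[2] - (seq_len(d[1]) - 0.5) * stack$cell_size
  row_area <- (stack$cell_size * 111.32)^2 * cos(lat * pi / 180)
  matrix(rep(row_area, d[2]), nrow = d[1], ncol = d[2])
}

#' Apply a future-scenario perturbation to an environmental stack
#'
#' Emulates deriving a future-period climate surface (e.g. 2050s or 2090s under
#' SSP126/SSP585) from the current one by a per-layer affine change:
#' `out = scale * layer + shift`. Layers not named in the delta are copied.
#'
#' @param stack an [env_stack()].
#' @param delta a [scenario_delta()].
#' @return a new `env_stack` labelled with the scenario.
#' @export
perturb_scenario <- function(stack, delta) {
  stopifnot(inherits(stack, "env_stack"), inherits(delta, "scenario_delta"))
  missing <- setdiff(union(names(delta$shift), names(delta$scale)), layer_names(stack))
  if (length(missing)) {
    stop("scenario delta names absent layers: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  layers <- stack$layers
  for (nm in names(layers)) {
    sc <- if (nm %in% names(delta$scale)) delta$scale[[nm]] else 1
    sh <- if (nm %in% names(delta$shift)) delta$shift[[nm]] else 0
    layers[[nm]] <- sc * layers[[nm]] + sh
  }
  env_stack(layers, origin = stack$origin, cell_size = stack$cell_size, label = delta$label)
}

#' Future-scenario delta
#'
#' Additive shifts and multiplicative scales applied layer-wise by
#' [perturb_scenario()]. A zero-shift, unit-scale delta is the identity.
#'
#' @param shift named numeric vector or list of per-layer additive shifts.
#' @param scale named numeric vector or list of per-layer multiplicative scales.
#' @param label scenario label, e.g. `"2050s-SSP126"`.
#' @return an object of class `scenario_delta`.
#' @export
scenario_delta <- function(shift = numeric(), scale = numeric(), label = "scenario") {
  structure(list(shift = as.list(shift), scale = as.list(scale), label = label),
    class = "scenario_delta"
  )
}

#' Write a single layer as an ESRI ASCII grid
#'
#' @param stack an [env_stack()].
#' @param layer layer name to write.
#' @param path output file path.
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(stack, layer, path, nodata = -9999) {
  m <- stack$layers[[layer]]
  if (is.null(m)) stop("no layer named '", layer, "'", call. = FALSE)
  d <- dim(m)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", stack$origin[1]),
    sprintf("yllcorner %.10g", stack$origin[2] - d[1] * stack$cell_size),
    sprintf("cellsize %.10g", stack$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a one-layer env_stack
#'
#' @param path grid file path.
#' @param layer name to give the layer.
#' @return an [env_stack()] with one layer.
#' @export
read_ascii_grid <- function(path, layer = "value") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  m[m == vals[["nodata_value"]]] <- NA
  origin <- c(vals[["xllcorner"]], vals[["yllcorner"]] + vals[["nrows"]] * vals[["cellsize"]])
  env_stack(stats::setNames(list(m), layer),
    origin = origin, cell_size = vals[["cellsize"]]
  )
}

#' Heat-map of the layers of an env_stack
#'
#' @param object an [env_stack()].
#' @param layers layers to draw (default all).
#' @param ... unused.
#' @return a ggplot object, facetted by layer.
#' @export
autoplot.env_stack <- function(object, layers = layer_names(object), ...) {
  df <- as_tibble.env_stack(object) |>
    dplyr::select(dplyr::all_of(c("lon", "lat", layers))) |>
    tidyr::pivot_longer(dplyr::all_of(layers), names_to = "layer", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude", title = object$label)
}
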