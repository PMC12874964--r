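#' PCA of the background environment (PCA-env)
#'
#' Correlation-matrix PCA (variables centred and scaled) of a background
#' environment table. The first two components define the environmental space
#' in which niche occupancy surfaces are compared. Component signs are fixed
#' by making the largest-magnitude loading of each retained component
#' positive, so projections are reproducible across runs.
#'
#' @param background data frame of background environmental values;
#'   non-numeric columns and `lon`/`lat` are ignored.
#' @param vars optional explicit variable set.
#' @return a `pca_env_space`: centring/scaling vectors, loadings, explained
#'   variance fractions.
#' @export
pca_env <- function(background, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(background)[vapply(background, is.numeric, logical(1))]
    vars <- setdiff(vars, c("lon", "lat"))
  }
  if (length(vars) < 2L) stop("need at least 2 variables", call. = FALSE)
  if (nrow(background) < 10L) stop("need at least 10 background rows", call. = FALSE)
  x <- as.matrix(background[vars])
  sds <- apply(x, 2, stats::sd)
  if (any(sds < .Machine$double.eps)) {
    stop(
      "constant variable(s): ", paste(vars[sds < .Machine$double.eps], collapse = ", "),
      "; pre-filter before PCA", call. = FALSE
    )
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  explained <- p$sdev^2 / sum(p$sdev^2)
  rot <- p$rotation
  for (j in seq_len(min(2L, ncol(rot)))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  structure(
    list(
      vars = vars, center = p$center, scale = p$scale,
      loadings = rot, explained = explained
    ),
    class = "pca_env_space"
  )
}

#' @export
print.pca_env_space <- function(x, ...) {
  cat(sprintf(
    "<pca_env_space> %d variables; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    length(x$vars), 100 * x$explained[1], 100 * x$explained[2]
  ))
  invisible(x)
}

#' Project environmental rows into PCA-env space
#'
#' @param space a `pca_env_space` from [pca_env()].
#' @param table data frame containing the space's variables.
#' @return a tibble with columns `PC1`, `PC2`.
#' @export
project_env <- function(space, table) {
  x <- scale(as.matrix(table[space$vars]), center = space$center, scale = space$scale)
  s <- x %*% space$loadings[, 1:2, drop = FALSE]
  tibble::tibble(PC1 = s[, 1], PC2 = s[, 2])
}

kde_on_grid <- function(px, py, xgrid, ygrid) {
  bw <- function(v) {
    h <- MASS::bandwidth.nrd(v)
    if (!is.finite(h) || h <= 0) h <- max(stats::sd(v), 1e-3) # degenerate spread fallback
    h
  }
  k <- MASS::kde2d(px, py,
    h = c(bw(px), bw(py)),
    n = c(length(xgrid), length(ygrid)),
    lims = c(range(xgrid), range(ygrid))
  )
  # kde2d returns z[x, y]; transpose so rows index the y axis
  t(k$z)
}

#' Occupancy surface on the PCA-env grid
#'
#' Projects occurrence and background environments into (PC1, PC2), lays an
#' `R x R` lattice over the background range, estimates Gaussian kernel
#' densities of occurrences (`o`) and of the available environment (`e`) on
#' the lattice (Silverman-type bandwidths), and forms the occupancy surface
#' `z`. With `correction = "availability"` (default) `z = o / e` where `e`
#' exceeds a small availability floor and 0 elsewhere; with
#' `correction = "none"`, `z = o / max(o)`. `z` is normalized to sum 1.
#'
#' @param space a `pca_env_space`.
#' @param occ_env environmental table at the occurrences (>= 5 rows).
#' @param background background environmental table.
#' @param R lattice resolution per axis (default 100).
#' @param correction `"availability"` or `"none"`.
#' @param e_floor_frac availability floor as a fraction of `max(e)`.
#' @return a `niche_grid`: lattice axes, `o`, `e`, and normalized `z`.
#' @export
build_niche_grid <- function(space, occ_env, background, R = 100,
                             correction = c("availability", "none"),
                             e_floor_frac = 0.01) {
  correction <- match.arg(correction)
  if (nrow(occ_env) < 5L) stop("need at least 5 occurrence rows", call. = FALSE)
  occ_s <- project_env(space, occ_env)
  bg_s <- project_env(space, background)
  rx <- range(bg_s$PC1)
  ry <- range(bg_s$PC2)
  if (diff(rx) <= 0 || diff(ry) <= 0) stop("background collapsed to a point", call. = FALSE)
  if (R == 1L) {
    return(structure(
      list(
        x = mean(rx), y = mean(ry),
        o = matrix(1), e = matrix(1), z = matrix(1),
        R = 1L, correction = correction
      ),
      class = "niche_grid"
    ))
  }
  xgrid <- seq(rx[1], rx[2], length.out = R)
  ygrid <- seq(ry[1], ry[2], length.out = R)
  e <- kde_on_grid(bg_s$PC1, bg_s$PC2, xgrid, ygrid)
  occupancy_grid(occ_s, xgrid, ygrid, e, correction, e_floor_frac)
}

# Occupancy surface given a precomputed background density `e` on the lattice.
# Split out so permutation tests can reuse the (expensive) background KDE
# across iterations; only the occurrence KDE depends on the permutation.
occupancy_grid <- function(occ_s, xgrid, ygrid, e, correction, e_floor_frac) {
  o <- kde_on_grid(occ_s$PC1, occ_s$PC2, xgrid, ygrid)
  z <- if (correction == "availability") {
    floor_e <- e_floor_frac * max(e)
    ifelse(e > floor_e, o / e, 0)
  } else {
    o / max(o)
  }
  z <- z / sum(z)
  structure(
    list(
      x = xgrid, y = ygrid, o = o, e = e, z = z,
      R = length(xgrid), correction = correction
    ),
    class = "niche_grid"
  )
}

#' @export
print.niche_grid <- function(x, ...) {
  cat(sprintf(
    "<niche_grid> %d x %d lattice, correction = %s\n",
    x$R, x$R, x$correction
  ))
  invisible(x)
}

#' @export
autoplot.niche_grid <- function(object, ...) {
  df <- expand.grid(PC1 = object$x, PC2 = object$y)
  df$z <- as.vector(t(object$z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "occupancy")
}

#' Schoener's D between two normalized surfaces
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)`, ranging from 0 (no overlap) to 1
#' (identical surfaces). Inputs may be `niche_grid` objects or plain numeric
#' arrays on the same lattice; each must sum to 1.
#'
#' @param z1,z2 normalized occupancy surfaces.
#' @return Schoener's D in `[0, 1]`.
#' @export
schoener_d <- function(z1, z2) {
  if (inherits(z1, "niche_grid")) z1 <- z1$z
  if (inherits(z2, "niche_grid")) z2 <- z2$z
  if (!identical(dim(as.matrix(z1)), dim(as.matrix(z2))) ||
    length(z1) != length(z2)) {
    stop("surfaces are on different lattices", call. = FALSE)
  }
  1 - 0.5 * sum(abs(z1 - z2))
}

#' Niche equivalency permutation test
#'
#' Observed Schoener's D between two occurrence groups in PCA-env space is
#' compared against a null built by pooling the occurrences, randomly
#' re-partitioning them into the original group sizes, rebuilding both
#' occupancy surfaces, and recomputing D, `n_iter` times. Both tails are
#' always reported: `p_greater = (1 + #(null <= observed)) / (n_iter + 1)`
#' and `p_lower = (1 + #(null >= observed)) / (n_iter + 1)`.
#'
#' @param occ1_env,occ2_env environmental tables of the two occurrence groups
#'   (>= 5 rows each).
#' @param background background environmental table.
#' @param space optional `pca_env_space`; computed from `background` if absent.
#' @param n_iter permutation iterations (>= 1; the source analysis uses 1000).
#' @param R niche-grid lattice resolution.
#' @param correction occupancy correction, see [build_niche_grid()].
#' @param seed RNG seed.
#' @return an `overlap_result`: observed `D`, the null sample, both tail
#'   p-values and settings.
#' @export
equivalency_test <- function(occ1_env, occ2_env, background, space = NULL,
                             n_iter = 1000, R = 100,
                             correction = "availability", seed = 1) {
  if (n_iter < 1L) stop("n_iter must be at least 1", call. = FALSE)
  if (nrow(occ1_env) < 5L || nrow(occ2_env) < 5L) {
    stop("each group needs at least 5 rows", call. = FALSE)
  }
  space <- space %||% pca_env(background)
  # the background density is permutation-invariant: compute it once
  bg_s <- project_env(space, background)
  rx <- range(bg_s$PC1)
  ry <- range(bg_s$PC2)
  if (diff(rx) <= 0 || diff(ry) <= 0) {
    stop("background collapsed to a point", call. = FALSE)
  }
  if (R == 1L) stop("equivalency test needs a lattice with R >= 2", call. = FALSE)
  xgrid <- seq(rx[1], rx[2], length.out = R)
  ygrid <- seq(ry[1], ry[2], length.out = R)
  e <- kde_on_grid(bg_s$PC1, bg_s$PC2, xgrid, ygrid)
  d_of <- function(a, b) {
    g1 <- occupancy_grid(project_env(space, a), xgrid, ygrid, e, correction, 0.01)
    g2 <- occupancy_grid(project_env(space, b), xgrid, ygrid, e, correction, 0.01)
    schoener_d(g1, g2)
  }
  observed <- d_of(occ1_env, occ2_env)
  n1 <- nrow(occ1_env)
  pooled <- dplyr::bind_rows(
    tibble::as_tibble(occ1_env[space$vars]),
    tibble::as_tibble(occ2_env[space$vars])
  )
  null_d <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample(nrow(pooled), n1)
      d_of(pooled[idx, ], pooled[-idx, ])
    }, numeric(1))
  })
  structure(
    list(
      D = observed, null_D = null_d,
      p_greater = (1 + sum(null_d <= observed)) / (n_iter + 1),
      p_lower = (1 + sum(null_d >= observed)) / (n_iter + 1),
      n_iter = n_iter, R = R, correction = correction, seed = seed
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> D = %.3f; p_greater = %.4g, p_lower = %.4g (n_iter = %d)\n",
    x$D, x$p_greater, x$p_lower, x$n_iter
  ))
  invisible(x)
}

#' Null distribution of an equivalency test
#'
#' @param x an `overlap_result`.
#' @param ... unused.
#' @return tibble with `iteration` and `null_D`.
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$null_D), null_D = x$null_D)
}

#' One-row overlap summary
#'
#' @param x an `overlap_result`.
#' @param ... unused.
#' @return tibble: `D`, both tail p-values, `n_iter`, and the conventional
#'   significant-overlap flag (`D > 0.6`).
#' @export
glance.overlap_result <- function(x, ...) {
  tibble::tibble(
    D = x$D, p_greater = x$p_greater, p_lower = x$p_lower,
    n_iter = x$n_iter, significant_overlap = x$D > 0.6
  )
}

#' @export
autoplot.overlap_result <- function(object, ...) {
  ggplot2::ggplot(tidy.overlap_result(object), ggplot2::aes(x = .data$null_D)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$D, colour = "red", linewidth = 1) +
    ggplot2::labs(x = "null Schoener's D", y = "count")
}

#' Human-impact overlap between with- and without-HFI suitability maps
#'
#' Both suitability rasters are normalized to sum 1 over their shared
#' non-nodata cells and compared with Schoener's D; the deviation `1 - D` is
#' reported as the human-impact index. `D > 0.6` is flagged as significant
#' overlap, the conventional interpretive threshold.
#'
#' @param map_with_hfi,map_without_hfi one-layer [env_stack()]s (or numeric
#'   matrices) of suitability in `[0, 1]` on the same grid.
#' @return a tibble: `D`, `impact` (= 1 - D), `significant_overlap`.
#' @export
impact_overlap <- function(map_with_hfi, map_without_hfi) {
  as_mat <- function(m) if (inherits(m, "env_stack")) m$layers[[1]] else as.matrix(m)
  a <- as_mat(map_with_hfi)
  b <- as_mat(map_without_hfi)
  if (!identical(dim(a), dim(b))) stop("grids differ", call. = FALSE)
  if (any(a < 0 | a > 1, na.rm = TRUE) || any(b < 0 | b > 1, na.rm = TRUE)) {
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  }
  shared <- !is.na(a) & !is.na(b)
  sa <- sum(a[shared])
  sb <- sum(b[shared])
  if (sa <= 0 || sb <= 0) stop("all-zero raster", call. = FALSE)
  d <- 1 - 0.5 * sum(abs(a[shared] / sa - b[shared] / sb))
  tibble::tibble(D = d, impact = 1 - d, significant_overlap = d > 0.6)
}
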