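#' Per-layer specification for a virtual landscape
#'
#' @param name layer name (use `"hfi"` for a human-footprint layer; it is
#'   clipped into the index's 0--50 scale).
#' @param mean,sd target cell-value mean and standard deviation.
#' @param range spatial autocorrelation range: the standard deviation, in
#'   cells, of the Gaussian smoothing kernel applied to the white-noise field.
#'   `0` gives spatially independent cells.
#' @return a one-row tibble; rows from several calls can be bound together.
#' @export
layer_spec <- function(name, mean = 0, sd = 1, range = 3) {
  tibble::tibble(name = name, mean = mean, sd = sd, range = range)
}

# Separable Gaussian smoothing of a matrix; kernel sd in cells.
gauss_smooth <- function(m, range) {
  if (range <= 0) return(m)
  r <- max(1L, ceiling(3 * range))
  g <- stats::dnorm(-r:r, sd = range)
  band <- function(n) {
    k <- outer(seq_len(n), seq_len(n), function(i, j) {
      d <- abs(i - j)
      ifelse(d <= r, g[d + r + 1L], 0)
    })
    k / rowSums(k)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Generate a synthetic environmental layer stack
#'
#' Builds WorldClim-style layers as spatially autocorrelated Gaussian random
#' fields: white noise is smoothed with a Gaussian kernel of the stated range,
#' the smoothed fields are standardized, a target inter-layer correlation
#' structure is imposed through a matrix square root (the empirical field
#' correlations are whitened first, so the realized cell-wise correlations
#' match the target), and each field is finally rescaled to its target
#' mean and standard deviation. A layer with `sd = 0` is constant at its mean.
#'
#' @param layer_specs tibble from [layer_spec()] rows (columns `name`, `mean`,
#'   `sd`, `range`).
#' @param dims grid dimension `c(nrow, ncol)`, at least 20 x 20.
#' @param target_corr optional symmetric positive-semidefinite correlation
#'   matrix across the non-constant layers (in `layer_specs` order).
#' @param origin,cell_size grid geometry passed to [env_stack()].
#' @param seed RNG seed; identical seed and specs give a bit-identical stack.
#' @return an [env_stack()].
#' @export
generate_env_stack <- function(layer_specs, dims = c(50, 50), target_corr = NULL,
                               origin = c(100, 35), cell_size = 0.1, seed = 1) {
  stopifnot(all(c("name", "mean", "sd", "range") %in% names(layer_specs)))
  if (any(dims < 20)) stop("dims must be at least 20 x 20", call. = FALSE)
  k <- nrow(layer_specs)
  live <- which(layer_specs$sd > 0)
  if (!is.null(target_corr)) {
    target_corr <- as.matrix(target_corr)
    if (nrow(target_corr) != length(live) || !isSymmetric(unname(target_corr))) {
      stop("target_corr must be symmetric with one row per non-constant layer", call. = FALSE)
    }
    ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("target_corr is not positive semidefinite", call. = FALSE)
  }
  fields <- with_seed(seed, {
    lapply(seq_len(k), function(i) {
      f <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
      gauss_smooth(f, layer_specs$range[i])
    })
  })
  z <- vapply(fields, function(f) {
    v <- as.vector(f)
    s <- stats::sd(v)
    if (s < .Machine$double.eps) v * 0 else (v - mean(v)) / s
  }, numeric(prod(dims)))
  if (!is.null(target_corr) && length(live) > 1) {
    zl <- z[, live, drop = FALSE]
    emp <- stats::cor(zl)
    w <- zl %*% solve(chol(emp)) # whiten realized correlations
    es <- eigen(target_corr, symmetric = TRUE)
    sq <- es$vectors %*% diag(sqrt(pmax(es$values, 0))) %*% t(es$vectors)
    zl <- w %*% sq
    zl <- scale(zl) # unit variance again; correlations preserved
    z[, live] <- zl
  }
  layers <- stats::setNames(vector("list", k), layer_specs$name)
  for (i in seq_len(k)) {
    vals <- layer_specs$mean[i] + layer_specs$sd[i] * z[, i]
    if (layer_specs$name[i] == "hfi") vals <- pmin(pmax(vals, 0), 50)
    layers[[i]] <- matrix(vals, dims[1], dims[2])
  }
  env_stack(layers, origin = origin, cell_size = cell_size, label = "synthetic-current")
}

#' Simulate a virtual species and a presence sample on a landscape
#'
#' The virtual species' true suitability is a logistic function of the layers:
#' `truth = plogis(intercept + sum(coef_l * layer_l))`. Presences are drawn
#' cell-wise with probability proportional to `truth * bias` (uniform bias by
#' default) and recorded at cell centres; a cell may be drawn more than once
#' unless `replace = FALSE`, so that spatial thinning has duplicates to remove.
#'
#' @param stack an [env_stack()].
#' @param coefficients named numeric vector of weights, names being layer names.
#' @param intercept scalar intercept on the logit scale.
#' @param n_presence number of presence records to draw.
#' @param bias_layer optional layer name whose (non-negative) values multiply
#'   the sampling weights, emulating sampling bias.
#' @param species species label written into the occurrence table.
#' @param replace sample cells with replacement (default `TRUE`).
#' @param seed RNG seed.
#' @return a list with `species` (a `virtual_species`: coefficients, intercept,
#'   logistic link, and the true suitability as a one-layer [env_stack()]) and
#'   `occurrences` (a tibble `species, lon, lat`).
#' @export
simulate_virtual_species <- function(stack, coefficients, intercept = 0,
                                     n_presence = 100, bias_layer = NULL,
                                     species = "virtual", replace = TRUE, seed = 1) {
  stopifnot(inherits(stack, "env_stack"), n_presence >= 1)
  missing <- setdiff(names(coefficients), layer_names(stack))
  if (length(missing)) {
    stop("coefficients name absent layers: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  lin <- matrix(intercept, nrow(stack$layers[[1]]), ncol(stack$layers[[1]]))
  for (nm in names(coefficients)) lin <- lin + coefficients[[nm]] * stack$layers[[nm]]
  truth <- stats::plogis(lin)
  w <- as.vector(truth)
  if (!is.null(bias_layer)) {
    if (!bias_layer %in% layer_names(stack)) stop("bias_layer not in stack", call. = FALSE)
    w <- w * pmax(as.vector(stack$layers[[bias_layer]]), 0)
  }
  valid <- which(!is.na(w))
  if (!length(valid) || sum(w[valid]) <= 0) {
    stop("true suitability (times bias) is zero everywhere; cannot draw presences", call. = FALSE)
  }
  cells <- with_seed(seed, sample(valid, n_presence, replace = replace, prob = w[valid]))
  centers <- cell_centers(stack)
  occ <- tibble::tibble(
    species = species,
    lon = centers$lon[cells],
    lat = centers$lat[cells]
  )
  vs <- structure(
    list(
      coefficients = coefficients, intercept = intercept, link = "logistic",
      truth = env_stack(list(truth = truth),
        origin = stack$origin,
        cell_size = stack$cell_size, label = paste0("truth-", species)
      )
    ),
    class = "virtual_species"
  )
  list(species = vs, occurrences = occ)
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(
    "<virtual_species> logistic link, intercept", x$intercept, "\ncoefficients:",
    paste(sprintf("%s=%g", names(x$coefficients), x$coefficients), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Simulate a two-group alignment with planted diagnostic sites
#'
#' Builds an aligned panel in which exactly `n_diagnostic_snps` columns carry a
#' fixed base-vs-base contrast between the groups and `n_diagnostic_indels`
#' columns carry a fixed base-vs-gap contrast; planted columns are mutually
#' non-adjacent. Additional non-diagnostic noise is sprinkled as singleton
#' substitutions at rate `within_group_poly_rate` per remaining column.
#'
#' @param n_a,n_b sequences per group (at least 2 each).
#' @param length alignment length (at least 500 columns).
#' @param n_diagnostic_snps,n_diagnostic_indels number of planted diagnostics.
#' @param within_group_poly_rate per-column probability of a singleton variant.
#' @param group_labels two group labels, used as id prefixes.
#' @param seed RNG seed.
#' @return an [alignment_panel()] with attribute `truth`: a tibble
#'   `column, kind, state_a, state_b` of the planted sites (1-based columns).
#' @export
simulate_alignment <- function(n_a = 8, n_b = 12, length = 2000,
                               n_diagnostic_snps = 5, n_diagnostic_indels = 1,
                               within_group_poly_rate = 0.01,
                               group_labels = c("A", "B"), seed = 1) {
  stopifnot(n_a >= 2, n_b >= 2)
  if (length < 500) stop("alignment length must be at least 500", call. = FALSE)
  n_diag <- n_diagnostic_snps + n_diagnostic_indels
  if (n_diag > length / 2) stop("requested diagnostics exceed length/2", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  out <- with_seed(seed, {
    ref <- sample(bases, length, replace = TRUE)
    # mutually non-adjacent planted columns, away from the alignment ends
    avail <- rep(TRUE, length)
    avail[c(1L, length)] <- FALSE
    planted <- integer(0)
    while (base::length(planted) < n_diag) {
      open <- which(avail)
      if (!base::length(open)) stop("alignment too short to place non-adjacent diagnostics", call. = FALSE)
      p <- if (base::length(open) == 1L) open else sample(open, 1L)
      planted <- c(planted, p)
      avail[max(1L, p - 1L):min(length, p + 1L)] <- FALSE
    }
    planted <- sort(planted)
    kinds <- sample(rep(c("SNP", "indel"), c(n_diagnostic_snps, n_diagnostic_indels)))
    n <- n_a + n_b
    mat <- matrix(rep(ref, each = n), nrow = n)
    grp <- rep(group_labels, c(n_a, n_b))
    b_rows <- which(grp == group_labels[2])
    truth <- tibble::tibble(
      column = planted, kind = kinds,
      state_a = ref[planted], state_b = NA_character_
    )
    for (i in seq_along(planted)) {
      col <- planted[i]
      alt <- if (kinds[i] == "indel") "-" else sample(setdiff(bases, ref[col]), 1L)
      mat[b_rows, col] <- alt
      truth$state_b[i] <- alt
    }
    # singleton polymorphism on columns not touching a planted site
    blocked <- unique(c(planted, planted - 1L, planted + 1L))
    free <- setdiff(seq_len(length), blocked)
    hit <- free[stats::runif(base::length(free)) < within_group_poly_rate]
    for (col in hit) {
      row <- sample.int(n, 1L)
      mat[row, col] <- sample(setdiff(bases, mat[row, col]), 1L)
    }
    ids <- c(
      paste0(group_labels[1], "|acc", seq_len(n_a)),
      paste0(group_labels[2], "|acc", seq_len(n_b))
    )
    panel <- alignment_panel(mat, groups = grp, ids = ids)
    attr(panel, "truth") <- truth
    panel
  })
  out
}
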