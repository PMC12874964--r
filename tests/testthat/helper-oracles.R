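# Independent oracle implementations used to cross-check the package's
# metric and overlap computations. Deliberately brute-force: correctness
# over speed, and structurally unlike the package versions.

# AUC as the literal all-pairs concordance probability: loop over every
# (presence, absence) pair, counting ties as 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Maximum TSS by exhaustive search over the same threshold lattice the
# package documents (0, 0.01, ..., 1), classifying presence when
# score >= threshold; ties broken toward the smallest threshold.
oracle_tss <- function(scores, labels) {
  thresholds <- seq(0, 1, by = 0.01)
  best_tss <- -Inf
  best_t <- NA_real_
  for (t in thresholds) {
    pred <- as.numeric(scores >= t)
    sens <- mean(pred[labels == 1] == 1)
    spec <- mean(pred[labels == 0] == 0)
    tss <- sens + spec - 1
    if (tss > best_tss) {
      best_tss <- tss
      best_t <- t
    }
  }
  list(tss = best_tss, threshold = best_t)
}

# Schoener's D from first principles on plain vectors.
oracle_schoener_d <- function(z1, z2) {
  1 - 0.5 * sum(abs(as.vector(z1) - as.vector(z2)))
}

# A small random environmental stack for tests that just need a grid.
test_stack <- function(seed = 1, dims = c(30, 30), with_hfi = TRUE) {
  specs <- dplyr::bind_rows(
    layer_spec("t_range", mean = 30, sd = 5, range = 3),
    layer_spec("precip", mean = 1000, sd = 250, range = 3),
    if (with_hfi) layer_spec("hfi", mean = 20, sd = 8, range = 2)
  )
  generate_env_stack(specs,
    dims = dims, origin = c(100, 30), cell_size = 0.1, seed = seed
  )
}

# An easy, strongly differentiated virtual species on `stack`: steep
# response to `var`, centred well into the favourable tail, so presences
# are separable from uniform background.
easy_species <- function(stack, var, var_mean, var_sd, n_presence = 120,
                         seed = 1, slope_per_sd = 12, centre_sd = 1.5,
                         minor = NULL) {
  coefs <- stats::setNames(slope_per_sd / var_sd, var)
  intercept <- -slope_per_sd / var_sd * (var_mean + centre_sd * var_sd)
  if (!is.null(minor)) {
    coefs <- c(coefs, stats::setNames(minor$slope_per_sd / minor$sd, minor$var))
    intercept <- intercept - minor$slope_per_sd / minor$sd * minor$mean
  }
  simulate_virtual_species(stack,
    coefficients = coefs, intercept = intercept,
    n_presence = n_presence, seed = seed
  )
}
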