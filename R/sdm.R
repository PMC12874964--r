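#' Sample pseudo-absence point sets
#'
#' Draws `n_sets` independent sets of `n` background ("pseudo-absence") points
#' uniformly without replacement from the grid cells that are neither nodata
#' nor occupied by a presence record — the random sampling strategy used to
#' provide background data for presence-only calibration (1,000 points,
#' repeated five times, in the source workflow).
#'
#' @param stack an [env_stack()].
#' @param presences tibble with `lon`, `lat` of presence records.
#' @param n points per set.
#' @param n_sets number of independent sets.
#' @param seed master seed; per-set seeds are derived from it.
#' @return a tibble: `pa_set`, `lon`, `lat`.
#' @export
sample_pseudo_absences <- function(stack, presences, n = 1000, n_sets = 5, seed = 1) {
  d <- dim(stack)
  nodata <- Reduce(`|`, lapply(stack$layers, is.na))
  pres_rc <- point_to_cell(stack, presences$lon, presences$lat)
  pres_cells <- unique((pres_rc$col - 1L) * d[1] + pres_rc$row)
  pres_cells <- pres_cells[!is.na(pres_cells)]
  candidates <- setdiff(which(!as.vector(nodata)), pres_cells)
  if (length(candidates) < n) {
    stop("only ", length(candidates), " candidate cells for n = ", n, call. = FALSE)
  }
  centers <- cell_centers(stack)
  purrr::map_dfr(seq_len(n_sets), function(s) {
    cells <- with_seed(sub_seed(seed, s), sample(candidates, n))
    tibble::tibble(pa_set = s, lon = centers$lon[cells], lat = centers$lat[cells])
  })
}

#' Algorithms available for single-model fitting
#'
#' `GLM` (logistic regression, optional quadratic terms), `GAM` (spline
#' smooths), `CTA` (single classification tree), `ANN` (one-hidden-layer
#' neural network), `RF` (random forest), `GBM` (gradient-boosted trees) and
#' `SRE` (surface range envelope: predict presence iff every variable lies
#' within the presence training values' central percentile interval).
#'
#' @return character vector of algorithm identifiers.
#' @export
sdm_algorithms <- function() c("GLM", "GAM", "CTA", "ANN", "RF", "GBM", "SRE")

fit_single <- function(algorithm, train, vars, seed, quadratic = TRUE, sre_q = 0.025) {
  x <- as.data.frame(train[vars])
  y <- train$label
  fit <- switch(algorithm,
    GLM = {
      terms <- vars
      if (quadratic) terms <- c(terms, sprintf("I(%s^2)", vars))
      f <- stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
      stats::glm(f, data = cbind(x, label = y), family = stats::binomial())
    },
    GAM = {
      terms <- vapply(vars, function(v) {
        if (length(unique(x[[v]])) > 8) sprintf("s(%s, k = 4)", v) else v
      }, character(1))
      f <- stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
      mgcv::gam(f, data = cbind(x, label = y), family = stats::binomial())
    },
    CTA = rpart::rpart(label ~ .,
      data = cbind(x, label = factor(y)),
      method = "class", control = rpart::rpart.control(cp = 0.005, minbucket = 5)
    ),
    ANN = {
      ctr <- lapply(x, mean)
      scl <- lapply(x, function(v) max(stats::sd(v), 1e-9))
      xs <- as.data.frame(purrr::map2(x, seq_along(x), function(v, i) {
        (v - ctr[[i]]) / scl[[i]]
      }))
      names(xs) <- vars
      net <- with_seed(seed, nnet::nnet(xs, y,
        size = 4, decay = 0.01,
        maxit = 250, trace = FALSE, entropy = TRUE
      ))
      list(net = net, center = ctr, scale = scl)
    },
    RF = with_seed(seed, randomForest::randomForest(x, factor(y), ntree = 300)),
    GBM = with_seed(seed, xgboost::xgb.train(
      params = list(
        objective = "binary:logistic", max_depth = 3, eta = 0.1, nthread = 1
      ),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
      nrounds = 60, verbose = 0
    )),
    SRE = {
      pres <- as.data.frame(train[train$label == 1, vars])
      bounds <- lapply(pres, stats::quantile, probs = c(sre_q, 1 - sre_q), names = FALSE)
      list(bounds = bounds)
    },
    stop("unknown algorithm id: ", algorithm, call. = FALSE)
  )
  structure(list(algorithm = algorithm, fit = fit, vars = vars), class = "sdm_fit")
}

#' Predict suitability scores from a fitted single model
#'
#' @param object an `sdm_fit`.
#' @param newdata data frame containing the model's variables.
#' @param ... unused.
#' @return numeric scores in `[0, 1]`.
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  x <- as.data.frame(newdata[object$vars])
  scores <- switch(object$algorithm,
    GLM = stats::predict(object$fit, newdata = x, type = "response"),
    GAM = as.numeric(stats::predict(object$fit, newdata = x, type = "response")),
    CTA = stats::predict(object$fit, newdata = x, type = "prob")[, "1"],
    ANN = {
      xs <- as.data.frame(purrr::map2(x, seq_along(x), function(v, i) {
        (v - object$fit$center[[i]]) / object$fit$scale[[i]]
      }))
      names(xs) <- object$vars
      as.numeric(stats::predict(object$fit$net, xs))
    },
    RF = stats::predict(object$fit, newdata = x, type = "prob")[, "1"],
    GBM = stats::predict(object$fit, xgboost::xgb.DMatrix(as.matrix(x))),
    SRE = {
      inside <- rep(TRUE, nrow(x))
      for (v in object$vars) {
        b <- object$fit$bounds[[v]]
        inside <- inside & x[[v]] >= b[1] & x[[v]] <= b[2]
      }
      as.numeric(inside)
    }
  )
  pmin(pmax(as.numeric(scores), 0), 1)
}

assemble_model_data <- function(stack, presences, pa_points) {
  pres <- extract_values(stack, presences[c("lon", "lat")])
  abs_ <- extract_values(stack, pa_points[c("lon", "lat")])
  dplyr::bind_rows(
    dplyr::mutate(pres, label = 1),
    dplyr::mutate(abs_, label = 0)
  )
}

#' Fit and evaluate single models across pseudo-absence sets and replicates
#'
#' For every (algorithm x pseudo-absence set x replicate) combination the
#' presence/pseudo-absence rows are split at random into `train_frac`
#' calibration and `1 - train_frac` independent validation parts (stratified,
#' preserving the presence:absence ratio), the model is fitted on the
#' calibration part, and [compute_metrics()] is evaluated on the held-out part
#' only. All sub-seeds are derived deterministically from `seed`.
#'
#' @param stack an [env_stack()].
#' @param presences tibble of presence records (`lon`, `lat`).
#' @param pa_sets pseudo-absence tibble from [sample_pseudo_absences()].
#' @param algorithms subset of [sdm_algorithms()].
#' @param train_frac fraction of rows used for calibration (default 0.75).
#' @param n_rep random-split replicates per pseudo-absence set (default 5).
#' @param quadratic add quadratic terms to the GLM (default `TRUE`).
#' @param sre_q tail fraction trimmed from each end of the SRE envelope.
#' @param seed master seed.
#' @return a tibble of class `sdm_runs`: one row per run with evaluation
#'   metrics and the fitted model in the `fit` list-column.
#' @export
run_single_models <- function(stack, presences, pa_sets,
                              algorithms = sdm_algorithms(),
                              train_frac = 0.75, n_rep = 5,
                              quadratic = TRUE, sre_q = 0.025, seed = 1) {
  if (!length(algorithms)) stop("no algorithms requested", call. = FALSE)
  unknown <- setdiff(algorithms, sdm_algorithms())
  if (length(unknown)) stop("unknown algorithm id: ", paste(unknown, collapse = ", "), call. = FALSE)
  vars <- layer_names(stack)
  grid <- expand.grid(
    pa_set = sort(unique(pa_sets$pa_set)), replicate = seq_len(n_rep),
    KEEP.OUT.ATTRS = FALSE
  )
  runs <- purrr::pmap_dfr(grid, function(pa_set, replicate) {
    data <- assemble_model_data(stack, presences, pa_sets[pa_sets$pa_set == pa_set, ])
    if (nrow(data) < 20L) stop("fewer than 20 rows for pa_set ", pa_set, call. = FALSE)
    split_seed <- sub_seed(seed, pa_set * 1000L + replicate)
    train_idx <- with_seed(split_seed, {
      pos <- which(data$label == 1)
      neg <- which(data$label == 0)
      c(
        sample(pos, max(1L, round(train_frac * length(pos)))),
        sample(neg, max(1L, round(train_frac * length(neg))))
      )
    })
    train <- data[train_idx, ]
    test <- data[-train_idx, ]
    stopifnot(length(unique(train$label)) == 2L, length(unique(test$label)) == 2L)
    purrr::map_dfr(algorithms, function(alg) {
      fit_seed <- sub_seed(split_seed, match(alg, sdm_algorithms()))
      fit <- fit_single(alg, train, vars, fit_seed, quadratic = quadratic, sre_q = sre_q)
      m <- compute_metrics(predict(fit, test), test$label)
      dplyr::bind_cols(
        tibble::tibble(algorithm = alg, pa_set = pa_set, replicate = replicate),
        m,
        tibble::tibble(fit = list(fit))
      )
    })
  })
  attr(runs, "vars") <- vars
  class(runs) <- c("sdm_runs", class(runs))
  runs
}

#' Select the model committee and build the ensemble suitability surface
#'
#' Runs with `tss > tss_min` and `roc_auc > roc_min` form the committee
#' (the screen applied before ensemble prediction in the source workflow);
#' the ensemble suitability at each grid cell is the unweighted mean of the
#' committee members' predicted probabilities (or a TSS-weighted mean with
#' `rule = "tss_weighted"`).
#'
#' @param runs an `sdm_runs` tibble from [run_single_models()].
#' @param stack the [env_stack()] to predict over.
#' @param tss_min,roc_min committee admission thresholds (defaults 0.8 / 0.9).
#' @param rule `"mean"` (default) or `"tss_weighted"`.
#' @return an `ensemble_result`: committee tibble, one-layer suitability
#'   [env_stack()], combination rule and member weights.
#' @export
select_and_ensemble <- function(runs, stack, tss_min = 0.8, roc_min = 0.9,
                                rule = c("mean", "tss_weighted")) {
  rule <- match.arg(rule)
  if (!nrow(runs)) stop("no runs supplied", call. = FALSE)
  committee <- dplyr::filter(runs, .data$tss > tss_min, .data$roc_auc > roc_min)
  if (!nrow(committee)) {
    near <- runs |>
      dplyr::group_by(.data$algorithm) |>
      dplyr::summarise(
        best_tss = max(.data$tss), best_roc = max(.data$roc_auc),
        .groups = "drop"
      )
    stop(
      "empty committee: no run passed tss > ", tss_min, " and roc > ", roc_min,
      "; per-algorithm best (tss, roc): ",
      paste(sprintf("%s (%.2f, %.2f)", near$algorithm, near$best_tss, near$best_roc),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  weights <- if (rule == "mean") {
    rep(1 / nrow(committee), nrow(committee))
  } else {
    committee$tss / sum(committee$tss)
  }
  cells <- as_tibble.env_stack(stack)
  vars <- attr(runs, "vars") %||% layer_names(stack)
  ok <- stats::complete.cases(cells[vars])
  suit <- rep(NA_real_, nrow(cells))
  if (any(ok)) {
    preds <- vapply(
      committee$fit, function(f) predict(f, cells[ok, vars]),
      numeric(sum(ok))
    )
    suit[ok] <- as.vector(preds %*% weights)
  }
  d <- dim(stack)
  result <- structure(
    list(
      committee = dplyr::select(committee, -"fit"),
      members = committee$fit,
      weights = weights,
      rule = rule,
      vars = vars,
      suitability = env_stack(list(suitability = matrix(suit, d[1], d[2])),
        origin = stack$origin, cell_size = stack$cell_size,
        label = paste0("ensemble-", stack$label)
      )
    ),
    class = "ensemble_result"
  )
  result
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result> committee of %d runs (%s), rule = %s\n",
    nrow(x$committee), paste(unique(x$committee$algorithm), collapse = ", "), x$rule
  ))
  invisible(x)
}

#' Predict ensemble suitability for new rows
#'
#' @param object an `ensemble_result`.
#' @param newdata data frame with the model variables.
#' @param ... unused.
#' @return numeric suitability scores in `[0, 1]`.
#' @export
predict.ensemble_result <- function(object, newdata, ...) {
  preds <- vapply(
    object$members, function(f) predict(f, newdata[object$vars]),
    numeric(nrow(newdata))
  )
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  as.vector(preds %*% object$weights)
}

#' Committee membership table of an ensemble
#'
#' @param x an `ensemble_result`.
#' @param ... unused.
#' @return the committee tibble (one row per accepted run, with metrics).
#' @export
tidy.ensemble_result <- function(x, ...) x$committee

#' One-row ensemble summary
#'
#' @param x an `ensemble_result`.
#' @param ... unused.
#' @return tibble: committee size, number of algorithms, mean TSS/ROC, rule.
#' @export
glance.ensemble_result <- function(x, ...) {
  tibble::tibble(
    n_members = nrow(x$committee),
    n_algorithms = dplyr::n_distinct(x$committee$algorithm),
    mean_tss = mean(x$committee$tss),
    mean_roc_auc = mean(x$committee$roc_auc),
    rule = x$rule
  )
}

#' @export
autoplot.ensemble_result <- function(object, ...) {
  autoplot.env_stack(object$suitability) +
    ggplot2::labs(fill = "suitability")
}

#' Permutation variable importance of an ensemble
#'
#' For each variable: its column in `data` is permuted, the ensemble
#' re-predicted, and raw importance taken as `1 - cor(reference, permuted)`
#' averaged over `n_perm` permutations; raw values are then normalized to
#' percentages summing to 100 (the importance-contribution-rate convention).
#'
#' @param result an `ensemble_result`.
#' @param data data frame of evaluation rows (>= 30) containing the variables.
#' @param n_perm permutations per variable (default 10).
#' @param seed RNG seed.
#' @return a tibble `variable, raw_importance, importance_pct`, sorted by
#'   decreasing importance.
#' @export
variable_importance <- function(result, data, n_perm = 10, seed = 1) {
  if (nrow(data) < 30L) stop("need at least 30 evaluation rows", call. = FALSE)
  vars <- result$vars
  ref <- predict(result, data)
  raw <- vapply(seq_along(vars), function(i) {
    v <- vars[i]
    mean(vapply(seq_len(n_perm), function(p) {
      perm <- with_seed(sub_seed(seed, i * 1000L + p), sample(nrow(data)))
      shuffled <- data
      shuffled[[v]] <- data[[v]][perm]
      pred <- predict(result, shuffled)
      r <- suppressWarnings(stats::cor(ref, pred))
      if (is.na(r)) r <- if (isTRUE(all.equal(ref, pred))) 1 else 0
      1 - r
    }, numeric(1)))
  }, numeric(1))
  raw <- pmax(raw, 0)
  if (sum(raw) <= 0) stop("zero total raw importance: no variable is used", call. = FALSE)
  tibble::tibble(
    variable = vars,
    raw_importance = raw,
    importance_pct = 100 * raw / sum(raw)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance_pct))
}
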