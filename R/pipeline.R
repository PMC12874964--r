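#' Default pipeline configuration
#'
#' Nested list of every stage's parameters with the package defaults: a
#' synthetic two-species study (one precipitation-dominated, one
#' temperature-range-dominated species on correlated, spatially
#' autocorrelated layers with an anthropogenic-pressure layer on the 0-50
#' scale), 10-km thinning, |r| > 0.7 collinearity screening, pseudo-absence
#' sampling, 75/25 evaluation with TSS > 0.8 / ROC > 0.9 committee selection,
#' niche overlap and equivalency testing, graded/binary range dynamics, and
#' mini-barcode discovery on a simulated plastome-style alignment.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param out_dir output directory for stage artifacts.
#' @return a named list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1, out_dir = tempfile("paridis_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    simulate = list(
      dims = c(60, 60), cell_size = 0.1, origin = c(100, 35),
      n_presence_a = 150, n_presence_b = 150,
      alignment = list(
        n_a = 8, n_b = 12, length = 2000,
        n_diagnostic_snps = 5, n_diagnostic_indels = 1,
        within_group_poly_rate = 0.01
      )
    ),
    prep = list(resolution_km = 10, collinearity_threshold = 0.7),
    sdm = list(
      algorithms = c("GLM", "CTA", "RF", "GBM"),
      n_pseudo_absence = 300, n_pa_sets = 2, train_frac = 0.75, n_rep = 2,
      tss_min = 0.8, roc_min = 0.9, ensemble_rule = "mean", n_perm = 5
    ),
    niche = list(n_iter = 99, R = 50, correction = "availability"),
    dynamics = list(threshold = 0.6, strict = TRUE, breaks = c(0.2, 0.4, 0.6, 0.8)),
    barcode = list(
      window = 500, target_len = 200, flank_len = 20,
      min_flank_conservation = 1.0, max_missing = 0
    )
  )
}

pipeline_schema <- function() {
  list(
    seed = NULL, out_dir = NULL,
    simulate = c(
      "dims", "cell_size", "origin", "n_presence_a", "n_presence_b",
      "alignment"
    ),
    prep = c("resolution_km", "collinearity_threshold"),
    sdm = c(
      "algorithms", "n_pseudo_absence", "n_pa_sets", "train_frac", "n_rep",
      "tss_min", "roc_min", "ensemble_rule", "n_perm"
    ),
    niche = c("n_iter", "R", "correction"),
    dynamics = c("threshold", "strict", "breaks"),
    barcode = c(
      "window", "target_len", "flank_len", "min_flank_conservation",
      "max_missing"
    )
  )
}

validate_config <- function(config) {
  schema <- pipeline_schema()
  unknown_top <- setdiff(names(config), names(schema))
  if (length(unknown_top)) {
    stop("unknown config key(s): ", paste(unknown_top, collapse = ", "), call. = FALSE)
  }
  for (stage in setdiff(names(schema), c("seed", "out_dir"))) {
    if (is.null(config[[stage]])) next
    bad <- setdiff(names(config[[stage]]), schema[[stage]])
    if (length(bad)) {
      stop(
        "unknown key(s) in config$", stage, ": ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override [default_config()] defaults; unknown
#' keys are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param seed optional master-seed override.
#' @return a validated config list.
#' @export
read_config <- function(path, seed = NULL) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  config <- utils::modifyList(default_config(), raw)
  if (!is.null(seed)) config$seed <- seed
  validate_config(config)
  config
}

log_line <- function(state, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), paste0(...))
  state$log <- c(state$log, msg)
  message(msg)
  state
}

record_artifact <- function(state, name, path) {
  state$manifest[[name]] <- list(
    path = path,
    md5 = unname(tools::md5sum(path))
  )
  state
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic study
#' defined by the configuration, writing plain-text artifacts (CSV tables,
#' ASCII grids, FASTA, JSON reports) under `config$out_dir` and returning a
#' manifest of everything produced with content hashes. The same config and
#' seed reproduce identical artifacts.
#'
#' Stages: `simulate` (landscape, two virtual species, alignment), `prep`
#' (thinning, extraction, collinearity screen, biome labels), `sdm`
#' (pseudo-absences, single models, committee, ensembles with and without the
#' human-footprint layer, variable importance), `niche` (PCA-env, overlap,
#' equivalency test, human-impact overlap), `dynamics` (grading, binary
#' change, centroids, long-term intersection) and `barcode` (window scan,
#' diagnostic sites, candidate design, self-classification).
#'
#' @param config list from [default_config()] or [read_config()].
#' @param stages subset of the stage names above (dependencies must be
#'   included or already satisfied in `state`).
#' @param state optional state returned by a previous call, to resume.
#' @return invisibly, the pipeline state: `manifest`, `log`, and the in-memory
#'   stage results.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "prep", "sdm", "niche", "dynamics", "barcode"),
                         state = NULL) {
  validate_config(config)
  all_stages <- c("simulate", "prep", "sdm", "niche", "dynamics", "barcode")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(
    simulate = character(), prep = "simulate", sdm = "prep",
    niche = "sdm", dynamics = "sdm", barcode = "simulate"
  )
  state <- state %||% list(manifest = list(), log = character(), results = list())
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in all_stages[all_stages %in% stages]) {
    missing <- setdiff(deps[[stage]], names(state$results))
    if (length(missing)) {
      stop(
        "stage '", stage, "' requires output of stage(s): ",
        paste(missing, collapse = ", "), call. = FALSE
      )
    }
    state <- log_line(state, "stage ", stage, " started (seed ", config$seed, ")")
    state <- tryCatch(
      switch(stage,
        simulate = stage_simulate(config, state),
        prep = stage_prep(config, state),
        sdm = stage_sdm(config, state),
        niche = stage_niche(config, state),
        dynamics = stage_dynamics(config, state),
        barcode = stage_barcode(config, state)
      ),
      error = function(e) {
        stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
      }
    )
    state <- log_line(state, "stage ", stage, " done")
  }
  writeLines(state$log, file.path(config$out_dir, "pipeline.log"))
  jsonlite::write_json(state$manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(state)
}

stage_simulate <- function(config, state) {
  cs <- config$simulate
  seed <- sub_seed(config$seed, 1)
  specs <- dplyr::bind_rows(
    layer_spec("bio7", mean = 30, sd = 5, range = 4), # temperature annual range
    layer_spec("bio12", mean = 1200, sd = 300, range = 4), # annual precipitation
    layer_spec("bio15", mean = 60, sd = 15, range = 4),
    layer_spec("elev", mean = 1500, sd = 600, range = 5),
    layer_spec("hfi", mean = 15, sd = 8, range = 3)
  )
  corr <- diag(5)
  corr[2, 3] <- corr[3, 2] <- 0.4 # precipitation vs its seasonality
  corr[1, 4] <- corr[4, 1] <- 0.3 # temperature range vs elevation
  stack <- generate_env_stack(specs,
    dims = cs$dims, target_corr = corr,
    origin = cs$origin, cell_size = cs$cell_size, seed = seed
  )
  # Species A is precipitation-dominated, species B temperature-range-dominated.
  # Both use steep responses centred 1.5 sd into the favourable tail, so true
  # suitability is near 0 over most of the landscape and near 1 in a compact
  # region: a strongly differentiated (habitat-specialist) virtual species
  # whose occurrences are separable from background at committee-grade skill.
  sp_a <- simulate_virtual_species(stack,
    coefficients = c(bio12 = 12 / 300, bio7 = -2 / 5),
    intercept = -12 / 300 * (1200 + 1.5 * 300) + 2 / 5 * 30,
    n_presence = cs$n_presence_a, bias_layer = "hfi",
    species = "sp_precip", seed = sub_seed(seed, 2)
  )
  sp_b <- simulate_virtual_species(stack,
    coefficients = c(bio7 = -12 / 5, bio12 = 2 / 300),
    intercept = 12 / 5 * (30 - 1.5 * 5) - 2 / 300 * 1200,
    n_presence = cs$n_presence_b, bias_layer = "hfi",
    species = "sp_trange", seed = sub_seed(seed, 3)
  )
  aln <- do.call(simulate_alignment, c(cs$alignment, list(seed = sub_seed(seed, 4))))
  occ <- dplyr::bind_rows(sp_a$occurrences, sp_b$occurrences)
  occ_path <- file.path(config$out_dir, "occurrences.csv")
  readr::write_csv(occ, occ_path)
  grid_path <- file.path(config$out_dir, "layer_bio12.asc")
  write_ascii_grid(stack, "bio12", grid_path)
  aln_path <- file.path(config$out_dir, "alignment.fasta")
  write_alignment(aln, aln_path)
  truth_path <- file.path(config$out_dir, "alignment_truth.json")
  jsonlite::write_json(attr(aln, "truth"), truth_path, auto_unbox = TRUE, pretty = TRUE)
  state$results$simulate <- list(
    stack = stack, species_a = sp_a, species_b = sp_b, alignment = aln
  )
  state <- record_artifact(state, "occurrences", occ_path)
  state <- record_artifact(state, "layer_bio12", grid_path)
  state <- record_artifact(state, "alignment", aln_path)
  record_artifact(state, "alignment_truth", truth_path)
}

stage_prep <- function(config, state) {
  sim <- state$results$simulate
  seed <- sub_seed(config$seed, 2)
  occ <- dplyr::bind_rows(sim$species_a$occurrences, sim$species_b$occurrences)
  clean <- load_and_clean(occ)
  thin <- clean |>
    dplyr::group_by(.data$species) |>
    dplyr::group_modify(~ spatial_thin(.x, config$prep$resolution_km, seed = seed)) |>
    dplyr::ungroup()
  env <- extract_values(sim$stack, thin)
  screen <- collinearity_filter(env,
    threshold = config$prep$collinearity_threshold,
    vars = setdiff(layer_names(sim$stack), "hfi")
  )
  thin_path <- file.path(config$out_dir, "occurrences_thinned.csv")
  readr::write_csv(thin, thin_path)
  env_path <- file.path(config$out_dir, "env_table.csv")
  readr::write_csv(env, env_path)
  cor_path <- file.path(config$out_dir, "correlation_matrix.csv")
  utils::write.csv(screen$cor_matrix, cor_path)
  state$results$prep <- list(thinned = thin, env = env, screen = screen)
  state <- record_artifact(state, "occurrences_thinned", thin_path)
  state <- record_artifact(state, "env_table", env_path)
  record_artifact(state, "correlation_matrix", cor_path)
}

fit_one_species <- function(stack, presences, cfg, seed) {
  pa <- sample_pseudo_absences(stack, presences,
    n = cfg$n_pseudo_absence,
    n_sets = cfg$n_pa_sets, seed = seed
  )
  runs <- run_single_models(stack, presences, pa,
    algorithms = cfg$algorithms,
    train_frac = cfg$train_frac, n_rep = cfg$n_rep, seed = seed
  )
  ens <- select_and_ensemble(runs, stack,
    tss_min = cfg$tss_min,
    roc_min = cfg$roc_min, rule = cfg$ensemble_rule
  )
  list(pa = pa, runs = runs, ensemble = ens)
}

drop_layer <- function(stack, layer) {
  env_stack(stack$layers[setdiff(layer_names(stack), layer)],
    origin = stack$origin, cell_size = stack$cell_size,
    label = paste0(stack$label, "-no-", layer)
  )
}

stage_sdm <- function(config, state) {
  sim <- state$results$simulate
  prep <- state$results$prep
  cfg <- config$sdm
  seed <- sub_seed(config$seed, 3)
  stack <- sim$stack
  stack_nohfi <- drop_layer(stack, "hfi")
  species <- split(prep$thinned, prep$thinned$species)
  out <- purrr::imap(species, function(occ, sp) {
    with_hfi <- fit_one_species(stack, occ, cfg, sub_seed(seed, 1))
    without_hfi <- fit_one_species(stack_nohfi, occ, cfg, sub_seed(seed, 2))
    data <- assemble_model_data(stack, occ, with_hfi$pa[with_hfi$pa$pa_set == 1, ])
    importance <- variable_importance(with_hfi$ensemble, data,
      n_perm = cfg$n_perm, seed = sub_seed(seed, 3)
    )
    list(with_hfi = with_hfi, without_hfi = without_hfi, importance = importance)
  })
  ledger <- purrr::imap_dfr(out, function(res, sp) {
    dplyr::mutate(
      dplyr::select(res$with_hfi$runs, -"fit"),
      species = sp, .before = 1
    )
  })
  ledger_path <- file.path(config$out_dir, "run_ledger.tsv")
  readr::write_tsv(ledger, ledger_path)
  imp_path <- file.path(config$out_dir, "variable_importance.csv")
  readr::write_csv(
    purrr::imap_dfr(out, ~ dplyr::mutate(.x$importance, species = .y, .before = 1)),
    imp_path
  )
  state$results$sdm <- out
  state <- record_artifact(state, "run_ledger", ledger_path)
  record_artifact(state, "variable_importance", imp_path)
}

stage_niche <- function(config, state) {
  sim <- state$results$simulate
  prep <- state$results$prep
  cfg <- config$niche
  seed <- sub_seed(config$seed, 4)
  vars <- prep$screen$retained
  background <- as_tibble.env_stack(sim$stack, drop_na = TRUE)
  space <- pca_env(background, vars = vars)
  by_sp <- split(prep$env, prep$env$species)
  eq <- equivalency_test(by_sp[[1]], by_sp[[2]], background,
    space = space,
    n_iter = cfg$n_iter, R = cfg$R, correction = cfg$correction, seed = seed
  )
  impacts <- purrr::imap_dfr(state$results$sdm, function(res, sp) {
    dplyr::mutate(
      impact_overlap(
        res$with_hfi$ensemble$suitability,
        res$without_hfi$ensemble$suitability
      ),
      species = sp, .before = 1
    )
  })
  report <- c(
    glance.overlap_result(eq),
    list(pc1_explained = space$explained[1], pc2_explained = space$explained[2])
  )
  rep_path <- file.path(config$out_dir, "niche_overlap.json")
  jsonlite::write_json(report, rep_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  null_path <- file.path(config$out_dir, "equivalency_null.csv")
  readr::write_csv(tidy.overlap_result(eq), null_path)
  imp_path <- file.path(config$out_dir, "human_impact.csv")
  readr::write_csv(impacts, imp_path)
  state$results$niche <- list(space = space, equivalency = eq, impact = impacts)
  state <- record_artifact(state, "niche_overlap", rep_path)
  state <- record_artifact(state, "equivalency_null", null_path)
  record_artifact(state, "human_impact", imp_path)
}

stage_dynamics <- function(config, state) {
  cfg <- config$dynamics
  out <- purrr::imap(state$results$sdm, function(res, sp) {
    with_map <- res$with_hfi$ensemble$suitability
    without_map <- res$without_hfi$ensemble$suitability
    graded <- classify_and_area(with_map, breaks = cfg$breaks)
    change <- binarize_and_change(without_map, with_map,
      threshold = cfg$threshold, strict = cfg$strict
    )
    bmaps <- list(
      without_hfi = env_stack(
        list(suitable = binary_map(without_map, cfg$threshold, cfg$strict)),
        origin = with_map$origin, cell_size = with_map$cell_size
      ),
      with_hfi = env_stack(
        list(suitable = binary_map(with_map, cfg$threshold, cfg$strict)),
        origin = with_map$origin, cell_size = with_map$cell_size
      )
    )
    centroids <- centroid_shift(bmaps)
    longterm <- longterm_intersection(bmaps)
    list(
      graded = graded, change = change, centroids = centroids,
      longterm = longterm, binary = bmaps
    )
  })
  areas_path <- file.path(config$out_dir, "class_areas.csv")
  readr::write_csv(
    purrr::imap_dfr(out, ~ dplyr::mutate(.x$graded$areas, species = .y, .before = 1)),
    areas_path
  )
  cent_path <- file.path(config$out_dir, "centroids.csv")
  readr::write_csv(
    purrr::imap_dfr(out, ~ dplyr::mutate(.x$centroids$centroids, species = .y, .before = 1)),
    cent_path
  )
  state$results$dynamics <- out
  state <- record_artifact(state, "class_areas", areas_path)
  record_artifact(state, "centroids", cent_path)
}

stage_barcode <- function(config, state) {
  cfg <- config$barcode
  panel <- state$results$simulate$alignment
  stats <- window_stats(panel, window = cfg$window)
  sites <- find_diagnostic_sites(panel, max_missing = cfg$max_missing)
  cands <- design_candidates(panel, sites,
    target_len = cfg$target_len,
    flank_len = cfg$flank_len,
    min_flank_conservation = cfg$min_flank_conservation
  )
  calls <- purrr::map_chr(seq_len(nrow(panel$mat)), function(i) {
    w <- cands[1, ]
    q <- paste(panel$mat[i, w$start:w$end], collapse = "")
    classify_sample(q, cands, panel, sites)$call
  })
  self_report <- tibble::tibble(
    id = panel$ids, group = panel$groups, call = calls,
    correct = calls == panel$groups
  )
  stats_path <- file.path(config$out_dir, "window_stats.tsv")
  readr::write_tsv(stats, stats_path)
  sites_path <- file.path(config$out_dir, "diagnostic_sites.tsv")
  readr::write_tsv(sites, sites_path)
  cand_path <- file.path(config$out_dir, "barcode_candidates.tsv")
  readr::write_tsv(
    dplyr::mutate(cands,
      site_columns = purrr::map_chr(.data$site_columns, paste, collapse = ",")
    ),
    cand_path
  )
  class_path <- file.path(config$out_dir, "self_classification.tsv")
  readr::write_tsv(self_report, class_path)
  state$results$barcode <- list(
    window_stats = stats, sites = sites,
    candidates = cands, self_classification = self_report
  )
  state <- record_artifact(state, "window_stats", stats_path)
  state <- record_artifact(state, "diagnostic_sites", sites_path)
  state <- record_artifact(state, "barcode_candidates", cand_path)
  record_artifact(state, "self_classification", class_path)
}
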