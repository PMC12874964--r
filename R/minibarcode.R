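ALPHABET <- c("A", "C", "G", "T", "-", "N")

# per-column character counts within a row subset; 6 x L matrix
col_counts <- function(mat, rows) {
  sub <- mat[rows, , drop = FALSE]
  out <- vapply(ALPHABET, function(ch) colSums(sub == ch), numeric(ncol(mat)))
  t(out) # 6 x L
}

#' Sliding-window variability of a two-group alignment
#'
#' For each window of `window` columns advanced by `step`: the number of
#' parsimony-informative sites (columns with at least two distinct non-gap,
#' non-N states each carried by at least two sequences) and the number of
#' indel events (maximal gap runs, deduplicated across sequences by their
#' coordinates, that intersect the window). Columns are 1-based inclusive.
#'
#' @param panel an [alignment_panel()].
#' @param window window length in columns (classically 500).
#' @param step step between window starts (default = `window`).
#' @return a tibble: `start`, `end`, `n_indels`, `n_pi_sites`.
#' @export
window_stats <- function(panel, window = 500, step = window) {
  stopifnot(window >= 1, step >= 1)
  mat <- panel$mat
  L <- ncol(mat)
  if (window > L) {
    warning("window longer than alignment; returning a single terminal window")
    window <- L
  }
  counts <- col_counts(mat, seq_len(nrow(mat)))
  base_counts <- counts[1:4, , drop = FALSE]
  pi_col <- colSums(base_counts >= 2) >= 2
  # unique maximal gap runs across sequences (lapply keeps a list even when
  # every row is gap-free, where apply() would collapse to NULL)
  run_list <- lapply(seq_len(nrow(mat)), function(i) {
    r <- rle(mat[i, ] == "-")
    if (!any(r$values)) {
      return(NULL)
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  })
  runs <- unique(do.call(rbind, run_list))
  starts <- seq(1L, L, by = step)
  purrr::map_dfr(starts, function(ws) {
    we <- min(ws + window - 1L, L)
    n_ind <- if (is.null(runs)) 0L else sum(runs[, 1] <= we & runs[, 2] >= ws)
    tibble::tibble(
      start = ws, end = we,
      n_indels = as.integer(n_ind),
      n_pi_sites = as.integer(sum(pi_col[ws:we]))
    )
  })
}

#' Line plot of sliding-window variability
#'
#' @param stats tibble from [window_stats()].
#' @return a ggplot of parsimony-informative sites and indels per window.
#' @export
plot_window_stats <- function(stats) {
  df <- tidyr::pivot_longer(stats, c("n_indels", "n_pi_sites"),
    names_to = "statistic", values_to = "count"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$start + .data$end) / 2,
    y = .data$count, colour = .data$statistic
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "alignment position (window midpoint)", y = "count")
}

#' Species-diagnostic sites of a two-group alignment
#'
#' Columns where, after ignoring up to `max_missing` `N` rows per group, group
#' A is fixed for one state and group B fixed for a different state. A
#' base-vs-gap contrast is an indel diagnostic; a run of consecutive indel
#' columns with the same state pair is reported once, at its first column.
#' Any within-group polymorphism at a column disqualifies it. Columns are
#' 1-based inclusive.
#'
#' @param panel an [alignment_panel()] with at least two rows per group.
#' @param max_missing maximum `N` rows tolerated per group per column
#'   (default 0: strict fixation).
#' @return a tibble: `column`, `kind` (`"SNP"`/`"indel"`), `state_a`,
#'   `state_b` (states of the alphabetically first and second group).
#' @export
find_diagnostic_sites <- function(panel, max_missing = 0) {
  lev <- group_levels(panel)
  rows_a <- which(panel$groups == lev[1])
  rows_b <- which(panel$groups == lev[2])
  if (length(rows_a) < 2L || length(rows_b) < 2L) {
    stop("each group needs at least 2 sequences", call. = FALSE)
  }
  fixed_state <- function(rows) {
    cnt <- col_counts(panel$mat, rows) # 6 x L
    n_missing <- cnt["N", ]
    informative <- cnt[c("A", "C", "G", "T", "-"), , drop = FALSE]
    top <- apply(informative, 2, max)
    n_eff <- length(rows) - n_missing
    ok <- n_missing <= max_missing & n_eff >= 1 & top == n_eff
    state <- rownames(informative)[apply(informative, 2, which.max)]
    state[!ok] <- NA_character_
    state
  }
  sa <- fixed_state(rows_a)
  sb <- fixed_state(rows_b)
  diag_col <- which(!is.na(sa) & !is.na(sb) & sa != sb)
  if (!length(diag_col)) {
    return(tibble::tibble(
      column = integer(), kind = character(),
      state_a = character(), state_b = character()
    ))
  }
  out <- tibble::tibble(
    column = diag_col,
    kind = ifelse(sa[diag_col] == "-" | sb[diag_col] == "-", "indel", "SNP"),
    state_a = sa[diag_col],
    state_b = sb[diag_col]
  )
  # collapse multi-column gap runs: consecutive indel columns where the same
  # group carries the gap count as one event at the run start
  gap_side <- ifelse(out$kind == "indel", ifelse(out$state_a == "-", "a", "b"), "none")
  run_id <- cumsum(
    !(out$kind == "indel" &
      dplyr::lag(out$kind, default = "x") == "indel" &
      dplyr::lag(out$column, default = -10L) == out$column - 1L &
      dplyr::lag(gap_side, default = "x") == gap_side)
  )
  out |>
    dplyr::mutate(.run = run_id) |>
    dplyr::group_by(.data$.run) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".run")
}

# majority character per column over a row subset; ties broken by the fixed
# alphabet order (bases first, then gap, then N)
group_consensus <- function(panel, rows, cols = seq_len(ncol(panel$mat))) {
  cnt <- col_counts(panel$mat, rows)[, cols, drop = FALSE]
  ALPHABET[apply(cnt, 2, which.max)]
}

#' Design mini-barcode candidate windows around diagnostic sites
#'
#' For each diagnostic site a `target_len` window centred on it (shifted
#' inward at the alignment edges) is formed and retained iff both `flank_len`
#' terminal flanks are conserved across all rows of both groups at a fraction
#' of columns at least `min_flank_conservation`. Candidates covering the same
#' diagnostic-site set are deduplicated, keeping the best-conserved flanks.
#'
#' @param panel an [alignment_panel()].
#' @param sites diagnostic-site tibble from [find_diagnostic_sites()].
#' @param target_len candidate length in columns (default 200, the classic
#'   mini-barcode fragment size for degraded material).
#' @param flank_len flank length checked at each end (default 20).
#' @param min_flank_conservation minimum conserved fraction per flank
#'   (default 1.0 = fully conserved flanks).
#' @return a tibble: `start`, `end` (1-based inclusive), `n_sites`,
#'   `site_columns` (list-column), `flank_left`, `flank_right`.
#' @export
design_candidates <- function(panel, sites, target_len = 200, flank_len = 20,
                              min_flank_conservation = 1.0) {
  if (!nrow(sites)) stop("no diagnostic sites supplied", call. = FALSE)
  L <- ncol(panel$mat)
  if (L < target_len) stop("alignment shorter than target length", call. = FALSE)
  cnt <- col_counts(panel$mat, seq_len(nrow(panel$mat)))
  conserved <- apply(cnt, 2, max) == nrow(panel$mat)
  cand <- purrr::map_dfr(sites$column, function(c0) {
    start <- min(max(1L, c0 - floor(target_len / 2)), L - target_len + 1L)
    end <- start + target_len - 1L
    inside <- sites$column[sites$column >= start & sites$column <= end]
    tibble::tibble(
      start = start, end = end,
      n_sites = length(inside),
      site_columns = list(sort(inside)),
      flank_left = mean(conserved[start:(start + flank_len - 1L)]),
      flank_right = mean(conserved[(end - flank_len + 1L):end])
    )
  })
  cand <- dplyr::filter(
    cand,
    .data$flank_left >= min_flank_conservation,
    .data$flank_right >= min_flank_conservation
  )
  if (!nrow(cand)) {
    return(cand)
  }
  cand |>
    dplyr::mutate(.key = vapply(.data$site_columns, paste, character(1), collapse = ",")) |>
    dplyr::group_by(.data$.key) |>
    dplyr::arrange(
      dplyr::desc(pmin(.data$flank_left, .data$flank_right)),
      dplyr::desc(.data$flank_left + .data$flank_right),
      .data$start
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".key") |>
    dplyr::arrange(.data$start)
}

#' Classify a query sequence against mini-barcode candidates
#'
#' The query (an unaligned fragment, e.g. a Sanger read from a seedling) is
#' matched to each candidate window by ends-free pairwise alignment against
#' the window consensus of the base-carrying group, the diagnostic columns
#' are read out, and the call is the group whose diagnostic states all
#' readable sites support -- `"ambiguous"` on conflict or when no site is
#' readable. A candidate whose alignment identity falls below
#' `identity_floor` contributes no evidence; if no candidate matches at all,
#' an error is raised.
#'
#' @param query character string over `A,C,G,T,N` (at least 90% of the
#'   candidate length).
#' @param candidates tibble from [design_candidates()].
#' @param panel the [alignment_panel()] the candidates were designed on.
#' @param sites the diagnostic-site tibble used for the design.
#' @param identity_floor minimum alignment identity, as a fraction (0.9).
#' @return a list: `call` (a group label or `"ambiguous"`) and `evidence`
#'   (tibble of per-site readouts).
#' @export
classify_sample <- function(query, candidates, panel, sites, identity_floor = 0.9) {
  stopifnot(nrow(candidates) >= 1)
  lev <- group_levels(panel)
  rows_a <- which(panel$groups == lev[1])
  rows_b <- which(panel$groups == lev[2])
  query <- toupper(gsub("-", "", query))
  evidence <- purrr::map_dfr(seq_len(nrow(candidates)), function(ci) {
    start <- candidates$start[ci]
    end <- candidates$end[ci]
    if (nchar(query) < 0.9 * (end - start + 1L)) {
      return(NULL)
    }
    s <- sites[sites$column %in% candidates$site_columns[[ci]], ]
    # reference = window consensus of the group holding a base at the first site
    ref_group <- if (nrow(s) && s$state_a[1] == "-") "b" else "a"
    ref_rows <- if (ref_group == "a") rows_a else rows_b
    cons <- group_consensus(panel, ref_rows, start:end)
    keep <- cons != "-"
    ref_seq <- paste(cons[keep], collapse = "")
    ref_pos <- cumsum(keep) # subject position of each window column
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(query),
      subject = Biostrings::DNAString(ref_seq),
      type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE
      ),
      gapOpening = 4, gapExtension = 1
    )
    p_id <- Biostrings::pid(al)
    # pid() is NaN for a zero-width overlap (query and window share no
    # alignable region); treat that as failing the identity floor
    if (!is.finite(p_id) || p_id / 100 < identity_floor) {
      return(NULL)
    }
    ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    sub_start <- Biostrings::start(Biostrings::subject(al))
    sub_idx <- sub_start - 1L + cumsum(as_ != "-")
    read_at <- function(p) {
      hit <- which(as_ != "-" & sub_idx == p)
      if (!length(hit)) {
        return(NA_character_)
      }
      ap[hit[1]]
    }
    purrr::map_dfr(seq_len(nrow(s)), function(k) {
      col <- s$column[k]
      in_ref <- cons[col - start + 1L] != "-"
      obs <- if (in_ref) read_at(ref_pos[col - start + 1L]) else NA_character_
      base_state <- if (ref_group == "a") s$state_a[k] else s$state_b[k]
      other_state <- if (ref_group == "a") s$state_b[k] else s$state_a[k]
      vote <- dplyr::case_when(
        is.na(obs) ~ NA_character_,
        obs == base_state ~ ref_group,
        other_state == "-" & obs == "-" ~ setdiff(c("a", "b"), ref_group),
        obs == other_state ~ setdiff(c("a", "b"), ref_group),
        TRUE ~ NA_character_
      )
      tibble::tibble(
        candidate = ci, column = col, kind = s$kind[k],
        state_a = s$state_a[k], state_b = s$state_b[k],
        observed = obs,
        vote = dplyr::if_else(is.na(vote), NA_character_,
          dplyr::if_else(vote == "a", lev[1], lev[2])
        )
      )
    })
  })
  if (!nrow(evidence)) {
    stop("query matches no candidate window above the identity floor", call. = FALSE)
  }
  votes <- unique(stats::na.omit(evidence$vote))
  call <- if (length(votes) == 1L) votes else "ambiguous"
  list(call = call, evidence = evidence)
}
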