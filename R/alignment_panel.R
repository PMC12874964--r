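#' Two-group aligned sequence panel
#'
#' Container for an aligned multi-sequence panel partitioned into two species
#' groups (e.g. plastome accessions of two closely related taxa). Sequences are
#' stored as a character matrix (rows = accessions, columns = alignment
#' columns) over the alphabet `A, C, G, T, -, N`.
#'
#' @param sequences named character vector of equal-length aligned sequences,
#'   or a character matrix of single characters.
#' @param groups character vector of group labels, one per sequence; exactly
#'   two distinct labels.
#' @param ids accession identifiers; defaults to the names of `sequences`.
#' @return an object of class `alignment_panel`.
#' @export
alignment_panel <- function(sequences, groups, ids = NULL) {
  if (is.matrix(sequences)) {
    mat <- sequences
    ids <- ids %||% rownames(mat) %||% paste0("seq", seq_len(nrow(mat)))
  } else {
    ids <- ids %||% names(sequences) %||% paste0("seq", seq_along(sequences))
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) stop("all sequences must have equal length", call. = FALSE)
    mat <- do.call(rbind, strsplit(toupper(unname(sequences)), ""))
  }
  if (length(groups) != nrow(mat)) stop("one group label per sequence required", call. = FALSE)
  groups <- as.character(groups)
  if (length(unique(groups)) != 2L) stop("exactly two groups required", call. = FALSE)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad)) stop("unexpected characters in alignment: ", paste(bad, collapse = " "), call. = FALSE)
  rownames(mat) <- ids
  structure(list(mat = mat, groups = groups, ids = ids), class = "alignment_panel")
}

#' @export
print.alignment_panel <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf(
    "<alignment_panel> %d sequences x %d columns (%s)\n",
    nrow(x$mat), ncol(x$mat),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.alignment_panel <- function(x) dim(x$mat)

group_levels <- function(panel) sort(unique(panel$groups))

#' Read an aligned FASTA file as a two-group panel
#'
#' Group labels are parsed from the record identifier prefix before `|`
#' (e.g. `Pc|MK123456`), or taken from a sidecar table of `id -> group`.
#'
#' @param path aligned FASTA file.
#' @param groups optional data frame with columns `id` and `group` overriding
#'   prefix parsing.
#' @return an [alignment_panel()].
#' @export
read_alignment <- function(path, groups = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- toupper(as.character(seqs))
  if (is.null(groups)) {
    grp <- sub("\\|.*$", "", ids)
  } else {
    grp <- groups$group[match(ids, groups$id)]
    if (anyNA(grp)) stop("sidecar table misses some ids", call. = FALSE)
  }
  alignment_panel(stats::setNames(chars, ids), groups = grp)
}

#' Write a panel as aligned FASTA
#'
#' Record identifiers carry the group as a `group|id` prefix so the file
#' round-trips through [read_alignment()].
#'
#' @param panel an [alignment_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(panel, path) {
  seqs <- apply(panel$mat, 1, paste, collapse = "")
  ids <- ifelse(grepl("\\|", panel$ids), panel$ids, paste(panel$groups, panel$ids, sep = "|"))
  set <- Biostrings::BStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
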