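# A small hand-built two-group panel with known variability:
# - column 10: diagnostic SNP (A fixed in group A, T fixed in group B)
# - columns 20-22: diagnostic 3-column deletion in group B
# - column 30: parsimony-informative but NOT diagnostic (both states occur
#   within group A)
# - column 40: singleton substitution (not parsimony-informative)
hand_panel <- function() {
  base <- strrep("ACGT", 15) # 60 columns, identical backbone
  rows <- rep(base, 8)
  put <- function(s, i, ch) {
    substr(s, i, i + nchar(ch) - 1L) <- ch
    s
  }
  for (i in 1:4) rows[i] <- put(rows[i], 10, "A")
  for (i in 5:8) rows[i] <- put(rows[i], 10, "T")
  for (i in 5:8) rows[i] <- put(rows[i], 20, "---")
  rows[1] <- put(rows[1], 30, "T") # backbone col 30 is C
  rows[2] <- put(rows[2], 30, "T")
  rows[5] <- put(rows[5], 30, "T")
  rows[6] <- put(rows[6], 30, "T")
  rows[3] <- put(rows[3], 40, "G")
  alignment_panel(rows, groups = rep(c("A", "B"), each = 4))
}

test_that("window statistics count informative sites and indel events", {
  p <- hand_panel()
  ws <- window_stats(p, window = 30)
  expect_equal(ws$start, c(1, 31))
  expect_equal(ws$end, c(30, 60))
  # window 1 holds the diagnostic SNP (col 10) and the PI column 30;
  # backbone columns are invariant
  expect_equal(ws$n_pi_sites, c(2, 0))
  # one deduplicated gap run (cols 20-22, shared by all of group B)
  expect_equal(ws$n_indels, c(1, 0))
  # gap-free alignments work and report zero indels
  clean <- alignment_panel(rep(strrep("ACGT", 5), 4), groups = c("A", "A", "B", "B"))
  ws0 <- window_stats(clean, window = 20)
  expect_equal(ws0$n_indels, 0L)
})

test_that("diagnostic sites are exactly the fixed, differing columns", {
  p <- hand_panel()
  sites <- find_diagnostic_sites(p)
  # SNP at 10; the 3-column deletion collapses to its run start at 20
  expect_equal(sites$column, c(10L, 20L))
  expect_equal(sites$kind, c("SNP", "indel"))
  expect_equal(sites$state_a[1], "A")
  expect_equal(sites$state_b[1], "T")
  expect_equal(sites$state_b[2], "-")
})

test_that("max_missing tolerates Ns without inventing diagnostics", {
  p <- hand_panel()
  # blank one group-A observation of the diagnostic SNP
  p$mat[2, 10] <- "N"
  strict <- find_diagnostic_sites(p, max_missing = 0)
  lenient <- find_diagnostic_sites(p, max_missing = 1)
  expect_false(10 %in% strict$column)
  expect_true(10 %in% lenient$column)
})

test_that("candidates centre on diagnostic sites with conserved flanks", {
  aln <- simulate_alignment(
    n_a = 8, n_b = 10, length = 1500,
    n_diagnostic_snps = 3, n_diagnostic_indels = 1,
    within_group_poly_rate = 0, seed = 81
  )
  sites <- find_diagnostic_sites(aln)
  cands <- design_candidates(aln, sites, target_len = 200, flank_len = 20)
  expect_gt(nrow(cands), 0)
  expect_true(all(cands$end - cands$start + 1 == 200))
  expect_true(all(cands$flank_left == 1 & cands$flank_right == 1))
  # every candidate window really contains its claimed sites
  for (i in seq_len(nrow(cands))) {
    cols <- cands$site_columns[[i]]
    expect_true(all(cols >= cands$start[i] & cols <= cands$end[i]))
  }
})

test_that("classification calls the right group and flags poor queries", {
  aln <- simulate_alignment(
    n_a = 8, n_b = 10, length = 1500,
    n_diagnostic_snps = 3, n_diagnostic_indels = 1,
    within_group_poly_rate = 0, seed = 82
  )
  sites <- find_diagnostic_sites(aln)
  cands <- design_candidates(aln, sites, target_len = 200, flank_len = 20)
  row_a <- which(aln$groups == "A")[1]
  row_b <- which(aln$groups == "B")[1]
  qa <- paste(aln$mat[row_a, ], collapse = "")
  qb <- paste(aln$mat[row_b, ], collapse = "")
  ra <- classify_sample(qa, cands, aln, sites)
  rb <- classify_sample(qb, cands, aln, sites)
  expect_equal(ra$call, "A")
  expect_equal(rb$call, "B")
  # a query too short to cover any window yields no evidence
  expect_error(classify_sample("ACGTACGT", cands, aln, sites), "identity floor")
})
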