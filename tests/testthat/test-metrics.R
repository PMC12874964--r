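test_that("compute_metrics handles hand-worked cases exactly", {
  # perfectly separated: AUC 1, TSS 1 at the smallest separating threshold
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$roc_auc, 1)
  expect_equal(m$tss, 1)
  expect_equal(m$best_threshold, 0.21)

  # perfectly anti-separated: AUC 0
  m <- compute_metrics(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(m$roc_auc, 0)

  # all scores tied: every pair counts 1/2
  m <- compute_metrics(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(m$roc_auc, 0.5)

  # one crossing pair among 2x2: 3 concordant of 4 pairs
  m <- compute_metrics(c(0.7, 0.3, 0.4, 0.1), c(1, 1, 0, 0))
  expect_equal(m$roc_auc, 0.75)
})

test_that("compute_metrics agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:150, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4)) # force both classes
    scores <- round(runif(n), 3)
    got <- compute_metrics(scores, labels)
    ref <- suppressMessages(
      pROC::auc(pROC::roc(labels, scores, direction = "<", quiet = TRUE))
    )
    expect_equal(got$roc_auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("TSS equals sensitivity + specificity - 1 at the reported threshold", {
  set.seed(42)
  scores <- runif(80)
  labels <- rbinom(80, 1, 0.5)
  labels[1:2] <- c(0, 1)
  m <- compute_metrics(scores, labels)
  expect_equal(m$tss, m$sensitivity + m$specificity - 1)
  sens <- mean(scores[labels == 1] >= m$best_threshold)
  spec <- mean(scores[labels == 0] < m$best_threshold)
  expect_equal(m$sensitivity, sens)
  expect_equal(m$specificity, spec)
})

test_that("compute_metrics rejects degenerate inputs", {
  expect_error(compute_metrics(c(0.1, 0.9), c(1, 1)), "class")
  expect_error(compute_metrics(c(0.1, 0.9), c(0, 0)), "class")
  expect_error(compute_metrics(c(0.1), c(1, 0)), "length")
})
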