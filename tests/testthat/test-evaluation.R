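sites_df <- function(pos, contig = "ctg", strand = "+")
  data.frame(contig = contig, position = as.integer(pos), strand = strand,
             stringsAsFactors = FALSE)

test_that("shift-window matching follows the worked examples", {
  m <- match_with_shift(sites_df(10), sites_df(14), window = 4)
  expect_equal(m$correct_preds, 1)
  expect_equal(m$detected_truths, 1)

  m <- match_with_shift(sites_df(10), sites_df(15), window = 4)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 1)

  m <- match_with_shift(sites_df(c(10, 11)), sites_df(12), window = 4)
  s <- prf1(m)
  expect_equal(unname(s["precision"]), 1)
  expect_equal(unname(s["recall"]), 1)
})

test_that("matching respects contig and strand and is monotone in window", {
  pred <- sites_df(10, strand = "-")
  expect_equal(match_with_shift(pred, sites_df(10), window = 4)$tp, 0)
  expect_equal(match_with_shift(pred, sites_df(10, contig = "other",
                                               strand = "-"),
                                window = 4)$tp, 0)
  set.seed(41)
  for (i in 1:10) {
    pred <- sites_df(sample(0:100, 15))
    truth <- sites_df(sample(0:100, 10))
    prev <- NULL
    for (w in c(0, 2, 4, 8)) {
      m <- match_with_shift(pred, truth, window = w)
      if (w == 0)
        expect_equal(m$correct_preds,
                     sum(pred$position %in% truth$position))
      if (!is.null(prev)) {
        expect_gte(m$correct_preds, prev$correct_preds)
        expect_gte(m$detected_truths, prev$detected_truths)
      }
      prev <- m
    }
  }
})

test_that("true negatives count unscored universe sites away from truth", {
  universe <- sites_df(0:20)
  pred <- sites_df(c(3, 15))
  truth <- sites_df(3)
  m <- match_with_shift(pred, truth, window = 1, universe = universe)
  # truth-adjacent: 2,3,4; called-adjacent: 2,3,4,14,15,16 -> tn = 21-6
  expect_equal(m$tn, 15)
})

test_that("precision/recall/F1 define 0/0 as 0", {
  m <- list(correct_preds = 1, total_preds = 2, detected_truths = 1,
            total_truths = 2)
  expect_equal(prf1(m), c(precision = 0.5, recall = 0.5, f1 = 0.5))
  m0 <- list(correct_preds = 0, total_preds = 0, detected_truths = 0,
             total_truths = 5)
  expect_equal(prf1(m0), c(precision = 0, recall = 0, f1 = 0))
  mp <- list(correct_preds = 3, total_preds = 3, detected_truths = 4,
             total_truths = 4)
  expect_equal(prf1(mp), c(precision = 1, recall = 1, f1 = 1))
})

test_that("ROC-AUC handles the worked examples and rejects one-class input", {
  expect_equal(roc_auc(c(0.9, 0.1), c(1, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(1, 0), 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.8, 0.6, 0.4), c(1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), class = "nanodiff_param_error")
})

test_that("trapezoidal AUC equals the pairwise-concordance rank statistic", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels))
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  }
})

test_that("trapezoidal AUC agrees with pROC on a continuous instance", {
  set.seed(43)
  scores <- rnorm(60)
  labels <- as.integer(scores + rnorm(60) > 0)
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("region intersection uses the min rule and is symmetric", {
  A <- data.frame(contig = "c", start = 0L, end = 100L, strand = "+")
  B <- data.frame(contig = "c", start = c(10L, 30L), end = c(20L, 40L),
                  strand = "+")
  expect_equal(region_intersection_count(A, B), 1)
  expect_equal(region_intersection_count(B, A), 1)
  one <- data.frame(contig = "c", start = 5L, end = 9L, strand = "+")
  expect_equal(region_intersection_count(one, one), 1)
  disjoint <- data.frame(contig = "c", start = 200L, end = 300L,
                         strand = "+")
  expect_equal(region_intersection_count(A, disjoint), 0)

  set.seed(44)
  for (i in 1:20) {
    rand_regions <- function() {
      s <- sample(0:200, sample(1:12, 1))
      data.frame(contig = sample(c("c1", "c2"), length(s), replace = TRUE),
                 start = s, end = s + sample(1:30, length(s), replace = TRUE),
                 strand = sample(c("+", "-"), length(s), replace = TRUE))
    }
    A <- rand_regions(); B <- rand_regions()
    expect_equal(region_intersection_count(A, B),
                 oracle_region_intersection(A, B))
    expect_equal(region_intersection_count(A, B),
                 region_intersection_count(B, A))
  }
})

test_that("Phred conversion matches -log10(1 - accuracy) with a cap at 1", {
  expect_equal(as.numeric(phred_from_accuracy(0.9)), 1)
  expect_equal(as.numeric(phred_from_accuracy(0.99)), 2)
  p <- phred_from_accuracy(1)
  expect_equal(as.numeric(p), 60)
  expect_true(attr(p, "capped"))
  expect_error(phred_from_accuracy(1.1), class = "nanodiff_param_error")
  expect_error(phred_from_accuracy(-0.1), class = "nanodiff_param_error")
})

test_that("CPM scales counts to parts per million", {
  expect_equal(cpm(c(1, 1, 2)), c(250000, 250000, 500000))
  expect_equal(cpm(5), 1e6)
  expect_equal(cpm(c(0, 10)), c(0, 1e6))
  expect_equal(sum(cpm(runif(20))), 1e6)
  expect_error(cpm(c(0, 0)), class = "nanodiff_param_error")
  expect_error(cpm(c(-1, 2)), class = "nanodiff_param_error")
})
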