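test_that("identical WT and IVT groups give zero deltas and p-value 1", {
  set.seed(21)
  g <- random_group(40)
  for (m in c("manova", "ks")) {
    rec <- compare_site(g, g, method = m)
    expect_equal(rec$d_mean, 0)
    expect_equal(rec$d_median, 0)
    expect_equal(rec$d_std, 0)
    expect_equal(rec$d_dwell, 0)
    expect_equal(rec$pval, 1)
  }
})

test_that("a clean shift with disjoint supports saturates the K-S test", {
  set.seed(22)
  ivt <- random_group(50)
  ivt$mean <- runif(50, 0, 0.2)
  wt <- ivt
  wt[] <- lapply(wt, function(col) col + 0.5)
  rec <- compare_site(wt, ivt, method = "ks")
  expect_equal(rec$d_mean, 0.5)
  expect_lt(rec$pval, 1e-10)
  # asymptotic K-S tail at D = 1 is the leading series term 2 exp(-2 nm/(n+m))
  expect_equal(rec$pval, 2 * exp(-2 * (50 * 50 / 100) * 1^2),
               tolerance = 1e-6)
})

test_that("balance subsamples to the smaller group and is seed-reproducible", {
  set.seed(23)
  wt <- random_group(100, shift = 0.1)
  ivt <- random_group(50)
  a <- compare_site(wt, ivt, method = "manova", balance = TRUE, seed = 7,
                    contig = "c", position = 42L)
  b <- compare_site(wt, ivt, method = "manova", balance = TRUE, seed = 7,
                    contig = "c", position = 42L)
  expect_identical(a, b)
  expect_equal(a$cov_wt, 100)
  expect_equal(a$cov_ivt, 50)
  c50 <- compare_site(wt, ivt, method = "manova", balance = TRUE, seed = 8,
                      contig = "c", position = 42L)
  expect_false(identical(a$pval, c50$pval))  # different stream, different draw
})

test_that("the closed-form two-group MANOVA matches stats::manova Pillai", {
  set.seed(24)
  for (i in 1:10) {
    n1 <- sample(8:40, 1); n2 <- sample(8:40, 1)
    wt <- random_group(n1, shift = runif(1, 0, 0.5))
    ivt <- random_group(n2)
    rec <- compare_site(wt, ivt, method = "manova")
    Y <- as.matrix(rbind(wt, ivt))
    grp <- factor(rep(c("wt", "ivt"), c(n1, n2)))
    ref <- summary(stats::manova(Y ~ grp), test = "Pillai")$stats
    expect_equal(rec$pval, ref["grp", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("MANOVA with zero variance in every feature degenerates to p = 1", {
  const <- data.frame(mean = rep(1, 10), median = 1, std = 0, dwell = 5)
  rec <- compare_site(const, const, method = "manova")
  expect_equal(rec$pval, 1)
  expect_true(attr(rec, "degenerate"))
})

test_that("the logistic-regression p-value is the df-1 likelihood-ratio test", {
  set.seed(25)
  for (i in 1:5) {
    wt <- random_group(30, shift = runif(1, 0, 0.3))
    ivt <- random_group(25)
    rec <- compare_site(wt, ivt, method = "lr")
    y <- rep(1:0, c(30, 25))
    x <- c(wt$mean, ivt$mean)
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    ref <- stats::anova(fit, test = "Chisq")["x", "Pr(>Chi)"]
    expect_equal(rec$pval, ref, tolerance = 1e-8)
  }
})

test_that("BH adjustment follows the step-up formula and rejects bad input", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "nanodiff_param_error")
  expect_error(bh_adjust(c(-0.1)), class = "nanodiff_param_error")

  set.seed(26)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
  }
})

test_that("swapping WT and IVT negates deltas and keeps p-values", {
  set.seed(27)
  for (m in c("manova", "lr", "ks")) {
    wt <- random_group(30, shift = 0.2)
    ivt <- random_group(30)
    a <- compare_site(wt, ivt, method = m)
    b <- compare_site(ivt, wt, method = m)
    expect_equal(c(a$d_mean, a$d_median, a$d_std, a$d_dwell),
                 -c(b$d_mean, b$d_median, b$d_std, b$d_dwell))
    expect_equal(a$pval, b$pval, tolerance = 1e-12)
  }
})

test_that("compare_features reproduces compare_site at every shared site", {
  sim <- simulate_pair(sim_config(contig_length = 40, n_mod_sites = 1,
                                  coverage_wt = 25, coverage_ivt = 15,
                                  seed = 3))
  for (m in c("manova", "ks")) {
    cmp <- compare_features(sim$wt, sim$ivt, method = m, balance = TRUE,
                            seed = 5)
    expect_equal(nrow(cmp), 40)
    for (p in c(0L, 17L, 39L)) {
      rec <- compare_site(sim$wt[sim$wt$position == p, ],
                          sim$ivt[sim$ivt$position == p, ],
                          method = m, balance = TRUE, seed = 5,
                          contig = "synctg", position = p)
      row <- cmp[cmp$position == p, ]
      expect_equal(row$pval, rec$pval)
      expect_equal(row$d_mean, rec$d_mean)
      expect_equal(row$cov_wt, rec$cov_wt)
    }
    expect_equal(cmp$padj, bh_adjust(cmp$pval))
    expect_true(all(cmp$padj >= cmp$pval))
  }
})

test_that("sites present in only one sample are not tested", {
  wt <- make_features(position = c(1, 2, 2, 3), mean = rnorm(4))
  ivt <- make_features(position = c(2, 2, 4), mean = rnorm(3))
  cmp <- compare_features(wt, ivt, method = "ks")
  expect_equal(cmp$position, 2L)
  expect_equal(cmp$cov_wt, 2L)
  expect_equal(cmp$cov_ivt, 2L)
})
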