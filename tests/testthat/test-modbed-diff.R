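bedmethyl_line <- function(contig = "ecK12", pos = 100, code = "17802",
                           strand = "+", cov = 30, frac = 80) {
  sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t255,0,0\t%d\t%.2f\t%d\t%d\t0\t0\t0\t0\t0",
          contig, pos, pos + 1, code, cov, strand, pos, pos + 1, cov, frac,
          round(cov * frac / 100), cov - round(cov * frac / 100))
}

write_bm <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("bedMethyl rows parse coverage and fraction modified", {
  rec <- read_bedmethyl(write_bm(bedmethyl_line(cov = 30, frac = 80)))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$n_valid_cov, 30)
  expect_equal(rec$fraction_modified, 80)
  expect_equal(rec$position, 100)
  expect_equal(rec$mod_code, "17802")
})

test_that("an unparseable bedMethyl file is a format error; bad lines are counted", {
  expect_error(read_bedmethyl(write_bm(character(0))),
               class = "nanodiff_param_error")
  expect_error(read_bedmethyl(write_bm("just one field")),
               class = "nanodiff_param_error")
  path <- write_bm(c(bedmethyl_line(), "truncated\tline"))
  expect_message(rec <- read_bedmethyl(path), "skipped 1")
  expect_equal(nrow(rec), 1)
})

test_that("mixed modification codes keep their identity through the join", {
  wt <- read_bedmethyl(write_bm(c(bedmethyl_line(code = "a", frac = 70),
                                  bedmethyl_line(code = "17802", frac = 90))))
  expect_setequal(wt$mod_code, c("a", "17802"))
  ivt <- read_bedmethyl(write_bm(c(bedmethyl_line(code = "a", frac = 10),
                                   bedmethyl_line(code = "17802", frac = 5))))
  d <- fraction_diff(wt, ivt)
  expect_equal(d$diff[d$mod_code == "a"], 60)
  expect_equal(d$diff[d$mod_code == "17802"], 85)
})

test_that("differential sites need adequate coverage in both samples", {
  wt <- read_bedmethyl(write_bm(bedmethyl_line(cov = 30, frac = 80)))
  ivt <- read_bedmethyl(write_bm(bedmethyl_line(cov = 25, frac = 10)))
  d <- fraction_diff(wt, ivt, min_valid_cov = 20)
  expect_equal(d$diff, 70)

  low <- read_bedmethyl(write_bm(bedmethyl_line(cov = 15, frac = 80)))
  expect_equal(nrow(fraction_diff(low, ivt)), 0)
  # coverage must be strictly greater than the threshold
  edge <- read_bedmethyl(write_bm(bedmethyl_line(cov = 20, frac = 80)))
  expect_equal(nrow(fraction_diff(edge, ivt)), 0)
})

test_that("sites present in only one sample are excluded from the join", {
  wt <- read_bedmethyl(write_bm(c(bedmethyl_line(pos = 100),
                                  bedmethyl_line(pos = 200))))
  ivt <- read_bedmethyl(write_bm(bedmethyl_line(pos = 100, frac = 10)))
  d <- fraction_diff(wt, ivt)
  expect_equal(d$position, 100)
})

test_that("fraction differences are antisymmetric under sample swap", {
  set.seed(51)
  mk <- function(fracs) read_bedmethyl(write_bm(vapply(seq_along(fracs),
    function(i) bedmethyl_line(pos = i * 10, frac = fracs[i]),
    character(1))))
  wt <- mk(round(runif(8, 0, 100), 2))
  ivt <- mk(round(runif(8, 0, 100), 2))
  expect_equal(fraction_diff(wt, ivt)$diff, -fraction_diff(ivt, wt)$diff)
})

test_that("high-confidence filtering is a monotone subset by threshold", {
  d <- data.frame(contig = "c", position = 1:5, strand = "+",
                  mod_code = "17802", frac_wt = c(80, 45, 36, 90, 20),
                  frac_ivt = c(10, 10, 1, 35, 0),
                  diff = c(70, 35, 35, 55, 20))
  expect_equal(high_confidence(d, 35)$diff, c(70, 35, 35, 55))
  expect_equal(high_confidence(d, 50)$diff, c(70, 55))
  expect_true(all(high_confidence(d, 50)$position %in%
                    high_confidence(d, 35)$position))
})

test_that("sites are assigned to 100-bp-expanded annotation features", {
  ann <- data.frame(contig = "c", start = c(500L, 50L, 480L),
                    end = c(1500L, 200L, 1600L),
                    gene = c("geneA", "geneB", "geneC"),
                    strand = c("+", "+", "+"),
                    class = c("CDS", "tRNA", "rRNA"))
  sites <- data.frame(contig = "c", position = c(450L, 250L, 5000L, 450L),
                      strand = c("+", "+", "+", "-"))
  out <- assign_features(sites, ann, expand = 100)
  # 450 on + overlaps expanded geneA [400,1600) and geneC [380,1700):
  # rRNA outranks CDS for the primary label
  expect_equal(out$feature, c("rRNA", "tRNA", "others", "others"))
  expect_equal(out$genes[1], "geneA,geneC")
  # expansion of geneB is clipped at the contig start
  clip <- assign_features(data.frame(contig = "c", position = 0L,
                                     strand = "+"), ann, expand = 100)
  expect_equal(clip$feature, "tRNA")
})
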