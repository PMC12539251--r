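## Seeded generator of paired WT/IVT per-read per-site feature tables with
## planted modification footprints. Used for calibration and testing; it
## emulates normalized current levels and dwell, not raw pore kinetics.

#' Configuration for the paired WT/IVT feature simulator
#'
#' The generator draws a per-position baseline current level once per
#' contig, then simulates per-read per-site features around it. Every read
#' spans the whole contig (a fully covered transcript), so `coverage_*` is
#' both the read count and the per-site coverage. A set of modification
#' sites is planted at evenly spread positions; in the WT sample each read
#' carries the modifications with probability `stoichiometry`, and on a
#' modified read every position within `footprint` bases of a planted site
#' has its mean shifted by `delta_mean` and its expected dwell by
#' `delta_dwell` (modified bases perturb the current of neighbouring
#' positions, which is what shift-window matching has to cope with).
#'
#' @param contig Contig name. Default `"synctg"`.
#' @param contig_length Contig length in bases. Default 10000.
#' @param n_mod_sites Number of planted modification sites. Default 20.
#' @param coverage_wt,coverage_ivt Reads per site. Default 100.
#' @param sigma Between-read SD of the per-site mean, normalized units.
#'   Default 0.3.
#' @param sigma_within Within-read per-sample SD, normalized units,
#'   driving the simulated per-site `std` and the median's extra noise.
#'   Default 1.
#' @param delta_mean Mean-current effect at modified positions,
#'   normalized units. Default 0.5.
#' @param delta_dwell Dwell effect at modified positions, samples.
#'   Default 3.
#' @param footprint Half-width (bases) of the signal footprint around each
#'   planted site. Default 2.
#' @param stoichiometry Fraction of WT reads carrying the modifications,
#'   in `[0, 1]`. Default 1.
#' @param dwell_base_mean Expected dwell per base, raw samples. Default 30
#'   (about 4 kHz sampling at ~130 bases/s translocation).
#' @param seed Integer RNG seed. Default 1.
#' @return A validated list of class `nanodiff_sim_config`.
#' @export
sim_config <- function(contig = "synctg", contig_length = 10000,
                       n_mod_sites = 20, coverage_wt = 100,
                       coverage_ivt = 100, sigma = 0.3, sigma_within = 1,
                       delta_mean = 0.5, delta_dwell = 3, footprint = 2,
                       stoichiometry = 1, dwell_base_mean = 30, seed = 1) {
  cfg <- list(contig = contig, contig_length = as.integer(contig_length),
              n_mod_sites = as.integer(n_mod_sites),
              coverage_wt = as.integer(coverage_wt),
              coverage_ivt = as.integer(coverage_ivt), sigma = sigma,
              sigma_within = sigma_within, delta_mean = delta_mean,
              delta_dwell = delta_dwell, footprint = as.integer(footprint),
              stoichiometry = stoichiometry,
              dwell_base_mean = dwell_base_mean, seed = as.integer(seed))
  if (cfg$contig_length < 1 || cfg$coverage_wt < 1 || cfg$coverage_ivt < 1)
    stop_param("contig_length and coverages must be >= 1")
  if (cfg$n_mod_sites < 0 || cfg$n_mod_sites > cfg$contig_length)
    stop_param("n_mod_sites must be in [0, contig_length]")
  if (!is.numeric(cfg$sigma) || cfg$sigma <= 0)
    stop_param("sigma must be > 0")
  if (cfg$stoichiometry < 0 || cfg$stoichiometry > 1)
    stop_param("stoichiometry must be in [0, 1]")
  if (cfg$footprint < 0) stop_param("footprint must be >= 0")
  if (cfg$dwell_base_mean < 1) stop_param("dwell_base_mean must be >= 1")
  structure(cfg, class = "nanodiff_sim_config")
}

#' Simulate a paired WT/IVT per-read feature table with planted sites
#'
#' Per read and position: `mean ~ Normal(baseline + effect, sigma)` where
#' the effect is `delta_mean` within the footprint of a planted site on a
#' modified WT read and 0 otherwise; `dwell ~ 1 + Poisson(dwell_base_mean
#' - 1 + dwell effect)` so dwell >= 1; `std` is a population SD drawn from
#' the scaled chi distribution implied by `sigma_within` and the dwell;
#' the `median` tracks the mean with only 80% of the modification effect
#' (the median is robust to the subset of perturbed samples inside the
#' dwell window) plus sampling noise `0.75 * sigma_within / sqrt(dwell)`.
#' Identical configurations and seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return List with `wt` and `ivt` feature data.frames (columns of
#'   [read_feature_tsv()]), `truth` (data.frame `contig`, `position`,
#'   `strand`, `mod_type = "synthetic"`), and `config`.
#' @export
simulate_pair <- function(config = sim_config()) {
  if (!inherits(config, "nanodiff_sim_config"))
    stop_param("config must come from sim_config()")
  with_seed(config$seed, {
    L <- config$contig_length
    baseline <- rnorm(L, 0, 1)
    truth_pos <- plant_sites(L, config$n_mod_sites, config$footprint)
    mask <- logical(L)
    for (p in truth_pos)
      mask[(max(0, p - config$footprint):min(L - 1, p + config$footprint)) +
             1L] <- TRUE
    wt_mod <- rbinom(config$coverage_wt, 1, config$stoichiometry) == 1
    wt <- simulate_sample(config, baseline, mask, wt_mod, "wt")
    ivt <- simulate_sample(config, baseline, mask,
                           rep(FALSE, config$coverage_ivt), "ivt")
    truth <- data.frame(contig = rep(config$contig, length(truth_pos)),
                        position = truth_pos,
                        strand = rep("+", length(truth_pos)),
                        mod_type = rep("synthetic", length(truth_pos)),
                        stringsAsFactors = FALSE)
    list(wt = wt, ivt = ivt, truth = truth, config = config)
  })
}

## evenly spread planted sites: one per equal-width bin, away from the
## contig edges by footprint + 4 so merged regions stay on the contig
plant_sites <- function(L, n, footprint) {
  if (n == 0) return(integer(0))
  margin <- footprint + 4L
  bins <- floor(seq(margin, L - 1 - margin, length.out = n + 1))
  pos <- integer(n)
  for (k in seq_len(n)) {
    lo <- bins[k]; hi <- max(lo, bins[k + 1] - 2L * margin)
    pos[k] <- if (hi > lo) lo + sample.int(hi - lo, 1) else lo
  }
  sort(unique(pos))
}

simulate_sample <- function(config, baseline, mask, read_mod, prefix) {
  n <- length(read_mod); L <- config$contig_length
  N <- n * L
  read_idx <- rep(seq_len(n), each = L)
  pos <- rep.int(seq_len(L) - 1L, n)
  affected <- mask[pos + 1] & read_mod[read_idx]
  mu <- baseline[pos + 1] + config$delta_mean * affected
  m <- mu + rnorm(N, 0, config$sigma)
  lambda <- pmax(0, config$dwell_base_mean - 1 +
                   config$delta_dwell * affected)
  dwell <- 1 + rpois(N, lambda)
  std <- ifelse(dwell > 1,
                config$sigma_within * sqrt(rchisq(N, pmax(dwell - 1, 1)) /
                                             dwell),
                0)
  med <- m - 0.2 * config$delta_mean * affected +
    rnorm(N, 0, 0.75 * config$sigma_within / sqrt(dwell))
  data.frame(read_id = sprintf("%s_%05d", prefix, read_idx),
             contig = rep(config$contig, N), position = pos,
             strand = rep("+", N), mean = m, median = med, std = std,
             dwell = as.numeric(dwell), stringsAsFactors = FALSE)
}

#' Write planted truth sites as a BED6 file
#'
#' One single-base interval per site, the modification type in the name
#' column.
#'
#' @param truth Data.frame with `contig`, `position`, `strand` and
#'   optionally `mod_type`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tname\tscore\tstrand", con)
  if (NROW(truth) > 0) {
    name <- if ("mod_type" %in% names(truth)) truth$mod_type else "."
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", truth$contig,
                       as.integer(truth$position),
                       as.integer(truth$position) + 1L, name, truth$strand),
               con)
  }
  invisible(path)
}

#' Expand a feature table into eventalign-style per-event rows
#'
#' For every feature row, `dwell` samples are generated whose mean,
#' population SD and count reproduce the row's `mean`, `std` and `dwell`
#' to within the 1e-6 rounding of the emitted text (the median is only
#' approximate). Samples are emitted on the
#' normalized scale, so re-extraction must use
#' `extract_features(..., normalize = FALSE)`; re-applying the per-read
#' median/MAD normalization would not be invertible site by site.
#'
#' @param features Feature data.frame (see [read_feature_tsv()]).
#' @param path Optional output TSV path; when `NULL` the event table is
#'   returned instead.
#' @param seed Seed for the sample-shape draws. Default 1.
#' @return The event data.frame (columns `contig`, `position`,
#'   `read_name`, `strand`, `samples`), invisibly when written to `path`.
#' @export
write_eventalign_like <- function(features, path = NULL, seed = 1) {
  sample_strings <- with_seed(seed, vapply(seq_len(NROW(features)),
                                           function(i) {
    d <- as.integer(features$dwell[i])
    mu <- features$mean[i]; s <- features$std[i]
    x <- if (d == 1 || s == 0) rep(mu, d) else {
      z <- rnorm(d)
      sz <- sqrt(mean((z - mean(z))^2))
      if (sz == 0) { z <- seq_len(d); sz <- sqrt(mean((z - mean(z))^2)) }
      mu + s * (z - mean(z)) / sz
    }
    paste(sprintf("%.6f", x), collapse = ",")
  }, character(1)))
  out <- data.frame(contig = features$contig, position = features$position,
                    read_name = features$read_id, strand = features$strand,
                    samples = sample_strings, stringsAsFactors = FALSE)
  if (is.null(path)) return(out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
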