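## Calibrated cutoffs, site calling, and merging positive sites into regions.

#' Calling cutoffs for positive sites and region merging
#'
#' Defaults are the cutoffs calibrated on the well-characterised E. coli
#' rRNA modification sites: minimum per-sample coverage of 50 reads, an
#' absolute mean-current difference of 0.18 normalized units, an absolute
#' dwell-time difference of 1 raw sample, and -log10 adjusted p-value of 3
#' (i.e. adjusted p <= 1e-3, the recommended universal MANOVA cutoff).
#' Positive sites closer than `merge_gap` bases are connected and the
#' resulting clusters expanded by `expand` bases on each side.
#'
#' @param min_cov Minimum of WT and IVT coverage, reads. Default 50.
#' @param min_abs_mean Minimum `|d_mean|`, normalized units. Default 0.18.
#' @param min_abs_dwell Minimum `|d_dwell|`, samples. Default 1.
#' @param min_neglog10_padj Minimum `-log10(padj)`. Default 3.
#' @param merge_gap Maximum distance (bases) between successive positive
#'   sites joined into one cluster. Default 4.
#' @param expand Bases added to each side of a cluster. Default 4.
#' @return A list of class `nanodiff_call_params`.
#' @export
call_params <- function(min_cov = 50, min_abs_mean = 0.18, min_abs_dwell = 1,
                        min_neglog10_padj = 3, merge_gap = 4, expand = 4) {
  p <- list(min_cov = min_cov, min_abs_mean = min_abs_mean,
            min_abs_dwell = min_abs_dwell,
            min_neglog10_padj = min_neglog10_padj,
            merge_gap = merge_gap, expand = expand)
  bad <- vapply(p, function(v) !is.numeric(v) || length(v) != 1 || v < 0,
                logical(1))
  if (any(bad))
    stop_param("call parameters must be single non-negative numbers: ",
               paste(names(p)[bad], collapse = ", "))
  structure(p, class = "nanodiff_call_params")
}

#' Select high-confidence positive sites
#'
#' A site is positive iff it passes all four cutoffs:
#' `min(cov_wt, cov_ivt) >= min_cov`, `|d_mean| >= min_abs_mean`,
#' `|d_dwell| >= min_abs_dwell` and `-log10(padj) >= min_neglog10_padj`.
#' Raising any threshold can only remove sites.
#'
#' @param comparison A `nanodiff_comparison` (or data.frame with its
#'   columns, including `padj`).
#' @param params A [call_params()].
#' @return The positive subset of `comparison` rows (plain data.frame).
#' @export
call_sites <- function(comparison, params = call_params()) {
  if (!"padj" %in% names(comparison))
    stop_param("comparison records must carry adjusted p-values (padj)")
  keep <- pmin(comparison$cov_wt, comparison$cov_ivt) >= params$min_cov &
    abs(comparison$d_mean) >= params$min_abs_mean &
    abs(comparison$d_dwell) >= params$min_abs_dwell &
    -log10(pmax(comparison$padj, .Machine$double.xmin)) >=
      params$min_neglog10_padj
  out <- as.data.frame(comparison)[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge positive site positions into expanded regions
#'
#' Successive sites at distance `<= merge_gap` form one cluster; each
#' cluster spanning `[a, b]` becomes the half-open interval
#' `[a - expand, b + expand + 1)`, clipped to `[0, contig_length)`.
#' Expanded intervals that overlap or touch are unioned.
#'
#' @param positions Integer vector of positive site positions (0-based) on
#'   one contig and strand; need not be sorted.
#' @param merge_gap,expand See [call_params()].
#' @param contig_length Upper clip bound for expansion (default unbounded).
#' @return Data.frame with `start`, `end` (0-based half-open) and
#'   `n_sites`, sorted and non-overlapping.
#' @export
#' @examples
#' merge_sites(c(100, 103, 120))  # [96,108) and [116,125)
merge_sites <- function(positions, merge_gap = 4, expand = 4,
                        contig_length = Inf) {
  if (length(positions) == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_sites = integer()))
  pos <- sort(unique(as.integer(positions)))
  new_cluster <- c(TRUE, diff(pos) > merge_gap)
  firsts <- which(new_cluster)
  lasts <- c(firsts[-1] - 1L, length(pos))
  start <- pmax(0, pos[firsts] - expand)
  end <- pmin(contig_length, pos[lasts] + expand + 1)
  n_sites <- lasts - firsts + 1L
  ## union expanded intervals that overlap or touch
  merged_start <- integer(0); merged_end <- integer(0); merged_n <- integer(0)
  for (k in seq_along(start)) {
    if (k > 1 && start[k] <= merged_end[length(merged_end)]) {
      last <- length(merged_end)
      merged_end[last] <- max(merged_end[last], end[k])
      merged_n[last] <- merged_n[last] + n_sites[k]
    } else {
      merged_start <- c(merged_start, start[k])
      merged_end <- c(merged_end, end[k])
      merged_n <- c(merged_n, n_sites[k])
    }
  }
  data.frame(start = as.integer(merged_start), end = as.integer(merged_end),
             n_sites = merged_n)
}

#' Call positive sites and merge them into regions
#'
#' Runs [call_sites()] then [merge_sites()] per contig and strand (strands
#' never merge), recording for each region the number of merged positive
#' sites and the largest absolute mean difference among them.
#'
#' @inheritParams call_sites
#' @param contig_lengths Optional named vector clipping expansion at
#'   contig ends.
#' @return An object of class `nanodiff_regions`: data.frame with columns
#'   `contig`, `start`, `end`, `strand`, `n_sites`, `max_abs_d_mean`,
#'   sorted by (contig, start); attribute `positive_sites` holds the
#'   per-site table.
#' @export
call_regions <- function(comparison, params = call_params(),
                         contig_lengths = NULL) {
  sites <- call_sites(comparison, params)
  groups <- split(seq_len(nrow(sites)),
                  list(contig = sites$contig, strand = sites$strand),
                  drop = TRUE)
  out <- lapply(groups, function(i) {
    contig <- sites$contig[i[1]]; strand <- sites$strand[i[1]]
    len <- if (!is.null(contig_lengths) && contig %in% names(contig_lengths))
      contig_lengths[[contig]] else Inf
    reg <- merge_sites(sites$position[i], merge_gap = params$merge_gap,
                       expand = params$expand, contig_length = len)
    if (nrow(reg) == 0) return(NULL)
    reg$contig <- contig
    reg$strand <- strand
    reg$max_abs_d_mean <- vapply(seq_len(nrow(reg)), function(r) {
      inside <- sites$position[i] >= reg$start[r] &
        sites$position[i] < reg$end[r]
      max(abs(sites$d_mean[i][inside]))
    }, numeric(1))
    reg
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(), n_sites = integer(),
                      contig = character(), strand = character(),
                      max_abs_d_mean = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start, out$strand),
             c("contig", "start", "end", "strand", "n_sites",
               "max_abs_d_mean")]
  rownames(out) <- NULL
  structure(out, class = c("nanodiff_regions", "data.frame"),
            positive_sites = sites, params = params)
}

#' @export
print.nanodiff_regions <- function(x, ...) {
  sites <- attr(x, "positive_sites")
  cat(sprintf("nanodiff regions: %d region(s) from %d positive site(s)\n",
              nrow(x), if (is.null(sites)) NA_integer_ else nrow(sites)))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more region(s)\n")
  invisible(x)
}

#' Write regions as BED6
#'
#' One line per region: chrom, start, end, `region_<k>`,
#' `score = round(1000 * min(1, max_abs_d_mean))`, strand, sorted by
#' (chrom, start). A comment header names the columns; an empty region set
#' yields a header-only file.
#'
#' @param regions A `nanodiff_regions` (or data.frame with its columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(regions) > 0) {
    o <- order(regions$contig, regions$start)
    r <- regions[o, , drop = FALSE]
    score <- if ("max_abs_d_mean" %in% names(r))
      round(1000 * pmin(1, r$max_abs_d_mean)) else rep(0L, nrow(r))
    writeLines(sprintf("%s\t%d\t%d\tregion_%d\t%d\t%s", r$contig,
                       as.integer(r$start), as.integer(r$end),
                       seq_len(nrow(r)), as.integer(score), r$strand), con)
  }
  invisible(path)
}

#' Read a BED file of sites or regions
#'
#' Accepts BED3-BED6 (plus extra columns, kept as `extra1`, ...). For
#' single-base records the `position` column equals `start`. The name
#' column is returned as `name` (used for modification-type labels in
#' ground-truth BEDs).
#'
#' @param path BED file path; `#`/`track`/`browser` lines are skipped.
#' @return Data.frame with `contig`, `start`, `end`, `position`, `name`,
#'   `score`, `strand` (missing columns filled with defaults).
#' @export
read_bed_sites <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), position = integer(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(parts))
  if (ncol_min < 3) stop_param("BED lines need at least 3 columns")
  get <- function(k, default) vapply(parts, function(p)
    if (length(p) >= k) p[[k]] else default, character(1))
  out <- data.frame(contig = get(1, ""),
                    start = as.integer(get(2, "0")),
                    end = as.integer(get(3, "0")),
                    name = get(4, "."),
                    score = suppressWarnings(as.numeric(get(5, "0"))),
                    strand = get(6, "+"), stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  out$position <- out$start
  out[c("contig", "start", "end", "position", "name", "score", "strand")]
}
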