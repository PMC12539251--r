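## Differential filter for modified-basecalling bedMethyl (Modbed) output:
## modification basecallers produce many false positives on bacterial RNA;
## subtracting the IVT control's fraction-modified removes most of them.

#' Read a bedMethyl (modkit pileup dialect) file
#'
#' Parses the 9+2 column bedMethyl produced by `modkit pileup`: chrom,
#' start, end, modification code, score, strand, thickStart, thickEnd,
#' color, Nvalid_cov, fraction modified (percent), ... Only the columns
#' nanodiff uses are kept. Malformed lines are counted and skipped.
#'
#' @param path File path.
#' @return Data.frame with `contig`, `position` (0-based), `strand`,
#'   `mod_code`, `n_valid_cov`, `fraction_modified` (percent in
#'   `[0, 100]`); attribute `n_skipped`. A file with no parseable line is
#'   a format error.
#' @export
read_bedmethyl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parse1 <- function(p) {
    if (length(p) < 11) return(NULL)
    pos <- suppressWarnings(as.integer(p[[2]]))
    cov <- suppressWarnings(as.numeric(p[[10]]))
    frac <- suppressWarnings(as.numeric(p[[11]]))
    if (anyNA(c(pos, cov, frac)) || frac < 0 || frac > 100) return(NULL)
    list(contig = p[[1]], position = pos, strand = p[[6]],
         mod_code = p[[4]], n_valid_cov = cov, fraction_modified = frac)
  }
  rec <- lapply(parts, parse1)
  ok <- !vapply(rec, is.null, logical(1))
  if (!any(ok))
    stop_param("no parseable bedMethyl lines in ", path)
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message("read_bedmethyl: skipped ", n_skipped, " malformed line(s)")
  out <- do.call(rbind, lapply(rec[ok], as.data.frame))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' WT - IVT difference in fraction modified per shared site
#'
#' Joins the two tables on (contig, position, strand, modification code),
#' keeps sites with valid coverage strictly above `min_valid_cov` in BOTH
#' samples, and reports `diff = frac_wt - frac_ivt` in percent. Sites
#' present in only one sample are excluded.
#'
#' @param wt,ivt Data.frames from [read_bedmethyl()].
#' @param min_valid_cov Coverage must exceed this in both samples.
#'   Default 20.
#' @return Data.frame `contig`, `position`, `strand`, `mod_code`,
#'   `frac_wt`, `frac_ivt`, `diff`.
#' @export
fraction_diff <- function(wt, ivt, min_valid_cov = 20) {
  wt <- wt[wt$n_valid_cov > min_valid_cov, , drop = FALSE]
  ivt <- ivt[ivt$n_valid_cov > min_valid_cov, , drop = FALSE]
  key_wt <- paste(wt$contig, wt$position, wt$strand, wt$mod_code, sep = "\r")
  key_ivt <- paste(ivt$contig, ivt$position, ivt$strand, ivt$mod_code,
                   sep = "\r")
  m <- match(key_wt, key_ivt)
  keep <- !is.na(m)
  out <- data.frame(contig = wt$contig[keep], position = wt$position[keep],
                    strand = wt$strand[keep], mod_code = wt$mod_code[keep],
                    frac_wt = wt$fraction_modified[keep],
                    frac_ivt = ivt$fraction_modified[m[keep]],
                    stringsAsFactors = FALSE)
  out$diff <- out$frac_wt - out$frac_ivt
  o <- order(out$contig, out$position, out$strand, out$mod_code)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep high-confidence differential sites
#'
#' Retains sites whose WT - IVT fraction-modified difference is at least
#' `min_diff` percent. A threshold of 35 recovers the well-characterised
#' pseudouridine rRNA sites; 50 is used for the m5C and A-to-I callers
#' where no single validated cutoff exists.
#'
#' @param diffs Data.frame from [fraction_diff()].
#' @param min_diff Minimum difference in percent. Default 35.
#' @return The retained subset (always a subset of the input; monotone in
#'   `min_diff`).
#' @export
high_confidence <- function(diffs, min_diff = 35) {
  if (min_diff < 0) stop_param("min_diff must be >= 0")
  out <- diffs[diffs$diff >= min_diff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene annotation BED
#'
#' BED6 with the gene name in column 4 and an optional 7th column giving
#' the feature class (`tRNA`, `rRNA`, `ncRNA`, `CDS`); absent classes
#' default to `CDS` (bacterial annotations carry coding sequences only).
#'
#' @param path BED file path.
#' @return Data.frame `contig`, `start`, `end`, `gene`, `strand`, `class`.
#' @export
read_gene_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(k, default) vapply(parts, function(p)
    if (length(p) >= k) p[[k]] else default, character(1))
  data.frame(contig = get(1, ""), start = as.integer(get(2, "0")),
             end = as.integer(get(3, "0")), gene = get(4, "."),
             strand = get(6, "+"), class = get(7, "CDS"),
             stringsAsFactors = FALSE)
}

#' Assign differential sites to expanded annotation features
#'
#' Bacterial GFF-derived annotations lack UTRs, so each gene interval is
#' expanded by `expand` bases on both sides (clipped at 0) before a
#' strand-aware overlap test. Sites overlapping several expanded genes
#' keep all labels; the `feature` column carries a primary label chosen by
#' the precedence tRNA > rRNA > ncRNA > CDS. Sites overlapping nothing are
#' labelled `others`.
#'
#' @param sites Data.frame with `contig`, `position`, `strand` (e.g. from
#'   [high_confidence()]).
#' @param annotation Data.frame from [read_gene_bed()].
#' @param expand Bases added on each side of every gene. Default 100.
#' @return `sites` with added columns `feature` (primary class), `genes`
#'   (comma-separated overlapping gene names, `.` if none) and `classes`
#'   (comma-separated classes of those genes).
#' @export
assign_features <- function(sites, annotation, expand = 100) {
  precedence <- c("tRNA", "rRNA", "ncRNA", "CDS")
  a_start <- pmax(0, annotation$start - expand)
  a_end <- annotation$end + expand
  n <- NROW(sites)
  feature <- character(n); genes <- character(n); classes <- character(n)
  for (i in seq_len(n)) {
    hit <- annotation$contig == sites$contig[i] &
      annotation$strand == sites$strand[i] &
      a_start <= sites$position[i] & sites$position[i] < a_end
    if (!any(hit)) {
      feature[i] <- "others"; genes[i] <- "."; classes[i] <- "."
    } else {
      cls <- annotation$class[hit]
      rank <- match(cls, precedence)
      rank[is.na(rank)] <- length(precedence) + 1
      feature[i] <- cls[which.min(rank)]
      genes[i] <- paste(annotation$gene[hit], collapse = ",")
      classes[i] <- paste(cls, collapse = ",")
    }
  }
  out <- as.data.frame(sites)
  out$feature <- feature
  out$genes <- genes
  out$classes <- classes
  out
}
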