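## Per-read signal normalization and per-site feature computation.

#' Normalize a read's raw current with median shift and MAD scale
#'
#' All raw samples mapped for one read are normalized as
#' `(x - median(x)) / mad(x)` where `mad` is the unscaled median absolute
#' deviation (no 1.4826 consistency factor), then clipped to
#' `[-clip, +clip]`: values beyond the bound are replaced by the bound.
#' Downstream effect-size cutoffs (e.g. the 0.18 mean-difference default in
#' [call_params()]) are defined on this normalized scale.
#'
#' @param samples Numeric vector of raw current samples (pA) for one read.
#' @param clip Positive clipping bound in normalized units. Default 5.
#' @return A list with `normalized` (numeric vector) and `params` (list
#'   with `shift`, `scale`, `clip`).
#' @section Degenerate reads: a read whose MAD is zero (constant signal)
#'   cannot be scale-normalized; a condition of class
#'   `nanodiff_degenerate_read` is signalled and callers skip the read.
#' @export
#' @examples
#' normalize_read(c(1, 2, 3, 4, 5))$normalized  # -2 -1 0 1 2
normalize_read <- function(samples, clip = 5) {
  if (length(samples) == 0) stop_param("samples must be non-empty")
  if (!is.numeric(clip) || length(clip) != 1 || clip <= 0)
    stop_param("clip must be a single positive number")
  shift <- median(samples)
  scale <- median(abs(samples - shift))
  if (scale == 0)
    stop(structure(class = c("nanodiff_degenerate_read", "error", "condition"),
                   list(message = "degenerate read: MAD of raw samples is 0",
                        call = sys.call())))
  x <- (samples - shift) / scale
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  list(normalized = x, params = list(shift = shift, scale = scale, clip = clip))
}

#' Summarise the normalized samples of one read at one reference base
#'
#' @param samples Non-empty numeric vector of normalized current samples
#'   assigned to a single (read, reference base) pair.
#' @return Named numeric vector with `mean`, `median`, `std` (population
#'   standard deviation) and `dwell` (number of raw samples, i.e. how long
#'   the base resided in the pore).
#' @export
#' @examples
#' site_features(c(-1, 1))  # mean 0, median 0, std 1, dwell 2
site_features <- function(samples) {
  if (length(samples) == 0) stop_param("samples must be non-empty")
  m <- mean(samples)
  c(mean = m, median = median(samples),
    std = sqrt(mean((samples - m)^2)), dwell = length(samples))
}

#' Correct the k-mer offset between signal and base coordinates
#'
#' A pore's current is sensitive to a k-mer, not a single base, so
#' event-aligned positions carry a systematic kit-specific offset. The
#' offset is added on the plus strand and subtracted on the minus strand.
#' Shifted positions that fall below zero are flagged `NA` so callers can
#' drop and count them.
#'
#' @param position Integer vector of 0-based positions.
#' @param strand Character vector (`+`/`-`), recycled against `position`.
#' @param offset Integer k-mer shift; default 0 (offsets for specific pore
#'   chemistries are supplied via configuration, e.g. `--kit-shift`).
#' @return Integer vector of shifted positions, `NA` where the shift left
#'   the reference.
#' @export
apply_kmer_shift <- function(position, strand, offset = 0) {
  shifted <- as.integer(position + ifelse(strand == "+", offset, -offset))
  shifted[shifted < 0] <- NA_integer_
  shifted
}

#' Drop each read's unstable first and last aligned bases
#'
#' Current is unstable while a read enters and leaves the pore, so the
#' first and last `n` aligned reference positions of every read are
#' discarded. Reads with `<= 2n` aligned positions contribute nothing.
#'
#' @param features Per-read feature data.frame (see [read_feature_tsv()]).
#' @param n Number of positions trimmed from each end. Default 10.
#' @return The filtered feature data.frame.
#' @export
trim_read_edges <- function(features, n = 10) {
  if (!is.numeric(n) || length(n) != 1 || n < 0)
    stop_param("n must be a single integer >= 0")
  if (n == 0 || nrow(features) == 0) return(features)
  keep <- unlist(lapply(split(seq_len(nrow(features)),
                              list(features$read_id, features$contig),
                              drop = TRUE),
                        function(i) {
    pos <- features$position[i]
    u <- sort(unique(pos))
    if (length(u) <= 2 * n) return(integer(0))
    inner <- u[(n + 1):(length(u) - n)]
    i[pos %in% inner]
  }), use.names = FALSE)
  out <- features[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract per-read per-site current features from eventalign events
#'
#' Runs the whole feature-extraction stage: collapse events per
#' (read, base), normalize each read's pooled raw samples (median shift,
#' MAD scale, clipping — skipped for pre-normalized input), summarise each
#' base's samples into mean/median/std/dwell, apply the k-mer shift, and
#' trim read edges.
#'
#' @param events Data.frame from [read_eventalign()] (or a path to an
#'   eventalign-style TSV, read with `dialect`).
#' @param clip Clipping bound in normalized units, see [normalize_read()].
#' @param trim Bases trimmed from each read end, see [trim_read_edges()].
#' @param kit_shift K-mer shift offset, see [apply_kmer_shift()].
#' @param normalize If `FALSE` the samples are taken as already being in
#'   normalized units (only clipping is applied); used when consuming
#'   synthetic input from [write_eventalign_like()], whose samples are
#'   emitted on the normalized scale.
#' @param dialect Column dialect when `events` is a path.
#' @return Feature data.frame (columns of [read_feature_tsv()]); attributes
#'   `n_degenerate_reads` and `n_shift_dropped` count skipped records.
#' @export
extract_features <- function(events, clip = 5, trim = 10, kit_shift = 0,
                             normalize = TRUE,
                             dialect = eventalign_dialect()) {
  if (is.character(events)) events <- read_eventalign(events, dialect)
  ev <- collapse_events(events)
  n_degenerate <- 0L
  if (nrow(ev) > 0) {
    keep <- rep(TRUE, nrow(ev))
    for (i in split(seq_len(nrow(ev)), ev$read_id)) {
      pooled <- unlist(ev$samples[i], use.names = FALSE)
      norm <- if (normalize) {
        res <- tryCatch(normalize_read(pooled, clip = clip),
                        nanodiff_degenerate_read = function(e) NULL)
        if (is.null(res)) { keep[i] <- FALSE; n_degenerate <- n_degenerate + 1L; next }
        res$normalized
      } else pmin(pmax(pooled, -clip), clip)
      ends <- cumsum(lengths(ev$samples[i]))
      starts <- c(1L, head(ends, -1L) + 1L)
      ev$samples[i] <- mapply(function(a, b) norm[a:b], starts, ends,
                              SIMPLIFY = FALSE)
    }
    ev <- ev[keep, , drop = FALSE]
  }
  if (n_degenerate > 0)
    message("extract_features: skipped ", n_degenerate,
            " degenerate read(s) with zero MAD")
  feats <- vapply(ev$samples, site_features, numeric(4))
  out <- data.frame(read_id = ev$read_id, contig = ev$contig,
                    position = apply_kmer_shift(ev$position, ev$strand,
                                                kit_shift),
                    strand = ev$strand,
                    mean = feats["mean", ], median = feats["median", ],
                    std = feats["std", ], dwell = feats["dwell", ],
                    stringsAsFactors = FALSE)
  n_shift_dropped <- sum(is.na(out$position))
  if (n_shift_dropped > 0) {
    message("extract_features: dropped ", n_shift_dropped,
            " record(s) shifted off the reference start")
    out <- out[!is.na(out$position), , drop = FALSE]
  }
  out <- trim_read_edges(out, n = trim)
  out <- sort_features(out)
  attr(out, "n_degenerate_reads") <- n_degenerate
  attr(out, "n_shift_dropped") <- n_shift_dropped
  out
}
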