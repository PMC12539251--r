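## Reading f5c-eventalign-style TSV and the internal per-read feature table.
## Coordinates are 0-based half-open throughout.

#' Column dialect for eventalign-style TSV input
#'
#' Maps the logical fields nanodiff needs (read id, contig, 0-based
#' position, per-event raw samples, optionally strand) onto column names of
#' a tab-separated signal-alignment file. Defaults match f5c eventalign
#' output with `--samples`-style per-event sample lists.
#'
#' @param read_id,contig,position,samples Column names carrying the read
#'   identifier, reference name, 0-based reference position and the
#'   comma-separated raw current samples (pA) of the event.
#' @param strand Column name carrying the mapped strand (`+`/`-`), or `NULL`
#'   if absent, in which case `+` is assumed for every event.
#' @param sample_sep Separator inside the samples field.
#' @return A named list of class `nanodiff_dialect`.
#' @export
#' @examples
#' eventalign_dialect()
eventalign_dialect <- function(read_id = "read_name", contig = "contig",
                               position = "position", samples = "samples",
                               strand = "strand", sample_sep = ",") {
  structure(list(read_id = read_id, contig = contig, position = position,
                 samples = samples, strand = strand, sample_sep = sample_sep),
            class = "nanodiff_dialect")
}

#' Read an f5c-eventalign-style TSV into per-event records
#'
#' Each row becomes one event carrying its raw current samples. Rows whose
#' samples field cannot be parsed into at least one finite number are
#' skipped; the skip count is attached as attribute `n_skipped` and
#' reported via `message()`.
#'
#' @param path Path to a tab-separated file with a header line (may be
#'   gzipped), or a connection.
#' @param dialect An [eventalign_dialect()] naming the columns.
#' @return A data.frame with columns `read_id`, `contig`, `position`
#'   (integer, 0-based), `strand`, and a list column `samples` of numeric
#'   vectors; attribute `n_skipped` counts dropped rows. An empty file
#'   yields a zero-row data.frame.
#' @export
read_eventalign <- function(path, dialect = eventalign_dialect()) {
  tab <- tryCatch(read.table(path, header = TRUE, sep = "\t", quote = "",
                             comment.char = "", stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE),
                  error = function(e) {
                    if (grepl("no lines available", conditionMessage(e)))
                      return(NULL)  # an empty file is an empty event set
                    stop(e)
                  })
  if (is.null(tab) || (nrow(tab) == 0 && ncol(tab) == 0))
    return(empty_events())
  need <- c(read_id = dialect$read_id, contig = dialect$contig,
            position = dialect$position, samples = dialect$samples)
  missing_cols <- need[!need %in% names(tab)]
  if (length(missing_cols))
    stop_param("eventalign input lacks mandatory column(s): ",
               paste(missing_cols, collapse = ", "))
  strand <- if (!is.null(dialect$strand) && dialect$strand %in% names(tab))
    tab[[dialect$strand]] else rep("+", nrow(tab))
  parsed <- lapply(strsplit(tab[[dialect$samples]], dialect$sample_sep,
                            fixed = TRUE),
                   function(s) suppressWarnings(as.numeric(s)))
  ok <- vapply(parsed, function(x) length(x) > 0 && all(is.finite(x)),
               logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message("read_eventalign: skipped ", n_skipped,
            " row(s) with unparseable samples field")
  out <- data.frame(read_id = tab[[dialect$read_id]][ok],
                    contig = tab[[dialect$contig]][ok],
                    position = as.integer(tab[[dialect$position]][ok]),
                    strand = strand[ok],
                    stringsAsFactors = FALSE)
  out$samples <- parsed[ok]
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_events <- function() {
  out <- data.frame(read_id = character(), contig = character(),
                    position = integer(), strand = character(),
                    stringsAsFactors = FALSE)
  out$samples <- list()
  attr(out, "n_skipped") <- 0L
  out
}

#' Concatenate events mapping to the same read and reference base
#'
#' A signal aligner may emit several events for one read at one reference
#' base; their raw samples all belong to that base's dwell and are
#' concatenated in input order.
#'
#' @param events Data.frame from [read_eventalign()].
#' @return A data.frame with one row per unique
#'   (read_id, contig, position, strand) key, `samples` concatenated.
#' @export
collapse_events <- function(events) {
  if (nrow(events) == 0) return(empty_events())
  key <- paste(events$read_id, events$contig, events$position,
               events$strand, sep = "\r")
  first <- !duplicated(key)
  out <- events[first, c("read_id", "contig", "position", "strand")]
  rownames(out) <- NULL
  idx <- split(seq_len(nrow(events)), factor(key, levels = key[first]))
  out$samples <- lapply(idx, function(i) unlist(events$samples[i],
                                                use.names = FALSE))
  attr(out, "n_skipped") <- attr(events, "n_skipped")
  out
}

feature_cols <- c("read_id", "contig", "position", "strand",
                  "mean", "median", "std", "dwell")

#' Read / write the internal per-read per-site feature table
#'
#' The internal format is a plain TSV with header columns `read_id`,
#' `contig`, `position` (0-based), `strand`, `mean`, `median`, `std`,
#' `dwell`. It is what [extract_features()] produces and what the
#' comparison stage consumes, and lets simulators and tests bypass raw
#' signal entirely.
#'
#' @param path File path (gzipped paths are handled transparently).
#' @param features A feature data.frame with the columns above.
#' @return `read_feature_tsv()` returns the feature data.frame;
#'   `write_feature_tsv()` returns `path` invisibly.
#' @export
read_feature_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c(read_id = "character", contig = "character",
                                   position = "integer", strand = "character",
                                   mean = "numeric", median = "numeric",
                                   std = "numeric", dwell = "numeric"))
  missing_cols <- setdiff(feature_cols, names(tab))
  if (length(missing_cols))
    stop_param("feature table lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  tab[feature_cols]
}

#' @rdname read_feature_tsv
#' @export
write_feature_tsv <- function(features, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(format_features(features), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## fixed numeric formatting so identical features give identical bytes
format_features <- function(features) {
  f <- features[feature_cols]
  for (col in c("mean", "median", "std"))
    f[[col]] <- sprintf("%.6f", f[[col]])
  f$dwell <- sprintf("%g", f$dwell)
  f
}

#' Store a feature table as fixed-width genomic chunks
#'
#' Features are partitioned into aligned windows of `chunk_size` bases per
#' contig (`[k*chunk_size, (k+1)*chunk_size)`) and each occupied window is
#' written as a gzipped TSV named `<contig>_<start>_<end>.tsv.gz`. Chunking
#' bounds memory during comparison and is purely an on-disk layout: reading
#' the chunks back reproduces the records exactly, and downstream results
#' are independent of `chunk_size`.
#'
#' @param features Feature data.frame (see [read_feature_tsv()]).
#' @param dir Output directory, created if needed.
#' @param chunk_size Window width in bases; must be >= 1. Default 100000.
#' @return `write_chunks()` invisibly returns the written file paths;
#'   `read_chunks()` returns the reassembled feature data.frame sorted by
#'   (contig, position, read_id).
#' @export
write_chunks <- function(features, dir, chunk_size = 100000) {
  if (!is.numeric(chunk_size) || length(chunk_size) != 1 || chunk_size < 1)
    stop_param("chunk_size must be a single integer >= 1")
  chunk_size <- as.integer(chunk_size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bin <- features$position %/% chunk_size
  grp <- split(seq_len(nrow(features)),
               list(contig = features$contig, bin = bin), drop = TRUE)
  paths <- character(0)
  for (g in grp) {
    contig <- features$contig[g[1]]
    start <- (features$position[g[1]] %/% chunk_size) * chunk_size
    end <- start + chunk_size
    path <- file.path(dir, sprintf("%s_%d_%d.tsv.gz", contig, start, end))
    write_feature_tsv(sort_features(features[g, , drop = FALSE]), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_chunks
#' @export
read_chunks <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.tsv\\.gz$", full.names = TRUE))
  if (length(paths) == 0) {
    out <- data.frame(read_id = character(), contig = character(),
                      position = integer(), strand = character(),
                      mean = numeric(), median = numeric(), std = numeric(),
                      dwell = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  sort_features(do.call(rbind, lapply(paths, read_feature_tsv)))
}

sort_features <- function(features) {
  o <- order(features$contig, features$position, features$read_id,
             features$strand)
  out <- features[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
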