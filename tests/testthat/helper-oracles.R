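# Independent brute-force oracles used to check the fast implementations.

# Interval merging by boolean base mask: mark sites, bridge successive
# sites at distance <= gap, dilate by `expand`, read off runs of TRUE.
oracle_merge <- function(sites, gap = 4, expand = 4) {
  if (length(sites) == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_sites = integer()))
  sites <- sort(unique(as.integer(sites)))
  width <- max(sites) + expand + 2L
  mask <- logical(width + 1L)
  mask[sites + 1L] <- TRUE
  for (i in seq_along(sites)[-1])
    if (sites[i] - sites[i - 1] <= gap)
      mask[(sites[i - 1]:sites[i]) + 1L] <- TRUE
  dilated <- logical(length(mask))
  for (b in which(mask))
    dilated[max(1L, b - expand):min(length(mask), b + expand)] <- TRUE
  r <- rle(dilated)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  keep <- r$values
  out <- data.frame(start = starts[keep] - 1L, end = ends[keep])
  out$n_sites <- vapply(seq_len(nrow(out)), function(k)
    sum(sites >= out$start[k] & sites < out$end[k]), integer(1))
  out
}

# All-pairs overlap count with the min rule.
oracle_region_intersection <- function(A, B) {
  hits <- function(P, Q) {
    n <- 0L
    for (i in seq_len(NROW(P))) {
      found <- FALSE
      for (j in seq_len(NROW(Q)))
        if (P$contig[i] == Q$contig[j] && P$strand[i] == Q$strand[j] &&
            P$start[i] < Q$end[j] && Q$start[j] < P$end[i])
          found <- TRUE
      n <- n + found
    }
    n
  }
  min(hits(A, B), hits(B, A))
}

# Pairwise-concordance (rank) AUC, ties counted one half.
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  sp <- scores[labels]; sn <- scores[!labels]
  conc <- 0
  for (a in sp) for (b in sn) conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(sp) * length(sn))
}

# Benjamini-Hochberg step-up: adj(i) = min_{j >= i} p(j) * m / j on the
# sorted p-values, capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Feature-table builder for hand-constructed comparison inputs.
make_features <- function(position, mean, median = mean, std = 1,
                          dwell = 10, read_id = NULL, contig = "ctg",
                          strand = "+") {
  n <- max(length(position), length(mean))
  if (is.null(read_id)) read_id <- sprintf("r%04d", seq_len(n))
  data.frame(read_id = read_id, contig = contig,
             position = as.integer(position), strand = strand,
             mean = mean, median = median, std = std,
             dwell = as.numeric(dwell), stringsAsFactors = FALSE)
}

# One-row comparison record for exercising the calling cutoffs.
make_record <- function(d_mean = 0.2, d_dwell = 1.5, padj = 1e-4,
                        cov_wt = 60, cov_ivt = 60, position = 100,
                        pval = padj, contig = "ctg", strand = "+") {
  data.frame(contig = contig, position = as.integer(position),
             strand = strand, cov_wt = cov_wt, cov_ivt = cov_ivt,
             d_mean = d_mean, d_median = d_mean, d_std = 0,
             d_dwell = d_dwell, pval = pval, padj = padj,
             stringsAsFactors = FALSE)
}

# Random per-read feature groups for property tests.
random_group <- function(n, shift = 0) {
  data.frame(mean = rnorm(n, shift), median = rnorm(n, shift),
             std = abs(rnorm(n, 1, 0.1)), dwell = 1 + rpois(n, 20))
}
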