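#' Filter read mappings by aligned-length fraction and identity
#'
#' Keeps mappings aligned over at least `min_len_frac` of the read at an
#' identity of at least `min_identity` (both inclusive), the standard
#' competitive-recruitment filter (>= 90% of read length, >= 95% identity).
#'
#' @param mappings `data.frame` with columns `read_len`, `aligned_len`,
#'   `identity` (identity as a fraction).
#' @param min_len_frac Minimum `aligned_len / read_len` (default 0.90).
#' @param min_identity Minimum identity (default 0.95).
#' @return The retained rows of `mappings`.
#' @export
filter_mappings <- function(mappings, min_len_frac = 0.90,
                            min_identity = 0.95) {
  need <- c("read_len", "aligned_len", "identity")
  miss <- setdiff(need, names(mappings))
  if (length(miss) > 0L)
    stop("mapping table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(mappings[need])) stop("missing values in mapping fields")
  keep <- mappings$aligned_len / mappings$read_len >= min_len_frac &
    mappings$identity >= min_identity
  mappings[keep, , drop = FALSE]
}

#' Trimmed-percentile mean depth (tpmean)
#'
#' Mean per-base depth after discarding positions whose depth falls strictly
#' below the 5th or strictly above the 95th percentile of the contig's depth
#' distribution. Percentiles use the nearest-rank definition on the sorted
#' depth vector, so a constant track returns the constant.
#'
#' @param depth Per-base depth vector (non-empty).
#' @param lower,upper Trim percentiles as fractions (defaults 0.05, 0.95).
#' @return The trimmed mean depth.
#' @export
tpmean <- function(depth, lower = 0.05, upper = 0.95) {
  n <- length(depth)
  if (n == 0L) stop("empty depth track")
  s <- sort(depth)
  lo <- s[max(1L, ceiling(lower * n))]
  hi <- s[max(1L, ceiling(upper * n))]
  mean(depth[depth >= lo & depth <= hi])
}

#' Breadth of coverage (horizontal coverage)
#'
#' Fraction of contig positions with depth >= 1.
#'
#' @param depth Per-base depth vector.
#' @return Fraction in `[0, 1]`; 0 for an empty vector.
#' @export
breadth <- function(depth) {
  if (length(depth) == 0L) return(0)
  mean(depth >= 1)
}

#' Per-sample population abundance with the presence rule
#'
#' For each population representative in each sample, the abundance is its
#' [tpmean()] depth if its [breadth()] reaches `min_breadth`, and exactly 0
#' otherwise (the presence rule that suppresses spurious detections), then
#' optionally normalized per million mapped reads in the sample.
#'
#' @param tracks Nested list: `tracks[[sample_id]][[population_id]]` is the
#'   per-base depth of the population representative in that sample. A
#'   missing track yields 0 with a warning.
#' @param total_reads Named vector of per-sample read totals (> 0).
#' @param min_breadth Presence threshold on breadth (default 0.70).
#' @param normalize `"per_million_reads"` (default) or `"raw_tpmean"`.
#' @return Numeric matrix populations x samples with attributes
#'   `normalization` and `min_breadth`; companion breadth matrix in
#'   attribute `breadth`.
#' @export
population_abundance <- function(tracks, total_reads,
                                 min_breadth = 0.70,
                                 normalize = c("per_million_reads",
                                               "raw_tpmean")) {
  normalize <- match.arg(normalize)
  samples <- names(tracks)
  stopifnot(!is.null(samples), all(samples %in% names(total_reads)))
  if (any(total_reads[samples] <= 0)) stop("total_reads must be > 0")
  pops <- unique(unlist(lapply(tracks, names)))
  vals <- matrix(0, nrow = length(pops), ncol = length(samples),
                 dimnames = list(pops, samples))
  brd <- vals
  for (s in samples) {
    for (p in pops) {
      tr <- tracks[[s]][[p]]
      if (is.null(tr)) {
        warning("no coverage track for population '", p, "' in sample '",
                s, "'; abundance set to 0")
        next
      }
      b <- breadth(tr)
      brd[p, s] <- b
      if (b >= min_breadth) vals[p, s] <- tpmean(tr)
    }
    if (normalize == "per_million_reads")
      vals[, s] <- vals[, s] * 1e6 / total_reads[[s]]
  }
  attr(vals, "normalization") <- normalize
  attr(vals, "min_breadth") <- min_breadth
  attr(vals, "breadth") <- brd
  vals
}

#' Reads per kilobase per million mapped reads
#'
#' @param read_count Reads mapped to the contig (>= 0).
#' @param contig_len_bp Contig length in bp (> 0).
#' @param total_reads Total mapped reads in the sample (> 0).
#' @return RPKM value (vectorized).
#' @export
rpkm <- function(read_count, contig_len_bp, total_reads) {
  if (any(contig_len_bp <= 0)) stop("contig length must be > 0")
  if (any(total_reads <= 0)) stop("total reads must be > 0")
  if (any(read_count < 0)) stop("read counts must be >= 0")
  read_count / (contig_len_bp / 1e3) / (total_reads / 1e6)
}

#' Subsample read identifiers to a fixed depth
#'
#' Uniform sampling without replacement, used to equalize sequencing depth
#' across datasets (default 5 million reads) before read mapping so that
#' dataset size does not inflate presence calls.
#'
#' @param read_ids Vector of read identifiers.
#' @param n Target number of reads (default 5e6). If `length(read_ids) <= n`
#'   all reads are returned.
#' @param seed Optional integer seed for reproducibility.
#' @return Subset of `read_ids`.
#' @export
subsample_reads <- function(read_ids, n = 5e6, seed = NULL) {
  if (n <= 0) stop("subsample size must be > 0")
  if (length(read_ids) <= n) return(read_ids)
  with_seed(seed, sample(read_ids, size = n, replace = FALSE))
}

#' Presence screen of isolate genomes across samples
#'
#' For each (genome, sample) pair reports breadth, RPKM, and presence calls
#' at a relaxed 40% and the standard 70% breadth cut-off.
#'
#' @param tracks Nested list `tracks[[sample_id]][[genome_id]]` of per-base
#'   depth vectors (from mappings already filtered with [filter_mappings()]).
#' @param read_counts Matrix genomes x samples of mapped-read counts.
#' @param genome_lengths Named vector of genome lengths (bp).
#' @param total_reads Named vector of per-sample totals.
#' @param cutoffs Breadth cut-offs for the presence columns
#'   (default `c(0.40, 0.70)`).
#' @return Long `data.frame`: `genome_id`, `sample_id`, `breadth`, `rpkm`,
#'   and one logical `present_at_<pct>` column per cut-off.
#' @export
isolate_presence_screen <- function(tracks, read_counts, genome_lengths,
                                    total_reads, cutoffs = c(0.40, 0.70)) {
  samples <- names(tracks)
  genomes <- rownames(read_counts)
  out <- do.call(rbind, lapply(samples, function(s) {
    do.call(rbind, lapply(genomes, function(g) {
      tr <- tracks[[s]][[g]]
      b <- if (is.null(tr)) 0 else breadth(tr)
      data.frame(genome_id = g, sample_id = s, breadth = b,
                 rpkm = rpkm(read_counts[g, s], genome_lengths[[g]],
                             total_reads[[s]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  for (co in cutoffs)
    out[[sprintf("present_at_%d", round(100 * co))]] <- out$breadth >= co
  rownames(out) <- NULL
  out
}
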