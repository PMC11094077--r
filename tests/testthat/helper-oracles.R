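# Independent oracles and fixture builders. Each oracle is a deliberately
# naive reimplementation, kept free of the package's internals.

# Brute-force greedy dereplication on a plain pair-statistics table
# (query, target, ani, cov_on_query): sort by length desc / id asc, seed
# populations, absorb shorter contigs passing both thresholds vs the seed.
oracle_greedy_cluster <- function(ids, lengths, pair_stats,
                                  min_ani = 0.95, min_cov = 0.85) {
  o <- order(-lengths, ids)
  ids <- ids[o]
  assigned <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (i in seq_along(ids)) {
    if (!is.na(assigned[ids[i]])) next
    assigned[ids[i]] <- ids[i]
    if (i == length(ids)) break
    for (j in (i + 1L):length(ids)) {
      cand <- ids[j]
      if (!is.na(assigned[cand])) next
      hit <- pair_stats$query == cand & pair_stats$target == ids[i]
      if (!any(hit)) next
      if (pair_stats$ani[hit][1L] >= min_ani &&
          pair_stats$cov[hit][1L] >= min_cov)
        assigned[cand] <- ids[i]
    }
  }
  assigned
}

# Random clustering instance: n contigs, a random subset of pairs aligned
# with one alignment block encoding the drawn ani/cov exactly. Returns the
# package-format inputs plus the pair-statistics table the oracle consumes.
random_cluster_instance <- function(n) {
  ids <- sprintf("c%02d", seq_len(n))
  lengths <- sample(1000:10000, n, replace = TRUE)
  names(lengths) <- ids
  aln <- list(); stats_rows <- list()
  if (n >= 2L) {
    pairs <- utils::combn(ids, 2L)
    for (k in seq_len(ncol(pairs))) {
      if (stats::runif(1) < 0.4) next  # pair unaligned
      a <- pairs[1L, k]; b <- pairs[2L, k]
      shorter <- if (lengths[a] <= lengths[b]) a else b
      longer <- setdiff(c(a, b), shorter)
      cov <- stats::runif(1, 0.6, 1.0)
      ani <- stats::runif(1, 0.90, 1.0)
      aln_len <- round(cov * lengths[shorter])
      n_matches <- round(ani * aln_len)
      aln[[length(aln) + 1L]] <- data.frame(
        query_id = shorter, target_id = longer,
        query_start = 0, query_end = aln_len,
        target_start = 0, target_end = aln_len,
        n_matches = n_matches, aln_len = aln_len,
        pct_identity = n_matches / aln_len,
        query_len = unname(lengths[shorter]),
        target_len = unname(lengths[longer]), stringsAsFactors = FALSE)
      # realized values after rounding, computed by plain arithmetic
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        query = shorter, target = longer,
        ani = n_matches / aln_len, cov = aln_len / lengths[shorter],
        stringsAsFactors = FALSE)
    }
  }
  alignments <- if (length(aln) > 0L) do.call(rbind, aln) else
    data.frame(query_id = character(0), target_id = character(0),
               query_start = numeric(0), query_end = numeric(0),
               target_start = numeric(0), target_end = numeric(0),
               n_matches = numeric(0), aln_len = numeric(0),
               pct_identity = numeric(0), query_len = numeric(0),
               target_len = numeric(0), stringsAsFactors = FALSE)
  pair_stats <- if (length(stats_rows) > 0L) do.call(rbind, stats_rows) else
    data.frame(query = character(0), target = character(0),
               ani = numeric(0), cov = numeric(0), stringsAsFactors = FALSE)
  # coverage is measured on the shorter contig whichever way the pair is
  # looked up, so mirror the rows for the oracle
  pair_stats <- rbind(pair_stats,
                      data.frame(query = pair_stats$target,
                                 target = pair_stats$query,
                                 ani = pair_stats$ani, cov = pair_stats$cov,
                                 stringsAsFactors = FALSE))
  list(contigs = data.frame(contig_id = ids, length = unname(lengths),
                            stringsAsFactors = FALSE),
       alignments = alignments, pair_stats = pair_stats)
}

# Sort-trim-mean oracle for tpmean using the type-1 (inverse ECDF) quantile.
oracle_tpmean <- function(depth) {
  q <- stats::quantile(depth, c(0.05, 0.95), type = 1, names = FALSE)
  mean(depth[depth >= q[1] & depth <= q[2]])
}

# Position-scan oracle for HVR calling.
oracle_hvrs <- function(depth, frac_cutoff = 0.20, min_len = 600) {
  thr <- frac_cutoff * stats::median(depth)
  low <- depth < thr
  out <- list()
  i <- 1L
  while (i <= length(depth)) {
    if (low[i]) {
      j <- i
      while (j < length(depth) && low[j + 1L]) j <- j + 1L
      if ((j - i + 1L) >= min_len && any(depth[i:j] == 0))
        out[[length(out) + 1L]] <- c(start = i - 1L, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out) == 0L)
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  else do.call(rbind, out)
}

# Pairwise-difference oracle for per-site pi: fraction of mismatching read
# pairs among all C(n, 2) pairs at the site.
oracle_pi_site <- function(counts) {
  n <- sum(counts)
  pairs_total <- choose(n, 2)
  pairs_same <- sum(choose(counts, 2))
  (pairs_total - pairs_same) / pairs_total
}

# Boolean-mask oracle for breakage counting.
oracle_breakage <- function(rep_len, starts, ends) {
  covered <- rep(FALSE, rep_len)
  for (k in seq_along(starts)) covered[(starts[k] + 1L):ends[k]] <- TRUE
  r <- rle(covered)
  list(n_breakages = sum(!r$values),
       pct_aligned = 100 * sum(covered) / rep_len)
}

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}

# Minimal writer for blast outfmt-6 fixture rows.
write_blast6 <- function(rows, path) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
}
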