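#' Pairwise ANI and query coverage from an alignment table
#'
#' Aggregates every alignment block between two contigs (in either
#' orientation) into a single average nucleotide identity — the
#' match-weighted mean `sum(n_matches) / sum(aln_len)` — and the fraction of
#' the query contig covered by the union of its aligned intervals.
#'
#' @param alignments Alignment table from [read_alignments()] (or the
#'   simulator); only rows linking `query_id` and `target_id` are used.
#' @param query_id Contig on which coverage is measured.
#' @param target_id The other contig of the pair.
#' @param query_len Length of the query contig; taken from the alignment rows
#'   when omitted.
#' @return Named numeric vector `c(ani =, query_cov =)`; `c(0, 0)` when the
#'   pair has no alignments.
#' @export
pairwise_ani <- function(alignments, query_id, target_id, query_len = NULL) {
  fwd <- alignments$query_id == query_id & alignments$target_id == target_id
  rev <- alignments$query_id == target_id & alignments$target_id == query_id
  if (!any(fwd) && !any(rev)) return(c(ani = 0, query_cov = 0))
  n_matches <- sum(alignments$n_matches[fwd | rev])
  aln_len <- sum(alignments$aln_len[fwd | rev])
  if (is.null(query_len)) {
    ql <- c(alignments$query_len[fwd], alignments$target_len[rev])
    ql <- ql[!is.na(ql)]
    if (length(ql) == 0L)
      stop("query length unknown for ", query_id, "; supply query_len")
    query_len <- ql[1L]
  }
  query_len <- unname(query_len)
  starts <- c(alignments$query_start[fwd], alignments$target_start[rev])
  ends <- c(alignments$query_end[fwd], alignments$target_end[rev])
  cov <- union_length(starts, ends) / query_len
  c(ani = n_matches / aln_len, query_cov = cov)
}

#' Dereplicate viral contigs into populations
#'
#' Greedy longest-first clustering at species rank: contigs are sorted by
#' length descending (ties by id); each still-unassigned contig seeds a
#' population and absorbs every unassigned shorter contig whose ANI to the
#' seed is at least `min_ani` and whose alignment coverage — measured on the
#' shorter (member) contig — is at least `min_cov`. The seed, being the
#' longest member, is the population representative. Clustering is greedy,
#' not transitive: a contig joins only if it passes the thresholds against
#' the representative itself.
#'
#' @param contigs Contig table (columns `contig_id`, `length`, optionally
#'   `source_tech`).
#' @param alignments Alignment table covering the candidate pairs.
#' @param min_ani Minimum ANI (default 0.95).
#' @param min_cov Minimum coverage of the shorter contig (default 0.85).
#' @return An object of class `viral_populations`: a list with
#'   `members` (`data.frame`: `contig_id`, `rep_id`) and `populations`
#'   (`data.frame`: `rep_id`, `rep_length`, `rep_source`, `n_members`,
#'   `mixed_source`). The members table is a partition of the input contigs.
#' @export
cluster_populations <- function(contigs, alignments, min_ani = 0.95,
                                min_cov = 0.85) {
  stopifnot(all(c("contig_id", "length") %in% names(contigs)))
  if (anyDuplicated(contigs$contig_id))
    stop("duplicate contig ids in input")
  ord <- order(-contigs$length, contigs$contig_id)
  ids <- contigs$contig_id[ord]
  lens <- contigs$length[ord]
  len_of <- stats::setNames(contigs$length, contigs$contig_id)

  # index alignment rows by unordered pair for fast lookup
  pair_key <- paste(pmin(alignments$query_id, alignments$target_id),
                    pmax(alignments$query_id, alignments$target_id),
                    sep = "\r")
  rows_by_pair <- split(seq_len(nrow(alignments)), pair_key)

  assigned <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (i in seq_along(ids)) {
    seed <- ids[i]
    if (!is.na(assigned[seed])) next
    assigned[seed] <- seed
    if (i == length(ids)) next
    for (j in seq((i + 1L), length(ids))) {
      cand <- ids[j]
      if (!is.na(assigned[cand])) next
      key <- paste(min(seed, cand), max(seed, cand), sep = "\r")
      rows <- rows_by_pair[[key]]
      if (is.null(rows)) next
      stat <- pairwise_ani(alignments[rows, , drop = FALSE], cand, seed,
                           query_len = len_of[cand])
      if (stat["ani"] >= min_ani && stat["query_cov"] >= min_cov)
        assigned[cand] <- seed
    }
  }

  members <- data.frame(contig_id = names(assigned),
                        rep_id = unname(assigned),
                        stringsAsFactors = FALSE, row.names = NULL)
  src_of <- if ("source_tech" %in% names(contigs))
    stats::setNames(contigs$source_tech, contigs$contig_id)
  else stats::setNames(rep(NA_character_, nrow(contigs)), contigs$contig_id)
  reps <- unique(members$rep_id)
  # preserve greedy (longest-first) order of discovery
  reps <- ids[ids %in% reps]
  pops <- do.call(rbind, lapply(reps, function(r) {
    mem <- members$contig_id[members$rep_id == r]
    srcs <- unique(src_of[mem])
    srcs <- srcs[!is.na(srcs)]
    data.frame(rep_id = r, rep_length = unname(len_of[r]),
               rep_source = unname(src_of[r]), n_members = length(mem),
               mixed_source = length(srcs) > 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(pops) <- NULL
  structure(list(members = members, populations = pops),
            class = "viral_populations",
            min_ani = min_ani, min_cov = min_cov)
}

#' @export
print.viral_populations <- function(x, ...) {
  cat("Viral populations:", nrow(x$populations), "populations from",
      nrow(x$members), "contigs\n")
  cat("  thresholds: ANI >=", attr(x, "min_ani"),
      ", coverage (shorter contig) >=", attr(x, "min_cov"), "\n")
  cat("  singletons:", sum(x$populations$n_members == 1L), "\n")
  invisible(x)
}

#' @export
summary.viral_populations <- function(object, ...) {
  p <- object$populations
  cat("Populations:", nrow(p), " (", sum(p$n_members > 1L), "multi-member )\n")
  print(utils::head(p[order(-p$n_members), ], 10L))
  invisible(p)
}

#' Assembly-breakage analysis of a population representative
#'
#' Quantifies how completely shorter (typically short-read) contigs tile a
#' long-read population representative: the union of their aligned intervals
#' on the representative is computed, every maximal uncovered run — terminal
#' runs included — counts as one breakage, and the percent of the
#' representative covered is reported.
#'
#' @param rep_id Representative contig id.
#' @param rep_length Representative length in bp.
#' @param alignments Alignment table; rows with `target_id == rep_id` are
#'   used (self-alignments of the representative are ignored).
#' @param min_member_len Minimum aligned-contig (query) length; queries
#'   shorter than this are ignored (1000 bp in the fragmentation screen of
#'   all short contigs). Requires `query_len` in the table when > 0.
#' @return A list of class `breakage_report`: `rep_id`, `rep_length`,
#'   `covered_intervals` (matrix, 0-based half-open), `uncovered_intervals`,
#'   `n_breakages`, `pct_aligned`.
#' @export
breakage_analysis <- function(rep_id, rep_length, alignments,
                              min_member_len = 0) {
  rows <- alignments$target_id == rep_id & alignments$query_id != rep_id
  aln <- alignments[rows, , drop = FALSE]
  if (min_member_len > 0 && nrow(aln) > 0L) {
    if (all(is.na(aln$query_len)))
      stop("query_len required to filter members by length")
    aln <- aln[!is.na(aln$query_len) & aln$query_len >= min_member_len, ,
               drop = FALSE]
  }
  if (nrow(aln) > 0L && any(aln$target_end > rep_length))
    stop("alignment interval exceeds representative length for ", rep_id)
  covered <- merge_intervals(aln$target_start, aln$target_end)
  # complement within [0, rep_length)
  bounds <- c(0, as.vector(t(covered)), rep_length)
  unc_s <- bounds[seq(1, length(bounds), by = 2)]
  unc_e <- bounds[seq(2, length(bounds), by = 2)]
  keep <- unc_s < unc_e
  uncovered <- cbind(start = unc_s[keep], end = unc_e[keep])
  structure(list(
    rep_id = rep_id,
    rep_length = rep_length,
    covered_intervals = covered,
    uncovered_intervals = uncovered,
    n_breakages = nrow(uncovered),
    pct_aligned = 100 * sum(covered[, "end"] - covered[, "start"]) / rep_length
  ), class = "breakage_report")
}

#' @export
print.breakage_report <- function(x, ...) {
  cat("Breakage report for", x$rep_id, "(", x$rep_length, "bp )\n")
  cat("  breakages:", x$n_breakages, " aligned:",
      sprintf("%.1f%%", x$pct_aligned), "\n")
  invisible(x)
}
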