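#' Prophage-BLAST evidence tier
#'
#' Scores a viral-contig-vs-MAG BLAST hit on the four-tier table used for
#' additive host linkage: tier 4 at >= 98% identity and >= 90% coverage,
#' tier 3 at >= 90% and >= 75%, tier 2 at >= 90% and >= 50%, tier 1 at
#' >= 90% and >= 30%. The highest tier whose identity AND coverage
#' thresholds are both met is returned; 0 if none.
#'
#' @param pct_identity Nucleotide identity as a fraction in `[0, 1]`.
#' @param coverage Alignment coverage as a fraction in `[0, 1]`.
#' @return Integer score in `{0, 1, 2, 3, 4}` (vectorized).
#' @export
blast_tier <- function(pct_identity, coverage) {
  stopifnot(all(pct_identity >= 0 & pct_identity <= 1),
            all(coverage >= 0 & coverage <= 1))
  out <- integer(length(pct_identity))
  out[pct_identity >= 0.90 & coverage >= 0.30] <- 1L
  out[pct_identity >= 0.90 & coverage >= 0.50] <- 2L
  out[pct_identity >= 0.90 & coverage >= 0.75] <- 3L
  out[pct_identity >= 0.98 & coverage >= 0.90] <- 4L
  out
}

#' tRNA-match evidence tier
#'
#' Scores a viral tRNA vs MAG tRNA match by percent identity: 3 at exactly
#' 100%, 2 at >= 95%, 1 at >= 90%, else 0.
#'
#' @param pct_identity Identity as a fraction in `[0, 1]`.
#' @return Integer score in `{0, 1, 2, 3}` (vectorized).
#' @export
trna_tier <- function(pct_identity) {
  stopifnot(all(pct_identity >= 0 & pct_identity <= 1))
  out <- integer(length(pct_identity))
  out[pct_identity >= 0.90] <- 1L
  out[pct_identity >= 0.95] <- 2L
  out[pct_identity >= 1.00] <- 3L
  out
}

#' WIsH evidence tier
#'
#' Scores an alignment-free host prediction by its reported p-value:
#' 2.5 at p <= 1e-10, 2 at p <= 1e-5, else 0.
#'
#' @param p_value WIsH p-value in `(0, 1]`.
#' @return Score in `{0, 2, 2.5}` (vectorized).
#' @export
wish_tier <- function(p_value) {
  stopifnot(all(p_value > 0 & p_value <= 1))
  out <- numeric(length(p_value))
  out[p_value <= 1e-5] <- 2
  out[p_value <= 1e-10] <- 2.5
  out
}

#' Combine host evidence into additive virus-host linkage scores
#'
#' Per (virus, MAG) pair each evidence kind contributes its best tier
#' (multiple rows of one kind never double-count); the three components are
#' summed and the pair is assigned as a putative host when the total is
#' >= `min_score`. Pairs with total 0 are omitted.
#'
#' @param evidence `data.frame` with columns `virus_id`, `mag_id`, `kind`
#'   (one of `"prophage_blast"`, `"trna"`, `"wish"`), and per kind:
#'   `pct_identity` (+ `coverage` for BLAST) or `p_value` (WIsH), each `NA`
#'   where not applicable.
#' @param min_score Assignment threshold on the total score (default 3).
#' @return `data.frame` with one row per scoring pair: `virus_id`, `mag_id`,
#'   `blast_score`, `trna_score`, `wish_score`, `total`, `assigned`.
#' @export
combine_linkages <- function(evidence, min_score = 3) {
  stopifnot(all(c("virus_id", "mag_id", "kind") %in% names(evidence)))
  bad <- setdiff(unique(evidence$kind), c("prophage_blast", "trna", "wish"))
  if (length(bad) > 0L)
    stop("unknown evidence kind(s): ", paste(bad, collapse = ", "))
  if (nrow(evidence) == 0L)
    return(data.frame(virus_id = character(0), mag_id = character(0),
                      blast_score = integer(0), trna_score = integer(0),
                      wish_score = numeric(0), total = numeric(0),
                      assigned = logical(0), stringsAsFactors = FALSE))
  score <- numeric(nrow(evidence))
  b <- evidence$kind == "prophage_blast"
  t <- evidence$kind == "trna"
  w <- evidence$kind == "wish"
  if (any(b)) score[b] <- blast_tier(evidence$pct_identity[b], evidence$coverage[b])
  if (any(t)) score[t] <- trna_tier(evidence$pct_identity[t])
  if (any(w)) score[w] <- wish_tier(evidence$p_value[w])
  key <- paste(evidence$virus_id, evidence$mag_id, sep = "\r")
  best <- function(kind_mask) {
    s <- tapply(ifelse(kind_mask, score, 0), key, max)
    s[unique(key)]
  }
  ukey <- unique(key)
  bs <- best(b)[ukey]; ts <- best(t)[ukey]; ws <- best(w)[ukey]
  pair <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  out <- data.frame(
    virus_id = pair[, 1L], mag_id = pair[, 2L],
    blast_score = as.integer(bs), trna_score = as.integer(ts),
    wish_score = as.numeric(ws), stringsAsFactors = FALSE, row.names = NULL
  )
  out$total <- out$blast_score + out$trna_score + out$wish_score
  out$assigned <- out$total >= min_score
  out <- out[out$total > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score MAG bin quality
#'
#' CheckM-style quality score `completeness - 2 * contamination`, with a
#' usability gate at completeness >= 70% and contamination <= 10%.
#'
#' @param completeness Completeness percent in `[0, 100]` (vectorized).
#' @param contamination Contamination percent in `[0, 100]`.
#' @param bin_id Optional bin labels.
#' @return `data.frame` with columns `bin_id`, `completeness`,
#'   `contamination`, `score`, `passes_gate`.
#' @export
bin_quality <- function(completeness, contamination, bin_id = NULL) {
  stopifnot(all(completeness >= 0 & completeness <= 100),
            all(contamination >= 0 & contamination <= 100),
            length(completeness) == length(contamination))
  if (is.null(bin_id)) bin_id <- paste0("bin_", seq_along(completeness))
  data.frame(
    bin_id = bin_id,
    completeness = completeness,
    contamination = contamination,
    score = completeness - 2 * contamination,
    passes_gate = completeness >= 70 & contamination <= 10,
    stringsAsFactors = FALSE
  )
}
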