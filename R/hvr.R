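#' Call hypervariable regions from per-base coverage
#'
#' A hypervariable region (HVR) is a contiguous run of positions whose depth
#' is strictly below `frac_cutoff` times the whole-contig median depth, at
#' least `min_len` bp long, and containing at least one position of exactly
#' zero depth. Candidate runs are maximal, so no two calls touch, and
#' extending any call by one base would violate the depth criterion. The
#' three conditions are conjunctive: deep-enough dips without a zero zone
#' and short dips are rejected.
#'
#' @param depth Per-base depth vector of one contig.
#' @param contig_id Contig label carried into the calls.
#' @param frac_cutoff Depth threshold as a fraction of the contig median
#'   (default 0.20, strict `<`).
#' @param min_len Minimum region length in bp (default 600).
#' @return `data.frame` of calls sorted by `start`: `contig_id`, `start`,
#'   `end` (0-based half-open), `length`, `median_contig_depth`,
#'   `max_region_fraction` (max depth in region / contig median),
#'   `contains_zero`. Zero rows when nothing qualifies.
#' @export
call_hvrs <- function(depth, contig_id = "contig", frac_cutoff = 0.20,
                      min_len = 600) {
  if (length(depth) < min_len)
    stop("track shorter than min_len (", length(depth), " < ", min_len, ")")
  med <- stats::median(depth)
  if (med == 0)
    stop("contig median depth is 0; contig is effectively unmapped")
  thr <- frac_cutoff * med
  low <- depth < thr
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_len)
  calls <- lapply(cand, function(i) {
    s <- starts[i]; e <- ends[i]
    region <- depth[s:e]
    if (!any(region == 0)) return(NULL)
    data.frame(contig_id = contig_id, start = s - 1L, end = e,
               length = e - s + 1L, median_contig_depth = med,
               max_region_fraction = max(region) / med,
               contains_zero = TRUE, stringsAsFactors = FALSE)
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (length(calls) == 0L)
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      median_contig_depth = numeric(0),
                      max_region_fraction = numeric(0),
                      contains_zero = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out[order(out$start), , drop = FALSE]
}

#' Call HVRs across the most abundant populations
#'
#' Applies [call_hvrs()] to the depth tracks of the `top_n` most abundant
#' populations (by row sum of the abundance matrix), skipping contigs that
#' are shorter than `min_len` or have zero median depth.
#'
#' @param tracks Named list of per-base depth vectors.
#' @param abundance Optional abundance matrix (populations x samples) used
#'   to rank populations; all tracks are screened when `NULL`.
#' @param top_n Number of top-ranked populations to screen (default 50).
#' @param frac_cutoff,min_len Passed to [call_hvrs()].
#' @return Combined call `data.frame` (possibly zero rows) with a `name`
#'   column suitable for [write_bed()].
#' @export
screen_hvrs <- function(tracks, abundance = NULL, top_n = 50,
                        frac_cutoff = 0.20, min_len = 600) {
  ids <- names(tracks)
  if (!is.null(abundance)) {
    ranked <- rownames(abundance)[order(-rowSums(abundance))]
    ids <- intersect(ranked, ids)[seq_len(min(top_n, length(ids)))]
  }
  calls <- lapply(ids, function(id) {
    tr <- tracks[[id]]
    if (length(tr) < min_len || stats::median(tr) == 0) return(NULL)
    call_hvrs(tr, contig_id = id, frac_cutoff = frac_cutoff,
              min_len = min_len)
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  out <- if (length(calls) > 0L) do.call(rbind, calls) else
    call_hvrs(rep(1L, min_len + 1L), "x", frac_cutoff, min_len)[0, ]
  if (nrow(out) > 0L)
    out$name <- paste0(out$contig_id, "_hvr_", seq_len(nrow(out)))
  else out$name <- character(0)
  rownames(out) <- NULL
  out
}
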