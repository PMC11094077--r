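# Internal helpers shared across modules.

# Run `expr` under a reproducible RNG state without disturbing the caller's
# stream. seed = NULL leaves the global stream untouched (and advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed by a fixed offset, kept inside the
# 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

# Merge 0-based half-open intervals into their disjoint sorted union.
# Returns a two-column matrix (start, end); zero rows for empty input.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L)
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  stopifnot(all(start < end))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  cbind(start = out_s, end = out_e)
}

# Total length covered by the union of 0-based half-open intervals.
union_length <- function(start, end) {
  m <- merge_intervals(start, end)
  if (nrow(m) == 0L) 0 else sum(m[, "end"] - m[, "start"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
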