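#' Bray-Curtis dissimilarity between samples
#'
#' Computes pairwise Bray-Curtis dissimilarity between the columns (samples)
#' of an abundance matrix, optionally after an elementwise cube-root
#' transform that damps the dominance of highly abundant populations:
#' `d(u, v) = sum|u_i - v_i| / sum(u_i + v_i)`.
#'
#' @param abundance Matrix populations x samples, non-negative.
#' @param transform `"cube_root"` (default) or `"none"`.
#' @return Symmetric matrix samples x samples with zero diagonal, entries in
#'   `[0, 1]`. A pair of all-zero samples gets distance 0 with a warning.
#' @export
bray_curtis <- function(abundance, transform = c("cube_root", "none")) {
  transform <- match.arg(transform)
  if (any(abundance < 0)) stop("negative abundances")
  x <- if (transform == "cube_root") abundance^(1 / 3) else abundance
  n <- ncol(x)
  labels <- colnames(x) %||% paste0("s", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    denom <- sum(x[, i] + x[, j])
    if (denom == 0) {
      warning("samples '", labels[i], "' and '", labels[j],
              "' are both all-zero; distance set to 0")
      dij <- 0
    } else dij <- sum(abs(x[, i] - x[, j])) / denom
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' Coordinates are the eigenvectors of the centered matrix scaled by the
#' square roots of their (positive) eigenvalues; axes with non-positive
#' eigenvalues are reported in `eigenvalues` but carry no coordinates
#' (Bray-Curtis is semi-metric, so negative eigenvalues are expected).
#'
#' @param d Square symmetric dissimilarity matrix.
#' @return Object of class `viropop_pcoa`: list with `coords` (samples x
#'   retained axes), `eigenvalues` (all, descending), `pct_explained`
#'   (per retained axis, of the positive-eigenvalue total).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("dissimilarity matrix must be square and symmetric")
  n <- nrow(d)
  labels <- rownames(d) %||% paste0("s", seq_len(n))
  a <- -0.5 * d^2
  centering <- diag(n) - matrix(1 / n, n, n)
  b <- centering %*% a %*% centering
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  dimnames(coords) <- list(labels, paste0("PCo", seq_along(pos)))
  structure(list(
    coords = coords,
    eigenvalues = e$values,
    pct_explained = 100 * e$values[pos] / sum(e$values[pos])
  ), class = "viropop_pcoa")
}

#' @export
print.viropop_pcoa <- function(x, ...) {
  cat("PCoA:", nrow(x$coords), "samples,", ncol(x$coords),
      "retained axes\n")
  cat("  first axes explain:",
      paste(sprintf("%.1f%%", utils::head(x$pct_explained, 3L)),
            collapse = ", "), "\n")
  if (any(x$eigenvalues < 0))
    cat("  negative eigenvalues present (semi-metric input)\n")
  invisible(x)
}

#' Scatter of the first two principal coordinates
#'
#' @param x A `viropop_pcoa` object.
#' @param groups Optional factor colouring the samples.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.viropop_pcoa <- function(x, groups = NULL, ...) {
  if (ncol(x$coords) < 2L) stop("fewer than two retained axes")
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  graphics::plot(x$coords[, 1L], x$coords[, 2L], col = col, pch = 19,
                 xlab = sprintf("PCo1 (%.1f%%)", x$pct_explained[1L]),
                 ylab = sprintf("PCo2 (%.1f%%)", x$pct_explained[2L]), ...)
  invisible(x)
}

#' One-factor PERMANOVA (Adonis-style)
#'
#' Partitions the squared dissimilarities into within- and between-group
#' components: `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within = sum_g
#' sum_{i<j in g} d_ij^2 / n_g`, and `pseudo-F = ((SS_total - SS_within) /
#' (g - 1)) / (SS_within / (n - g))`. Significance by label permutation with
#' the add-one correction, so the smallest attainable p at 999 permutations
#' is exactly 0.001.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param groups Group labels, one per sample (>= 2 groups).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return List of class `viropop_permanova`: `pseudo_F`, `r2`, `p_value`,
#'   `n_perm`, `ss_total`, `ss_within`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  groups <- as.character(groups)
  g <- length(unique(groups))
  if (g < 2L) stop("need at least two groups")
  if (any(table(groups) == n)) stop("a group equals the whole sample set")
  d2 <- d^2
  ss_from_labels <- function(lab) {
    ssw <- 0
    for (lv in unique(lab)) {
      idx <- which(lab == lv)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ssw
  }
  ss_total <- sum(d2) / (2 * n)
  ss_within <- ss_from_labels(groups)
  if (ss_within == 0 && ss_total == 0)
    stop("all pairwise dissimilarities are zero; pseudo-F undefined")
  f_obs <- ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
  if (!is.finite(f_obs)) stop("pseudo-F undefined (zero within-group SS)")
  p <- with_seed(seed, {
    f_perm <- vapply(seq_len(n_perm), function(i) {
      lab <- sample(groups)
      ssw <- ss_from_labels(lab)
      ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
    }, numeric(1))
    (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  })
  structure(list(pseudo_F = f_obs, r2 = (ss_total - ss_within) / ss_total,
                 p_value = p, n_perm = n_perm, ss_total = ss_total,
                 ss_within = ss_within),
            class = "viropop_permanova")
}

#' @export
print.viropop_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$r2, x$p_value, x$n_perm))
  invisible(x)
}

#' Euclidean distances between group centroids in ordination space
#'
#' Centroids are the means of the member samples' coordinates over all
#' retained ordination axes; all pairwise centroid distances are reported.
#'
#' @param ordination A `viropop_pcoa` object (or any list with a `coords`
#'   matrix).
#' @param groups Group labels, one per sample.
#' @return `data.frame`: `group_a`, `group_b`, `distance`.
#' @export
pairwise_centroid_distance <- function(ordination, groups) {
  coords <- ordination$coords
  stopifnot(length(groups) == nrow(coords))
  groups <- as.character(groups)
  levels <- unique(groups)
  if (length(levels) < 2L) stop("need at least two groups")
  cent <- t(vapply(levels, function(lv) {
    idx <- groups == lv
    if (!any(idx)) stop("empty group: ", lv)
    colMeans(coords[idx, , drop = FALSE])
  }, numeric(ncol(coords))))
  pairs <- utils::combn(levels, 2L)
  data.frame(
    group_a = pairs[1L, ], group_b = pairs[2L, ],
    distance = vapply(seq_len(ncol(pairs)), function(k)
      sqrt(sum((cent[pairs[1L, k], ] - cent[pairs[2L, k], ])^2)), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' For every between-group sample pair `(u, v)` the contribution of taxon
#' `i` is `|u_i - v_i| / sum_k(u_k + v_k)`; contributions are averaged over
#' pairs, normalized to fractions of the mean between-group dissimilarity,
#' and ranked descending (ties broken by taxon id).
#'
#' @param abundance Matrix populations x samples.
#' @param groups Group labels, one per sample; exactly two distinct groups.
#' @param transform `"cube_root"` (default) or `"none"`, applied before the
#'   decomposition, matching [bray_curtis()].
#' @return `data.frame` ranked by contribution: `taxon_id`,
#'   `mean_contribution` (fraction, sums to 1), `cumulative`, `rank`.
#' @export
simper <- function(abundance, groups, transform = c("cube_root", "none")) {
  transform <- match.arg(transform)
  stopifnot(length(groups) == ncol(abundance))
  groups <- as.character(groups)
  levels <- unique(groups)
  if (length(levels) != 2L) stop("SIMPER compares exactly two groups")
  x <- if (transform == "cube_root") abundance^(1 / 3) else abundance
  ia <- which(groups == levels[1L]); ib <- which(groups == levels[2L])
  taxa <- rownames(x) %||% paste0("t", seq_len(nrow(x)))
  contrib <- matrix(0, nrow = nrow(x), ncol = length(ia) * length(ib))
  k <- 0L
  for (i in ia) for (j in ib) {
    k <- k + 1L
    denom <- sum(x[, i] + x[, j])
    if (denom > 0) contrib[, k] <- abs(x[, i] - x[, j]) / denom
  }
  m <- rowMeans(contrib)
  frac <- if (sum(m) > 0) m / sum(m) else m
  o <- order(-frac, taxa)
  out <- data.frame(taxon_id = taxa[o], mean_contribution = frac[o],
                    stringsAsFactors = FALSE)
  out$cumulative <- cumsum(out$mean_contribution)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Bootstrap confidence interval for a prevalence median
#'
#' Resamples the per-population sample-occurrence counts with replacement
#' (`n_boot` replicates), takes each replicate's median, and reports the
#' observed median with the 2.5/97.5 percentile interval of the replicate
#' medians.
#'
#' @param presence_counts Non-empty integer vector: number of samples each
#'   population appears in.
#' @param n_boot Number of replicates (default 10000).
#' @param seed Optional integer seed.
#' @return List: `median`, `ci_low`, `ci_high`, `n_boot`.
#' @export
bootstrap_prevalence_median <- function(presence_counts, n_boot = 10000,
                                        seed = NULL) {
  if (length(presence_counts) == 0L) stop("empty presence counts")
  with_seed(seed, {
    meds <- vapply(seq_len(n_boot), function(i)
      stats::median(sample(presence_counts, replace = TRUE)), numeric(1))
    ci <- unname(stats::quantile(meds, c(0.025, 0.975), type = 7))
    list(median = stats::median(presence_counts), ci_low = ci[1L],
         ci_high = ci[2L], n_boot = n_boot)
  })
}
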