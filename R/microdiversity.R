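#' Filter SNV sites into usable SNV loci
#'
#' A site is retained as an SNV locus when its quality exceeds `min_qual`
#' (strict), and at least one non-reference allele has frequency strictly
#' above `min_af` while being supported by at least `min_alt_reads` reads.
#' Frequencies are evaluated on the raw (pre-subsampling) counts.
#'
#' @param snvs SNV table as returned by [read_vcf_snvs()].
#' @param min_qual Phred quality threshold (default 30, strict `>`).
#' @param min_af Minimum alternative-allele frequency (default 0.01,
#'   strict `>`).
#' @param min_alt_reads Minimum reads supporting the alternative allele
#'   (default 4, inclusive `>=`).
#' @return The retained rows of `snvs`.
#' @export
filter_snvs <- function(snvs, min_qual = 30, min_af = 0.01,
                        min_alt_reads = 4) {
  if (nrow(snvs) == 0L) return(snvs)
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(snvs[paste0("count_", bases)])
  colnames(cnt) <- bases
  depth <- rowSums(cnt)
  keep <- logical(nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    alt <- cnt[i, bases != snvs$ref_allele[i]]
    ok <- depth[i] > 0 &&
      any(alt / depth[i] > min_af & alt >= min_alt_reads)
    keep[i] <- ok && snvs$qual[i] > min_qual
  }
  out <- snvs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subsample one locus to a fixed depth
#'
#' Draws `target` reads without replacement from the allele pool (a
#' multivariate hypergeometric draw), equalizing per-locus coverage before
#' diversity estimation.
#'
#' @param counts Named integer vector of per-allele read counts, summing to
#'   at least `target`.
#' @param target Target depth (default 10; must be > 1).
#' @param seed Optional integer seed.
#' @return Named integer vector over the same alleles summing to `target`.
#' @export
subsample_locus <- function(counts, target = 10, seed = NULL) {
  if (target <= 1) stop("subsample target must be > 1")
  tot <- sum(counts)
  if (tot < target)
    stop("locus depth ", tot, " below subsample target ", target)
  if (tot == target) return(counts)
  with_seed(seed, {
    pool <- rep(names(counts), counts)
    drawn <- sample(pool, size = target, replace = FALSE)
    out <- stats::setNames(integer(length(counts)), names(counts))
    tab <- table(drawn)
    out[names(tab)] <- as.integer(tab)
    out
  })
}

# Unbiased per-site heterozygosity (n/(n-1)) * (1 - sum p_a^2); identical to
# the fraction of mismatching read pairs among the n*(n-1)/2 pairs at a site.
pi_site <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(0)
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Per-contig nucleotide diversity from subsampled SNV loci
#'
#' Computes per-site heterozygosity `(n/(n-1)) * (1 - sum p_a^2)` at each
#' subsampled SNV locus (equivalently the fraction of mismatching read
#' pairs) and averages over the contig's evaluable length: monomorphic
#' covered sites contribute 0, so `pi = sum(site pi) / covered_len`.
#'
#' @param locus_counts Matrix (loci x alleles) or list of named count
#'   vectors, each already subsampled to the target depth.
#' @param covered_len Number of evaluable positions (pre-subsampling depth at
#'   least the target); must be > 0.
#' @param contig_id Contig label.
#' @return One-row `data.frame`: `contig_id`, `pi`, `n_snv_loci`,
#'   `covered_len`.
#' @export
pi_contig <- function(locus_counts, covered_len, contig_id = "contig") {
  if (covered_len <= 0) stop("covered_len must be > 0")
  if (is.matrix(locus_counts))
    locus_counts <- lapply(seq_len(nrow(locus_counts)),
                           function(i) locus_counts[i, ])
  site_pi <- vapply(locus_counts, pi_site, numeric(1))
  data.frame(contig_id = contig_id,
             pi = sum(site_pi) / covered_len,
             n_snv_loci = length(site_pi),
             covered_len = covered_len,
             stringsAsFactors = FALSE)
}

#' Per-population pi with filtering, subsampling and inclusion gates
#'
#' Full microdiversity pipeline for one contig: SNV sites are filtered with
#' [filter_snvs()], loci with depth below `target_depth` are excluded, the
#' remainder are subsampled to `target_depth` reads, and pi is averaged over
#' the contig positions whose coverage reaches `target_depth`. Contigs
#' failing the inclusion gate (breadth >= `min_breadth` and mean depth >=
#' `min_mean_depth`) return zero rows.
#'
#' @param snvs SNV table ([read_vcf_snvs()] layout), any mix of contigs.
#' @param tracks Named list of per-base depth vectors.
#' @param target_depth Per-locus subsample depth (default 10).
#' @param min_breadth Inclusion gate on breadth (default 0.70).
#' @param min_mean_depth Inclusion gate on mean depth (default 10).
#' @param min_qual,min_af,min_alt_reads SNV filters, see [filter_snvs()].
#' @param seed Optional integer seed for the subsampling draws.
#' @return `data.frame` with one row per included contig: `contig_id`, `pi`,
#'   `n_snv_loci`, `covered_len`, `breadth`, `mean_depth`.
#' @export
estimate_pi <- function(snvs, tracks, target_depth = 10, min_breadth = 0.70,
                        min_mean_depth = 10, min_qual = 30, min_af = 0.01,
                        min_alt_reads = 4, seed = NULL) {
  bases <- c("A", "C", "G", "T")
  kept <- filter_snvs(snvs, min_qual, min_af, min_alt_reads)
  with_seed(seed, {
    rows <- lapply(names(tracks), function(id) {
      tr <- tracks[[id]]
      b <- breadth(tr)
      md <- mean(tr)
      if (b < min_breadth || md < min_mean_depth) return(NULL)
      covered_len <- sum(tr >= target_depth)
      if (covered_len == 0L) return(NULL)
      sub <- kept[kept$contig_id == id, , drop = FALSE]
      loci <- list()
      if (nrow(sub) > 0L) {
        for (i in seq_len(nrow(sub))) {
          cnt <- stats::setNames(as.integer(sub[i, paste0("count_", bases)]),
                                 bases)
          if (sum(cnt) < target_depth) next  # locus not evaluable at target
          loci[[length(loci) + 1L]] <- subsample_locus(cnt, target_depth)
        }
      }
      est <- if (length(loci) == 0L)
        data.frame(contig_id = id, pi = 0, n_snv_loci = 0L,
                   covered_len = covered_len, stringsAsFactors = FALSE)
      else pi_contig(loci, covered_len, contig_id = id)
      est$breadth <- b
      est$mean_depth <- md
      est
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L)
      return(data.frame(contig_id = character(0), pi = numeric(0),
                        n_snv_loci = integer(0), covered_len = integer(0),
                        breadth = numeric(0), mean_depth = numeric(0),
                        stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Bootstrap the mean of a set of pi values
#'
#' Each replicate draws `subsample` values with replacement and records
#' their mean; the bootstrap mean and the 2.5/97.5 percentile interval of
#' the replicate means are reported.
#'
#' @param pi_values Non-empty numeric vector of per-population pi values.
#' @param n_boot Number of replicates (default 1000).
#' @param subsample Values drawn per replicate (default 100).
#' @param seed Optional integer seed.
#' @return List: `mean`, `ci_low`, `ci_high`, `boot_means`, `n_boot`,
#'   `subsample`.
#' @export
bootstrap_mean_pi <- function(pi_values, n_boot = 1000, subsample = 100,
                              seed = NULL) {
  if (length(pi_values) == 0L) stop("no pi values supplied")
  with_seed(seed, {
    bm <- vapply(seq_len(n_boot), function(i)
      mean(sample(pi_values, size = subsample, replace = TRUE)), numeric(1))
    ci <- unname(stats::quantile(bm, c(0.025, 0.975), type = 7))
    list(mean = mean(bm), ci_low = ci[1L], ci_high = ci[2L],
         boot_means = bm, n_boot = n_boot, subsample = subsample)
  })
}

#' Two-sided permutation test on a difference of group means
#'
#' The observed statistic is `mean(group_a) - mean(group_b)`. The null pools
#' both groups, shuffles labels, and re-splits at the original sizes;
#' `p = (1 + #{|stat_perm| >= |stat_obs|}) / (n_perm + 1)`.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param n_perm Number of label shuffles (default 1000).
#' @param seed Optional integer seed.
#' @return List: `statistic`, `p_value`, `n_perm`.
#' @export
permutation_test_pi <- function(group_a, group_b, n_perm = 1000,
                                seed = NULL) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  obs <- mean(group_a) - mean(group_b)
  with_seed(seed, {
    tot <- sum(pooled)
    perm <- vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(length(pooled), na)
      sa <- sum(pooled[ia])
      sa / na - (tot - sa) / (length(pooled) - na)
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
    list(statistic = obs, p_value = p, n_perm = n_perm)
  })
}
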