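#' Configuration for the synthetic virome generator
#'
#' Bundles every knob of the simulator with defaults that emulate the
#' statistical structure of a stratified marine virome study: clusters of
#' related contigs around the species-rank dereplication threshold,
#' depth-stratified sample groups, Poisson coverage tracks with engineered
#' low-coverage dips, and biallelic SNV sites at chosen allele frequencies.
#' One global `seed` fans out to fixed per-component child seeds so each
#' stage regenerates stably.
#'
#' @param seed Global integer seed; fixes all randomness.
#' @param n_populations Number of viral populations (default 10).
#' @param contigs_per_population Members per population (default 3).
#' @param contig_len_range Contig length range in bp (default 5000-10000).
#' @param within_pop_identity Nucleotide identity of members to their
#'   population seed (default 0.97; values >= 0.95 keep members in one
#'   population under the dereplication rule).
#' @param n_samples Number of samples (default 8).
#' @param group_labels Group label per sample; recycled (default two depth
#'   strata `"80m"`/`"200m"`).
#' @param mean_depth_range Range of per-contig mean read depth
#'   (default 40-80).
#' @param hvr_spec `data.frame` (`contig`, `start`, `end`, `floor_depth`) of
#'   engineered coverage dips; `NULL` for none. Coordinates 0-based
#'   half-open.
#' @param snv_spec `data.frame` (`contig`, `n_sites`, `allele_freq`) of SNV
#'   sites to plant; `NULL` for none.
#' @param snv_depth Mean read depth at simulated SNV sites (default 100).
#' @param effect_size Multiplicative between-group abundance effect on the
#'   effect taxa (default 8).
#' @param n_effect_taxa Number of taxa carrying the group effect
#'   (default 10).
#' @return Object of class `virosim_config` (a named list).
#' @export
sim_config <- function(seed = 1, n_populations = 10,
                       contigs_per_population = 3,
                       contig_len_range = c(5000, 10000),
                       within_pop_identity = 0.97, n_samples = 8,
                       group_labels = c("80m", "200m"),
                       mean_depth_range = c(40, 80), hvr_spec = NULL,
                       snv_spec = NULL, snv_depth = 100, effect_size = 8,
                       n_effect_taxa = 10) {
  if (within_pop_identity <= 0 || within_pop_identity > 1)
    stop("within_pop_identity must be in (0, 1]")
  if (snv_depth < 1) stop("snv_depth must be >= 1")
  if (effect_size < 0) stop("effect_size must be >= 0")
  structure(list(
    seed = seed, n_populations = n_populations,
    contigs_per_population = contigs_per_population,
    contig_len_range = contig_len_range,
    within_pop_identity = within_pop_identity, n_samples = n_samples,
    group_labels = rep(group_labels, length.out = n_samples),
    mean_depth_range = mean_depth_range, hvr_spec = hvr_spec,
    snv_spec = snv_spec, snv_depth = snv_depth, effect_size = effect_size,
    n_effect_taxa = n_effect_taxa
  ), class = "virosim_config")
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_at <- function(chars, pos, alt = NULL) {
  for (k in seq_along(pos)) {
    p <- pos[k]
    chars[p] <- if (is.null(alt))
      sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    else alt[k]
  }
  chars
}

#' Simulate populations of related contigs with exact truth alignments
#'
#' Each population is a star around a random consensus contig: member 1 is
#' the consensus itself (full length, hence the true representative) and
#' every other member is a possibly truncated copy diverged from it at the
#' configured identity. Divergence follows a shared-polymorphism model —
#' 70% of each member's mutations come from a population-wide pool of
#' segregating sites common to all members, the rest are private — so
#' member-to-representative identity equals `within_pop_identity` while
#' member-to-member identity stays well above the dereplication threshold.
#' Alignments within a population are computed from the sequences themselves
#' (full-overlap blocks with exact mismatch tallies), so pairwise ANI is
#' exact without running an aligner, and no alignment is emitted between
#' unrelated populations.
#'
#' @param config A [sim_config()].
#' @return List: `contigs` (contig table; the first, full-length member of
#'   each population is longest and long-read-labelled), `truth`
#'   (`data.frame`: `contig_id`, `population_id`, `is_rep`), `alignments`
#'   (exact pairwise alignment table in the [read_alignments()] layout).
#' @export
simulate_contig_population <- function(config) {
  stopifnot(inherits(config, "virosim_config"))
  with_seed(child_seed(config$seed, 101L), {
    contigs <- list(); truth <- list(); alns <- list()
    for (p in seq_len(config$n_populations)) {
      L <- sample(config$contig_len_range[1L]:config$contig_len_range[2L], 1L)
      seed_seq <- random_sequence(L)
      seed_chars <- strsplit(seed_seq, "", fixed = TRUE)[[1L]]
      ids <- sprintf("pop%02d_c%02d", p, seq_len(config$contigs_per_population))
      seqs <- character(length(ids))
      d <- 1 - config$within_pop_identity
      shared_frac <- 0.7
      shared_pos <- sample.int(L, round(shared_frac * d * L))
      shared_alt <- vapply(shared_pos, function(q)
        sample(setdiff(c("A", "C", "G", "T"), seed_chars[q]), 1L), character(1))
      for (m in seq_along(ids)) {
        if (m == 1L) {  # the consensus itself: full length, representative
          seqs[m] <- seed_seq
          next
        }
        # members truncated up to 10% so lengths are distinct
        len_m <- L - sample.int(max(1L, round(0.1 * L)), 1L)
        chars <- seed_chars[seq_len(len_m)]
        in_range <- shared_pos <= len_m
        chars <- mutate_at(chars, shared_pos[in_range], shared_alt[in_range])
        n_private <- round((1 - shared_frac) * d * len_m)
        if (n_private > 0L)
          chars <- mutate_at(chars, sample.int(len_m, n_private))
        seqs[m] <- paste(chars, collapse = "")
      }
      contigs[[p]] <- data.frame(
        contig_id = ids, sequence = seqs, length = nchar(seqs),
        source_tech = c("long_read",
                        rep("short_read", length(ids) - 1L)),
        sample_id = NA_character_, stringsAsFactors = FALSE)
      truth[[p]] <- data.frame(contig_id = ids,
                               population_id = sprintf("pop%02d", p),
                               is_rep = seq_along(ids) == 1L,
                               stringsAsFactors = FALSE)
      if (length(ids) > 1L) {
        pr <- utils::combn(seq_along(ids), 2L)
        alns[[p]] <- do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
          i <- pr[1L, k]; j <- pr[2L, k]
          # query is the shorter member; overlap is its full length
          if (nchar(seqs[i]) <= nchar(seqs[j])) { q <- i; t <- j } else { q <- j; t <- i }
          ov <- nchar(seqs[q])
          mism <- sum(strsplit(substr(seqs[q], 1L, ov), "")[[1L]] !=
                        strsplit(substr(seqs[t], 1L, ov), "")[[1L]])
          data.frame(query_id = ids[q], target_id = ids[t],
                     query_start = 0, query_end = ov,
                     target_start = 0, target_end = ov,
                     n_matches = ov - mism, aln_len = ov,
                     pct_identity = (ov - mism) / ov,
                     query_len = nchar(seqs[q]), target_len = nchar(seqs[t]),
                     stringsAsFactors = FALSE)
        }))
      }
    }
    alns <- alns[!vapply(alns, is.null, logical(1))]
    list(contigs = do.call(rbind, contigs),
         truth = do.call(rbind, truth),
         alignments = if (length(alns) > 0L) do.call(rbind, alns)
         else empty_alignments())
  })
}

#' Simulate per-base coverage tracks with engineered dips
#'
#' Outside dips, depth is Poisson at a per-contig mean drawn from
#' `mean_depth_range`. Inside each dip from `hvr_spec` the depth is held at
#' the dip's `floor_depth`: a floor of 0 yields an exact-zero zone (a true
#' hypervariable-region signature), a positive floor yields a zero-free
#' low-coverage decoy. The truth table records which dips meet the HVR
#' definition (length >= `min_len` and zero floor).
#'
#' @param config A [sim_config()].
#' @param contigs Contig table giving ids and lengths (e.g. from
#'   [simulate_contig_population()]).
#' @param min_len HVR length threshold used to label truth (default 600).
#' @param frac_cutoff HVR depth fraction used to validate dip floors
#'   (default 0.20).
#' @return List: `tracks` (named list of integer depth vectors), `truth`
#'   (`data.frame`: `contig_id`, `start`, `end`, `floor_depth`,
#'   `is_true_hvr`).
#' @export
simulate_coverage <- function(config, contigs, min_len = 600,
                              frac_cutoff = 0.20) {
  stopifnot(inherits(config, "virosim_config"))
  spec <- config$hvr_spec
  if (!is.null(spec) && nrow(spec) > 0L) {
    for (cid in unique(spec$contig)) {
      iv <- spec[spec$contig == cid, , drop = FALSE]
      iv <- iv[order(iv$start), , drop = FALSE]
      if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
        stop("overlapping dip intervals on contig ", cid)
      len <- contigs$length[contigs$contig_id == cid]
      if (length(len) == 0L) stop("hvr_spec names unknown contig ", cid)
      if (any(iv$start < 0) || any(iv$end > len))
        stop("dip interval out of bounds on contig ", cid)
    }
  }
  with_seed(child_seed(config$seed, 202L), {
    tracks <- list(); truth <- list()
    for (i in seq_len(nrow(contigs))) {
      cid <- contigs$contig_id[i]
      len <- contigs$length[i]
      mu <- stats::runif(1L, config$mean_depth_range[1L],
                         config$mean_depth_range[2L])
      depth <- stats::rpois(len, mu)
      if (!is.null(spec)) {
        iv <- spec[spec$contig == cid, , drop = FALSE]
        for (k in seq_len(nrow(iv))) {
          idx <- (iv$start[k] + 1L):iv$end[k]
          depth[idx] <- as.integer(iv$floor_depth[k])
          truth[[length(truth) + 1L]] <- data.frame(
            contig_id = cid, start = iv$start[k], end = iv$end[k],
            floor_depth = iv$floor_depth[k],
            is_true_hvr = (iv$end[k] - iv$start[k]) >= min_len &&
              iv$floor_depth[k] == 0,
            stringsAsFactors = FALSE)
        }
      }
      tracks[[cid]] <- depth
    }
    truth <- if (length(truth) > 0L) do.call(rbind, truth) else
      data.frame(contig_id = character(0), start = integer(0),
                 end = integer(0), floor_depth = numeric(0),
                 is_true_hvr = logical(0), stringsAsFactors = FALSE)
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate biallelic SNV sites at chosen allele frequencies
#'
#' For each `snv_spec` row, `n_sites` distinct positions on the contig get a
#' site whose depth is Poisson around `snv_depth` and whose alternative
#' count is Binomial(depth, `allele_freq`) — i.e. reads are independent
#' Bernoulli draws of the alternative allele. The truth table records the
#' planted frequency and the analytic expectation of the per-site
#' heterozygosity estimator under this read model, `2 f (1 - f)` (the
#' estimator with the `n/(n-1)` correction is unbiased for the population
#' heterozygosity, whatever the subsample size).
#'
#' @param config A [sim_config()] with a non-`NULL` `snv_spec`.
#' @param contigs Contig table giving ids and lengths.
#' @param qual Phred quality written for every simulated site (default 40).
#' @return List: `snvs` (table in the [read_vcf_snvs()] layout), `truth`
#'   (`data.frame`: `contig_id`, `allele_freq`, `n_sites`,
#'   `expected_site_pi`).
#' @export
simulate_snvs <- function(config, contigs, qual = 40) {
  stopifnot(inherits(config, "virosim_config"))
  spec <- config$snv_spec
  if (is.null(spec) || nrow(spec) == 0L) stop("config carries no snv_spec")
  if (any(spec$allele_freq <= 0 | spec$allele_freq >= 1))
    stop("allele_freq must be in (0, 1)")
  bases <- c("A", "C", "G", "T")
  with_seed(child_seed(config$seed, 303L), {
    rows <- list(); truth <- list()
    for (k in seq_len(nrow(spec))) {
      cid <- spec$contig[k]
      len <- contigs$length[contigs$contig_id == cid]
      if (length(len) == 0L) stop("snv_spec names unknown contig ", cid)
      f <- spec$allele_freq[k]
      ns <- spec$n_sites[k]
      if (ns > len) stop("more SNV sites than positions on contig ", cid)
      pos <- sort(sample.int(len, ns)) - 1L
      depth <- pmax(2L, stats::rpois(ns, config$snv_depth))
      ref <- sample(bases, ns, replace = TRUE)
      # alternative allele differs from the reference at every site
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
      n_alt <- stats::rbinom(ns, depth, f)
      cnt <- matrix(0L, nrow = ns, ncol = 4L, dimnames = list(NULL, bases))
      cnt[cbind(seq_len(ns), match(ref, bases))] <- depth - n_alt
      cnt[cbind(seq_len(ns), match(alt, bases))] <-
        cnt[cbind(seq_len(ns), match(alt, bases))] + n_alt
      rows[[k]] <- data.frame(
        contig_id = cid, pos = pos, ref_allele = ref, qual = qual,
        count_A = cnt[, "A"], count_C = cnt[, "C"], count_G = cnt[, "G"],
        count_T = cnt[, "T"], stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(contig_id = cid, allele_freq = f,
                               n_sites = ns,
                               expected_site_pi = 2 * f * (1 - f),
                               stringsAsFactors = FALSE)
    }
    snvs <- do.call(rbind, rows)
    rownames(snvs) <- NULL
    list(snvs = snvs, truth = do.call(rbind, truth))
  })
}

#' Simulate an abundance matrix with a known between-group effect
#'
#' Log-normal abundances for `n_populations` taxa across `n_samples`
#' samples in the configured groups; the first `n_effect_taxa` taxa are
#' multiplied by `effect_size` in the second group, so the discriminating
#' taxa are known exactly. `effect_size = 1` gives exchangeable samples
#' (a null community), values > 1 a real community shift.
#'
#' @param config A [sim_config()]; needs >= 2 groups with >= 2 samples each.
#' @return List: `abundance` (matrix populations x samples), `groups`
#'   (label per sample), `effect_taxa` (character vector of truth taxa).
#' @export
simulate_abundance_matrix <- function(config) {
  stopifnot(inherits(config, "virosim_config"))
  groups <- config$group_labels
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) stop("each group needs at least two samples")
  n_taxa <- config$n_populations
  n_eff <- min(config$n_effect_taxa, n_taxa)
  with_seed(child_seed(config$seed, 404L), {
    taxa <- sprintf("pop%02d", seq_len(n_taxa))
    samples <- sprintf("s%02d_%s", seq_len(config$n_samples), groups)
    base_mean <- stats::runif(n_taxa, 1, 4)  # per-taxon log-abundance level
    m <- matrix(stats::rlnorm(n_taxa * config$n_samples,
                              meanlog = rep(base_mean, config$n_samples),
                              sdlog = 0.4),
                nrow = n_taxa, dimnames = list(taxa, samples))
    second <- groups == unique(groups)[2L]
    if (n_eff > 0L && config$effect_size != 1)
      m[seq_len(n_eff), second] <- m[seq_len(n_eff), second] * config$effect_size
    list(abundance = m, groups = groups,
         effect_taxa = if (config$effect_size != 1) taxa[seq_len(n_eff)]
         else character(0))
  })
}
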