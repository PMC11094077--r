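#' Default thresholds of the virome pipeline
#'
#' All named constants used across the pipeline, in one place: the
#' dereplication thresholds, read-mapping filters, tpmean trim percentiles,
#' presence cut-offs, read-subsampling depth, HVR definition, SNV filters
#' and pi subsampling target, resampling sizes, host-linkage tier tables and
#' assignment gate, and the MAG quality gate. Functions carry the same
#' values as their argument defaults; this list is the single schema a
#' caller (or a test) can audit.
#'
#' @return Named list of defaults.
#' @export
viropop_defaults <- function() {
  list(
    min_ani = 0.95, min_cov = 0.85,
    breakage_min_member_len = 1000,
    map_min_len_frac = 0.90, map_min_identity = 0.95,
    tpmean_lower = 0.05, tpmean_upper = 0.95,
    min_breadth = 0.70, relaxed_breadth = 0.40,
    subsample_reads_n = 5e6,
    hvr_frac_cutoff = 0.20, hvr_min_len = 600, hvr_top_n = 50,
    snv_min_qual = 30, snv_min_af = 0.01, snv_min_alt_reads = 4,
    pi_target_depth = 10, pi_min_breadth = 0.70, pi_min_mean_depth = 10,
    boot_n = 1000, boot_subsample = 100, perm_n = 1000,
    permanova_n_perm = 999, prevalence_boot_n = 10000,
    host_min_score = 3,
    blast_tiers = data.frame(score = 4:1,
                             min_identity = c(0.98, 0.90, 0.90, 0.90),
                             min_coverage = c(0.90, 0.75, 0.50, 0.30)),
    trna_tiers = data.frame(score = 3:1,
                            min_identity = c(1.00, 0.95, 0.90)),
    wish_tiers = data.frame(score = c(2.5, 2), max_p = c(1e-10, 1e-5)),
    bin_min_completeness = 70, bin_max_contamination = 10
  )
}

demo_check <- function(checks, name, ok) {
  checks[[name]] <- isTRUE(ok)
  if (!isTRUE(ok)) stop("demo stage failed: ", name, call. = FALSE)
  checks
}

#' End-to-end demonstration on a synthetic virome
#'
#' Simulates a virome with known ground truth and runs the full pipeline —
#' dereplication, breakage analysis, abundance with the presence rule, HVR
#' calling, host-linkage scoring, microdiversity, and community ecology —
#' checking every recovered quantity against the simulator truth. Any
#' recovery failure raises an error naming the stage. Output files carry no
#' timestamps, so a fixed seed reproduces the report byte for byte.
#'
#' @param seed Integer seed driving all randomness.
#' @param out_dir Report directory (created if needed).
#' @return Invisibly, a list with `checks` (named logicals, all `TRUE`),
#'   `out_dir`, and the main result objects.
#' @export
run_demo <- function(seed = 1, out_dir = file.path(tempdir(), "viropop_demo")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  defaults <- viropop_defaults()
  checks <- list()

  ## --- populations & dereplication ---------------------------------------
  cfg <- sim_config(seed = seed, n_populations = 8,
                    contigs_per_population = 3,
                    contig_len_range = c(4000, 8000), n_samples = 8)
  sim <- simulate_contig_population(cfg)
  pops <- cluster_populations(sim$contigs, sim$alignments,
                              min_ani = defaults$min_ani,
                              min_cov = defaults$min_cov)
  truth_map <- stats::setNames(sim$truth$population_id, sim$truth$contig_id)
  rec_map <- stats::setNames(pops$members$rep_id, pops$members$contig_id)
  same_partition <- all(vapply(unique(sim$truth$population_id), function(pp) {
    mem <- sim$truth$contig_id[truth_map[sim$truth$contig_id] == pp]
    length(unique(rec_map[mem])) == 1L
  }, logical(1))) &&
    nrow(pops$populations) == length(unique(sim$truth$population_id))
  checks <- demo_check(checks, "population_recovery", same_partition)
  rep_truth <- sim$truth$contig_id[sim$truth$is_rep]
  checks <- demo_check(checks, "representatives_are_longest",
                       setequal(pops$populations$rep_id, rep_truth))
  utils::write.table(pops$members, file.path(out_dir, "populations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- breakage analysis ---------------------------------------------------
  rep1 <- pops$populations$rep_id[1L]
  rep1_len <- pops$populations$rep_length[1L]
  br <- breakage_analysis(rep1, rep1_len, sim$alignments)
  mem_len <- max(sim$alignments$query_len[sim$alignments$target_id == rep1])
  checks <- demo_check(checks, "breakage_truth",
                       br$n_breakages == 1L &&
                         abs(br$pct_aligned - 100 * mem_len / rep1_len) < 1e-9)

  ## --- coverage, presence rule, decoys ------------------------------------
  reps <- pops$populations$rep_id
  rep_contigs <- sim$contigs[sim$contigs$contig_id %in% reps, , drop = FALSE]
  samples <- sprintf("s%02d", seq_len(cfg$n_samples))
  tracks_by_sample <- list()
  for (si in seq_along(samples)) {
    scfg <- cfg; scfg$seed <- child_seed(seed, 1000L + si)
    cov <- simulate_coverage(scfg, rep_contigs)
    # last two representatives become decoys at breadth 0.5 in every sample
    for (d in utils::tail(reps, 2L)) {
      tr <- cov$tracks[[d]]
      tr[seq_len(floor(length(tr) / 2))] <- 0L
      cov$tracks[[d]] <- tr
    }
    tracks_by_sample[[samples[si]]] <- cov$tracks
  }
  total_reads <- stats::setNames(rep(1e6, length(samples)), samples)
  ab <- population_abundance(tracks_by_sample, total_reads,
                             min_breadth = defaults$min_breadth)
  present <- utils::head(reps, length(reps) - 2L)
  decoys <- utils::tail(reps, 2L)
  checks <- demo_check(checks, "presence_rule",
                       all(ab[present, ] > 0) && all(ab[decoys, ] == 0))
  utils::write.table(data.frame(population = rownames(ab), ab,
                                check.names = FALSE),
                     file.path(out_dir, "abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- hypervariable regions ----------------------------------------------
  hvr_contig <- rep_contigs[1L, , drop = FALSE]
  hcfg <- sim_config(seed = child_seed(seed, 2000L), mean_depth_range = c(80, 120),
                     hvr_spec = data.frame(
                       contig = hvr_contig$contig_id,
                       start = c(500L, 2000L, 3000L),
                       end = c(1200L, 2500L, 3700L),
                       floor_depth = c(0, 0, 10)))
  hcov <- simulate_coverage(hcfg, hvr_contig,
                            min_len = defaults$hvr_min_len,
                            frac_cutoff = defaults$hvr_frac_cutoff)
  calls <- call_hvrs(hcov$tracks[[1L]], hvr_contig$contig_id,
                     frac_cutoff = defaults$hvr_frac_cutoff,
                     min_len = defaults$hvr_min_len)
  want <- hcov$truth[hcov$truth$is_true_hvr, , drop = FALSE]
  checks <- demo_check(checks, "hvr_recovery",
                       nrow(calls) == nrow(want) &&
                         all(calls$start == want$start) &&
                         all(calls$end == want$end))
  calls$name <- paste0(calls$contig_id, "_hvr_", seq_len(nrow(calls)))
  calls$score <- signif(calls$max_region_fraction, 4)
  write_bed(calls, file.path(out_dir, "hvr_calls.bed"))

  ## --- host-linkage scoring -----------------------------------------------
  evidence <- data.frame(
    virus_id = c("v1", "v2", "v2", "v3"),
    mag_id = c("mag1", "mag2", "mag2", "mag3"),
    kind = c("prophage_blast", "trna", "wish", "trna"),
    pct_identity = c(0.98, 0.95, NA, 0.90),
    coverage = c(0.90, NA, NA, NA),
    p_value = c(NA, NA, 1e-6, NA), stringsAsFactors = FALSE)
  links <- combine_linkages(evidence, min_score = defaults$host_min_score)
  expect_assigned <- c(v1 = TRUE, v2 = TRUE, v3 = FALSE)
  got <- stats::setNames(links$assigned, links$virus_id)[names(expect_assigned)]
  checks <- demo_check(checks, "host_linkage_scores",
                       identical(unname(got), unname(expect_assigned)) &&
                         all(links$total == links$blast_score +
                               links$trna_score + links$wish_score))
  utils::write.table(links, file.path(out_dir, "linkages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- microdiversity ------------------------------------------------------
  mcfg <- sim_config(seed = child_seed(seed, 3000L),
                     mean_depth_range = c(40, 60),
                     snv_spec = data.frame(contig = hvr_contig$contig_id,
                                           n_sites = 200,
                                           allele_freq = 0.5))
  msim <- simulate_snvs(mcfg, hvr_contig)
  mcov <- simulate_coverage(mcfg, hvr_contig)
  pi_est <- estimate_pi(msim$snvs, mcov$tracks,
                        target_depth = defaults$pi_target_depth,
                        seed = child_seed(seed, 3001L))
  expected_pi <- 200 * msim$truth$expected_site_pi / hvr_contig$length
  checks <- demo_check(checks, "pi_recovery",
                       nrow(pi_est) == 1L &&
                         abs(pi_est$pi - expected_pi) / expected_pi < 0.15)
  utils::write.table(pi_est, file.path(out_dir, "pi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bt <- bootstrap_mean_pi(rep(pi_est$pi, 120), n_boot = defaults$boot_n,
                          subsample = defaults$boot_subsample,
                          seed = child_seed(seed, 3002L))
  checks <- demo_check(checks, "bootstrap_degenerate",
                       abs(bt$mean - pi_est$pi) < 1e-12)

  ## --- community ecology ---------------------------------------------------
  ecfg <- sim_config(seed = child_seed(seed, 4000L), n_populations = 40,
                     n_samples = 12, group_labels = c("80m", "200m"),
                     effect_size = 8, n_effect_taxa = 10)
  esim <- simulate_abundance_matrix(ecfg)
  d <- bray_curtis(esim$abundance, transform = "cube_root")
  ord <- pcoa(d)
  pv <- permanova(d, esim$groups, n_perm = defaults$permanova_n_perm,
                  seed = child_seed(seed, 4001L))
  checks <- demo_check(checks, "permanova_detects_effect", pv$p_value <= 0.05)
  sim_rows <- simper(esim$abundance, esim$groups)
  top <- sim_rows$taxon_id[seq_along(esim$effect_taxa)]
  checks <- demo_check(checks, "simper_recovers_effect_taxa",
                       setequal(top, esim$effect_taxa))
  cent <- pairwise_centroid_distance(ord, esim$groups)
  checks <- demo_check(checks, "centroids_separated", all(cent$distance > 0))
  prev <- bootstrap_prevalence_median(rowSums(esim$abundance > 0),
                                      n_boot = defaults$prevalence_boot_n,
                                      seed = child_seed(seed, 4002L))
  utils::write.table(sim_rows, file.path(out_dir, "simper.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  summary_lines <- c(
    sprintf("seed\t%d", as.integer(seed)),
    sprintf("populations_recovered\t%d", nrow(pops$populations)),
    sprintf("breakages_rep1\t%d", br$n_breakages),
    sprintf("pct_aligned_rep1\t%.3f", br$pct_aligned),
    sprintf("hvr_calls\t%d", nrow(calls)),
    sprintf("host_linkages_assigned\t%d", sum(links$assigned)),
    sprintf("mean_pi\t%.6g", pi_est$pi),
    sprintf("permanova_pseudo_F\t%.4f", pv$pseudo_F),
    sprintf("permanova_p\t%.4g", pv$p_value),
    sprintf("prevalence_median\t%g", prev$median),
    sprintf("checks_passed\t%d/%d", sum(unlist(checks)), length(checks))
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(list(checks = checks, out_dir = out_dir, populations = pops,
                 abundance = ab, hvr_calls = calls, linkages = links,
                 pi = pi_est, permanova = pv, simper = sim_rows))
}
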