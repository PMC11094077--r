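test_that("identical configs give bit-identical simulations", {
  cfg <- sim_config(seed = 7, n_populations = 3, contigs_per_population = 3,
                    contig_len_range = c(2000, 4000),
                    hvr_spec = data.frame(contig = "pop01_c01", start = 100L,
                                          end = 900L, floor_depth = 0),
                    snv_spec = data.frame(contig = "pop01_c01", n_sites = 20,
                                          allele_freq = 0.3))
  a <- simulate_contig_population(cfg)
  b <- simulate_contig_population(cfg)
  expect_identical(a, b)
  expect_identical(simulate_coverage(cfg, a$contigs),
                   simulate_coverage(cfg, b$contigs))
  expect_identical(simulate_snvs(cfg, a$contigs),
                   simulate_snvs(cfg, b$contigs))
  expect_identical(simulate_abundance_matrix(cfg),
                   simulate_abundance_matrix(cfg))
})

test_that("population simulation matches its own truth alignments", {
  cfg <- sim_config(seed = 3, n_populations = 1, contigs_per_population = 1,
                    contig_len_range = c(1000, 2000))
  sim <- simulate_contig_population(cfg)
  expect_equal(nrow(sim$contigs), 1L)
  expect_true(sim$truth$is_rep)
  expect_equal(nrow(sim$alignments), 0L)

  cfg <- sim_config(seed = 3, n_populations = 1, contigs_per_population = 3,
                    contig_len_range = c(3000, 5000),
                    within_pop_identity = 0.97)
  sim <- simulate_contig_population(cfg)
  # all pairwise ANI at or above the dereplication threshold, and ANI in the
  # emitted records equals a direct mismatch count on the sequences
  for (k in seq_len(nrow(sim$alignments))) {
    a <- sim$alignments[k, ]
    q <- sim$contigs$sequence[sim$contigs$contig_id == a$query_id]
    t <- sim$contigs$sequence[sim$contigs$contig_id == a$target_id]
    ov <- a$query_end
    mism <- sum(strsplit(substr(q, 1, ov), "")[[1]] !=
                  strsplit(substr(t, 1, ov), "")[[1]])
    expect_equal(a$n_matches, ov - mism)
    expect_gte(a$pct_identity, 0.95)
  }

  cfg2 <- sim_config(seed = 3, n_populations = 2, contigs_per_population = 2)
  sim2 <- simulate_contig_population(cfg2)
  pop_of <- stats::setNames(sim2$truth$population_id, sim2$truth$contig_id)
  expect_true(all(pop_of[sim2$alignments$query_id] ==
                    pop_of[sim2$alignments$target_id]))
})

test_that("representatives are the longest members at the target identity", {
  cfg <- sim_config(seed = 11, n_populations = 4, contigs_per_population = 4)
  sim <- simulate_contig_population(cfg)
  for (p in unique(sim$truth$population_id)) {
    mem <- sim$truth$contig_id[sim$truth$population_id == p]
    rep_id <- sim$truth$contig_id[sim$truth$population_id == p & sim$truth$is_rep]
    lens <- sim$contigs$length[match(mem, sim$contigs$contig_id)]
    expect_equal(sim$contigs$length[sim$contigs$contig_id == rep_id], max(lens))
  }
  expect_error(sim_config(within_pop_identity = 1.2), "identity")
})

test_that("coverage simulation plants dips and rejects bad specs", {
  contigs <- data.frame(contig_id = "c1", length = 5000L,
                        stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 5, mean_depth_range = c(50, 50),
                    hvr_spec = data.frame(
                      contig = "c1", start = c(1000L, 3000L, 4000L),
                      end = c(1700L, 3500L, 4700L),
                      floor_depth = c(0, 0, 10)))
  cov <- simulate_coverage(cfg, contigs)
  tr <- cov$tracks$c1
  expect_length(tr, 5000L)
  expect_true(all(tr[1001:1700] == 0))       # zero-floor dip
  expect_true(all(tr[4001:4700] == 10))      # non-zero-floor decoy
  expect_equal(cov$truth$is_true_hvr, c(TRUE, FALSE, FALSE))

  cfg_null <- sim_config(seed = 5, mean_depth_range = c(50, 50))
  tr0 <- simulate_coverage(cfg_null, contigs)$tracks$c1
  expect_gt(stats::median(tr0), 40)
  expect_true(all(tr0 > 0.2 * stats::median(tr0)))  # no spurious dips

  cfg_bad <- sim_config(seed = 5, hvr_spec = data.frame(
    contig = "c1", start = c(100L, 400L), end = c(500L, 900L),
    floor_depth = c(0, 0)))
  expect_error(simulate_coverage(cfg_bad, contigs), "overlapping")
  cfg_oob <- sim_config(seed = 5, hvr_spec = data.frame(
    contig = "c1", start = 4900L, end = 5200L, floor_depth = 0))
  expect_error(simulate_coverage(cfg_oob, contigs), "bounds")
})

test_that("SNV simulation respects frequencies and records correct truth", {
  contigs <- data.frame(contig_id = "c1", length = 10000L,
                        stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 9, snv_depth = 100,
                    snv_spec = data.frame(contig = "c1", n_sites = 500,
                                          allele_freq = 0.3))
  sim <- simulate_snvs(cfg, contigs)
  cnt <- as.matrix(sim$snvs[paste0("count_", c("A", "C", "G", "T"))])
  depth <- rowSums(cnt)
  ref_cnt <- cnt[cbind(seq_len(nrow(cnt)),
                       match(sim$snvs$ref_allele, c("A", "C", "G", "T")))]
  f_hat <- mean((depth - ref_cnt) / depth)
  expect_lt(abs(f_hat - 0.3), 0.02)
  expect_equal(sim$truth$expected_site_pi, 2 * 0.3 * 0.7)
  expect_true(all(!duplicated(sim$snvs$pos)))

  # sub-threshold frequencies mostly fail the alternative-allele filters
  cfg_lo <- sim_config(seed = 9, snv_depth = 100,
                       snv_spec = data.frame(contig = "c1", n_sites = 200,
                                             allele_freq = 0.005))
  lo <- simulate_snvs(cfg_lo, contigs)
  kept <- filter_snvs(lo$snvs)
  expect_lt(nrow(kept) / nrow(lo$snvs), 0.05)

  expect_error(
    simulate_snvs(sim_config(seed = 1, snv_spec = data.frame(
      contig = "c1", n_sites = 5, allele_freq = 0)), contigs),
    "allele_freq")
})

test_that("abundance simulation encodes the group effect it reports", {
  cfg <- sim_config(seed = 21, n_populations = 30, n_samples = 10,
                    group_labels = c("80m", "200m"), effect_size = 6,
                    n_effect_taxa = 5)
  sim <- simulate_abundance_matrix(cfg)
  expect_equal(dim(sim$abundance), c(30L, 10L))
  expect_length(sim$effect_taxa, 5L)
  g2 <- sim$groups == "200m"
  ratio <- rowMeans(sim$abundance[sim$effect_taxa, g2, drop = FALSE]) /
    rowMeans(sim$abundance[sim$effect_taxa, !g2, drop = FALSE])
  expect_true(all(ratio > 2))

  null_cfg <- sim_config(seed = 21, n_populations = 30, n_samples = 10,
                         effect_size = 1)
  expect_length(simulate_abundance_matrix(null_cfg)$effect_taxa, 0L)

  expect_error(simulate_abundance_matrix(
    sim_config(seed = 1, n_samples = 2, group_labels = c("a", "b"))),
    "at least two samples")
})
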