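make_aln <- function(q, t, qs, qe, ts, te, nm, ql, tl) {
  data.frame(query_id = q, target_id = t, query_start = qs, query_end = qe,
             target_start = ts, target_end = te, n_matches = nm,
             aln_len = qe - qs, pct_identity = nm / (qe - qs),
             query_len = ql, target_len = tl, stringsAsFactors = FALSE)
}

test_that("pairwise ANI aggregates blocks and unions query intervals", {
  one <- make_aln("q", "t", 0, 1000, 0, 1000, 950, 1000, 1500)
  one$query_end <- 1000; one$aln_len <- 1000
  # a single 1000 bp block with 950 matches covering 900/1000 bp of the query
  one <- make_aln("q", "t", 100, 1000, 0, 900, 950, 1000, 1500)
  one$aln_len <- 1000
  got <- pairwise_ani(one, "q", "t")
  expect_equal(unname(got["ani"]), 0.95)
  expect_equal(unname(got["query_cov"]), 0.90)

  # overlapping query intervals [0,600) and [400,1000) cover all 1000 bp
  two <- rbind(make_aln("q", "t", 0, 600, 0, 600, 580, 1000, 1500),
               make_aln("q", "t", 400, 1000, 400, 1000, 590, 1000, 1500))
  got <- pairwise_ani(two, "q", "t")
  expect_equal(unname(got["query_cov"]), 1.0)
  # match-weighted mean over the blocks
  expect_equal(unname(got["ani"]), (580 + 590) / (600 + 600))

  expect_equal(pairwise_ani(two, "x", "y", query_len = 10),
               c(ani = 0, query_cov = 0))
})

test_that("coverage is measured on the shorter contig whichever side it is", {
  # same pair recorded with the short contig as target
  aln <- make_aln("long", "short", 0, 800, 0, 800, 790, 2000, 1000)
  got <- pairwise_ani(aln, "short", "long", query_len = 1000)
  expect_equal(unname(got["query_cov"]), 0.8)
})

test_that("greedy dereplication follows the thresholds exactly", {
  contigs <- data.frame(contig_id = c("a", "b", "c"),
                        length = c(3000, 2000, 1000),
                        stringsAsFactors = FALSE)
  full <- function(q, t, ani, cov, ql, tl) {
    len <- round(cov * ql)
    make_aln(q, t, 0, len, 0, len, round(ani * len), ql, tl)
  }
  # fully connected at (0.97, 0.90): one population under the longest rep
  aln <- rbind(full("b", "a", 0.97, 0.90, 2000, 3000),
               full("c", "a", 0.97, 0.90, 1000, 3000),
               full("c", "b", 0.97, 0.90, 1000, 2000))
  pops <- cluster_populations(contigs, aln)
  expect_equal(nrow(pops$populations), 1L)
  expect_equal(pops$populations$rep_id, "a")

  # coverage below 0.85 splits the pair
  aln2 <- full("b", "a", 0.97, 0.80, 2000, 3000)
  pops2 <- cluster_populations(contigs[1:2, ], aln2)
  expect_equal(nrow(pops2$populations), 2L)

  # chain a-b pass, b-c pass, a-c fail: greedy keeps c out of a's population
  aln3 <- rbind(full("b", "a", 0.97, 0.90, 2000, 3000),
                full("c", "b", 0.97, 0.90, 1000, 2000),
                full("c", "a", 0.90, 0.90, 1000, 3000))
  pops3 <- cluster_populations(contigs, aln3)
  oracle <- oracle_greedy_cluster(
    contigs$contig_id, contigs$length,
    data.frame(query = c("b", "c", "c"), target = c("a", "b", "a"),
               ani = c(0.97, 0.97, 0.90), cov = c(0.90, 0.90, 0.90),
               stringsAsFactors = FALSE))
  got <- stats::setNames(pops3$members$rep_id, pops3$members$contig_id)
  expect_equal(got[names(oracle)], oracle)
  expect_equal(sort(pops3$populations$rep_id), c("a", "c"))

  expect_error(cluster_populations(
    data.frame(contig_id = c("a", "a"), length = c(1, 2)), aln3),
    "duplicate")
})

test_that("populations partition the input and reps are maximal", {
  for (seed in 1:5) {
    inst <- with_seed_local(seed, random_cluster_instance(12))
    pops <- cluster_populations(inst$contigs, inst$alignments)
    expect_setequal(pops$members$contig_id, inst$contigs$contig_id)
    expect_equal(anyDuplicated(pops$members$contig_id), 0L)
    len_of <- stats::setNames(inst$contigs$length, inst$contigs$contig_id)
    expect_true(all(len_of[pops$members$rep_id] >=
                      len_of[pops$members$contig_id]))
  }
})

test_that("simulated populations are recovered exactly; diverged decoys stay out", {
  cfg <- sim_config(seed = 31, n_populations = 5, contigs_per_population = 4,
                    within_pop_identity = 0.97)
  sim <- simulate_contig_population(cfg)
  decoy_cfg <- sim_config(seed = 32, n_populations = 2,
                          contigs_per_population = 3,
                          within_pop_identity = 0.90)
  decoy <- simulate_contig_population(decoy_cfg)
  decoy$contigs$contig_id <- sub("pop", "dec", decoy$contigs$contig_id)
  decoy$truth$contig_id <- sub("pop", "dec", decoy$truth$contig_id)
  for (col in c("query_id", "target_id"))
    decoy$alignments[[col]] <- sub("pop", "dec", decoy$alignments[[col]])
  contigs <- rbind(sim$contigs, decoy$contigs)
  aln <- rbind(sim$alignments, decoy$alignments)
  pops <- cluster_populations(contigs, aln)
  rec <- stats::setNames(pops$members$rep_id, pops$members$contig_id)
  # every 0.97-identity population maps onto exactly one recovered population
  for (p in unique(sim$truth$population_id)) {
    mem <- sim$truth$contig_id[sim$truth$population_id == p]
    expect_length(unique(rec[mem]), 1L)
  }
  # members of different true populations are never merged
  pop_of <- stats::setNames(c(sim$truth$population_id,
                              paste0("X", decoy$truth$population_id)),
                            c(sim$truth$contig_id, decoy$truth$contig_id))
  for (r in unique(rec))
    expect_length(unique(pop_of[names(rec)[rec == r]]), 1L)
  # 0.90-identity decoy members never join their representative
  dec_members <- decoy$truth$contig_id[!decoy$truth$is_rep]
  expect_true(all(rec[dec_members] == dec_members))  # all singletons
})

test_that("breakage analysis counts uncovered runs including terminal ones", {
  aln_full <- make_aln("m1", "rep", 0, 10000, 0, 10000, 9800, 10000, 10000)
  br <- breakage_analysis("rep", 10000, aln_full)
  expect_equal(br$n_breakages, 0L)
  expect_equal(br$pct_aligned, 100)

  two <- rbind(make_aln("m1", "rep", 0, 4000, 0, 4000, 3900, 4000, 10000),
               make_aln("m2", "rep", 0, 4000, 6000, 10000, 3900, 4000, 10000))
  br2 <- breakage_analysis("rep", 10000, two)
  expect_equal(br2$n_breakages, 1L)
  expect_equal(br2$pct_aligned, 80)
  orc <- oracle_breakage(10000, c(0, 6000), c(4000, 10000))
  expect_equal(br2$n_breakages, orc$n_breakages)
  expect_equal(br2$pct_aligned, orc$pct_aligned)

  br3 <- breakage_analysis("rep", 10000, aln_full[0, ])
  expect_equal(br3$n_breakages, 1L)
  expect_equal(br3$pct_aligned, 0)

  # members below the length cut-off are ignored
  short <- make_aln("tiny", "rep", 0, 500, 2000, 2500, 490, 500, 10000)
  br4 <- breakage_analysis("rep", 10000, rbind(two, short),
                           min_member_len = 1000)
  expect_equal(br4$pct_aligned, 80)

  oob <- make_aln("m1", "rep", 0, 500, 9800, 10300, 490, 500, 10000)
  expect_error(breakage_analysis("rep", 10000, oob), "exceeds")
})

test_that("random breakage fixtures agree with the boolean-mask oracle", {
  for (seed in 1:10) {
    set.seed(seed + 400)
    rep_len <- sample(5000:20000, 1)
    k <- sample(1:6, 1)
    starts <- sort(sample(0:(rep_len - 200), k))
    ends <- pmin(starts + sample(100:4000, k, replace = TRUE), rep_len)
    aln <- do.call(rbind, lapply(seq_len(k), function(i)
      make_aln(paste0("m", i), "rep", 0, ends[i] - starts[i], starts[i],
               ends[i], ends[i] - starts[i], ends[i] - starts[i], rep_len)))
    br <- breakage_analysis("rep", rep_len, aln)
    orc <- oracle_breakage(rep_len, starts, ends)
    expect_equal(br$n_breakages, orc$n_breakages)
    expect_equal(br$pct_aligned, orc$pct_aligned)
  }
})
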