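snv_row <- function(contig = "c1", pos = 0L, ref = "A", qual = 40,
                    A = 0L, C = 0L, G = 0L, T = 0L) {
  data.frame(contig_id = contig, pos = pos, ref_allele = ref, qual = qual,
             count_A = A, count_C = C, count_G = G, count_T = T,
             stringsAsFactors = FALSE)
}

test_that("SNV filters are strict on quality and frequency, inclusive on reads", {
  tab <- rbind(
    snv_row(qual = 30, A = 80, C = 20),          # qual exactly 30: dropped
    snv_row(qual = 35, A = 98, C = 4, pos = 1L), # af 0.039, 4 reads: kept
    snv_row(qual = 35, A = 57, C = 3, pos = 2L), # af 0.05 but 3 reads: dropped
    snv_row(qual = 35, A = 396, C = 4, pos = 3L),# af exactly 0.01: dropped
    snv_row(qual = 31, A = 90, C = 10, pos = 4L) # kept
  )
  kept <- filter_snvs(tab)
  expect_equal(kept$pos, c(1L, 4L))
})

test_that("quality and frequency filters commute", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 40
    tab <- do.call(rbind, lapply(seq_len(n), function(i)
      snv_row(pos = i, qual = sample(20:45, 1),
              A = sample(0:120, 1), C = sample(0:10, 1))))
    q_then_f <- filter_snvs(filter_snvs(tab, min_af = 0, min_alt_reads = 0),
                            min_qual = 0)
    f_then_q <- filter_snvs(filter_snvs(tab, min_qual = 0),
                            min_af = 0, min_alt_reads = 0)
    expect_equal(q_then_f, f_then_q)
  }
})

test_that("locus subsampling is a hypergeometric draw preserving total depth", {
  expect_equal(subsample_locus(c(A = 10L), 10), c(A = 10L))
  expect_equal(subsample_locus(c(A = 5L, C = 5L), 10), c(A = 5L, C = 5L))
  out <- subsample_locus(c(A = 90L, C = 10L), 10, seed = 3)
  expect_equal(sum(out), 10L)
  expect_true(all(out <= c(A = 90L, C = 10L)))
  expect_identical(subsample_locus(c(A = 90L, C = 10L), 10, seed = 3), out)
  expect_error(subsample_locus(c(A = 3L), 10), "below")
  expect_error(subsample_locus(c(A = 10L), 1), "> 1")

  # mean of the minor-allele count matches the hypergeometric expectation
  draws <- vapply(1:600, function(s)
    subsample_locus(c(A = 90L, C = 10L), 10, seed = s)[["C"]], numeric(1))
  m <- 10 * 10 / 100                      # n K / N
  v <- 10 * (10 / 100) * (90 / 100) * (90 / 99)
  expect_lt(abs(mean(draws) - m), 3 * sqrt(v / 600))
})

test_that("per-site pi equals the pairwise-difference fraction", {
  expect_equal(pi_contig(list(c(A = 5L, C = 5L)), 1000)$pi, (25 / 45) / 1000)
  expect_equal(pi_contig(list(c(A = 5L, C = 5L)), 1000)$pi * 1000,
               oracle_pi_site(c(5, 5)))
  set.seed(4)
  for (rep in 1:20) {
    cnt <- c(A = sample(0:6, 1), C = sample(0:6, 1), G = sample(0:6, 1))
    cnt <- cnt + c(A = 2L, C = 0L, G = 0L)  # ensure n >= 2
    expect_equal(pi_contig(list(cnt), 100)$pi * 100, oracle_pi_site(cnt))
  }
  # additivity: two identical loci double pi exactly
  one <- pi_contig(list(c(A = 7L, C = 3L)), 500)$pi
  two <- pi_contig(list(c(A = 7L, C = 3L), c(A = 7L, C = 3L)), 500)$pi
  expect_equal(two, 2 * one)
  # no loci -> pi 0
  expect_equal(pi_contig(list(), 500)$pi, 0)
})

test_that("the pi estimator is unbiased for 2f(1-f) on simulated loci", {
  contigs <- data.frame(contig_id = "c1", length = 20000L,
                        stringsAsFactors = FALSE)
  f <- 0.2
  cfg <- sim_config(seed = 41, snv_depth = 100,
                    snv_spec = data.frame(contig = "c1", n_sites = 4000,
                                          allele_freq = f))
  sim <- simulate_snvs(cfg, contigs)
  cnt <- as.matrix(sim$snvs[paste0("count_", c("A", "C", "G", "T"))])
  set.seed(42)
  site_pi <- apply(cnt, 1, function(x) {
    x <- as.integer(x); names(x) <- c("A", "C", "G", "T")
    sub <- subsample_locus(x, 10)
    pi_contig(list(sub), 1)$pi
  })
  expect_lt(abs(mean(site_pi) - 2 * f * (1 - f)) / (2 * f * (1 - f)), 0.05)
})

test_that("estimate_pi applies the inclusion gates and covered-length rule", {
  snvs <- rbind(snv_row(contig = "good", pos = 10L, A = 50L, C = 50L),
                snv_row(contig = "shallow", pos = 10L, A = 50L, C = 50L),
                snv_row(contig = "patchy", pos = 10L, A = 50L, C = 50L))
  tracks <- list(
    good = rep(100L, 1000),
    shallow = rep(5L, 1000),                        # mean depth < 10
    patchy = c(rep(100L, 500), rep(0L, 500))        # breadth 0.5
  )
  est <- estimate_pi(snvs, tracks, seed = 8)
  expect_equal(est$contig_id, "good")
  expect_equal(est$covered_len, 1000L)
  expect_equal(est$n_snv_loci, 1L)
  expect_gt(est$pi, 0)

  # a contig passing the gates but with no usable loci reports pi = 0
  est0 <- estimate_pi(snv_row(contig = "good", qual = 10, A = 50L, C = 50L),
                      tracks["good"], seed = 8)
  expect_equal(est0$pi, 0)
  expect_equal(est0$n_snv_loci, 0L)
})

test_that("bootstrap of mean pi is reproducible with percentile intervals", {
  b <- bootstrap_mean_pi(rep(0.3, 50), n_boot = 200, seed = 2)
  expect_equal(b$mean, 0.3)
  expect_equal(b$ci_low, 0.3)
  expect_equal(b$ci_high, 0.3)
  x <- c(rep(0, 60), rep(1, 60))
  b1 <- bootstrap_mean_pi(x, seed = 5)
  b2 <- bootstrap_mean_pi(x, seed = 5)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$mean)
  expect_gte(b1$ci_high, b1$mean)
  # CI covers the true mean in most repeated runs
  hits <- vapply(1:200, function(s) {
    set.seed(s + 900)
    y <- sample(c(0, 1), 150, replace = TRUE)
    bb <- bootstrap_mean_pi(y, n_boot = 200, subsample = 100, seed = s)
    bb$ci_low <= 0.5 && 0.5 <= bb$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("label-shuffle permutation test behaves under null and shift", {
  x <- rnorm(40)
  same <- permutation_test_pi(x, x, n_perm = 300, seed = 1)
  expect_gt(same$p_value, 0.5)
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50) + 5
  shift <- permutation_test_pi(a, b, n_perm = 999, seed = 3)
  expect_lte(shift$p_value, 0.01)
  expect_identical(permutation_test_pi(a, b, n_perm = 99, seed = 4),
                   permutation_test_pi(a, b, n_perm = 99, seed = 4))
  expect_error(permutation_test_pi(numeric(0), b), "non-empty")
})
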