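# Brute-force oracle: expand a count vector into reads and count the
# fraction of read pairs that differ.
pi_bruteforce <- function(counts) {
  reads <- rep(c("A", "T", "C", "G"), counts[1:4])
  C <- length(reads)
  if (C < 2) return(NA_real_)
  diff_pairs <- sum(outer(reads, reads, "!=")[upper.tri(diag(C))])
  diff_pairs / choose(C, 2)
}

test_that("pi_site equals brute-force read-pair enumeration", {
  expect_equal(pi_site(c(5, 5, 0, 0, 0, 0)), 25 / 45)
  expect_equal(pi_site(c(20, 0, 0, 0, 0, 0)), 0)
  expect_equal(pi_site(c(3, 1, 0, 0, 0, 0)), 0.5)
  # all compositions up to moderate coverage
  for (C in 2:10) {
    for (a in 0:C) for (b in 0:(C - a)) for (cc in 0:(C - a - b)) {
      v <- c(a, b, cc, C - a - b - cc, 0, 0)
      expect_equal(pi_site(v), pi_bruteforce(v), tolerance = 1e-12)
    }
  }
  expect_true(is.na(pi_site(c(1, 0, 0, 0, 0, 0))))
})

test_that("Watterson's theta uses the harmonic correction", {
  expect_equal(theta_watterson(0, 10, 100), 0)
  expect_equal(theta_watterson(1, 2, 100), 0.01)  # a_1 = 1
  expect_equal(sum(1 / 1:9), 2.828968, tolerance = 1e-6)
  expect_equal(theta_watterson(10, 10, 1000), 10 / (2.828968 * 1000),
               tolerance = 1e-6)
  expect_error(theta_watterson(1, 10, 0), "positive")
})

test_that("Tajima's D is zero when pi equals theta_W and NA when undefined", {
  n <- 12
  S <- 10
  a1 <- sum(1 / seq_len(n - 1))
  expect_equal(tajimas_d(S / a1, S, n), 0)
  expect_true(is.na(tajimas_d(1.0, 2, n)))       # below min_snps
  expect_true(tajimas_d(8, 5, n) > 0)            # pi above theta
  expect_true(tajimas_d(0.2, 5, n) < 0)          # pi below theta
})

test_that("FST matches the frequency formula on worked cases", {
  # p1 = p2 = 0.5
  expect_equal(fst_site(c(5, 5, 0, 0, 0, 0), c(10, 10, 0, 0, 0, 0)), 0)
  # fixed difference
  expect_equal(fst_site(c(10, 0, 0, 0, 0, 0), c(0, 10, 0, 0, 0, 0)), 1)
  # p1 = 0.8, p2 = 0.2 -> (0.5 - 0.32)/0.5
  expect_equal(fst_site(c(16, 4, 0, 0, 0, 0), c(4, 16, 0, 0, 0, 0)), 0.36)
  # both monomorphic for the same allele
  expect_true(is.na(fst_site(c(10, 0, 0, 0, 0, 0), c(9, 0, 0, 0, 0, 0))))
})

test_that("FST is symmetric and clamped to [0, 1]", {
  set.seed(3)
  for (i in 1:50) {
    v1 <- c(rmultinom(1, 40, c(0.4, 0.4, 0.1, 0.1)), 0, 0)
    v2 <- c(rmultinom(1, 60, c(0.25, 0.25, 0.25, 0.25)), 0, 0)
    f12 <- fst_site(v1, v2)
    expect_equal(f12, fst_site(v2, v1))
    expect_true(is.na(f12) || (f12 >= 0 && f12 <= 1))
  }
})

test_that("heterozygosity and its H_E > 0.30 boundary behave as stated", {
  expect_equal(heterozygosity(0.5), 0.5)
  expect_equal(heterozygosity(0), 0)
  # 2p(1-p) = 0.3 at p = (1 - sqrt(0.4))/2 = 0.1837722...
  p_star <- (1 - sqrt(0.4)) / 2
  expect_true(heterozygosity(0.18377) < 0.30)
  expect_true(heterozygosity(p_star + 1e-6) > 0.30)
  expect_error(heterozygosity(1.2), "0, 1")
})

test_that("folded SFS bins, folds, and sums to one", {
  s <- folded_sfs(c(0.1, 0.5, 0.9), n_bins = 5)
  expect_equal(s$proportion, c(2 / 3, 0, 0, 0, 1 / 3))
  s2 <- folded_sfs(rep(0.5, 7), n_bins = 5)
  expect_equal(s2$proportion, c(0, 0, 0, 0, 1))
  set.seed(8)
  s3 <- folded_sfs(runif(500, 0.01, 0.99), n_bins = 8)
  expect_equal(sum(s3$proportion), 1, tolerance = 1e-9)
  expect_error(folded_sfs(numeric()), "no frequencies")
  expect_error(folded_sfs(c(0.5, 1)), "strictly inside")
})

test_that("bootstrap with a single gene gives a degenerate CI; n_boot = 0 none", {
  f <- c(0.1, 0.2, 0.45)
  s <- folded_sfs(f, n_bins = 5, bootstrap_units = rep("g1", 3), n_boot = 50)
  expect_equal(s$ci_lower, s$proportion)
  expect_equal(s$ci_upper, s$proportion)
  s0 <- folded_sfs(f, n_bins = 5, n_boot = 0)
  expect_true(all(is.na(s0$ci_lower)))
})

test_that("pool-read and exact-haplotype statistics agree at deep coverage", {
  cfg <- sim_config(seed = 21,
                    populations = c(POP = "atlantic"),
                    pool_sizes = c(POP = 38),
                    locus_length = 10000)
  hs <- simulate_neutral_locus(cfg, 1)
  focal <- which(hs$info$species == "focal")
  exact <- haplotype_window_stats(hs$alleles[focal, , drop = FALSE],
                                  hs$length)
  pool <- sample_pool_reads(hs, "POP", coverage_mean = 2000,
                            error_rate = 0, seed = 4)
  cm <- matrix(pool$counts[, 1, ], ncol = 6)
  ps <- window_pool_stats(cm, n_chrom = 76, window_length = hs$length,
                          min_count = 1, maf = 0, min_cov = 2)
  expect_equal(ps$pi, exact$pi, tolerance = 0.02)
  expect_equal(ps$n_snps, exact$n_snps, tolerance = 0.02)
  # D normalizes a difference, which amplifies the finite-pool 1/(2n)
  # bias of read-level pi; compare on an absolute scale instead
  expect_lt(abs(ps$tajimas_d - exact$tajimas_d), 0.05)
})

test_that("an implanted balanced locus pushes Tajima's D positive", {
  cfg <- tiny_config(seed = 31)
  pos <- 0L
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    hs <- implant_balanced_locus(cfg, i)$haplotypes
    rows <- which(hs$info$population == "A1")
    st <- haplotype_window_stats(hs$alleles[rows, , drop = FALSE], hs$length)
    if (!is.na(st$tajimas_d) && st$tajimas_d > 0) pos <- pos + 1L
  }
  expect_gte(pos / n_rep, 0.9)
})
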