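test_that("zero mutation rate gives haplotypes identical to the reference", {
  cfg <- tiny_config(mu = 0)
  hs <- simulate_neutral_locus(cfg, 1)
  expect_length(hs$positions, 0L)
  expect_equal(ncol(hs$alleles), 0L)
})

test_that("the same seed reproduces a locus exactly", {
  cfg <- tiny_config(seed = 5)
  a <- simulate_neutral_locus(cfg, 3)
  b <- simulate_neutral_locus(cfg, 3)
  expect_identical(a, b)
  c1 <- implant_balanced_locus(cfg, 2)
  c2 <- implant_balanced_locus(cfg, 2)
  expect_identical(c1, c2)
})

test_that("neutral within-population diversity matches the coalescent expectation", {
  cfg <- calib_config(seed = 17, locus_length = 2000)
  theta <- 4 * cfg$ne * cfg$mu
  n_rep <- 120
  pis <- vapply(seq_len(n_rep), function(i) {
    hs <- simulate_neutral_locus(cfg, i)
    rows <- which(hs$info$species == "focal")
    haplotype_window_stats(hs$alleles[rows, , drop = FALSE], hs$length)$pi
  }, numeric(1))
  se <- sd(pis) / sqrt(n_rep)
  expect_lt(abs(mean(pis) - theta), 3 * se)
})

test_that("balanced-locus diverged-site counts follow the Poisson expectation", {
  cfg <- sim_config(seed = 23,
                    populations = c(P1 = "pacific", A1 = "atlantic"),
                    pool_sizes = c(P1 = 10, A1 = 10),
                    locus_length = 300)
  lambda <- 2 * cfg$mu * cfg$t_balanced * cfg$locus_length
  n_rep <- 300
  nd <- vapply(seq_len(n_rep), function(i)
    implant_balanced_locus(cfg, i)$truth$n_diverged, numeric(1))
  se <- sd(nd) / sqrt(n_rep)
  expect_lt(abs(mean(nd) - lambda), 3 * se)
})

test_that("balanced truth guarantees both classes everywhere and a shared SNP", {
  cfg <- tiny_config(seed = 9)
  for (i in 1:10) {
    bl <- implant_balanced_locus(cfg, i)
    cls <- bl$truth$class
    info <- bl$haplotypes$info
    for (p in unique(info$population)) {
      expect_setequal(unique(cls[info$population == p]), c("X", "Y"))
    }
    expect_gte(bl$truth$n_diverged, 1)
    # a diverged site is polymorphic in every population incl. the outgroup
    j <- match(bl$truth$diverged_pos[1], bl$haplotypes$positions)
    al <- bl$haplotypes$alleles[, j]
    for (p in unique(info$population)) {
      expect_gt(length(unique(al[info$population == p])), 1)
    }
  }
})

test_that("t_balanced = 0 degenerates to no class divergence", {
  cfg <- tiny_config(seed = 2, t_balanced = 2e6, t_split_oceans = 2e6,
                     t_split_species = 2e6, mu = 0)
  bl <- implant_balanced_locus(cfg, 1, trans_species = FALSE)
  # Poisson(0) diverged sites once mu = 0
  expect_equal(bl$truth$n_diverged, 0L)
})

test_that("pool read sampling respects the observation model", {
  cfg <- tiny_config(mu = 0)
  hs <- simulate_neutral_locus(cfg, 1)
  # monomorphic haplotypes, no error: impossible to observe variation
  sc <- sample_pool_reads(hs, "A1", coverage_mean = 50, error_rate = 0,
                          seed = 1)
  expect_equal(nrow(sc$sites), 0L)

  # frequency concentration at deep coverage: true pool frequency 0.5
  cfg2 <- tiny_config(seed = 4)
  hs2 <- simulate_neutral_locus(cfg2, 2)
  rows <- which(hs2$info$population == "A1")
  half <- hs2$alleles
  half[rows[1:10], ] <- "A"
  half[rows[11:20], ] <- "T"
  hs2$alleles <- half
  sc2 <- sample_pool_reads(hs2, "A1", coverage_mean = 10000, error_rate = 0,
                           seed = 2)
  freqA <- sc2$counts[, 1, 1] / rowSums(sc2$counts[, 1, 1:4])
  expect_true(all(freqA > 0.48 & freqA < 0.52))

  expect_identical(sample_pool_reads(hs2, "A1", seed = 7),
                   sample_pool_reads(hs2, "A1", seed = 7))
  expect_error(sample_pool_reads(hs2, "A1", pool_size = 99),
               "exceeds available")
})

test_that("emitted datasets are self-consistent on disk", {
  sim <- default_sim() # 5 neutral + 2 balanced genes
  gm <- read_gff(sim$paths$gff)
  expect_length(gm, 7L)
  expect_equal(nrow(sim$truth), 7L)
  expect_setequal(sim$truth$label, c("neutral", "balanced"))

  # sync rows = sites polymorphic among the focal pools' chromosomes
  sync <- read_sync(sim$paths$sync, names(sim$pool_sizes))
  cfg <- sim$config
  n_seg <- 0L
  for (i in seq_len(nrow(sim$truth))) {
    hs <- if (sim$truth$label[i] == "balanced") {
      implant_balanced_locus(cfg, i)$haplotypes
    } else {
      simulate_neutral_locus(cfg, i)
    }
    focal <- which(hs$info$species == "focal")
    n_seg <- n_seg + sum(vapply(seq_along(hs$positions), function(s)
      length(unique(hs$alleles[focal, s])) > 1, logical(1)))
  }
  expect_equal(nrow(sync$sites), n_seg)

  # refusal to clobber an existing dataset
  expect_error(emit_dataset(cfg, sim$dir), "overwrite")
})

test_that("emission is deterministic: same config, byte-identical files", {
  cfg <- tiny_config(seed = 77)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  emit_dataset(cfg, d1, overwrite = TRUE)
  emit_dataset(cfg, d2, overwrite = TRUE)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
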