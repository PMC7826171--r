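# Small allele matrix with named haplotypes.
hap_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  m
}

test_that("window extraction yields two haplotypes per phased diploid", {
  sim <- default_sim()
  phased <- read_phased_vcf(sim$paths$vcf, sim$manifest)
  models <- read_gff(sim$paths$gff)
  bal <- sim$truth[sim$truth$label == "balanced", ][1, ]
  pos <- as.integer(strsplit(bal$diverged_pos, ";")[[1]][1])
  hw <- extract_window(bal$contig, pos, phased, models)
  expect_s3_class(hw, "hap_window")
  expect_equal(nrow(hw$alleles), 14L)  # 6 focal + 1 outgroup diploids
  # the exon window was used
  expect_equal(unname(hw$window), c(bal$start, bal$end))
})

test_that("unusable windows are skipped with a reason", {
  sim <- default_sim()
  phased <- read_phased_vcf(sim$paths$vcf, sim$manifest)
  sk <- extract_window("ctg1", 10, phased, NULL, window_bp = 5)
  expect_s3_class(sk, "skipped_locus")
  expect_match(sk$reason, "no SNPs")

  # an individual masked across the window loses both haplotypes
  phased2 <- phased
  bal <- sim$truth[sim$truth$label == "balanced", ][1, ]
  pos <- as.integer(strsplit(bal$diverged_pos, ";")[[1]][1])
  in_gene <- phased2$sites$pos >= bal$start & phased2$sites$pos <= bal$end
  phased2$haps[in_gene, c("ME_ind1_h1", "ME_ind1_h2")] <- NA
  hw2 <- extract_window(bal$contig, pos, phased2, read_gff(sim$paths$gff))
  expect_equal(nrow(hw2$alleles), 12L)
})

test_that("p-distances follow mismatch counting with pairwise deletion", {
  m <- hap_matrix(a = "ACGT", b = "ACGA", c = "ACGT")
  D <- pairwise_distance(m)
  expect_equal(D["a", "b"], 0.25)
  expect_equal(D["a", "c"], 0)
  expect_equal(D, t(D))
  m2 <- hap_matrix(a = "ACGT", b = "ANGA")
  m2[m2 == "N"] <- NA
  expect_equal(pairwise_distance(m2)["a", "b"], 1 / 3)
})

test_that("p-distance matrices are symmetric and satisfy the triangle inequality", {
  set.seed(12)
  for (r in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T"), 8 * 30, replace = TRUE), 8, 30)
    rownames(m) <- paste0("h", 1:8)
    D <- pairwise_distance(m)
    expect_equal(D, t(D))
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
    }
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  true <- read_newick(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(true)
  tr <- build_tree(D)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)

  # two tips: a single split carrying their full distance
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- build_tree(D2)
  expect_equal(ape::cophenetic.phylo(t2)["x", "y"], 3)

  # all-zero matrix: zero branch lengths everywhere
  D0 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  t0 <- build_tree(D0)
  expect_true(all(t0$edge.length == 0))
})

test_that("outgroup rooting is applied when possible and flagged otherwise", {
  true <- read_newick(text = "((A:1,B:2):1,(C:3,OU:4):1);")
  D <- ape::cophenetic.phylo(true)
  tr <- build_tree(D, outgroup_tips = "OU")
  expect_true(attr(tr, "rooted"))
  expect_true(ape::is.rooted(tr))
  tr2 <- build_tree(D, outgroup_tips = "nope")
  expect_false(attr(tr2, "rooted"))
})

test_that("CPD_w-b reproduces the worked examples", {
  # ancient-type: each population heterozygous for the deep classes
  t1 <- read_newick(text = "((P1x:1,P2x:1):4,(P1y:1,P2y:1):4);")
  pops1 <- c(P1x = "P1", P1y = "P1", P2x = "P2", P2y = "P2")
  r1 <- cpd_wb(t1, pops1)
  expect_equal(r1$mean_within, 10)
  expect_equal(r1$mean_between, 6)
  expect_equal(r1$cpd_wb, 4)
  expect_equal(r1$n_within, 2)
  expect_equal(r1$n_between, 4)

  # phylogeographic expectation: populations monophyletic
  t2 <- read_newick(text = "((P1a:1,P1b:1):4,(P2a:1,P2b:1):4);")
  pops2 <- c(P1a = "P1", P1b = "P1", P2a = "P2", P2b = "P2")
  r2 <- cpd_wb(t2, pops2)
  expect_equal(r2$cpd_wb, -8)

  # star tree with equal lengths: all pair distances equal
  t3 <- read_newick(text = "(P1a:1,P1b:1,P2a:1,P2b:1);")
  expect_equal(cpd_wb(t3, pops2)$cpd_wb, 0)
})

test_that("cpd_wb is invariant under relabeling populations on balanced designs", {
  t1 <- read_newick(text = "((P1x:1,P2x:1):4,(P1y:1,P2y:1):4);")
  pops <- c(P1x = "P1", P1y = "P1", P2x = "P2", P2y = "P2")
  swapped <- c(P1x = "P2", P1y = "P2", P2x = "P1", P2y = "P1")
  expect_equal(cpd_wb(t1, pops)$cpd_wb, cpd_wb(t1, swapped)$cpd_wb)
})

test_that("the permutation test follows its formula and is deterministic", {
  # strong separation: within pairs far larger than anything permutable
  set.seed(5)
  b <- runif(12, 0, 0.01)
  D <- outer(b, b, "+")
  idx <- cbind(c(1, 3, 5, 7, 9, 11), c(2, 4, 6, 8, 10, 12))
  D[idx] <- D[idx] + 10 + runif(6)    # the 6 within pairs
  D[idx[, 2:1]] <- D[idx]
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("h", 1:12)
  pops <- setNames(rep(paste0("P", 1:6), each = 2), rownames(D))
  pt <- permutation_test(D, pops, n_perm = 999, seed = 3)
  expect_gte(pt$p_value, 1 / 1000)
  expect_identical(pt$p_value,
                   permutation_test(D, pops, n_perm = 999, seed = 3)$p_value)
  expect_error(permutation_test(D, setNames(rep("P1", 12), rownames(D)),
                                n_perm = 999), "one population")
  expect_error(permutation_test(D, pops, n_perm = 10), "at least 99")
})

test_that("the pair-level Welch test matches t.test on the extracted pairs", {
  set.seed(31)
  D <- matrix(runif(144), 12, 12)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("h", 1:12)
  pops <- setNames(rep(paste0("P", 1:6), each = 2), rownames(D))
  labels <- unname(pops)
  same <- outer(labels, labels, "==")
  ut <- upper.tri(D)
  ref <- t.test(D[ut & same], D[ut & !same], alternative = "greater")
  got <- cpd_pair_test(D, pops)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(got$statistic), unname(ref$statistic), tolerance = 1e-12)
})

test_that("locus classification combines sign, significance and topology", {
  t1 <- read_newick(text = "((P1x:1,P2x:1):4,(P1y:1,P2y:1):4,OU:9);")
  t1 <- build_tree(ape::cophenetic.phylo(t1), outgroup_tips = "OU")
  basins <- c(P1x = "pacific", P1y = "pacific", P2x = "atlantic",
              P2y = "atlantic")
  anc <- classify_locus(4, 1e-6, t1, basins)
  expect_equal(anc$class, "ancient")
  expect_true(anc$phylogeography_violated)
  # cpd <= 0 is always recent
  expect_equal(classify_locus(-8, 1e-6, t1, basins)$class, "recent")
  # not significant is recent
  expect_equal(classify_locus(4, 0.2, t1, basins)$class, "recent")
  # unrooted tree: decided on cpd + p alone, flagged
  t2 <- read_newick(text = "((P1x:1,P2x:1):4,(P1y:1,P2y:1):4);")
  attr(t2, "rooted") <- FALSE
  cl2 <- classify_locus(4, 1e-6, t2, basins)
  expect_equal(cl2$class, "ancient")
  expect_true(cl2$flagged)
})
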