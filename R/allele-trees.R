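# Allele trees from phased haplotypes around candidate TSPs, the
# cophenetic-distance statistic CPD_w-b (mean within-population minus
# mean between-population tip distance, outgroup excluded), permutation
# significance, and the ancient/recent classification.

#' Extract phased haplotypes over a tree window
#'
#' The window is the TSP-bearing exon when the TSP is exonic and
#' `pos +/- window_bp` otherwise. Haplotypes with more than half of the
#' window's sites masked are dropped; the locus is skipped (a
#' `skipped_locus` object is returned) when fewer than 4 usable
#' haplotypes or no segregating site remains.
#'
#' @param contig,pos Location of the focal TSP.
#' @param phased A `phased_genotypes` object.
#' @param gene_models Optional `gene_models`; supplies the exon window.
#' @param window_bp Half-window used when the TSP is not exonic.
#' @return A `hap_window` (contig, window, sites, alleles matrix
#'   haplotypes x sites, info) or a `skipped_locus` with a `reason`.
#' @export
extract_window <- function(contig, pos, phased, gene_models = NULL,
                           window_bp = 500) {
  win <- c(pos - window_bp, pos + window_bp)
  if (!is.null(gene_models)) {
    for (gm in gene_models) {
      if (gm$contig != contig || nrow(gm$exons) == 0) next
      inx <- which(pos >= gm$exons[, 1] & pos <= gm$exons[, 2])
      if (length(inx)) {
        win <- c(gm$exons[inx[1], 1], gm$exons[inx[1], 2])
        break
      }
    }
  }
  in_win <- phased$sites$contig == contig &
    phased$sites$pos >= win[1] & phased$sites$pos <= win[2]
  if (!any(in_win)) {
    return(structure(list(reason = "no SNPs in window"),
                     class = "skipped_locus"))
  }
  al <- t(phased$haps[in_win, , drop = FALSE])
  rownames(al) <- phased$info$hap_id
  masked_frac <- rowMeans(is.na(al))
  keep <- masked_frac <= 0.5
  al <- al[keep, , drop = FALSE]
  info <- phased$info[keep, , drop = FALSE]
  if (nrow(al) < 4) {
    return(structure(list(reason = "fewer than 4 usable haplotypes"),
                     class = "skipped_locus"))
  }
  seg <- apply(al, 2, function(col) length(unique(col[!is.na(col)])) > 1)
  if (!any(seg)) {
    return(structure(list(reason = "no segregating sites among usable haplotypes"),
                     class = "skipped_locus"))
  }
  structure(list(contig = contig, window = win,
                 sites = phased$sites[in_win, , drop = FALSE],
                 alleles = al, info = info),
            class = "hap_window")
}

#' Pairwise p-distances between haplotypes
#'
#' Mismatch proportion over jointly unmasked sites; symmetric with a zero
#' diagonal. A pair with no jointly unmasked site gets `NA` (callers skip
#' such loci).
#'
#' @param hw A `hap_window`, or a character allele matrix (haplotypes x
#'   sites, `NA` = masked).
#' @return Symmetric numeric matrix with haplotype ids as dimnames.
#' @export
pairwise_distance <- function(hw) {
  al <- if (inherits(hw, "hap_window")) hw$alleles else hw
  n <- nrow(al)
  stopifnot(n >= 2)
  D <- matrix(0, n, n, dimnames = list(rownames(al), rownames(al)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(al[i, ]) & !is.na(al[j, ])
      D[i, j] <- D[j, i] <-
        if (!any(ok)) NA_real_ else mean(al[i, ok] != al[j, ok])
    }
  }
  D
}

#' Neighbor-joining allele tree
#'
#' Builds a neighbor-joining tree from a distance matrix, clamps negative
#' branch lengths to zero (keeping the cophenetic distance a metric), and
#' roots it on the outgroup tips. When the outgroup tips are absent the
#' unrooted tree is returned with attribute `rooted = FALSE`.
#'
#' @param D Symmetric distance matrix with tip names.
#' @param outgroup_tips Tip labels to root on.
#' @return An [ape::phylo] tree; attribute `rooted` records whether
#'   outgroup rooting succeeded.
#' @export
build_tree <- function(D, outgroup_tips = character()) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 2)
  if (anyNA(D)) stop("distance matrix contains missing entries")
  tips <- rownames(D)
  if (nrow(D) == 2) {
    tr <- structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                         edge.length = rep(D[1, 2] / 2, 2),
                         tip.label = tips, Nnode = 1L),
                    class = "phylo")
  } else {
    tr <- ape::nj(as.dist(D))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  og <- intersect(outgroup_tips, tr$tip.label)
  rooted <- FALSE
  if (length(og) > 0 && length(og) < length(tr$tip.label)) {
    rt <- tryCatch(ape::root(tr, outgroup = og, resolve.root = TRUE),
                   error = function(e) NULL)
    if (is.null(rt)) {
      rt <- tryCatch(ape::root(tr, outgroup = og[1], resolve.root = TRUE),
                     error = function(e) NULL)
    }
    if (!is.null(rt)) {
      tr <- rt
      rooted <- TRUE
    }
  }
  attr(tr, "rooted") <- rooted
  tr
}

# Core CPD_w-b statistic on a distance/cophenetic matrix restricted to
# labeled tips. Returns NA when no within pair exists.
cpd_stat <- function(D, labels) {
  same <- outer(labels, labels, "==")
  ut <- upper.tri(D)
  w <- D[ut & same]
  b <- D[ut & !same]
  if (length(w) == 0 || length(b) == 0) return(NA_real_)
  mean(w) - mean(b)
}

#' Cophenetic within-minus-between statistic (CPD_w-b)
#'
#' Computes the cophenetic (tree path) distance between all tip pairs,
#' and contrasts the mean distance of within-population pairs against
#' between-population pairs, excluding the outgroup. Positive values mean
#' haplotypes from the same population are *more* diverged from each
#' other than from other populations' haplotypes — the signature of
#' anciently balanced allelic classes cutting across geography.
#'
#' @param tree An [ape::phylo] allele tree with branch lengths.
#' @param populations Named character vector mapping (non-outgroup) tip
#'   labels to populations; tips absent from it are excluded.
#' @return A list: `cpd_wb`, `mean_within`, `mean_between`,
#'   `iqr_within`, `iqr_between`, `n_within`, `n_between`.
#' @export
cpd_wb <- function(tree, populations) {
  stopifnot(inherits(tree, "phylo"))
  D <- ape::cophenetic.phylo(tree)
  tips <- intersect(rownames(D), names(populations))
  if (length(tips) < 2) stop("need at least 2 labeled tips")
  D <- D[tips, tips]
  labels <- unname(populations[tips])
  if (length(unique(labels)) < 2) {
    stop("need haplotypes from at least 2 populations")
  }
  same <- outer(labels, labels, "==")
  ut <- upper.tri(D)
  w <- D[ut & same]
  b <- D[ut & !same]
  list(cpd_wb = if (length(w) == 0) NA_real_ else mean(w) - mean(b),
       mean_within = if (length(w)) mean(w) else NA_real_,
       mean_between = mean(b),
       iqr_within = if (length(w)) unname(diff(quantile(w, c(0.25, 0.75))))
                    else NA_real_,
       iqr_between = unname(diff(quantile(b, c(0.25, 0.75)))),
       n_within = length(w), n_between = length(b))
}

#' Welch test on within- vs between-population cophenetic distances
#'
#' One-sided Welch t test of whether the within-population tip pair
#' distances exceed the between-population ones (i.e. CPD_w-b > 0),
#' treating pair distances as observations. With a single diploid per
#' population a label-permutation test has a hard resolution floor (any
#' permutation re-creating a perfect cross-class pairing reproduces the
#' observed statistic), so this pair-level test is what locus
#' classification uses; note it treats tip pairs as exchangeable
#' observations and is therefore anticonservative in absolute terms.
#'
#' @inheritParams cpd_wb
#' @return List with `statistic` (t), `df`, `p_value` (one-sided,
#'   greater), `n_within`, `n_between`.
#' @export
cpd_pair_test <- function(tree, populations) {
  D <- if (inherits(tree, "phylo")) ape::cophenetic.phylo(tree) else tree
  tips <- intersect(rownames(D), names(populations))
  D <- D[tips, tips]
  labels <- unname(populations[tips])
  same <- outer(labels, labels, "==")
  ut <- upper.tri(D)
  w <- D[ut & same]
  b <- D[ut & !same]
  if (length(w) < 2 || length(b) < 2) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                n_within = length(w), n_between = length(b)))
  }
  vw <- stats::var(w) / length(w)
  vb <- stats::var(b) / length(b)
  se <- sqrt(vw + vb)
  if (se == 0) {
    p <- if (mean(w) > mean(b)) 0 else 1
    return(list(statistic = if (mean(w) == mean(b)) 0 else Inf * sign(mean(w) - mean(b)),
                df = NA_real_, p_value = p,
                n_within = length(w), n_between = length(b)))
  }
  tstat <- (mean(w) - mean(b)) / se
  df <- se^4 / (vw^2 / (length(w) - 1) + vb^2 / (length(b) - 1))
  list(statistic = tstat, df = df,
       p_value = stats::pt(tstat, df, lower.tail = FALSE),
       n_within = length(w), n_between = length(b))
}

#' Permutation test for CPD_w-b > 0
#'
#' Permutes population labels over the non-outgroup tips and reports the
#' one-sided p-value `(1 + #{permuted >= observed}) / (n_perm + 1)`.
#'
#' @param tree An [ape::phylo] tree, or directly a cophenetic/distance
#'   matrix with tip dimnames.
#' @param populations Named character vector (tip label -> population) of
#'   the tips entering the statistic.
#' @param n_perm Number of permutations (>= 99).
#' @param seed RNG seed.
#' @return List with `p_value`, `observed` and `n_perm`.
#' @export
permutation_test <- function(tree, populations, n_perm = 999, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  D <- if (inherits(tree, "phylo")) ape::cophenetic.phylo(tree) else tree
  tips <- intersect(rownames(D), names(populations))
  D <- D[tips, tips]
  labels <- unname(populations[tips])
  if (length(unique(labels)) < 2) {
    stop("population labels are degenerate: only one population")
  }
  obs <- cpd_stat(D, labels)
  if (is.na(obs)) {
    return(list(p_value = NA_real_, observed = NA_real_, n_perm = n_perm))
  }
  ge <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      cpd_stat(D, sample(labels)) >= obs
    }, logical(1)))
  })
  list(p_value = (1 + ge) / (n_perm + 1), observed = obs, n_perm = n_perm)
}

#' Classify a candidate locus as under ancient or recent balancing selection
#'
#' `"ancient"` requires all three of: CPD_w-b > 0, Bonferroni-adjusted
#' permutation p below `alpha`, and an allele-tree topology violating the
#' phylogeographic expectation (at least one ocean basin's tips
#' non-monophyletic on the rooted tree). Anything else is `"recent"`.
#' On an unrooted tree the monophyly check is skipped and the decision is
#' flagged.
#'
#' @param cpd Observed CPD_w-b.
#' @param adjusted_p Bonferroni-adjusted permutation p-value.
#' @param tree The rooted allele tree.
#' @param basins Named character vector (tip label -> ocean basin) for the
#'   non-outgroup tips.
#' @param alpha Significance level on the adjusted p-value.
#' @return List with `class` (`"ancient"`/`"recent"`),
#'   `phylogeography_violated` and `flagged` (monophyly check skipped).
#' @export
classify_locus <- function(cpd, adjusted_p, tree, basins, alpha = 0.05) {
  rooted <- isTRUE(attr(tree, "rooted"))
  violated <- NA
  flagged <- !rooted
  if (rooted) {
    basin_levels <- unique(unname(basins))
    mono <- vapply(basin_levels, function(b) {
      tips <- intersect(names(basins)[basins == b], tree$tip.label)
      if (length(tips) < 2) return(TRUE)
      ape::is.monophyletic(tree, tips)
    }, logical(1))
    violated <- !all(mono)
  }
  sig <- !is.na(cpd) && cpd > 0 && !is.na(adjusted_p) && adjusted_p < alpha
  cls <- if (sig && (is.na(violated) || violated)) "ancient" else "recent"
  list(class = cls, phylogeography_violated = violated, flagged = flagged)
}
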