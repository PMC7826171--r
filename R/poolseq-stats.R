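# Diversity and differentiation estimators from pooled read counts, and
# the same estimators from exact haplotype counts (the oracle path used
# for calibration). Count vectors follow sync order A,T,C,G,N,del; only
# A,C,G,T enter any statistic.

#' Per-site nucleotide diversity from read counts
#'
#' The unbiased average pairwise difference among reads:
#' `pi = C/(C-1) * (1 - sum_a (c_a/C)^2)` with `C` the usable (A+T+C+G)
#' coverage. Identical to enumerating all read pairs and counting the
#' fraction that differ.
#'
#' @param counts Numeric vector (length >= 4, sync base order) or matrix
#'   with sites in rows.
#' @param min_coverage Sites with usable coverage below this (and always
#'   below 2) return `NA`.
#' @return Per-site diversity, vectorized over rows.
#' @examples
#' pi_site(c(5, 5, 0, 0, 0, 0)) # 25/45
#' @export
pi_site <- function(counts, min_coverage = 2) {
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  acgt <- m[, 1:4, drop = FALSE]
  C <- rowSums(acgt)
  p2 <- rowSums((acgt / ifelse(C > 0, C, 1))^2)
  out <- ifelse(C >= max(2, min_coverage), C / (C - 1) * (1 - p2), NA_real_)
  if (is.matrix(counts)) out else out[1]
}

# Harmonic number sum_{i=1}^{n-1} 1/i used by Watterson's estimator.
harmonic_a1 <- function(n_chrom) sum(1 / seq_len(n_chrom - 1L))

#' Watterson's theta per site
#'
#' @param n_snps Number of segregating sites in the window.
#' @param n_chrom Number of sampled chromosomes (2 x pooled diploids).
#' @param window_length Window length in bp.
#' @return `n_snps / (a_n * window_length)`.
#' @export
theta_watterson <- function(n_snps, n_chrom, window_length) {
  if (any(window_length == 0)) stop("window_length must be positive")
  stopifnot(n_chrom >= 2)
  n_snps / (harmonic_a1(n_chrom) * window_length)
}

#' Tajima's D
#'
#' Standard normalization of the difference between the pairwise-diversity
#' and Watterson estimates of theta, with the classic variance constants
#' evaluated at `n_chrom` sampled chromosomes.
#'
#' @param pi_sum Sum of per-site pairwise diversity over the window.
#' @param n_snps Number of segregating sites.
#' @param n_chrom Number of sampled chromosomes.
#' @param min_snps Return `NA` when fewer segregating sites than this.
#' @return Tajima's D, or `NA` when undefined.
#' @export
tajimas_d <- function(pi_sum, n_snps, n_chrom, min_snps = 3) {
  n <- n_chrom
  stopifnot(n >= 2)
  if (is.na(n_snps) || n_snps < min_snps) return(NA_real_)
  a1 <- harmonic_a1(n)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * n_snps + e2 * n_snps * (n_snps - 1)
  if (v <= 0) return(NA_real_)
  (pi_sum - n_snps / a1) / sqrt(v)
}

#' Per-site FST between two pools
#'
#' `FST = (pi_T - pi_S) / pi_T` where `pi_S` is the mean within-pool
#' heterozygosity `1 - sum p_a^2` and `pi_T` uses the unweighted mean of
#' the two pools' allele frequencies. Negative values are clamped to 0;
#' the value is `NA` when both pools are monomorphic for the same allele
#' (`pi_T = 0`) or either pool fails the coverage floor.
#'
#' @param counts1,counts2 Count vectors (sync base order) for the two pools.
#' @param min_coverage Minimum usable coverage per pool.
#' @return FST in `[0, 1]`, or `NA`.
#' @examples
#' fst_site(c(16, 4, 0, 0, 0, 0), c(4, 16, 0, 0, 0, 0)) # 0.36
#' @export
fst_site <- function(counts1, counts2, min_coverage = 2) {
  a1 <- counts1[1:4]; a2 <- counts2[1:4]
  C1 <- sum(a1); C2 <- sum(a2)
  if (C1 < max(1, min_coverage) || C2 < max(1, min_coverage)) return(NA_real_)
  p1 <- a1 / C1; p2 <- a2 / C2
  pi_s <- mean(c(1 - sum(p1^2), 1 - sum(p2^2)))
  pbar <- (p1 + p2) / 2
  pi_t <- 1 - sum(pbar^2)
  if (pi_t == 0) return(NA_real_)
  max(0, (pi_t - pi_s) / pi_t)
}

#' Expected heterozygosity of a biallelic site
#'
#' @param p Allele frequency in `[0, 1]`.
#' @return `2 p (1 - p)`, vectorized.
#' @export
heterozygosity <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  2 * p * (1 - p)
}

#' Folded site frequency spectrum with gene-level bootstrap
#'
#' Folds allele frequencies to the minor side `min(p, 1 - p)`, bins them
#' into `n_bins` equal bins over `(0, 0.5]`, and attaches percentile
#' bootstrap confidence intervals obtained by resampling the grouping
#' units (typically genes) with replacement.
#'
#' @param frequencies Allele frequencies strictly inside `(0, 1)`.
#' @param n_bins Number of equal-width bins over `(0, 0.5]`.
#' @param bootstrap_units Grouping factor (one per frequency) resampled by
#'   the bootstrap; default treats each SNP as its own unit.
#' @param n_boot Bootstrap replicates; 0 returns point estimates only.
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level for the percentile interval.
#' @return An `sfs_spectrum`: bin edges, per-bin proportion (summing to
#'   1), CI bounds, SNP count.
#' @export
folded_sfs <- function(frequencies, n_bins = 5, bootstrap_units = NULL,
                       n_boot = 0, seed = 1L, conf = 0.95) {
  if (length(frequencies) == 0) stop("no frequencies supplied")
  if (any(frequencies <= 0 | frequencies >= 1)) {
    stop("frequencies must lie strictly inside (0, 1)")
  }
  if (is.null(bootstrap_units)) bootstrap_units <- seq_along(frequencies)
  stopifnot(length(bootstrap_units) == length(frequencies))
  w <- 0.5 / n_bins
  breaks <- seq(0, 0.5, length.out = n_bins + 1)
  bin_of <- function(p) {
    q <- pmin(p, 1 - p)
    pmin(pmax(ceiling(q / w - 1e-9), 1L), n_bins)
  }
  prop_of <- function(p) tabulate(bin_of(p), nbins = n_bins) / length(p)
  prop <- prop_of(frequencies)
  ci_lo <- ci_hi <- rep(NA_real_, n_bins)
  if (n_boot > 0) {
    units <- unique(bootstrap_units)
    idx_of <- split(seq_along(frequencies), bootstrap_units)
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        take <- sample(as.character(units), length(units), replace = TRUE)
        prop_of(frequencies[unlist(idx_of[take], use.names = FALSE)])
      }, numeric(n_bins))
    })
    if (n_bins == 1) boot <- matrix(boot, nrow = 1)
    alpha <- (1 - conf) / 2
    ci_lo <- apply(boot, 1, quantile, probs = alpha, names = FALSE)
    ci_hi <- apply(boot, 1, quantile, probs = 1 - alpha, names = FALSE)
  }
  structure(list(breaks = breaks, proportion = prop, ci_lower = ci_lo,
                 ci_upper = ci_hi, n_snps = length(frequencies),
                 n_boot = n_boot),
            class = "sfs_spectrum")
}

#' @export
print.sfs_spectrum <- function(x, ...) {
  cat(sprintf("folded SFS over %d SNPs, %d bins:\n", x$n_snps,
              length(x$proportion)))
  lab <- sprintf("(%.2f,%.2f]", head(x$breaks, -1), x$breaks[-1])
  print(setNames(round(x$proportion, 4), lab))
  invisible(x)
}

# ---- window-level statistics ----------------------------------------------

#' Window diversity statistics for one pool
#'
#' Applies coverage and SNP-calling filters to a matrix of per-site counts
#' and returns per-site pi, Watterson theta and Tajima's D over a window.
#' Sites absent from the count matrix are treated as covered and
#' monomorphic (sync files list polymorphic sites only), so per-site
#' values divide by `window_length`. A site is called a SNP when its
#' second-most-common base has read count >= `min_count` and within-pool
#' frequency >= `maf`.
#'
#' @param counts Matrix sites x 6 (sync base order) for one pool; may have
#'   zero rows.
#' @param n_chrom Chromosomes in the pool (2 x diploids).
#' @param window_length Window length in bp.
#' @param min_count,maf SNP-calling filters.
#' @param min_cov,max_cov Per-site usable-coverage bounds.
#' @param min_snps_for_d Tajima's D is `NA` below this SNP count.
#' @return List: `pi` (per site), `theta_w` (per site), `tajimas_d`,
#'   `n_snps`, `pi_sum`, `mean_coverage`, `n_usable`.
#' @export
window_pool_stats <- function(counts, n_chrom, window_length,
                              min_count = 2, maf = 0.05,
                              min_cov = 2, max_cov = Inf,
                              min_snps_for_d = 3) {
  if (is.null(counts) || nrow(counts) == 0) {
    return(list(pi = 0, theta_w = 0, tajimas_d = NA_real_, n_snps = 0L,
                pi_sum = 0, mean_coverage = NA_real_, n_usable = 0L))
  }
  acgt <- counts[, 1:4, drop = FALSE]
  C <- rowSums(acgt)
  usable <- C >= max(2, min_cov) & C <= max_cov
  pi_vals <- pi_site(counts, min_coverage = max(2, min_cov))
  pi_sum <- sum(pi_vals[usable], na.rm = TRUE)
  second <- apply(acgt, 1, function(v) sort(v, decreasing = TRUE)[2])
  is_snp <- usable & second >= min_count & (second / C) >= maf
  S <- sum(is_snp)
  list(pi = pi_sum / window_length,
       theta_w = theta_watterson(S, n_chrom, window_length),
       tajimas_d = tajimas_d(pi_sum, S, n_chrom, min_snps = min_snps_for_d),
       n_snps = as.integer(S), pi_sum = pi_sum,
       mean_coverage = mean(C), n_usable = as.integer(sum(usable)))
}

#' Window diversity statistics from exact haplotypes
#'
#' The oracle path: identical formulas to [window_pool_stats()] but with
#' allele counts tabulated directly from a haplotype-by-site allele
#' matrix, so coverage equals the chromosome count at every site.
#'
#' @param alleles Character matrix, haplotypes x sites.
#' @param window_length Window length in bp.
#' @param min_count,maf Optional SNP-calling filters (defaults call every
#'   segregating site).
#' @inheritParams window_pool_stats
#' @return As [window_pool_stats()].
#' @export
haplotype_window_stats <- function(alleles, window_length,
                                   min_count = 1, maf = 0,
                                   min_snps_for_d = 3) {
  n_chrom <- nrow(alleles)
  n_site <- ncol(alleles)
  counts <- matrix(0, nrow = n_site, ncol = 6,
                   dimnames = list(NULL, SYNC_BASES))
  if (n_site > 0) {
    for (s in seq_len(n_site)) {
      counts[s, match(ACGT, SYNC_BASES)] <-
        tabulate(match(alleles[, s], ACGT), nbins = 4)
    }
  }
  window_pool_stats(counts, n_chrom, window_length, min_count = min_count,
                    maf = maf, min_cov = 2, max_cov = Inf,
                    min_snps_for_d = min_snps_for_d)
}
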