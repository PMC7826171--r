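# Contrasts of diversity statistics between TSP-bearing exons and all
# other exons, as a function of exon length, plus the folded-SFS contrast
# between candidate and reference gene sets. Both groups run through
# exactly the same code path.

#' Diversity statistics for one exon
#'
#' Restricts the window statistics to the exon interval for every pool,
#' averages pairwise FST over all population pairs and SNP sites, and
#' accumulates expected heterozygosity separately over nonsynonymous and
#' synonymous coding SNPs (sums of per-site H_E; their ratio measures
#' sheltered load and is `NA` when the synonymous sum is 0).
#'
#' @param gene_id,exon_index,contig,start,end Exon identity and interval.
#' @param sync A `sync_counts` object over all pools.
#' @param pool_sizes Named vector of diploids per pool.
#' @param snp_info Optional data.frame with `pos`, `is_tsp`, `effect`
#'   (`"NS"`/`"S"`/other) and `he` for annotated SNPs on this contig.
#' @param min_count,maf,min_cov,max_cov Filters as in
#'   [window_pool_stats()].
#' @return One-row data.frame: identity, `length`, `has_tsp`, per-pool
#'   `pi_*` and `d_*`, `pi_mean`, `d_mean`, `fst_mean`, `he_ns_sum`,
#'   `he_s_sum`, `he_ratio`, `n_snps`.
#' @export
per_exon_stats <- function(gene_id, exon_index, contig, start, end,
                           sync, pool_sizes, snp_info = NULL,
                           min_count = 2, maf = 0.05, min_cov = 10,
                           max_cov = Inf) {
  len <- end - start + 1L
  stopifnot(len >= 1)
  pops <- sync$population_ids
  in_win <- sync$sites$contig == contig &
    sync$sites$pos >= start & sync$sites$pos <= end
  pi_v <- d_v <- setNames(numeric(length(pops)), pops)
  n_snps <- 0L
  for (j in seq_along(pops)) {
    cm <- matrix(sync$counts[in_win, j, ], ncol = 6)
    st <- window_pool_stats(cm, 2 * pool_sizes[[pops[j]]], len,
                            min_count = min_count, maf = maf,
                            min_cov = min_cov, max_cov = max_cov)
    pi_v[j] <- st$pi
    d_v[j] <- st$tajimas_d
    n_snps <- max(n_snps, st$n_snps)
  }
  # mean pairwise FST over all population pairs, averaged over sites
  fst_mean <- NA_real_
  if (length(pops) >= 2 && any(in_win)) {
    idx <- which(in_win)
    pair_means <- c()
    for (a in 1:(length(pops) - 1)) {
      for (b in (a + 1):length(pops)) {
        v <- vapply(idx, function(i)
          fst_site(sync$counts[i, a, ], sync$counts[i, b, ],
                   min_coverage = min_cov), numeric(1))
        pair_means <- c(pair_means, mean(v, na.rm = TRUE))
      }
    }
    fst_mean <- mean(pair_means, na.rm = TRUE)
    if (is.nan(fst_mean)) fst_mean <- NA_real_
  }
  has_tsp <- FALSE
  he_ns <- he_s <- 0
  if (!is.null(snp_info) && nrow(snp_info) > 0) {
    inside <- snp_info$pos >= start & snp_info$pos <= end
    has_tsp <- any(inside & snp_info$is_tsp, na.rm = TRUE)
    eff <- snp_info$effect[inside]
    he <- snp_info$he[inside]
    he_ns <- sum(he[!is.na(eff) & eff == "NS"], na.rm = TRUE)
    he_s <- sum(he[!is.na(eff) & eff == "S"], na.rm = TRUE)
  }
  data.frame(gene_id = gene_id, exon_index = exon_index, contig = contig,
             start = start, end = end, length = len, has_tsp = has_tsp,
             t(setNames(pi_v, paste0("pi_", pops))),
             t(setNames(d_v, paste0("d_", pops))),
             pi_mean = mean(pi_v, na.rm = TRUE),
             d_mean = if (all(is.na(d_v))) NA_real_ else mean(d_v, na.rm = TRUE),
             fst_mean = fst_mean,
             he_ns_sum = he_ns, he_s_sum = he_s,
             he_ratio = if (he_s > 0) he_ns / he_s else NA_real_,
             n_snps = n_snps,
             stringsAsFactors = FALSE)
}

#' Length-binned contrast of an exon statistic
#'
#' Partitions exons into length bins (default 250-bp bins up to 3 kb,
#' last bin open-ended) and, per bin and group (TSP-bearing vs other),
#' reports the mean of the chosen statistic with a percentile bootstrap
#' confidence interval over exons. `n_boot = 0` returns point estimates
#' only, deterministically.
#'
#' @param exon_stats data.frame of [per_exon_stats()] rows.
#' @param statistic Column name to contrast (e.g. `"d_mean"`).
#' @param bin_width,max_length Bin layout in bp.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level.
#' @return data.frame: `bin_lo`, `bin_hi`, `group`, `n`, `mean`,
#'   `ci_lower`, `ci_upper`.
#' @export
length_binned_contrast <- function(exon_stats, statistic, bin_width = 250,
                                   max_length = 3000, n_boot = 200,
                                   seed = 1L, conf = 0.95) {
  stopifnot(statistic %in% names(exon_stats), nrow(exon_stats) >= 1)
  n_closed <- max_length %/% bin_width
  bin <- pmin(ceiling(exon_stats$length / bin_width), n_closed + 1L)
  lo <- (seq_len(n_closed + 1L) - 1L) * bin_width
  hi <- c(seq_len(n_closed) * bin_width, Inf)
  groups <- c("tsp", "other")
  grp <- ifelse(exon_stats$has_tsp, "tsp", "other")
  x <- exon_stats[[statistic]]
  alpha <- (1 - conf) / 2
  rows <- list()
  for (b in seq_len(n_closed + 1L)) {
    for (g in groups) {
      sel <- which(bin == b & grp == g)
      v <- x[sel]
      v_ok <- v[!is.na(v)]
      mn <- if (length(v_ok)) mean(v_ok) else NA_real_
      ci <- c(NA_real_, NA_real_)
      if (n_boot > 0 && length(v_ok) > 0) {
        boot <- with_seed(derive_seed(seed, paste0("bin", b, "_", g)), {
          vapply(seq_len(n_boot), function(r)
            mean(sample(v_ok, length(v_ok), replace = TRUE)), numeric(1))
        })
        ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        bin_lo = lo[b], bin_hi = hi[b], group = g, n = length(sel),
        mean = mn, ci_lower = ci[1], ci_upper = ci[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Folded-SFS contrast between gene sets
#'
#' Computes the folded site frequency spectrum, with gene-level bootstrap
#' confidence intervals, for the SNPs of a candidate gene set and of a
#' reference gene set.
#'
#' @param candidate_gene_ids Genes of interest (non-empty).
#' @param reference_gene_ids Reference genes (e.g. all other annotated
#'   genes, or all genes).
#' @param snp_gene_ids Gene id of every SNP (`NA` = not in a gene).
#' @param frequencies Allele frequency of every SNP.
#' @param n_bins Folded-SFS bins.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @return List with `candidate` and `reference` [folded_sfs()] spectra.
#' @export
gene_set_sfs_contrast <- function(candidate_gene_ids, reference_gene_ids,
                                  snp_gene_ids, frequencies,
                                  n_bins = 5, n_boot = 0, seed = 1L) {
  if (length(candidate_gene_ids) == 0) stop("candidate gene set is empty")
  stopifnot(length(snp_gene_ids) == length(frequencies))
  one <- function(gene_set, label) {
    sel <- !is.na(snp_gene_ids) & snp_gene_ids %in% gene_set
    if (!any(sel)) stop("no SNPs in ", label, " gene set")
    folded_sfs(frequencies[sel], n_bins = n_bins,
               bootstrap_units = snp_gene_ids[sel], n_boot = n_boot,
               seed = derive_seed(seed, label))
  }
  list(candidate = one(candidate_gene_ids, "candidate"),
       reference = one(reference_gene_ids, "reference"))
}
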