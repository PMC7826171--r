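# Calling cosmopolitan SNPs and trans-species polymorphisms (TSPs),
# distance thinning, genomic-class and synonymous/nonsynonymous
# annotation, expected-heterozygosity filtering and per-class enrichment.

GENOMIC_CLASSES <- c("coding", "utr5", "utr3", "intron", "promoter",
                     "intergenic")

#' Site-level SNP table from sync counts
#'
#' For every sync site, applies per-pool coverage filters, determines the
#' supported alleles (a base is supported when at least one passing pool
#' shows it at read count >= `min_count` and frequency >= `maf`), and
#' flags biallelic, discovered (supported polymorphism in >= 1 pool) and
#' cosmopolitan (minor allele at count >= `min_count` and frequency >=
#' `maf` in *every* pool) sites. Sites with more than two supported
#' alleles are excluded from TSP logic but remain available to diversity
#' statistics.
#'
#' @param sync A `sync_counts` object.
#' @param min_count Minimum minor-allele read count.
#' @param maf Minimum minor-allele frequency.
#' @param min_cov,max_cov Usable-coverage bounds per pool.
#' @return A `snp_table`: list with `sites` (contig, pos, ref, alt,
#'   n_alleles, biallelic, discovered, cosmopolitan), `freq` (alt-allele
#'   frequency matrix, sites x pools, `NA` where coverage fails), `cov`
#'   and `pass` matrices, and the filter settings.
#' @export
scan_snps <- function(sync, min_count = 2, maf = 0.05,
                      min_cov = 10, max_cov = Inf) {
  stopifnot(inherits(sync, "sync_counts"))
  n <- nrow(sync$sites)
  pops <- sync$population_ids
  np <- length(pops)
  bases <- SYNC_BASES[1:4]
  cov <- matrix(0, n, np, dimnames = list(NULL, pops))
  supported <- matrix(FALSE, n, 4, dimnames = list(NULL, bases))
  pass <- matrix(FALSE, n, np, dimnames = list(NULL, pops))
  cnt4 <- array(0, dim = c(n, np, 4))
  if (n > 0) {
    for (j in seq_len(np)) {
      cj <- sync$counts[, j, 1:4, drop = FALSE]
      dim(cj) <- c(n, 4)
      cnt4[, j, ] <- cj
      cov[, j] <- rowSums(cj)
      pass[, j] <- cov[, j] >= min_cov & cov[, j] <= max_cov
      fr <- cj / ifelse(cov[, j] > 0, cov[, j], 1)
      supported <- supported |
        (pass[, j] & cj >= min_count & fr >= maf)
    }
  }
  n_alleles <- rowSums(supported)
  biallelic <- n_alleles == 2
  ref <- sync$sites$ref
  alt <- rep(NA_character_, n)
  a1 <- rep(NA_character_, n)
  for (i in which(biallelic)) {
    pair <- bases[supported[i, ]]
    if (ref[i] %in% pair) {
      a1[i] <- ref[i]
      alt[i] <- setdiff(pair, ref[i])
    } else {
      tot <- colSums(matrix(cnt4[i, , ], nrow = np))
      names(tot) <- bases
      pair <- pair[order(-tot[pair])]
      a1[i] <- pair[1]
      alt[i] <- pair[2]
    }
  }
  freq <- matrix(NA_real_, n, np, dimnames = list(NULL, pops))
  for (j in seq_len(np)) {
    idx <- which(biallelic & pass[, j])
    if (length(idx)) {
      ai <- match(alt[idx], bases)
      freq[idx, j] <- cnt4[cbind(idx, j, ai)] / cov[idx, j]
    }
  }
  minor_freq <- pmin(freq, 1 - freq)
  alt_count <- matrix(NA_real_, n, np)
  for (j in seq_len(np)) {
    idx <- which(biallelic)
    if (length(idx)) {
      ai <- match(alt[idx], bases)
      alt_count[idx, j] <- cnt4[cbind(idx, j, ai)]
    }
  }
  minor_count <- pmin(alt_count, cov - alt_count)
  discovered <- biallelic &
    rowSums(!is.na(minor_freq) & minor_freq >= maf & minor_count >= min_count,
            na.rm = FALSE) >= 1
  discovered[is.na(discovered)] <- FALSE
  cosmopolitan <- biallelic & rowSums(pass) == np &
    apply(minor_freq >= maf & minor_count >= min_count, 1,
          function(z) all(!is.na(z) & z))
  sites <- data.frame(contig = sync$sites$contig, pos = sync$sites$pos,
                      ref = a1, ref_base = ref, alt = alt,
                      n_alleles = n_alleles, biallelic = biallelic,
                      discovered = discovered, cosmopolitan = cosmopolitan,
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, freq = freq, cov = cov, pass = pass,
                 settings = list(min_count = min_count, maf = maf,
                                 min_cov = min_cov, max_cov = max_cov)),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d sites, %d discovered SNPs, %d cosmopolitan\n",
              nrow(x$sites), sum(x$sites$discovered),
              sum(x$sites$cosmopolitan)))
  invisible(x)
}

#' Is a site cosmopolitan?
#'
#' A biallelic site is cosmopolitan when its minor-allele frequency is at
#' least `maf_threshold` in every focal population; any missing frequency
#' (failed coverage) makes the site non-cosmopolitan.
#'
#' @param freqs Per-population frequencies of one allele.
#' @param maf_threshold Minor-allele frequency threshold.
#' @return Logical scalar.
#' @examples
#' call_cosmopolitan(c(0.3, 0.4, 0.5))  # TRUE
#' call_cosmopolitan(c(0.3, 0.4, 1.0))  # FALSE: fixed in one population
#' @export
call_cosmopolitan <- function(freqs, maf_threshold = 0.05) {
  if (length(freqs) == 0 || any(is.na(freqs))) return(FALSE)
  all(pmin(freqs, 1 - freqs) >= maf_threshold)
}

#' Call trans-species polymorphisms against outgroup genotypes
#'
#' A cosmopolitan site is a TSP when both of its alleles are observed in
#' the outgroup sample (for a single diploid outgroup: a heterozygous
#' genotype carrying the same two alleles). Sites absent from the VCF, or
#' masked/mismatching in the outgroup, get `outgroup_state = "missing"`.
#'
#' @param snps A `snp_table` from [scan_snps()].
#' @param phased A `phased_genotypes` object containing the outgroup.
#' @return data.frame of the cosmopolitan sites with `outgroup_state`
#'   (`both_alleles`, `ref_only`, `alt_only`, `missing`), `is_tsp`, and
#'   per-population alt-frequency columns `freq_<pop>`.
#' @export
call_tsp <- function(snps, phased) {
  stopifnot(inherits(snps, "snp_table"), inherits(phased, "phased_genotypes"))
  idx <- which(snps$sites$cosmopolitan)
  out_cols <- which(phased$info$species == "outgroup")
  if (length(out_cols) == 0) stop("no outgroup haplotypes in phased genotypes")
  key_vcf <- paste(phased$sites$contig, phased$sites$pos)
  res <- snps$sites[idx, c("contig", "pos", "ref", "alt"), drop = FALSE]
  state <- rep("missing", length(idx))
  m <- match(paste(res$contig, res$pos), key_vcf)
  for (k in seq_along(idx)) {
    if (is.na(m[k])) next
    og <- phased$haps[m[k], out_cols]
    if (any(is.na(og))) next
    has_ref <- any(og == res$ref[k])
    has_alt <- any(og == res$alt[k])
    if (any(!og %in% c(res$ref[k], res$alt[k]))) next # third allele
    state[k] <- if (has_ref && has_alt) "both_alleles"
                else if (has_ref) "ref_only" else "alt_only"
  }
  res$outgroup_state <- state
  res$is_tsp <- state == "both_alleles"
  fr <- snps$freq[idx, , drop = FALSE]
  colnames(fr) <- paste0("freq_", colnames(fr))
  cbind(res, as.data.frame(fr), stringsAsFactors = FALSE)
}

#' Thin sites by distance
#'
#' Greedy left-to-right thinning: on each contig keep a site iff it lies
#' at least `min_dist` bp from the last kept site (a distance of exactly
#' `min_dist` is kept).
#'
#' @param sites data.frame with `contig` and `pos`, sorted by position
#'   within each contig.
#' @param min_dist Minimum distance in bp.
#' @return Logical vector of retained rows.
#' @export
thin_by_distance <- function(sites, min_dist) {
  keep <- logical(nrow(sites))
  for (ct in unique(sites$contig)) {
    i <- which(sites$contig == ct)
    p <- sites$pos[i]
    if (is.unsorted(p, strictly = FALSE)) {
      stop("sites must be sorted by position within contig ", ct)
    }
    last <- -Inf
    for (k in seq_along(i)) {
      if (p[k] - last >= min_dist) {
        keep[i[k]] <- TRUE
        last <- p[k]
      }
    }
  }
  keep
}

#' Assign a genomic class to positions
#'
#' Classes partition every position, resolved in the priority order
#' coding > 5'-UTR > 3'-UTR > intron > promoter > intergenic; the
#' promoter is the `promoter_bp` window immediately upstream of the TSS
#' on the coding strand.
#'
#' @param contig,pos Vectors of positions.
#' @param gene_models A `gene_models` object.
#' @param promoter_bp Promoter window size in bp.
#' @return data.frame with `genomic_class` (factor over the six classes)
#'   and `gene_id` (`NA` for intergenic).
#' @export
assign_genomic_class <- function(contig, pos, gene_models,
                                 promoter_bp = 1000) {
  n <- length(pos)
  cls <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  rank <- setNames(seq_along(GENOMIC_CLASSES), GENOMIC_CLASSES)
  best <- rep(rank[["intergenic"]], n)
  hit <- function(iv, ctg) {
    if (is.null(iv) || nrow(iv) == 0) return(logical(n))
    out <- logical(n)
    on_ctg <- contig == ctg
    for (r in seq_len(nrow(iv))) {
      out <- out | (on_ctg & pos >= iv[r, 1] & pos <= iv[r, 2])
    }
    out
  }
  for (gm in gene_models) {
    intron <- interval_complement(gm$exons, gm$start, gm$end)
    prom <- if (gm$strand == "-") {
      iv_matrix(gm$tss + 1L, gm$tss + promoter_bp)
    } else {
      iv_matrix(max(1L, gm$tss - promoter_bp), gm$tss - 1L)
    }
    feats <- list(coding = gm$cds, utr5 = gm$utr5, utr3 = gm$utr3,
                  intron = intron, promoter = prom)
    for (cl in names(feats)) {
      h <- hit(feats[[cl]], gm$contig)
      better <- h & rank[[cl]] < best
      if (any(better)) {
        cls[better] <- cl
        gene[better] <- gm$gene_id
        best[better] <- rank[[cl]]
      }
    }
  }
  data.frame(genomic_class = factor(cls, levels = GENOMIC_CLASSES),
             gene_id = gene, stringsAsFactors = FALSE)
}

# Intervals inside [lo, hi] not covered by `iv` (used for introns).
interval_complement <- function(iv, lo, hi) {
  if (is.null(iv) || nrow(iv) == 0) return(iv_matrix(lo, hi))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  gaps_s <- integer(); gaps_e <- integer()
  cur <- lo
  for (r in seq_len(nrow(iv))) {
    if (iv[r, 1] > cur) {
      gaps_s <- c(gaps_s, cur)
      gaps_e <- c(gaps_e, iv[r, 1] - 1L)
    }
    cur <- max(cur, iv[r, 2] + 1L)
  }
  if (cur <= hi) {
    gaps_s <- c(gaps_s, cur)
    gaps_e <- c(gaps_e, hi)
  }
  iv_matrix(gaps_s, gaps_e)
}

#' Classify a coding SNP as synonymous or nonsynonymous
#'
#' Translates the reference codon and the codon with the alternate allele
#' substituted, reverse-complementing on minus-strand gene models, under
#' the standard genetic code.
#'
#' @param pos Genomic position (1-based) of the SNP.
#' @param ref_allele,alt_allele The two alleles as genomic-strand bases.
#' @param gene_model A `gene_model` whose CDS contains `pos`.
#' @param ref_seq Reference sequence of the model's contig.
#' @return `"NS"`, `"S"`, `"noncoding"` (pos outside the CDS), or `NA`
#'   when the codon contains an ambiguous base or the model is unusable.
#' @export
classify_ns_s <- function(pos, ref_allele, alt_allele, gene_model, ref_seq) {
  gm <- gene_model
  if (!isTRUE(gm$cds_ok)) return(NA_character_)
  if (nrow(gm$cds) == 0) return("noncoding")
  gpos <- unlist(lapply(seq_len(nrow(gm$cds)),
                        function(r) seq(gm$cds[r, 1], gm$cds[r, 2])))
  if (gm$strand == "-") gpos <- rev(gpos)
  if (gm$phase > 0) gpos <- gpos[-seq_len(gm$phase)]
  ci <- match(pos, gpos)
  if (is.na(ci)) return("noncoding")
  codon_i <- (ci - 1L) %/% 3L
  within <- (ci - 1L) %% 3L
  cpos <- gpos[codon_i * 3L + 1:3]
  bases <- toupper(substring(ref_seq, cpos, cpos))
  raw_ref <- toupper(ref_allele); raw_alt <- toupper(alt_allele)
  if (gm$strand == "-") {
    bases <- comp_base(bases)
    raw_ref <- comp_base(raw_ref)
    raw_alt <- comp_base(raw_alt)
  }
  codon_ref <- bases
  codon_ref[within + 1L] <- raw_ref
  codon_alt <- bases
  codon_alt[within + 1L] <- raw_alt
  if (any(!codon_ref %in% ACGT) || any(!codon_alt %in% ACGT)) {
    return(NA_character_)
  }
  aa_ref <- Biostrings::GENETIC_CODE[[paste(codon_ref, collapse = "")]]
  aa_alt <- Biostrings::GENETIC_CODE[[paste(codon_alt, collapse = "")]]
  if (aa_ref == aa_alt) "S" else "NS"
}

#' Per-class TSP enrichment
#'
#' For every genomic class, builds the 2x2 table (TSP in/out of class vs
#' non-TSP in/out of class), computes the odds ratio `ad/bc` and a
#' two-sided Fisher exact test, and Bonferroni-adjusts across the tested
#' classes. Classes with zero SNPs in both groups are skipped with a note.
#'
#' @param tsp_class Genomic classes of the TSPs.
#' @param other_class Genomic classes of the non-TSP SNPs.
#' @return data.frame with class, a, b, c, d, odds_ratio, p_value,
#'   adjusted_p, skipped.
#' @export
enrichment_test <- function(tsp_class, other_class) {
  tsp_class <- as.character(tsp_class)
  other_class <- as.character(other_class)
  out <- lapply(GENOMIC_CLASSES, function(cl) {
    a <- sum(tsp_class == cl)
    b <- sum(tsp_class != cl)
    c_ <- sum(other_class == cl)
    d <- sum(other_class != cl)
    if (a + c_ == 0) {
      return(data.frame(class = cl, a = a, b = b, c = c_, d = d,
                        odds_ratio = NA_real_, p_value = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    or <- (a * d) / (b * c_)
    p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2))$p.value
    data.frame(class = cl, a = a, b = b, c = c_, d = d, odds_ratio = or,
               p_value = p, skipped = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  tested <- !res$skipped
  res$adjusted_p <- NA_real_
  res$adjusted_p[tested] <- pmin(1, res$p_value[tested] * sum(tested))
  res
}

#' Filter TSPs by expected heterozygosity
#'
#' Keeps records whose expected heterozygosity `2p(1-p)` exceeds `he_min`
#' (strictly) in every focal population.
#'
#' @param tsp_records data.frame from [call_tsp()] with `freq_<pop>`
#'   columns.
#' @param he_min Heterozygosity threshold.
#' @return Logical vector of retained rows.
#' @export
filter_by_he <- function(tsp_records, he_min = 0.30) {
  fc <- grep("^freq_", names(tsp_records), value = TRUE)
  if (length(fc) == 0) stop("no freq_<pop> columns in tsp_records")
  he <- heterozygosity(as.matrix(tsp_records[, fc, drop = FALSE]))
  apply(he, 1, function(z) all(!is.na(z) & z > he_min))
}
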