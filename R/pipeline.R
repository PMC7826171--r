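# End-to-end orchestration: from sync/VCF/GFF/FASTA inputs to the ranked
# candidate-gene table, with every stochastic stage seeded from one
# master seed (per-stage derived seeds, so runs are byte-reproducible).

#' Scan configuration
#'
#' Bundles input paths and all thresholds of the scan. Defaults follow
#' the scan design: SNP panel at minor-allele frequency > 5%, 500-bp
#' LD thinning, H_E > 0.30 high-frequency filter, 1-kb promoters,
#' +/- 500 bp tree windows (LD decays below 1 kb in the study system).
#'
#' @param sync,vcf,gff,fasta Input file paths.
#' @param manifest Sample manifest: data.frame (or TSV path) with
#'   `sample_id`, `population_id`, `species`, `basin`.
#' @param pool_sizes Named vector of pooled diploids per population.
#' @param maf_threshold Minor-allele frequency threshold.
#' @param min_count Minimum minor-allele read count.
#' @param min_cov Minimum usable coverage per pool per site.
#' @param max_cov Maximum coverage (guards collapsed repeats); `NULL` =
#'   2 x the pool's mean observed coverage.
#' @param thin_distance LD-thinning distance in bp.
#' @param he_min Expected-heterozygosity threshold for the
#'   high-frequency TSP set.
#' @param promoter_bp Promoter window upstream of the TSS.
#' @param window_bp Half-window for allele trees at non-exonic TSPs.
#' @param n_perm Permutations for the CPD_w-b test.
#' @param n_boot Bootstrap replicates for contrasts and SFS.
#' @param sfs_bins Folded-SFS bins.
#' @param bin_width,max_exon_bin Exon-length bin layout (bp).
#' @param alpha Significance level on Bonferroni-adjusted p-values.
#' @param seed Master seed.
#' @param out_dir Optional output directory for TSV/newick/JSON outputs.
#' @return A `scan_config` object.
#' @export
scan_config <- function(sync, vcf, gff, fasta, manifest, pool_sizes,
                        maf_threshold = 0.05, min_count = 2, min_cov = 10,
                        max_cov = NULL, thin_distance = 500, he_min = 0.30,
                        promoter_bp = 1000, window_bp = 500, n_perm = 999,
                        n_boot = 200, sfs_bins = 5, bin_width = 250,
                        max_exon_bin = 3000, alpha = 0.05, seed = 1L,
                        out_dir = NULL) {
  if (is.character(manifest)) {
    manifest <- read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "population_id", "species") %in% names(manifest)))
  stopifnot(maf_threshold > 0, maf_threshold < 0.5,
            he_min >= 0, he_min < 0.5, thin_distance >= 0,
            min_count >= 0, min_cov >= 0, alpha > 0, alpha < 1,
            n_perm >= 99, n_boot >= 0)
  structure(list(sync = sync, vcf = vcf, gff = gff, fasta = fasta,
                 manifest = manifest, pool_sizes = pool_sizes,
                 maf_threshold = maf_threshold, min_count = min_count,
                 min_cov = min_cov, max_cov = max_cov,
                 thin_distance = thin_distance, he_min = he_min,
                 promoter_bp = promoter_bp, window_bp = window_bp,
                 n_perm = n_perm, n_boot = n_boot, sfs_bins = sfs_bins,
                 bin_width = bin_width, max_exon_bin = max_exon_bin,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
            class = "scan_config")
}

#' Scan configuration from a simulated dataset
#'
#' @param sim A `sim_dataset` from [emit_dataset()].
#' @param ... Overrides passed to [scan_config()].
#' @return A `scan_config` pointing at the dataset's files.
#' @export
scan_config_from_sim <- function(sim, ...) {
  stopifnot(inherits(sim, "sim_dataset"))
  args <- list(sync = sim$paths$sync, vcf = sim$paths$vcf,
               gff = sim$paths$gff, fasta = sim$paths$fasta,
               manifest = sim$manifest, pool_sizes = sim$pool_sizes,
               seed = sim$config$seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scan_config, args)
}

#' Run the full balancing-selection scan
#'
#' Stages: read inputs -> site filters and SNP discovery -> cosmopolitan
#' and TSP calling -> genomic-class and NS/S annotation -> per-class
#' enrichment -> H_E filter -> per-exon statistics and length-binned
#' contrasts -> gene-set SFS contrast -> allele trees, CPD_w-b,
#' permutation test, Bonferroni correction -> ancient/recent
#' classification -> ranked candidate table. Deterministic given the
#' config (one master seed fans out to all stochastic stages).
#'
#' @param config A [scan_config()].
#' @return A `tsp_scan` object: list with `snps`, `tsps`, `enrichment`,
#'   `exon_stats`, `contrasts`, `sfs_contrast`, `cpd_results`,
#'   `candidates`, `trees`, `counts`, `config`.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  ref <- read_fasta(config$fasta)
  models <- read_gff(config$gff)
  manifest <- config$manifest
  focal_pops <- manifest$population_id[manifest$species == "focal"]
  sync <- read_sync(config$sync, names(config$pool_sizes))
  phased <- read_phased_vcf(config$vcf, manifest)

  check_contigs <- function(ctgs, what) {
    bad <- setdiff(unique(ctgs), names(ref))
    if (length(bad)) {
      stop(sprintf("contig '%s' in %s is absent from the reference FASTA",
                   bad[1], what))
    }
  }
  check_contigs(sync$sites$contig, "sync")
  check_contigs(vapply(models, `[[`, "", "contig"), "GFF")
  check_contigs(phased$sites$contig, "VCF")

  max_cov <- config$max_cov
  if (is.null(max_cov)) {
    mean_cov <- mean(vapply(seq_along(sync$population_ids), function(j)
      mean(rowSums(matrix(sync$counts[, j, 1:4], ncol = 4))), numeric(1)))
    max_cov <- if (is.finite(mean_cov)) 2 * mean_cov else Inf
  }

  snps <- scan_snps(sync, min_count = config$min_count,
                    maf = config$maf_threshold,
                    min_cov = config$min_cov, max_cov = max_cov)
  disc <- which(snps$sites$discovered)
  thin_keep <- thin_by_distance(snps$sites[disc, , drop = FALSE],
                                config$thin_distance)

  tsps <- call_tsp(snps, phased)

  # genomic class + NS/S annotation for every discovered SNP
  ds <- snps$sites[disc, , drop = FALSE]
  cls <- assign_genomic_class(ds$contig, ds$pos, models,
                              promoter_bp = config$promoter_bp)
  effect <- rep("noncoding", nrow(ds))
  for (k in which(cls$genomic_class == "coding")) {
    gm <- models[[cls$gene_id[k]]]
    effect[k] <- classify_ns_s(ds$pos[k], ds$ref[k], ds$alt[k], gm,
                               ref[[gm$contig]]) %||% NA_character_
  }
  mean_freq <- rowMeans(snps$freq[disc, , drop = FALSE], na.rm = TRUE)
  annot <- data.frame(contig = ds$contig, pos = ds$pos,
                      genomic_class = as.character(cls$genomic_class),
                      gene_id = cls$gene_id, effect = effect,
                      mean_freq = mean_freq,
                      he = heterozygosity(mean_freq),
                      thinned = thin_keep,
                      stringsAsFactors = FALSE)
  key <- paste(annot$contig, annot$pos)
  tsp_key <- paste(tsps$contig, tsps$pos)
  annot$is_tsp <- key %in% tsp_key[tsps$is_tsp]
  tsps$genomic_class <- annot$genomic_class[match(tsp_key, key)]
  tsps$gene_id <- annot$gene_id[match(tsp_key, key)]
  tsps$effect <- annot$effect[match(tsp_key, key)]

  enr <- enrichment_test(annot$genomic_class[annot$is_tsp],
                         annot$genomic_class[!annot$is_tsp])
  tsp_set <- tsps[tsps$is_tsp, , drop = FALSE]
  high_he <- filter_by_he(tsp_set, config$he_min)

  # per-exon statistics over every exon of every gene model
  exon_rows <- list()
  for (gm in models) {
    for (e in seq_len(nrow(gm$exons))) {
      exon_rows[[length(exon_rows) + 1L]] <- per_exon_stats(
        gm$gene_id, e, gm$contig, gm$exons[e, 1], gm$exons[e, 2],
        sync, config$pool_sizes,
        snp_info = annot[annot$contig == gm$contig, , drop = FALSE],
        min_count = config$min_count, maf = config$maf_threshold,
        min_cov = config$min_cov, max_cov = max_cov)
    }
  }
  exon_stats <- do.call(rbind, exon_rows)
  contrasts <- lapply(
    setNames(nm = c("d_mean", "pi_mean", "fst_mean", "he_ratio")),
    function(stat) length_binned_contrast(
      exon_stats, stat, bin_width = config$bin_width,
      max_length = config$max_exon_bin, n_boot = config$n_boot,
      seed = derive_seed(config$seed, paste0("contrast_", stat))))

  # gene-set SFS: candidate genes = genes with >= 1 nonsynonymous TSP
  cand_genes <- sort(unique(tsp_set$gene_id[
    !is.na(tsp_set$effect) & tsp_set$effect == "NS"]))
  all_genes <- vapply(models, `[[`, "", "gene_id")
  ref_genes <- setdiff(all_genes, cand_genes)
  if (length(ref_genes) == 0) ref_genes <- all_genes
  in_gene <- annot$genomic_class %in% c("coding", "utr5", "utr3", "intron")
  sfs_contrast <- NULL
  if (length(cand_genes) > 0 && any(in_gene)) {
    sfs_contrast <- gene_set_sfs_contrast(
      cand_genes, ref_genes,
      snp_gene_ids = ifelse(in_gene, annot$gene_id, NA_character_),
      frequencies = annot$mean_freq,
      n_bins = config$sfs_bins, n_boot = config$n_boot,
      seed = derive_seed(config$seed, "sfs"))
  }

  # allele trees and CPD_w-b for candidate genes
  focal_info <- phased$info[phased$info$species == "focal", , drop = FALSE]
  trees <- list()
  cpd_rows <- list()
  for (g in cand_genes) {
    tg <- tsp_set[!is.na(tsp_set$gene_id) & tsp_set$gene_id == g &
                    tsp_set$effect %in% "NS", , drop = FALSE]
    tg <- tg[order(tg$pos), , drop = FALSE]
    row <- data.frame(gene_id = g, focal_pos = tg$pos[1],
                      cpd_wb = NA_real_, iqr_within = NA_real_,
                      iqr_between = NA_real_, p_value = NA_real_,
                      p_perm = NA_real_, skipped = NA_character_,
                      stringsAsFactors = FALSE)
    hw <- extract_window(tg$contig[1], tg$pos[1], phased, models,
                         window_bp = config$window_bp)
    if (inherits(hw, "skipped_locus")) {
      row$skipped <- hw$reason
      cpd_rows[[g]] <- row
      next
    }
    D <- pairwise_distance(hw)
    if (anyNA(D)) {
      row$skipped <- "haplotype pair with no jointly unmasked sites"
      cpd_rows[[g]] <- row
      next
    }
    og_tips <- hw$info$hap_id[hw$info$species == "outgroup"]
    tr <- build_tree(D, og_tips)
    pops_map <- setNames(hw$info$population_id, hw$info$hap_id)
    pops_map <- pops_map[hw$info$species == "focal"]
    st <- tryCatch(cpd_wb(tr, pops_map), error = function(e) NULL)
    if (is.null(st) || is.na(st$cpd_wb)) {
      row$skipped <- "no within-population haplotype pairs"
      cpd_rows[[g]] <- row
      next
    }
    pt <- permutation_test(tr, pops_map, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, paste0("perm_", g)))
    wt <- cpd_pair_test(tr, pops_map)
    row$cpd_wb <- st$cpd_wb
    row$iqr_within <- st$iqr_within
    row$iqr_between <- st$iqr_between
    row$p_value <- wt$p_value
    row$p_perm <- pt$p_value
    basins <- setNames(hw$info$basin, hw$info$hap_id)
    basins <- basins[hw$info$species == "focal"]
    trees[[g]] <- list(tree = tr, basins = basins)
    cpd_rows[[g]] <- row
  }
  cpd_results <- if (length(cpd_rows)) do.call(rbind, cpd_rows) else
    data.frame(gene_id = character(), focal_pos = integer(),
               cpd_wb = numeric(), iqr_within = numeric(),
               iqr_between = numeric(), p_value = numeric(),
               p_perm = numeric(), skipped = character(),
               stringsAsFactors = FALSE)
  tested <- which(!is.na(cpd_results$p_value))
  cpd_results$adjusted_p <- NA_real_
  cpd_results$adjusted_p[tested] <-
    pmin(1, cpd_results$p_value[tested] * length(tested))
  cpd_results$class <- NA_character_
  cpd_results$phylogeography_violated <- NA
  for (i in tested) {
    g <- cpd_results$gene_id[i]
    cl <- classify_locus(cpd_results$cpd_wb[i], cpd_results$adjusted_p[i],
                         trees[[g]]$tree, trees[[g]]$basins,
                         alpha = config$alpha)
    cpd_results$class[i] <- cl$class
    cpd_results$phylogeography_violated[i] <- cl$phylogeography_violated
  }

  # ranked candidate table
  n_tsps_gene <- table(tsp_set$gene_id[!is.na(tsp_set$gene_id)])
  n_ns_gene <- table(tsp_set$gene_id[!is.na(tsp_set$effect) &
                                       tsp_set$effect == "NS"])
  candidates <- cpd_results
  candidates$n_tsps <- as.integer(n_tsps_gene[candidates$gene_id])
  candidates$n_ns_tsps <- as.integer(n_ns_gene[candidates$gene_id])
  ord <- order(-ifelse(is.na(candidates$cpd_wb), -Inf, candidates$cpd_wb))
  candidates <- candidates[ord, , drop = FALSE]
  rownames(candidates) <- NULL

  counts <- list(
    n_sync_sites = nrow(snps$sites),
    n_discovered = length(disc),
    n_thinned = sum(thin_keep),
    n_cosmopolitan = sum(snps$sites$cosmopolitan),
    n_tsp = sum(tsp_set$is_tsp),
    n_tsp_high_he = sum(high_he),
    n_ns_tsp = sum(tsp_set$effect == "NS", na.rm = TRUE),
    n_genes = length(models),
    n_candidate_genes = length(cand_genes),
    n_trees_tested = length(tested),
    n_ancient = sum(cpd_results$class == "ancient", na.rm = TRUE),
    n_recent = sum(cpd_results$class == "recent", na.rm = TRUE))

  obj <- structure(list(config = config, snps = snps, annot = annot,
                        tsps = tsp_set, high_he = high_he,
                        enrichment = enr, exon_stats = exon_stats,
                        contrasts = contrasts, sfs_contrast = sfs_contrast,
                        cpd_results = cpd_results, candidates = candidates,
                        trees = trees, counts = counts),
                   class = "tsp_scan")
  if (!is.null(config$out_dir)) write_scan_outputs(obj, config$out_dir)
  obj
}

# Serialized reproducibility record embedded at the top of every output.
config_record <- function(config) {
  keys <- c("maf_threshold", "min_count", "min_cov", "thin_distance",
            "he_min", "promoter_bp", "window_bp", "n_perm", "n_boot",
            "alpha", "seed")
  vals <- vapply(keys, function(k) format(config[[k]]), character(1))
  sprintf("# tspscan %s; %s",
          as.character(packageVersion("tspscan")),
          paste(keys, vals, sep = "=", collapse = "; "))
}

write_scan_outputs <- function(obj, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- config_record(obj$config)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wt(obj$tsps, "tsps.tsv")
  wt(obj$enrichment, "enrichment.tsv")
  wt(obj$exon_stats, "exon_stats.tsv")
  if (!is.null(obj$sfs_contrast)) {
    sf <- do.call(rbind, lapply(names(obj$sfs_contrast), function(g) {
      s <- obj$sfs_contrast[[g]]
      data.frame(set = g, bin_lo = head(s$breaks, -1), bin_hi = s$breaks[-1],
                 proportion = s$proportion, ci_lower = s$ci_lower,
                 ci_upper = s$ci_upper, stringsAsFactors = FALSE)
    }))
    wt(sf, "sfs.tsv")
  }
  wt(obj$cpd_results, "cpd_results.tsv")
  wt(obj$candidates, "candidates.tsv")
  if (length(obj$trees)) {
    tdir <- file.path(out_dir, "trees")
    dir.create(tdir, showWarnings = FALSE)
    for (g in names(obj$trees)) {
      write_newick(obj$trees[[g]]$tree, file.path(tdir, paste0(g, ".nwk")))
    }
  }
  summary_list <- c(list(tspscan_version =
                           as.character(packageVersion("tspscan")),
                         seed = obj$config$seed),
                    obj$counts)
  jsonlite::write_json(summary_list, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.tsp_scan <- function(x, ...) {
  ct <- x$counts
  cat("tspscan balancing-selection scan\n")
  cat(sprintf("  sites: %d sync, %d discovered SNPs (%d after %d-bp thinning)\n",
              ct$n_sync_sites, ct$n_discovered, ct$n_thinned,
              x$config$thin_distance))
  cat(sprintf("  TSPs: %d cosmopolitan, %d trans-species, %d with H_E > %.2f everywhere\n",
              ct$n_cosmopolitan, ct$n_tsp, ct$n_tsp_high_he, x$config$he_min))
  cat(sprintf("  candidates: %d nonsynonymous TSPs in %d of %d genes\n",
              ct$n_ns_tsp, ct$n_candidate_genes, ct$n_genes))
  cat(sprintf("  allele trees: %d tested, %d ancient, %d recent\n",
              ct$n_trees_tested, ct$n_ancient, ct$n_recent))
  invisible(x)
}

#' @export
summary.tsp_scan <- function(object, ...) {
  print(object)
  cat("\nTSP enrichment by genomic class:\n")
  print(object$enrichment[, c("class", "a", "c", "odds_ratio", "p_value",
                              "adjusted_p")], row.names = FALSE)
  if (nrow(object$candidates)) {
    cat("\nTop candidates by CPD_w-b:\n")
    print(head(object$candidates[, c("gene_id", "n_tsps", "n_ns_tsps",
                                     "cpd_wb", "adjusted_p", "class")], 10),
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.tsp_scan <- function(x, ...) {
  cd <- x$candidates[!is.na(x$candidates$cpd_wb), , drop = FALSE]
  if (nrow(cd) == 0) {
    message("no candidate loci with a CPD_w-b value to plot")
    return(invisible(x))
  }
  cols <- ifelse(cd$class == "ancient", "firebrick", "grey60")
  bp <- graphics::barplot(cd$cpd_wb, names.arg = cd$gene_id, las = 2,
                          col = cols, ylab = "CPD within - between",
                          main = "Candidate genes ranked by CPD_w-b", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::segments(bp, cd$cpd_wb - cd$iqr_within / 2,
                     bp, cd$cpd_wb + cd$iqr_within / 2)
  invisible(x)
}

#' Ecological load
#'
#' The fitness cost of offspring settling in habitats suboptimal for
#' their genotype: `Le = (Wmax - Wbar) / Wmax`.
#'
#' @param w_max Optimal fitness across habitats (> 0).
#' @param w_mean Mean fitness (0 < w_mean <= w_max).
#' @return The load in `[0, 1)`.
#' @examples
#' ecological_load(1, 0.25) # 0.75
#' @export
ecological_load <- function(w_max, w_mean) {
  if (any(w_max <= 0)) stop("w_max must be positive")
  if (any(w_mean <= 0)) stop("w_mean must be positive")
  if (any(w_mean > w_max)) stop("w_mean must not exceed w_max")
  (w_max - w_mean) / w_max
}

#' Survival fraction between settlement and maturity
#'
#' @param density_settlement Density at settlement (per unit area, > 0).
#' @param density_maturity Density at maturity (> 0, at most the
#'   settlement density).
#' @return Percent survival, rounded to one decimal.
#' @examples
#' survival_fraction(76, 0.15) # 0.2
#' @export
survival_fraction <- function(density_settlement, density_maturity) {
  if (any(density_settlement <= 0) || any(density_maturity <= 0)) {
    stop("densities must be positive")
  }
  if (any(density_maturity > density_settlement)) {
    stop("maturity density must not exceed settlement density")
  }
  round(100 * density_maturity / density_settlement, 1)
}
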