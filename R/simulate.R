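# Synthetic data with the statistical structure the scan assumes:
# neutral loci under a three-level split phylogeography (outgroup species
# split, ocean-basin split, panmixia within basins) and balanced loci
# carrying two anciently diverged haplotype classes segregating in every
# population and in the outgroup, plus pool-seq read sampling.

#' Simulation configuration
#'
#' Defaults emulate the study system: six focal populations (one Pacific,
#' five Atlantic) pooled at 20-38 diploids each, an outgroup species
#' sampled as one diploid, a basin split ~2 My ago and a species split
#' ~9 My ago (1 generation/year), and `mu`/`ne` chosen so that neutral
#' diversity is theta = 4*ne*mu = 1% per site, matching diversity levels
#' typical of large marine invertebrate populations.
#'
#' @param seed Integer master seed; every downstream draw derives from it.
#' @param populations Named character vector mapping population id to
#'   ocean basin.
#' @param pool_sizes Named integer vector, diploid individuals per pool
#'   (10-100).
#' @param coverage_mean Mean pool-seq depth per site (Poisson).
#' @param error_rate Per-base sequencing error probability (< 0.01).
#' @param mu Per-site per-generation mutation rate.
#' @param ne Diploid effective population size of each deme.
#' @param locus_length Locus length in bp.
#' @param n_neutral_loci,n_balanced_loci Locus counts for [emit_dataset()].
#' @param t_split_oceans,t_split_species Split times in generations.
#' @param t_balanced Age of the balanced polymorphism in generations; must
#'   be at least `t_split_oceans`, and at least `t_split_species` for
#'   trans-species loci.
#' @param class_freq_range Interval from which the per-population frequency
#'   of balanced class X is drawn.
#' @param het_excess Probability that the single sequenced adult at a
#'   balanced locus is a class heterozygote. Balancing selection by
#'   (marginal) overdominance acts on viability, so surviving adults show
#'   heterozygote excess relative to Hardy-Weinberg pairing; the default
#'   (1) is the diagnostic condition the allele-tree statistic targets,
#'   and lowering it emulates oversampling of class homozygotes.
#' @param outgroup_id Sample id of the outgroup individual.
#' @return A validated `sim_config` object.
#' @examples
#' cfg <- sim_config(seed = 1, n_neutral_loci = 2, n_balanced_loci = 1)
#' @export
sim_config <- function(seed = 1L,
                       populations = c(WCAN = "pacific", ME = "atlantic",
                                       RI = "atlantic", ICE = "atlantic",
                                       NOR = "atlantic", UK = "atlantic"),
                       pool_sizes = c(WCAN = 24L, ME = 38L, RI = 30L,
                                      ICE = 28L, NOR = 20L, UK = 36L),
                       coverage_mean = 60,
                       error_rate = 0.001,
                       mu = 5e-9,
                       ne = 5e5,
                       locus_length = 500L,
                       n_neutral_loci = 20L,
                       n_balanced_loci = 5L,
                       t_split_oceans = 2e6,
                       t_split_species = 9e6,
                       t_balanced = 9e6,
                       class_freq_range = c(0.2, 0.8),
                       het_excess = 1,
                       outgroup_id = "OUT") {
  stopifnot(length(populations) >= 1, !is.null(names(populations)))
  if (!setequal(names(populations), names(pool_sizes))) {
    stop("populations and pool_sizes must name the same populations")
  }
  pool_sizes <- pool_sizes[names(populations)]
  if (any(pool_sizes < 10 | pool_sizes > 100)) {
    stop("pool_sizes must lie in [10, 100] diploid individuals")
  }
  if (error_rate < 0 || error_rate >= 0.01) {
    stop("error_rate must lie in [0, 0.01)")
  }
  if (t_balanced < t_split_oceans) {
    stop("t_balanced must be >= t_split_oceans")
  }
  if (t_split_species < t_split_oceans) {
    stop("t_split_species must be >= t_split_oceans")
  }
  if (length(class_freq_range) != 2 || class_freq_range[1] <= 0 ||
      class_freq_range[2] >= 1 || diff(class_freq_range) < 0) {
    stop("class_freq_range must be an interval inside (0, 1)")
  }
  if (het_excess < 0 || het_excess > 1) stop("het_excess must be in [0, 1]")
  if (locus_length < 90) stop("locus_length must be >= 90 bp")
  structure(list(seed = as.integer(seed), populations = populations,
                 pool_sizes = pool_sizes, coverage_mean = coverage_mean,
                 error_rate = error_rate, mu = mu, ne = ne,
                 locus_length = as.integer(locus_length),
                 n_neutral_loci = as.integer(n_neutral_loci),
                 n_balanced_loci = as.integer(n_balanced_loci),
                 t_split_oceans = t_split_oceans,
                 t_split_species = t_split_species,
                 t_balanced = t_balanced,
                 class_freq_range = class_freq_range,
                 het_excess = het_excess,
                 outgroup_id = outgroup_id),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d focal pops, theta=%g, locus %d bp, ",
                     "%d neutral + %d balanced loci, seed %d\n"),
              length(x$populations), 4 * x$ne * x$mu, x$locus_length,
              x$n_neutral_loci, x$n_balanced_loci, x$seed))
  invisible(x)
}

# Layout of sampled haplotypes for a config: one row per haplotype with
# sample/population/species/basin labels. Haplotypes 2k-1, 2k form diploid
# individual k of a population; individual 1 is the one emitted to the VCF.
hap_layout <- function(config) {
  pops <- names(config$populations)
  rows <- lapply(pops, function(p) {
    n_ind <- config$pool_sizes[[p]]
    data.frame(
      hap_id = paste0(p, "_ind", rep(seq_len(n_ind), each = 2),
                      "_h", rep(1:2, n_ind)),
      sample_id = paste0(p, "_ind", rep(seq_len(n_ind), each = 2)),
      population = p, species = "focal",
      basin = unname(config$populations[[p]]),
      stringsAsFactors = FALSE)
  })
  out <- data.frame(hap_id = paste0(config$outgroup_id, "_h", 1:2),
                    sample_id = config$outgroup_id,
                    population = config$outgroup_id, species = "outgroup",
                    basin = "outgroup", stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(out)))
}

# Structured Kingman coalescent with stepwise deme mergers under the
# infinite-sites model. Returns a list of mutations; each element is the
# integer vector of descendant leaf ids carrying the derived allele.
# Branch lengths are in generations; coalescence in deme d occurs at rate
# choose(k_d, 2) / (2 ne_d).
sim_genealogy_mutations <- function(deme_of_leaf, ne, merges, mu_locus) {
  n <- length(deme_of_leaf)
  if (n < 2) return(list())
  sets <- as.list(seq_len(n))
  deme <- deme_of_leaf
  birth <- numeric(n)
  t <- 0
  muts <- list()
  if (is.null(merges)) merges <- data.frame(time = numeric(), from = character(),
                                            to = character())
  merges <- merges[order(merges$time), , drop = FALSE]
  next_merge <- 1L
  ne_of <- function(d) if (length(ne) == 1) ne else ne[[d]]
  while (length(sets) > 1) {
    demes_now <- unique(deme)
    k_d <- vapply(demes_now, function(d) sum(deme == d), numeric(1))
    rate_d <- vapply(seq_along(demes_now), function(i)
      k_d[i] * (k_d[i] - 1) / 2 / (2 * ne_of(demes_now[i])), numeric(1))
    rate <- sum(rate_d)
    t_next <- if (rate > 0) t + rexp(1, rate) else Inf
    if (next_merge <= nrow(merges) && merges$time[next_merge] <= t_next) {
      deme[deme == merges$from[next_merge]] <- merges$to[next_merge]
      t <- merges$time[next_merge]
      next_merge <- next_merge + 1L
      next
    }
    if (!is.finite(t_next)) {
      stop("coalescent stalled: isolated lineages and no pending merger")
    }
    t <- t_next
    d <- demes_now[sample.int(length(demes_now), 1L, prob = rate_d)]
    in_d <- which(deme == d)
    pair <- in_d[sample.int(length(in_d), 2L)]
    for (i in pair) {
      n_mut <- rpois(1L, mu_locus * (t - birth[i]))
      if (n_mut > 0) {
        for (k in seq_len(n_mut)) muts[[length(muts) + 1L]] <- sets[[i]]
      }
    }
    merged <- sort(c(sets[[pair[1]]], sets[[pair[2]]]))
    keep <- setdiff(seq_along(sets), pair)
    sets <- c(sets[keep], list(merged))
    deme <- c(deme[keep], d)
    birth <- c(birth[keep], t)
  }
  muts
}

# Assemble a haplotype_set from mutation carrier lists. Mutation positions
# are drawn without replacement (infinite sites); each derived allele is a
# uniform non-reference base. `fixed_muts` is an optional list of
# pre-specified mutations (carrier sets) appended with the same machinery;
# their positions are reported via attr "tagged_pos".
build_haplotype_set <- function(carriers, n_hap, ref, contig, info,
                                n_tagged = 0L) {
  L <- nchar(ref)
  m <- length(carriers)
  if (m > L) {
    stop(sprintf("infinite-sites approximation violated: %d mutations on a %d bp locus",
                 m, L))
  }
  positions <- if (m > 0) sample.int(L, m) else integer()
  ord <- order(positions)
  positions <- positions[ord]
  carriers <- carriers[ord]
  ref_bases <- if (m > 0) substring(ref, positions, positions) else character()
  alleles <- matrix(rep(ref_bases, each = n_hap), nrow = n_hap)
  derived <- character(m)
  for (j in seq_len(m)) {
    derived[j] <- sample(setdiff(ACGT, ref_bases[j]), 1L)
    alleles[carriers[[j]], j] <- derived[j]
  }
  tagged <- if (n_tagged > 0L) {
    # the last n_tagged elements of the *input* carrier list were tagged;
    # recover their positions after ordering
    positions[ord > (m - n_tagged)]
  } else integer()
  hs <- structure(list(contig = contig, ref = ref, length = L,
                       positions = positions, alleles = alleles,
                       derived = derived, info = info),
                  class = "haplotype_set")
  attr(hs, "tagged_pos") <- sort(tagged)
  hs
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes, %d segregating sites, %d bp (%s)\n",
              nrow(x$alleles), length(x$positions), x$length, x$contig))
  invisible(x)
}

random_reference <- function(L) {
  paste(sample(ACGT, L, replace = TRUE), collapse = "")
}

merge_schedule <- function(config) {
  basins <- unique(unname(config$populations))
  root <- basins[1]
  rows <- list()
  for (b in setdiff(basins, root)) {
    rows[[length(rows) + 1L]] <- data.frame(time = config$t_split_oceans,
                                            from = b, to = root)
  }
  rows[[length(rows) + 1L]] <- data.frame(time = config$t_split_species,
                                          from = "outgroup", to = root)
  do.call(rbind, rows)
}

#' Simulate a neutral locus
#'
#' Draws haplotypes for every focal population plus the outgroup from a
#' structured coalescent with panmixia within ocean basins, a basin merger
#' at `t_split_oceans` and an outgroup species merger at
#' `t_split_species`, then sprinkles infinite-sites mutations at rate
#' `mu` per site per generation.
#'
#' @param config A [sim_config()].
#' @param locus_index Integer index; combined with the master seed it
#'   fully determines the locus.
#' @return A `haplotype_set`: reference sequence, sorted segregating-site
#'   positions, haplotype-by-site allele matrix and per-haplotype labels.
#' @export
simulate_neutral_locus <- function(config, locus_index) {
  stopifnot(inherits(config, "sim_config"))
  info <- hap_layout(config)
  with_seed(derive_seed(config$seed, paste0("neutral_", locus_index)), {
    ref <- random_reference(config$locus_length)
    muts <- sim_genealogy_mutations(info$basin, config$ne, merge_schedule(config),
                                    config$mu * config$locus_length)
    build_haplotype_set(muts, nrow(info), ref,
                        sprintf("locus_%03d", locus_index), info)
  })
}

#' Implant a balanced locus
#'
#' Simulates an old balanced polymorphism as two allelic classes, X and Y,
#' that split `t_balanced` generations ago. Class-defining diverged sites
#' number `Poisson(2 * mu * t_balanced * locus_length)` and are carried by
#' every class-Y haplotype; each class additionally carries its own
#' neutral structured-coalescent genealogy (effective size `ne/2` per
#' class). Class frequencies are drawn independently per population from
#' `class_freq_range`; both classes are always present in every focal
#' population and in the outgroup diploid. The single sequenced adult of
#' each population is a class heterozygote with probability `het_excess`
#' (viability selection by overdominance enriches heterozygous adults).
#'
#' @inheritParams simulate_neutral_locus
#' @param trans_species If `TRUE` (default) require
#'   `t_balanced >= t_split_species` so the truth label is trans-species.
#' @return List with `haplotypes` (a `haplotype_set`) and `truth`
#'   (label, per-haplotype class, realized per-population class-X
#'   frequencies, diverged-site positions).
#' @export
implant_balanced_locus <- function(config, locus_index, trans_species = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (trans_species && config$t_balanced < config$t_split_species) {
    stop("trans-species balanced loci require t_balanced >= t_split_species")
  }
  info <- hap_layout(config)
  lo <- config$class_freq_range[1]
  hi <- config$class_freq_range[2]
  pops <- names(config$populations)
  min_copies <- min(lo, 1 - hi) * 2 * min(config$pool_sizes)
  if (min_copies < 1) {
    stop("class_freq_range incompatible with pool size: expected minor-class copies < 1")
  }
  with_seed(derive_seed(config$seed, paste0("balanced_", locus_index)), {
    ref <- random_reference(config$locus_length)
    cls <- character(nrow(info))
    freqs <- setNames(numeric(length(pops)), pops)
    for (p in pops) {
      rows <- which(info$population == p)
      f <- runif(1, lo, hi)
      # sequenced adult (haplotypes 1-2 of the population)
      if (runif(1) < config$het_excess) {
        cls[rows[1:2]] <- sample(c("X", "Y"))
      } else {
        cls[rows[1:2]] <- if (runif(1) < f) "X" else "Y"
      }
      rest <- rows[-(1:2)]
      cls[rest] <- ifelse(runif(length(rest)) < f, "X", "Y")
      # guarantee both classes segregate in the pool
      if (all(cls[rows] == "X")) cls[rows[length(rows)]] <- "Y"
      if (all(cls[rows] == "Y")) cls[rows[length(rows)]] <- "X"
      freqs[p] <- mean(cls[rows] == "X")
    }
    out_rows <- which(info$species == "outgroup")
    cls[out_rows] <- sample(c("X", "Y"))
    n_div <- rpois(1L, 2 * config$mu * config$t_balanced * config$locus_length)
    class_muts <- list()
    for (cl in c("X", "Y")) {
      members <- which(cls == cl)
      sub <- sim_genealogy_mutations(info$basin[members], config$ne / 2,
                                     merge_schedule(config),
                                     config$mu * config$locus_length)
      class_muts <- c(class_muts, lapply(sub, function(s) members[s]))
    }
    y_members <- sort(which(cls == "Y"))
    div_muts <- replicate(n_div, y_members, simplify = FALSE)
    hs <- build_haplotype_set(c(class_muts, div_muts), nrow(info), ref,
                              sprintf("locus_%03d", locus_index), info,
                              n_tagged = n_div)
    truth <- list(label = "balanced", class = setNames(cls, info$hap_id),
                  class_freqs = freqs,
                  diverged_pos = attr(hs, "tagged_pos"),
                  n_diverged = n_div)
    list(haplotypes = hs, truth = truth)
  })
}

#' Sample pooled sequencing reads over one population
#'
#' Draws `pool_size` diploid individuals without replacement from the
#' population's simulated individuals; per site, coverage is
#' `Poisson(coverage_mean)`, each read copies a uniformly chosen pool
#' chromosome, and with probability `error_rate` the read base is replaced
#' by a uniform different base.
#'
#' @param haps A `haplotype_set`.
#' @param population Population id to sample.
#' @param pool_size Diploids to pool; default all available.
#' @param coverage_mean Mean depth per site.
#' @param error_rate Per-base error probability.
#' @param seed Integer seed.
#' @return A `sync_counts` object with one pool, rows at the haplotype
#'   set's segregating positions.
#' @export
sample_pool_reads <- function(haps, population, pool_size = NULL,
                              coverage_mean = 60, error_rate = 0,
                              seed = 1L) {
  stopifnot(inherits(haps, "haplotype_set"))
  rows <- which(haps$info$population == population)
  if (length(rows) == 0) stop("unknown population: ", population)
  inds <- unique(haps$info$sample_id[rows])
  if (is.null(pool_size)) pool_size <- length(inds)
  if (pool_size > length(inds)) {
    stop(sprintf("pool_size %d exceeds available individuals (%d)",
                 pool_size, length(inds)))
  }
  with_seed(seed, {
    chosen <- sample(inds, pool_size)
    hrows <- rows[haps$info$sample_id[rows] %in% chosen]
    n_site <- length(haps$positions)
    counts <- matrix(0L, nrow = n_site, ncol = 6L,
                     dimnames = list(NULL, SYNC_BASES))
    if (n_site > 0) {
      cov <- rpois(n_site, coverage_mean)
      for (s in seq_len(n_site)) {
        base_n <- tabulate(match(haps$alleles[hrows, s], ACGT), nbins = 4L)
        if (cov[s] == 0) next
        reads <- as.integer(rmultinom(1L, cov[s], base_n / sum(base_n)))
        if (error_rate > 0) {
          for (b in which(reads > 0L)) {
            n_err <- rbinom(1L, reads[b], error_rate)
            if (n_err > 0L) {
              reads[b] <- reads[b] - n_err
              dest <- setdiff(1:4, b)
              reads[dest] <- reads[dest] +
                as.integer(rmultinom(1L, n_err, rep(1 / 3, 3)))
            }
          }
        }
        counts[s, match(ACGT, SYNC_BASES)] <- reads
      }
    }
    sites <- data.frame(
      contig = rep(haps$contig, n_site), pos = haps$positions,
      ref = if (n_site > 0) substring(haps$ref, haps$positions, haps$positions)
            else character(),
      stringsAsFactors = FALSE)
    cnt <- array(counts, dim = c(n_site, 1L, 6L),
                 dimnames = list(NULL, population, SYNC_BASES))
    new_sync(sites, cnt, population)
  })
}

#' Emit a complete synthetic dataset to disk
#'
#' Generates `n_neutral_loci` neutral and `n_balanced_loci` balanced loci,
#' lays each out as a single-exon gene (30 bp 5'-UTR, in-frame CDS, 3'-UTR
#' remainder, alternating strands) separated by 1 kb of intergenic
#' sequence on one contig, samples pool reads for every focal population,
#' and writes: reference FASTA, GFF3 gene models, sync allele counts
#' (rows at every site polymorphic among the focal pools' chromosomes),
#' a fully phased VCF for one diploid individual per population plus the
#' outgroup, a sample manifest, and a truth table.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param overwrite Refuse to write into a non-empty directory unless
#'   `TRUE`.
#' @return A `sim_dataset` object with file paths, the manifest, pool
#'   sizes, and the truth table (one row per locus).
#' @export
emit_dataset <- function(config, dir, overwrite = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop("output directory ", dir, " is not empty; set overwrite = TRUE")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_total <- config$n_neutral_loci + config$n_balanced_loci
  types <- with_seed(derive_seed(config$seed, "layout"),
                     sample(c(rep("balanced", config$n_balanced_loci),
                              rep("neutral", config$n_neutral_loci))))
  contig <- "ctg1"
  flank <- 1000L
  L <- config$locus_length
  pops <- names(config$populations)
  layout <- hap_layout(config)
  vcf_samples <- c(paste0(pops, "_ind1"), config$outgroup_id)

  ref_parts <- character()
  feats <- list(); truth_rows <- list(); sync_parts <- list()
  vcf_sites <- list(); vcf_geno <- list()
  offset <- 0L
  with_seed(derive_seed(config$seed, "flanks"), {
    for (i in seq_len(n_total)) {
      locus <- if (types[i] == "balanced") {
        implant_balanced_locus(config, i)
      } else {
        list(haplotypes = simulate_neutral_locus(config, i), truth = NULL)
      }
      hs <- locus$haplotypes
      left <- random_reference(flank)
      gs <- offset + flank + 1L
      ge <- gs + L - 1L
      offset <- ge
      ref_parts <- c(ref_parts, left, hs$ref)
      strand <- if (i %% 2L == 1L) "+" else "-"
      gid <- sprintf("g%03d", i)
      feats[[i]] <- gene_features(gid, contig, gs, ge, strand, L)
      pos_g <- gs + hs$positions - 1L

      # which sites segregate among the focal pools' chromosomes
      focal <- which(hs$info$species == "focal")
      ref_b <- substring(hs$ref, hs$positions, hs$positions)
      seg_focal <- vapply(seq_along(hs$positions), function(s)
        length(unique(hs$alleles[focal, s])) > 1, logical(1))

      pool_list <- lapply(pops, function(p)
        sample_pool_reads(hs, p, pool_size = NULL,
                          coverage_mean = config$coverage_mean,
                          error_rate = config$error_rate,
                          seed = derive_seed(config$seed,
                                             paste0("pool_", i, "_", p))))
      if (any(seg_focal)) {
        cnt <- array(0L, dim = c(sum(seg_focal), length(pops), 6L),
                     dimnames = list(NULL, pops, SYNC_BASES))
        for (j in seq_along(pops)) {
          cnt[, j, ] <- pool_list[[j]]$counts[seg_focal, 1L, ]
        }
        sync_parts[[length(sync_parts) + 1L]] <- new_sync(
          data.frame(contig = contig, pos = pos_g[seg_focal],
                     ref = ref_b[seg_focal], stringsAsFactors = FALSE),
          cnt, pops)
      }

      if (length(hs$positions) > 0) {
        alt_b <- hs$derived
        geno <- array(0L, dim = c(length(hs$positions), length(vcf_samples), 2L))
        for (s in seq_along(vcf_samples)) {
          hr <- which(layout$sample_id == vcf_samples[s])
          geno[, s, 1L] <- as.integer(hs$alleles[hr[1], ] == alt_b)
          geno[, s, 2L] <- as.integer(hs$alleles[hr[2], ] == alt_b)
        }
        vcf_sites[[length(vcf_sites) + 1L]] <- data.frame(
          contig = contig, pos = pos_g, ref = ref_b, alt = alt_b,
          stringsAsFactors = FALSE)
        vcf_geno[[length(vcf_geno) + 1L]] <- geno
      }

      truth_rows[[i]] <- data.frame(
        locus_id = gid, label = types[i], contig = contig,
        start = gs, end = ge, strand = strand,
        n_diverged = if (is.null(locus$truth)) 0L else locus$truth$n_diverged,
        diverged_pos = if (is.null(locus$truth)) "" else
          paste(gs + locus$truth$diverged_pos - 1L, collapse = ";"),
        class_freqs = if (is.null(locus$truth)) "" else
          paste(sprintf("%s=%.4f", pops, locus$truth$class_freqs),
                collapse = ";"),
        stringsAsFactors = FALSE)
    }
    ref_parts <- c(ref_parts, random_reference(flank))
  })

  paths <- list(fasta = file.path(dir, "reference.fasta"),
                gff = file.path(dir, "genes.gff3"),
                sync = file.path(dir, "pools.sync"),
                vcf = file.path(dir, "phased.vcf"),
                truth = file.path(dir, "truth.tsv"),
                manifest = file.path(dir, "manifest.tsv"))
  genome <- setNames(paste(ref_parts, collapse = ""), contig)
  write_fasta(genome, paths$fasta)
  write_gff3(do.call(rbind, feats), paths$gff)
  sync <- bind_sync(sync_parts, pops)
  write_sync(sync, paths$sync)
  sites <- do.call(rbind, vcf_sites)
  geno <- abind_geno(vcf_geno)
  write_phased_vcf(sites, geno, vcf_samples, paths$vcf)
  truth <- do.call(rbind, truth_rows)
  write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(
    sample_id = vcf_samples,
    population_id = c(pops, config$outgroup_id),
    species = c(rep("focal", length(pops)), "outgroup"),
    basin = c(unname(config$populations), "outgroup"),
    stringsAsFactors = FALSE)
  write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  structure(list(dir = dir, paths = paths, config = config,
                 manifest = manifest, pool_sizes = config$pool_sizes,
                 truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset in %s: %d loci (%d balanced), %d pools\n",
              x$dir, nrow(x$truth), sum(x$truth$label == "balanced"),
              length(x$pool_sizes)))
  invisible(x)
}

# Single-exon gene layout: 30 bp 5'-UTR, CDS of floor((L-60)/3)*3 bp in
# frame 0, remainder 3'-UTR; mirrored on the minus strand.
gene_features <- function(gid, contig, gs, ge, strand, L) {
  tid <- sub("^g", "t", gid)
  u5_len <- 30L
  cds_len <- ((L - 60L) %/% 3L) * 3L
  if (strand == "+") {
    u5 <- c(gs, gs + u5_len - 1L)
    cd <- c(gs + u5_len, gs + u5_len + cds_len - 1L)
    u3 <- c(cd[2] + 1L, ge)
  } else {
    u5 <- c(ge - u5_len + 1L, ge)
    cd <- c(ge - u5_len - cds_len + 1L, ge - u5_len)
    u3 <- c(gs, cd[1] - 1L)
  }
  data.frame(
    contig = contig,
    type = c("gene", "mRNA", "exon", "five_prime_UTR", "CDS",
             "three_prime_UTR"),
    start = c(gs, gs, gs, u5[1], cd[1], u3[1]),
    end = c(ge, ge, ge, u5[2], cd[2], u3[2]),
    strand = strand,
    phase = c(NA, NA, NA, NA, 0L, NA),
    id = c(gid, tid, paste0(tid, ".e1"), paste0(tid, ".u5"),
           paste0(tid, ".c1"), paste0(tid, ".u3")),
    parent = c(NA, gid, tid, tid, tid, tid),
    stringsAsFactors = FALSE)
}

bind_sync <- function(parts, pops) {
  if (length(parts) == 0) {
    return(new_sync(data.frame(contig = character(), pos = integer(),
                               ref = character(), stringsAsFactors = FALSE),
                    array(0L, dim = c(0L, length(pops), 6L)), pops))
  }
  sites <- do.call(rbind, lapply(parts, `[[`, "sites"))
  total <- sum(vapply(parts, function(p) nrow(p$sites), integer(1)))
  cnt <- array(0L, dim = c(total, length(pops), 6L),
               dimnames = list(NULL, pops, SYNC_BASES))
  at <- 0L
  for (p in parts) {
    n <- nrow(p$sites)
    if (n > 0) cnt[at + seq_len(n), , ] <- p$counts
    at <- at + n
  }
  new_sync(sites, cnt, pops)
}

abind_geno <- function(parts) {
  total <- sum(vapply(parts, function(g) dim(g)[1], integer(1)))
  out <- array(0L, dim = c(total, dim(parts[[1]])[2], 2L))
  at <- 0L
  for (g in parts) {
    n <- dim(g)[1]
    out[at + seq_len(n), , ] <- g
    at <- at + n
  }
  out
}
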