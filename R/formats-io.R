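# I/O for the four interchange formats (FASTA, GFF3, popoolation sync,
# phased VCF) plus newick trees. All external coordinates are 1-based
# inclusive, and that convention is kept internally as well, so positions
# read from any of these formats are directly comparable.

#' Read a FASTA reference
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of upper-case sequences, one per contig.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA: ", path)
  seqs
}

#' Write a FASTA reference
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read popoolation-style sync allele counts
#'
#' Each line is `contig<TAB>pos<TAB>ref<TAB>A:T:C:G:N:del` repeated once
#' per pool, with read counts per nucleotide.
#'
#' @param path Path to the sync file.
#' @param population_ids Character vector naming the pools, in column order.
#' @return A `sync_counts` object: list with `sites` (data.frame of
#'   contig, pos, ref), `counts` (array sites x pools x 6, bases
#'   A,T,C,G,N,del) and `population_ids`.
#' @export
read_sync <- function(path, population_ids) {
  stopifnot(is.character(population_ids), length(population_ids) >= 1)
  n_pop <- length(population_ids)
  raw <- readLines(path)
  keep <- nzchar(raw) & !startsWith(raw, "#")
  line_no <- which(keep)
  raw <- raw[keep]
  if (length(raw) == 0L) {
    return(new_sync(data.frame(contig = character(), pos = integer(),
                               ref = character(), stringsAsFactors = FALSE),
                    array(0L, dim = c(0L, n_pop, 6L)), population_ids))
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  lens <- lengths(parts)
  bad <- which(lens != 3L + n_pop)
  if (length(bad)) {
    stop(sprintf("sync line %d: expected %d pool column(s), found %d",
                 line_no[bad[1]], n_pop, max(lens[bad[1]] - 3L, 0L)))
  }
  m <- matrix(unlist(parts, use.names = FALSE), nrow = length(raw), byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) {
    stop(sprintf("sync line %d: non-integer position '%s'",
                 line_no[which(is.na(pos))[1]], m[which(is.na(pos))[1], 2]))
  }
  counts <- array(0L, dim = c(length(raw), n_pop, 6L),
                  dimnames = list(NULL, population_ids, SYNC_BASES))
  for (j in seq_len(n_pop)) {
    cs <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    badlen <- which(lengths(cs) != 6L)
    if (length(badlen)) {
      stop(sprintf("sync line %d: pool '%s' is not a 6-tuple",
                   line_no[badlen[1]], population_ids[j]))
    }
    v <- suppressWarnings(as.integer(unlist(cs, use.names = FALSE)))
    if (anyNA(v)) {
      bad_site <- ceiling(which(is.na(v))[1] / 6)
      stop(sprintf("sync line %d: non-integer count in pool '%s'",
                   line_no[bad_site], population_ids[j]))
    }
    if (any(v < 0L)) {
      bad_site <- ceiling(which(v < 0L)[1] / 6)
      stop(sprintf("sync line %d: negative count in pool '%s'",
                   line_no[bad_site], population_ids[j]))
    }
    counts[, j, ] <- matrix(v, ncol = 6L, byrow = TRUE)
  }
  sites <- data.frame(contig = m[, 1], pos = pos, ref = toupper(m[, 3]),
                      stringsAsFactors = FALSE)
  new_sync(sites, counts, population_ids)
}

new_sync <- function(sites, counts, population_ids) {
  structure(list(sites = sites, counts = counts,
                 population_ids = population_ids),
            class = "sync_counts")
}

#' @export
print.sync_counts <- function(x, ...) {
  cat(sprintf("sync_counts: %d sites, %d pools (%s)\n",
              nrow(x$sites), length(x$population_ids),
              paste(x$population_ids, collapse = ", ")))
  invisible(x)
}

#' Write sync allele counts
#'
#' @param sync A `sync_counts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sync, path) {
  stopifnot(inherits(sync, "sync_counts"))
  n <- nrow(sync$sites)
  pools <- vapply(seq_along(sync$population_ids), function(j) {
    apply(sync$counts[, j, , drop = FALSE], 1, paste, collapse = ":")
  }, character(n))
  if (n == 1L) pools <- matrix(pools, nrow = 1L)
  lines <- paste(sync$sites$contig, sync$sites$pos, sync$sites$ref,
                 apply(pools, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS (and, when present, UTR) features and returns
#' one gene model per gene, using the transcript with the longest total CDS
#' when a gene has several. UTR intervals are taken from explicit UTR
#' features when available and otherwise derived as the exonic sequence
#' outside the CDS span. A model whose CDS length (after phase adjustment)
#' is not divisible by 3 is kept but flagged unusable for
#' synonymous/nonsynonymous annotation (`cds_ok = FALSE`).
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_models` object: named list of `gene_model` lists with
#'   fields gene_id, transcript_id, contig, strand, start, end, exons,
#'   cds (2-column matrices of 1-based inclusive start/end), phase, utr5,
#'   utr3, tss, cds_ok.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  df$parent1 <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  txs <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  utr5f <- df[df$type %in% c("five_prime_UTR", "5UTR"), , drop = FALSE]
  utr3f <- df[df$type %in% c("three_prime_UTR", "3UTR"), , drop = FALSE]

  orphan <- cds[!is.na(cds$parent1) & !(cds$parent1 %in% txs$ID), , drop = FALSE]
  if (nrow(orphan) > 0) {
    warning(sprintf("%d CDS feature(s) without a parent transcript skipped",
                    nrow(orphan)))
  }

  models <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    gtx <- txs[!is.na(txs$parent1) & txs$parent1 == g$ID, , drop = FALSE]
    if (nrow(gtx) == 0) next
    cds_len <- vapply(gtx$ID, function(tid) {
      tc <- cds[!is.na(cds$parent1) & cds$parent1 == tid, , drop = FALSE]
      if (nrow(tc) == 0) 0L else sum(tc$end - tc$start + 1L)
    }, integer(1))
    tx <- gtx[which.max(cds_len), ]
    tex <- exons[!is.na(exons$parent1) & exons$parent1 == tx$ID, , drop = FALSE]
    tcd <- cds[!is.na(cds$parent1) & cds$parent1 == tx$ID, , drop = FALSE]
    tex <- tex[order(tex$start), , drop = FALSE]
    tcd <- tcd[order(tcd$start), , drop = FALSE]
    strand <- g$strand
    exon_mat <- iv_matrix(tex$start, tex$end)
    cds_mat <- iv_matrix(tcd$start, tcd$end)
    phase0 <- 0L
    if (nrow(tcd) > 0) {
      ph <- suppressWarnings(as.integer(as.character(tcd$phase)))
      ph[is.na(ph)] <- 0L
      # phase of the 5'-most CDS segment on the coding strand
      phase0 <- if (strand == "-") ph[nrow(tcd)] else ph[1]
    }
    total_cds <- if (nrow(cds_mat)) sum(cds_mat[, 2] - cds_mat[, 1] + 1L) else 0L
    cds_ok <- total_cds > 0 && ((total_cds - phase0) %% 3L == 0L)
    u5 <- utr5f[!is.na(utr5f$parent1) & utr5f$parent1 == tx$ID, , drop = FALSE]
    u3 <- utr3f[!is.na(utr3f$parent1) & utr3f$parent1 == tx$ID, , drop = FALSE]
    if (nrow(u5) + nrow(u3) > 0) {
      utr5 <- iv_matrix(u5$start, u5$end)
      utr3 <- iv_matrix(u3$start, u3$end)
    } else if (nrow(cds_mat) > 0 && nrow(exon_mat) > 0) {
      left <- iv_clip(exon_mat, 1L, min(cds_mat[, 1]) - 1L)
      right <- iv_clip(exon_mat, max(cds_mat[, 2]) + 1L, .Machine$integer.max)
      if (strand == "-") { utr5 <- right; utr3 <- left }
      else { utr5 <- left; utr3 <- right }
    } else {
      utr5 <- utr3 <- iv_matrix(integer(), integer())
    }
    models[[as.character(g$ID)]] <- structure(list(
      gene_id = as.character(g$ID), transcript_id = as.character(tx$ID),
      contig = g$seqnames, strand = strand,
      start = g$start, end = g$end,
      exons = exon_mat, cds = cds_mat, phase = phase0,
      utr5 = utr5, utr3 = utr3,
      tss = if (strand == "-") g$end else g$start,
      cds_ok = cds_ok), class = "gene_model")
  }
  structure(models, class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d contig(s)\n", length(x),
              length(unique(vapply(x, `[[`, "", "contig")))))
  invisible(x)
}

iv_matrix <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m[m[, 1] <= m[, 2], , drop = FALSE]
}

# Intersect interval rows with [lo, hi]; drop empties.
iv_clip <- function(iv, lo, hi) {
  if (nrow(iv) == 0) return(iv)
  s <- pmax(iv[, 1], lo)
  e <- pmin(iv[, 2], hi)
  iv_matrix(s[s <= e], e[s <= e])
}

#' Read phased genotypes from a VCF
#'
#' Extracts two haplotype sequences per diploid sample over all biallelic
#' SNP records. Heterozygous genotypes that are not phased (`0/1`) are
#' masked (`NA`) in both haplotypes of that sample; homozygous genotypes
#' carry no phase ambiguity and are always filled. Missing genotypes are
#' masked.
#'
#' @param path Path to a VCF (4.x) with GT fields; `|` marks phase.
#' @param manifest data.frame with columns `sample_id`, `population_id`,
#'   `species` (`"focal"` or `"outgroup"`) and optionally `basin`.
#' @return A `phased_genotypes` object: list with `sites` (contig, pos,
#'   ref, alt), `haps` (character matrix, sites x haplotypes, `NA` =
#'   masked) and `info` (one row per haplotype: hap_id, sample_id,
#'   population_id, species, basin).
#' @export
read_phased_vcf <- function(path, manifest) {
  stopifnot(all(c("sample_id", "population_id", "species") %in% names(manifest)))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  missing_samples <- setdiff(manifest$sample_id, colnames(gt))
  if (length(missing_samples)) {
    stop("samples in manifest but not in VCF: ",
         paste(missing_samples, collapse = ", "))
  }
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & ref %in% ACGT & alt %in% ACGT
  sites <- data.frame(contig = fix[snp, "CHROM"],
                      pos = as.integer(fix[snp, "POS"]),
                      ref = ref[snp], alt = alt[snp],
                      stringsAsFactors = FALSE)
  gt <- gt[snp, manifest$sample_id, drop = FALSE]
  n_site <- nrow(sites)
  n_samp <- nrow(manifest)
  haps <- matrix(NA_character_, nrow = n_site, ncol = 2L * n_samp)
  hap_ids <- as.vector(t(outer(manifest$sample_id, c("_h1", "_h2"), paste0)))
  colnames(haps) <- hap_ids
  for (s in seq_len(n_samp)) {
    g <- gt[, s]
    phased <- grepl("|", g, fixed = TRUE)
    al <- strsplit(g, "[|/]")
    a1 <- vapply(al, function(a) if (length(a) >= 1) a[1] else ".", character(1))
    a2 <- vapply(al, function(a) if (length(a) >= 2) a[2] else ".", character(1))
    ok1 <- a1 %in% c("0", "1")
    ok2 <- a2 %in% c("0", "1")
    het <- ok1 & ok2 & a1 != a2
    usable <- ok1 & ok2 & (phased | !het) # unphased het -> masked
    h1 <- h2 <- rep(NA_character_, n_site)
    h1[usable] <- ifelse(a1[usable] == "0", sites$ref[usable], sites$alt[usable])
    h2[usable] <- ifelse(a2[usable] == "0", sites$ref[usable], sites$alt[usable])
    haps[, 2L * s - 1L] <- h1
    haps[, 2L * s] <- h2
  }
  info <- data.frame(
    hap_id = hap_ids,
    sample_id = rep(manifest$sample_id, each = 2L),
    population_id = rep(manifest$population_id, each = 2L),
    species = rep(manifest$species, each = 2L),
    basin = rep(if ("basin" %in% names(manifest)) manifest$basin
                else NA_character_, each = 2L),
    stringsAsFactors = FALSE)
  structure(list(sites = sites, haps = haps, info = info),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat(sprintf("phased_genotypes: %d sites, %d haplotypes from %d samples\n",
              nrow(x$sites), ncol(x$haps), ncol(x$haps) / 2))
  invisible(x)
}

#' Serialize a tree to newick text
#'
#' Validates tip labels (present, unique, free of newick metacharacters)
#' and branch lengths (present, non-negative) before delegating to
#' [ape::write.tree()].
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param path Optional output path; when given the text is also written
#'   to file.
#' @return Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (is.null(labs) || any(is.na(labs)) || any(!nzchar(labs))) {
    stop("all tips must be labeled")
  }
  if (anyDuplicated(labs)) stop("tip labels must be unique")
  if (any(grepl("[][():;,[:space:]]", labs))) {
    stop("tip labels must not contain newick metacharacters")
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a newick tree
#'
#' @param path Path to a newick file (or a literal newick string via
#'   `text`).
#' @param text Optional newick string.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
}

# ---- emitters used by the simulator (plain text writers) -------------------

# Write minimal, valid GFF3 from a data.frame of gene structures as built
# by emit_dataset(): columns contig, type, start, end, strand, phase, id,
# parent.
write_gff3 <- function(feat, path) {
  attr_col <- ifelse(is.na(feat$parent),
                     paste0("ID=", feat$id),
                     paste0("ID=", feat$id, ";Parent=", feat$parent))
  lines <- paste(feat$contig, "tspscan", feat$type, feat$start, feat$end,
                 ".", feat$strand, ifelse(is.na(feat$phase), ".", feat$phase),
                 attr_col, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# Write a fully phased VCF for the given samples. `geno` is an integer
# array sites x samples x 2 of allele indexes (0 = ref, 1 = alt).
write_phased_vcf <- function(sites, geno, sample_ids, path) {
  stopifnot(dim(geno)[1] == nrow(sites), dim(geno)[2] == length(sample_ids))
  gt_cols <- vapply(seq_along(sample_ids), function(s)
    paste0(geno[, s, 1], "|", geno[, s, 2]), character(nrow(sites)))
  if (nrow(sites) == 1L) gt_cols <- matrix(gt_cols, nrow = 1L)
  header <- c("##fileformat=VCFv4.2",
              "##source=tspscan-simulator",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  body <- paste(sites$contig, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT",
                apply(gt_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
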