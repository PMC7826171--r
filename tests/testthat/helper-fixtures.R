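# Shared fixtures, all generated in code at test time.

# Small simulation config used across tests: two Atlantic and one Pacific
# population at the minimum pool size, short loci.
tiny_config <- function(seed = 11, n_neutral_loci = 2, n_balanced_loci = 1,
                        ...) {
  sim_config(seed = seed,
             populations = c(P1 = "pacific", A1 = "atlantic", A2 = "atlantic"),
             pool_sizes = c(P1 = 10, A1 = 10, A2 = 10),
             locus_length = 300,
             n_neutral_loci = n_neutral_loci,
             n_balanced_loci = n_balanced_loci,
             ...)
}

# Single-population config for coalescent calibration.
calib_config <- function(seed = 1, locus_length = 10000, ...) {
  sim_config(seed = seed,
             populations = c(POP = "atlantic"),
             pool_sizes = c(POP = 10),
             locus_length = locus_length, ...)
}

# Memoized default simulated dataset + scan (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(seed = 42, n_neutral_loci = 5, n_balanced_loci = 2)
    .fixture_env$sim <- emit_dataset(cfg, file.path(tempdir(), "tspscan_fix"),
                                     overwrite = TRUE)
  }
  .fixture_env$sim
}

default_scan <- function() {
  if (is.null(.fixture_env$scan)) {
    sc <- scan_config_from_sim(default_sim(), n_perm = 199, n_boot = 20)
    .fixture_env$scan <- run_scan(sc)
  }
  .fixture_env$scan
}

# A small hand-written GFF3 with two genes (one per strand).
write_test_gff <- function(path, plus_cds_len = 201) {
  lines <- c(
    "##gff-version 3",
    sprintf("chr1\ttest\tgene\t100\t400\t.\t+\t.\tID=gA"),
    sprintf("chr1\ttest\tmRNA\t100\t400\t.\t+\t.\tID=tA;Parent=gA"),
    sprintf("chr1\ttest\texon\t100\t400\t.\t+\t.\tID=tA.e1;Parent=tA"),
    sprintf("chr1\ttest\tCDS\t150\t%d\t.\t+\t0\tID=tA.c1;Parent=tA",
            150 + plus_cds_len - 1),
    "chr1\ttest\tgene\t1100\t1400\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t1100\t1400\t.\t-\t.\tID=tB;Parent=gB",
    "chr1\ttest\texon\t1100\t1400\t.\t-\t.\tID=tB.e1;Parent=tB",
    "chr1\ttest\tCDS\t1150\t1350\t.\t-\t0\tID=tB.c1;Parent=tB")
  writeLines(lines, path)
  path
}

# Hand-written VCF exercising phased/unphased/missing genotypes.
write_test_vcf <- function(path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", "S2", "OUT"), collapse = "\t"))
  body <- c(
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0|1",
    "chr1\t20\t.\tC\tG\t.\tPASS\t.\tGT\t0/1\t0|0\t0/0",
    "chr1\t30\t.\tG\tA\t.\tPASS\t.\tGT\t.\t1|0\t0|0")
  writeLines(c(hdr, body), path)
  path
}

test_manifest <- function() {
  data.frame(sample_id = c("S1", "S2", "OUT"),
             population_id = c("p1", "p2", "OUT"),
             species = c("focal", "focal", "outgroup"),
             basin = c("pacific", "atlantic", "outgroup"),
             stringsAsFactors = FALSE)
}
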