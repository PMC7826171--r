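#' Derive a stage-specific random seed from a master seed
#'
#' Mixes a master seed with a character label so that each pipeline stage
#' (and each simulated locus) gets its own reproducible RNG stream.
#' Adding a new stage with a new label never perturbs the streams of
#' existing stages.
#'
#' @param seed Integer master seed.
#' @param label Character scalar naming the stage/locus.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "neutral_locus_1")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer((abs(seed) %% m + h) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Nucleotide order used throughout for sync count vectors.
SYNC_BASES <- c("A", "T", "C", "G", "N", "del")
ACGT <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
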