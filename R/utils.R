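## Small shared helpers.  Coordinates are 0-based half-open everywhere inside
## the package; conversion to 1-based happens only at GFF/Bioconductor
## boundaries.

CATEGORY_LEVELS <- c("rRNA_genbank", "rRNA_rfam", "known_miRNA",
                     "repeat", "exon", "intron", "unann")

#' Reverse-complement nucleotide sequences
#'
#' Vectorised over a character vector of ACGT(N) sequences.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards.
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

## Derive a per-sample RNG seed < 2^31 from a base seed and a sample name,
## so adding a sample never perturbs the streams of the others.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587)
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## features data.frame (0-based half-open) -> GRanges (1-based closed)
features_to_granges <- function(feat) {
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(start = feat$start + 1L, end = feat$end),
    strand = feat$strand)
  S4Vectors::mcols(gr)$category <- feat$category
  S4Vectors::mcols(gr)$name <- feat$name
  gr
}

category_rank <- function(x) match(x, CATEGORY_LEVELS)

`%||%` <- function(a, b) if (is.null(a)) b else a
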