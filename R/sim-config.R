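#' Simulation configuration for the toy small RNA-seq study
#'
#' Bundles every tunable of the synthetic-data generator: genome geometry,
#' how many miRNA precursors of each kind to plant, raw-read geometry, the
#' mature-length distribution, per-class read shares and the X-dosage
#' multiplier.  Defaults describe the study conditions the package is built
#' to emulate: 18--30 nt clean reads peaked at 22--23 nt, 35-nt raw reads
#' carrying a 3' adaptor, roughly 60% miRNA / 15% other-annotated / 25%
#' unannotated clean reads, and a 2x X-linked dosage for cells with two
#' active X chromosomes.
#'
#' @param n_autosomes number of autosomes (named chr1, chr2, ...); a chrX is
#'   always added on top.
#' @param chrom_length bases per chromosome.
#' @param n_mirnas_per_chrom expressed known miRNA precursors planted per
#'   chromosome (standalone, spaced > 10 kb apart).
#' @param n_clustered_groups number of genomic miRNA clusters (3 known
#'   precursors each, consecutive first nucleotides < 10 kb apart), placed
#'   round-robin on the autosomes.
#' @param n_other_rna features per non-miRNA class (rRNA_genbank, rRNA_rfam,
#'   repeat, exon, intron) on each chromosome.
#' @param n_novel_mirnas planted hairpin precursors absent from the known
#'   annotation (their reads end up unannotated).
#' @param n_noise_mirnas known-catalog entries with sporadic expression
#'   (fractions of a read on average), the prey of the Poisson noise filter.
#' @param n_decoys non-hairpin loci whose reads have scattered 5' ends; they
#'   exercise rejection in the novel-miRNA caller.
#' @param adaptor_seq 3' adaptor ligated to every genuine insert.
#' @param raw_read_len fixed raw read length from the sequencer.
#' @param read_depth nominal raw reads per library.
#' @param mature_len_distribution named probability vector over insert
#'   lengths; default spans 19--28 nt peaked at 22--23 (a 35-nt raw read
#'   cannot carry a longer insert and still show a detectable adaptor).
#' @param frac_contaminant,frac_low_quality proportions of raw reads that
#'   are adaptor-free contaminants resp. low-quality reads.
#' @param frac_mirna,frac_degradation,frac_novel,frac_noise shares of the
#'   remaining (good) reads given to known miRNAs, feature-degradation
#'   fragments, novel-hairpin miRNAs and uniform background noise.
#' @param decoy_reads expected reads per decoy locus.
#' @param noise_mirna_reads expected reads per sporadic (noise) miRNA.
#' @param xci_ratio multiplier on X-linked miRNA output for samples with two
#'   active X chromosomes (default 2: two active X = twice one active X).
#' @param seed base RNG seed; per-sample streams are derived from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_autosomes = 3L,
                       chrom_length = 200000L,
                       n_mirnas_per_chrom = 8L,
                       n_clustered_groups = 2L,
                       n_other_rna = 4L,
                       n_novel_mirnas = 6L,
                       n_noise_mirnas = 10L,
                       n_decoys = 4L,
                       adaptor_seq = "TCGTATGCCGTCTTCTGCTTG",
                       raw_read_len = 35L,
                       read_depth = 200000L,
                       mature_len_distribution = NULL,
                       frac_contaminant = 0.05,
                       frac_low_quality = 0.05,
                       frac_mirna = 0.60,
                       frac_degradation = 0.15,
                       frac_novel = 0.22,
                       frac_noise = 0.005,
                       decoy_reads = 40,
                       noise_mirna_reads = 0.3,
                       xci_ratio = 2,
                       seed = 1L) {
  if (is.null(mature_len_distribution)) {
    lens <- 19:28
    w <- c(1, 2, 4, 10, 10, 4, 2, 1, 1, 1)
    mature_len_distribution <- setNames(w / sum(w), lens)
  }
  cfg <- list(n_autosomes = as.integer(n_autosomes),
              chrom_length = as.integer(chrom_length),
              n_mirnas_per_chrom = as.integer(n_mirnas_per_chrom),
              n_clustered_groups = as.integer(n_clustered_groups),
              n_other_rna = as.integer(n_other_rna),
              n_novel_mirnas = as.integer(n_novel_mirnas),
              n_noise_mirnas = as.integer(n_noise_mirnas),
              n_decoys = as.integer(n_decoys),
              adaptor_seq = toupper(adaptor_seq),
              raw_read_len = as.integer(raw_read_len),
              read_depth = as.integer(read_depth),
              mature_len_distribution = mature_len_distribution,
              frac_contaminant = frac_contaminant,
              frac_low_quality = frac_low_quality,
              frac_mirna = frac_mirna,
              frac_degradation = frac_degradation,
              frac_novel = frac_novel,
              frac_noise = frac_noise,
              decoy_reads = decoy_reads,
              noise_mirna_reads = noise_mirna_reads,
              xci_ratio = xci_ratio,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c("frac_contaminant", "frac_low_quality", "frac_mirna",
             "frac_degradation", "frac_novel", "frac_noise")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("config field '", p, "' must be a proportion in [0, 1]")
  }
  if (cfg$frac_contaminant + cfg$frac_low_quality >= 1)
    stop("contaminant + low-quality fractions must leave room for good reads")
  if (cfg$xci_ratio <= 0) stop("xci_ratio must be positive")
  if (cfg$n_autosomes < 1L) stop("need at least one autosome (chr1)")
  if (!grepl("^[ACGT]+$", cfg$adaptor_seq)) stop("adaptor must be ACGT")
  d <- cfg$mature_len_distribution
  if (is.null(names(d)) || any(is.na(as.integer(names(d)))) ||
      abs(sum(d) - 1) > 1e-8 || any(d < 0))
    stop("mature_len_distribution must be a named probability vector")
  lens <- as.integer(names(d))
  if (any(lens < 18L | lens > 30L))
    stop("mature lengths must lie in the 18-30 nt clean-read window")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_autosomes, "autosome(s) + chrX,",
      x$chrom_length, "bp each\n")
  cat("  planted per chrom:", x$n_mirnas_per_chrom, "known miRNAs;",
      x$n_clustered_groups, "cluster group(s);",
      x$n_novel_mirnas, "novel,", x$n_noise_mirnas, "noise,",
      x$n_decoys, "decoy loci genome-wide\n")
  cat("  depth", x$read_depth, "reads; raw length", x$raw_read_len,
      "nt; adaptor", x$adaptor_seq, "\n")
  cat("  xci_ratio", x$xci_ratio, "; seed", x$seed, "\n")
  invisible(x)
}

#' Read / write a simulation config as YAML
#'
#' @param path file path.
#' @param config a `sim_config` object.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$mature_len_distribution))
    raw$mature_len_distribution <- unlist(raw$mature_len_distribution)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  ## a named list serialises as a YAML map (a bare vector would lose names)
  x$mature_len_distribution <- as.list(x$mature_len_distribution)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}
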