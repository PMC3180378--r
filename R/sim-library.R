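## Simulated small RNA libraries: Poisson read counts around planted
## abundances, X-dosage scaling, adaptor-bearing 35-nt raw reads, plus
## contaminant and low-quality reads.

#' Simulate a small RNA-seq library from a toy genome
#'
#' Draws read counts for every planted locus from a Poisson distribution
#' around its expected abundance (scaled by `xci_ratio` on chrX for samples
#' with two active X chromosomes), adds feature-degradation fragments,
#' uniform background noise, decoy reads with scattered 5' ends,
#' adaptor-free contaminants and low-quality reads, and assembles fixed
#' length raw reads (insert + 3' adaptor, truncated to `raw_read_len`).
#'
#' @param genome a [generate_toy_genome()] result.
#' @param sample sample name.
#' @param xci_status one of `"male"`, `"one_active_X"`, `"two_active_X"`.
#'   Two active X chromosomes multiply the expected output of every
#'   X-linked miRNA by `config$xci_ratio`; male and one-active-X samples
#'   share the baseline dosage.
#' @param read_depth nominal raw read count (default from the config).
#' @param seed RNG seed for this library; defaults to a stream derived from
#'   the config seed and the sample name, so adding a sample does not
#'   perturb the others.
#' @param make_reads if `FALSE`, only the ground-truth counts are drawn
#'   (fast path for dosage checks at very high depth).
#' @param min_adaptor_overlap smallest adaptor suffix that must remain
#'   visible in a raw read; inserts longer than
#'   `raw_read_len - min_adaptor_overlap` are rejected with an error.
#' @return an object of class `sim_library`: list with `sample`,
#'   `xci_status`, `reads` and `quals` (character vectors, Phred+33),
#'   `truth_counts` (data.frame name/kind/chrom/true_count/expected) and
#'   `class_counts` (raw reads per simulation class).
#' @export
simulate_library <- function(genome, sample,
                             xci_status = c("male", "one_active_X",
                                            "two_active_X"),
                             read_depth = NULL, seed = NULL,
                             make_reads = TRUE,
                             min_adaptor_overlap = 6L) {
  stopifnot(inherits(genome, "toy_genome"))
  xci_status <- match.arg(xci_status)
  cfg <- genome$config
  depth <- as.integer(read_depth %||% cfg$read_depth)
  if (depth < 0) stop("read_depth must be >= 0")
  if (is.null(seed)) seed <- derive_seed(cfg$seed, sample)
  max_insert <- cfg$raw_read_len - as.integer(min_adaptor_overlap)
  if (any(genome$truth$mature_len > max_insert))
    stop("planted mature length exceeds raw read length minus the ",
         "minimum adaptor overlap (", max_insert, " nt)")
  with_seed(seed,
            build_library(genome, sample, xci_status, depth, cfg,
                          make_reads))
}

build_library <- function(genome, sample, xci_status, depth, cfg,
                          make_reads) {
  t <- genome$truth
  good <- max(0, 1 - cfg$frac_contaminant - cfg$frac_low_quality)

  expected <- numeric(nrow(t))
  for (kind in c("known", "novel")) {
    sel <- t$kind == kind
    share <- if (kind == "known") cfg$frac_mirna else cfg$frac_novel
    if (any(sel))
      expected[sel] <- t$weight[sel] / sum(t$weight[sel]) *
        share * good * depth
  }
  expected[t$kind == "noise"] <- cfg$noise_mirna_reads * depth /
    cfg$read_depth
  expected[t$kind == "decoy"] <- cfg$decoy_reads * depth / cfg$read_depth
  if (xci_status == "two_active_X") {
    xl <- t$chrom == "chrX" & t$kind %in% c("known", "novel", "noise")
    expected[xl] <- expected[xl] * cfg$xci_ratio
  }
  counts <- if (depth == 0) integer(nrow(t)) else rpois(nrow(t), expected)
  truth_counts <- data.frame(name = t$name, kind = t$kind, chrom = t$chrom,
                             true_count = counts, expected = expected,
                             stringsAsFactors = FALSE)

  n_deg <- if (depth == 0) 0L else rpois(1, cfg$frac_degradation * good * depth)
  n_unif <- if (depth == 0) 0L else rpois(1, cfg$frac_noise * good * depth)
  n_cont <- if (depth == 0) 0L else rpois(1, cfg$frac_contaminant * depth)
  n_lowq <- if (depth == 0) 0L else rpois(1, cfg$frac_low_quality * depth)
  class_counts <- c(mirna = sum(counts[t$kind != "decoy"]),
                    decoy = sum(counts[t$kind == "decoy"]),
                    degradation = n_deg, background = n_unif,
                    contaminant = n_cont, low_quality = n_lowq)

  lib <- list(sample = sample, xci_status = xci_status,
              truth_counts = truth_counts, class_counts = class_counts,
              read_depth = depth)
  if (!make_reads) {
    lib$reads <- NULL
    lib$quals <- NULL
    class(lib) <- "sim_library"
    return(lib)
  }

  inserts <- character(0)

  ## planted miRNA-class loci: exact mature sequence per read
  rep_idx <- rep.int(seq_len(nrow(t)), counts)
  rep_idx <- rep_idx[t$kind[rep_idx] != "decoy"]
  inserts <- c(inserts, t$mature_seq[rep_idx])

  ## decoy loci: 5' ends scattered over 6 positions, lengths 20-23
  for (i in which(t$kind == "decoy")) {
    k <- counts[i]
    if (k == 0) next
    off <- sample(0:5, k, replace = TRUE)
    len <- sample(20:23, k, replace = TRUE)
    inserts <- c(inserts, extract_insert(genome, t$chrom[i], t$strand[i],
                                         t$mat_start[i], t$mat_end[i],
                                         off, len))
  }

  ## degradation fragments from annotated non-miRNA features
  feats <- genome$features[genome$features$category != "known_miRNA", ]
  if (n_deg > 0 && nrow(feats) > 0) {
    flen <- feats$end - feats$start
    fi <- sample(nrow(feats), n_deg, replace = TRUE, prob = flen)
    len <- draw_insert_len(n_deg, cfg)
    len <- pmin(len, flen[fi])
    off <- floor(runif(n_deg) * (flen[fi] - len + 1))
    inserts <- c(inserts, extract_insert(genome, feats$chrom[fi],
                                         feats$strand[fi], feats$start[fi],
                                         feats$end[fi], off, len))
  }

  ## uniform background noise anywhere on the genome
  if (n_unif > 0) {
    chrn <- names(genome$chromosomes)
    clen <- nchar(genome$chromosomes)
    ci <- sample(length(chrn), n_unif, replace = TRUE, prob = clen)
    len <- draw_insert_len(n_unif, cfg)
    pos <- floor(runif(n_unif) * (clen[ci] - len))
    strand <- sample(c("+", "-"), n_unif, replace = TRUE)
    s <- substring(genome$chromosomes[ci], pos + 1L, pos + len)
    s[strand == "-"] <- revcomp(s[strand == "-"])
    inserts <- c(inserts, s)
  }

  n_good <- length(inserts)
  reads_good <- finish_read(inserts, cfg)
  quals_good <- quality_strings(n_good, cfg$raw_read_len, 30:40)

  ## low-quality reads: genuine inserts, mean Phred well below 20
  lowq_inserts <- if (n_lowq > 0)
    t$mature_seq[sample(which(t$kind == "known"), n_lowq, replace = TRUE)]
  else character(0)
  reads_lowq <- finish_read(lowq_inserts, cfg)
  quals_lowq <- quality_strings(n_lowq, cfg$raw_read_len, 3:12)

  ## contaminants: random sequence, no adaptor
  reads_cont <- random_dna(n_cont, cfg$raw_read_len)
  quals_cont <- quality_strings(n_cont, cfg$raw_read_len, 30:40)

  lib$reads <- c(reads_good, reads_lowq, reads_cont)
  lib$quals <- c(quals_good, quals_lowq, quals_cont)
  class(lib) <- "sim_library"
  lib
}

## 5'-offset extraction honouring strand: for "-" loci the 5' end of the
## transcript is the genomic *end* of the interval.
extract_insert <- function(genome, chrom, strand, start, end, off, len) {
  s <- character(length(off))
  plus <- strand == "+"
  if (any(plus)) {
    a <- start[plus] + off[plus]
    s[plus] <- substring(genome$chromosomes[chrom[plus]], a + 1L,
                         a + len[plus])
  }
  if (any(!plus)) {
    b <- end[!plus] - off[!plus]
    s[!plus] <- revcomp(substring(genome$chromosomes[chrom[!plus]],
                                  b - len[!plus] + 1L, b))
  }
  s
}

draw_insert_len <- function(n, cfg) {
  lens <- as.integer(names(cfg$mature_len_distribution))
  sample(lens, n, replace = TRUE,
         prob = unname(cfg$mature_len_distribution))
}

## insert + 3' adaptor, truncated/padded to the fixed raw read length
finish_read <- function(inserts, cfg) {
  if (length(inserts) == 0L) return(character(0))
  full <- paste0(inserts, cfg$adaptor_seq,
                 strrep("A", cfg$raw_read_len))
  substr(full, 1L, cfg$raw_read_len)
}

quality_strings <- function(n, len, qrange) {
  if (n == 0L) return(character(0))
  q <- sample(qrange, n, replace = TRUE)
  strrep(vapply(q + 33L, function(x) rawToChar(as.raw(x)), ""), len)
}

#' @export
print.sim_library <- function(x, ...) {
  cat("Simulated small RNA library '", x$sample, "' (", x$xci_status,
      ")\n", sep = "")
  cat("  raw reads:", length(x$reads %||% integer(0)),
      if (is.null(x$reads)) "(truth counts only)" else "", "\n")
  cat("  class counts:",
      paste(names(x$class_counts), x$class_counts, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
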