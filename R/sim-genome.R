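## Toy genome generation: random chromosomes with planted miRNA hairpins
## (known / novel / sporadic-noise), decoy loci, genomic clusters and
## non-miRNA feature tracks, plus a full ground-truth registry.

EXT_LEN <- 4L    # GC-rich stem extension between the mature arm and the loop
LOOP_LEN <- 10L  # terminal loop, drawn from {A,C} so it cannot pair with itself

#' Generate a toy genome with planted miRNA hairpins and annotation tracks
#'
#' Builds `config$n_autosomes` autosomes plus a chrX of random sequence and
#' overwrites planted elements into them: perfect-complement miRNA hairpins
#' (arm + GC extension + loop + their reverse complement) for known, novel
#' and sporadic-noise miRNAs; non-hairpin decoy loci; and rRNA/repeat/exon/
#' intron features.  Standalone miRNA-class loci are spaced more than 10 kb
#' apart so the only sub-10-kb neighbours are the planted cluster groups.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `toy_genome`: list with `chromosomes` (named
#'   character vector), `features` (data.frame: chrom, start, end, strand,
#'   category, name; 0-based half-open), `truth` (planted-locus registry
#'   with precursor/mature/star intervals, mature sequence, expression
#'   weight and cluster id) and `config`.
#' @export
generate_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "toy-genome"), build_toy_genome(config))
}

build_toy_genome <- function(config) {
  chroms <- c(paste0("chr", seq_len(config$n_autosomes)), "chrX")
  autosomes <- setdiff(chroms, "chrX")
  ## planted precursor arms stay canonical miRNA-sized (<= 26 nt); the
  ## full length distribution still shapes degradation/background reads
  lens <- as.integer(names(config$mature_len_distribution))
  probs <- unname(config$mature_len_distribution)
  keep <- lens <= 26L
  if (!any(keep)) stop("mature_len_distribution has no mass at <= 26 nt")
  hp_lens <- lens[keep]; hp_probs <- probs[keep] / sum(probs[keep])

  draw_len <- function(n) sample(hp_lens, n, replace = TRUE,
                                 prob = hp_probs)

  ## ---- plan the planted elements -----------------------------------------
  plan <- list()
  idx <- list(known = 0L, novel = 0L, noise = 0L, decoy = 0L)
  add <- function(kind, chrom, cluster_id = NA_integer_) {
    idx[[kind]] <<- idx[[kind]] + 1L
    plan[[length(plan) + 1L]] <<- list(
      kind = kind, chrom = chrom, cluster_id = cluster_id,
      name = sprintf("%s-mir-%s-%d",
                     switch(kind, known = "toy", novel = "nov",
                            noise = "low", decoy = "decoy"),
                     sub("^chr", "", chrom), idx[[kind]]))
  }
  for (ch in chroms)
    for (i in seq_len(config$n_mirnas_per_chrom)) add("known", ch)
  cl_id <- 0L
  for (g in seq_len(config$n_clustered_groups)) {
    cl_id <- cl_id + 1L
    ch <- autosomes[((g - 1L) %% length(autosomes)) + 1L]
    for (m in 1:3) add("known", ch, cluster_id = cl_id)
  }
  rr <- function(i) chroms[((i - 1L) %% length(chroms)) + 1L]
  for (i in seq_len(config$n_novel_mirnas)) add("novel", rr(i))
  for (i in seq_len(config$n_noise_mirnas)) add("noise", rr(i + 1L))
  for (i in seq_len(config$n_decoys)) add("decoy", rr(i + 2L))

  ## ---- lay the elements out along each chromosome ------------------------
  ## Standalone miRNA-class loci are separated by > 10,050 bp between first
  ## nucleotides; cluster members sit 2.5-4 kb apart.
  truth <- list()
  feat <- list()
  for (ch in chroms) {
    items <- Filter(function(p) p$chrom == ch, plan)
    singles <- Filter(function(p) is.na(p$cluster_id), items)
    grouped <- Filter(function(p) !is.na(p$cluster_id), items)
    groups <- split(grouped, vapply(grouped, function(p) p$cluster_id, 0L))

    cursor <- 300L
    place_one <- function(p) {
      mlen <- draw_len(1L)
      arm5 <- if (runif(1) < 0.5) "5p" else "3p"
      strand <- if (runif(1) < 0.7) "+" else "-"
      h <- build_hairpin(mlen, arm5, kind = p$kind)
      L <- nchar(h$seq)
      start <- cursor
      rec <- hairpin_record(p, ch, strand, start, h, L)
      cursor <<- start + L
      rec
    }
    for (p in singles) {
      truth[[length(truth) + 1L]] <- place_one(p)
      cursor <- cursor + 10050L + sample(0:800, 1L)
    }
    for (grp in groups) {
      firsts <- integer(0)
      for (p in grp) {
        anchor <- cursor
        truth[[length(truth) + 1L]] <- place_one(p)
        firsts <- c(firsts, anchor)
        cursor <- anchor + sample(2500:4000, 1L)   # first-nt gap <= 10 kb
      }
      cursor <- max(cursor, firsts[length(firsts)] + 120L) + 10050L
    }
    feat_need <- config$n_other_rna * 5L * 700L + 500L
    if (cursor > config$chrom_length - feat_need)
      stop("chrom_length too small: planted loci on ", ch,
           " need at least ", cursor + feat_need, " bases")

    ## non-miRNA feature tracks, placed after the miRNA territory
    other <- c("rRNA_genbank", "rRNA_rfam", "repeat", "exon", "intron")
    k <- 0L
    for (cat in rep(other, each = config$n_other_rna)) {
      k <- k + 1L
      flen <- sample(80:200, 1L)
      start <- cursor + sample(100:400, 1L)
      if (start + flen > config$chrom_length - 200L)
        stop("chrom_length too small for feature tracks on ", ch)
      feat[[length(feat) + 1L]] <- data.frame(
        chrom = ch, start = start, end = start + flen,
        strand = sample(c("+", "-"), 1L),
        category = cat, name = sprintf("%s-%s-%d", cat, ch, k),
        stringsAsFactors = FALSE)
      cursor <- start + flen
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  ## ---- chromosome sequences ---------------------------------------------
  chromosomes <- setNames(random_dna(length(chroms), config$chrom_length),
                          chroms)
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    seg <- r$planted_seq
    substr(chromosomes[[r$chrom]], r$pre_start + 1L, r$pre_end) <- seg
  }
  truth$planted_seq <- NULL

  ## known + noise miRNAs are annotated (precursor interval); novel and
  ## decoy loci deliberately are not.
  ann <- truth[truth$kind %in% c("known", "noise"), ]
  mir_feat <- data.frame(chrom = ann$chrom, start = ann$pre_start,
                         end = ann$pre_end, strand = ann$strand,
                         category = "known_miRNA", name = ann$name,
                         stringsAsFactors = FALSE)
  features <- rbind(do.call(rbind, feat), mir_feat)
  rownames(features) <- NULL

  ## expression weights (relative within kind; scaled at simulation time).
  ## chrX carries a small, fixed share of each kind's expression (~8%, as
  ## in real libraries where the major miRNA clusters are autosomal), so
  ## that X-dosage changes barely dilute autosomal TPM and chr1 profiles
  ## stay parallel across samples.
  truth$weight <- NA_real_
  truth$weight[truth$kind == "known"] <-
    rlnorm(sum(truth$kind == "known"), meanlog = 0, sdlog = 1)
  truth$weight[truth$kind == "novel"] <-
    rlnorm(sum(truth$kind == "novel"), meanlog = 0, sdlog = 0.5)
  truth$weight[truth$kind == "noise"] <- 1
  truth$weight[truth$kind == "decoy"] <- 1
  for (kind in c("known", "novel")) {
    on_x <- truth$kind == kind & truth$chrom == "chrX"
    off_x <- truth$kind == kind & truth$chrom != "chrX"
    if (any(on_x) && any(off_x)) {
      share <- 0.08
      truth$weight[on_x] <- truth$weight[on_x] /
        sum(truth$weight[on_x]) * share / (1 - share) *
        sum(truth$weight[off_x])
    }
  }

  g <- structure(list(chromosomes = chromosomes, features = features,
                      truth = truth, config = config),
                 class = "toy_genome")
  validate_toy_genome(g)
  g
}

## Build one hairpin (or decoy) in transcript orientation and return the
## planted sequence plus transcript-relative mature/star intervals.
build_hairpin <- function(mlen, arm, kind) {
  if (kind == "decoy") {
    L <- 2L * mlen + EXT_LEN * 2L + LOOP_LEN
    return(list(seq = random_dna(1L, L), mat = c(0L, mlen),
                star = c(L - mlen, L)))
  }
  armseq <- random_dna(1L, mlen)
  ext <- paste(sample(c("G", "C"), EXT_LEN, replace = TRUE), collapse = "")
  loop <- paste(sample(c("A", "C"), LOOP_LEN, replace = TRUE), collapse = "")
  seq <- paste0(armseq, ext, loop, revcomp(ext), revcomp(armseq))
  L <- nchar(seq)
  if (arm == "5p")
    list(seq = seq, mat = c(0L, mlen), star = c(L - mlen, L))
  else
    list(seq = seq, mat = c(L - mlen, L), star = c(0L, mlen))
}

## Transcript-relative interval [a,b) -> genomic interval for a locus of
## length L starting at `start`, given the strand.
tx_to_genomic <- function(start, L, iv, strand) {
  if (strand == "+") c(start + iv[1], start + iv[2])
  else c(start + L - iv[2], start + L - iv[1])
}

hairpin_record <- function(p, chrom, strand, start, h, L) {
  planted <- if (strand == "+") h$seq else revcomp(h$seq)
  mat <- tx_to_genomic(start, L, h$mat, strand)
  star <- tx_to_genomic(start, L, h$star, strand)
  mature_seq <- substr(h$seq, h$mat[1] + 1L, h$mat[2])
  data.frame(name = p$name, kind = p$kind, chrom = chrom, strand = strand,
             pre_start = start, pre_end = start + L,
             mat_start = mat[1], mat_end = mat[2],
             star_start = star[1], star_end = star[2],
             mature_seq = mature_seq, mature_len = h$mat[2] - h$mat[1],
             cluster_id = p$cluster_id, planted_seq = planted,
             stringsAsFactors = FALSE)
}

validate_toy_genome <- function(g) {
  t <- g$truth
  stopifnot(all(c("chrX", "chr1") %in% names(g$chromosomes)))
  if (any(t$mat_start < t$pre_start | t$mat_end > t$pre_end))
    stop("mature interval escapes its precursor")
  for (ch in unique(t$chrom)) {
    x <- t[t$chrom == ch, ]
    x <- x[order(x$pre_start), ]
    if (nrow(x) > 1 && any(x$pre_start[-1] < x$pre_end[-nrow(x)]))
      stop("planted precursors overlap on ", ch)
  }
  f <- g$features
  if (any(f$start < 0 | f$end > nchar(g$chromosomes[f$chrom])))
    stop("feature outside chromosome bounds")
  ## every planted mature sequence occurs verbatim at its interval
  for (i in seq_len(nrow(t))) {
    r <- t[i, ]
    s <- substr(g$chromosomes[[r$chrom]], r$mat_start + 1L, r$mat_end)
    if (r$strand == "-") s <- revcomp(s)
    if (s != r$mature_seq) stop("mature sequence mismatch for ", r$name)
  }
  invisible(g)
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("Toy genome:", length(x$chromosomes), "chromosomes (",
      paste(names(x$chromosomes), collapse = ", "), "),",
      nchar(x$chromosomes[[1]]), "bp each\n")
  tab <- table(x$truth$kind)
  cat("  planted loci:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  cat("  features:", nrow(x$features), "in",
      length(unique(x$features$category)), "categories\n")
  invisible(x)
}

#' Known-miRNA catalog of a toy genome
#'
#' The coordinate catalog that stands in for a reference miRNA track:
#' precursor and mature intervals for every annotated (known or sporadic)
#' miRNA, with the first-nucleotide position used for cluster grouping.
#'
#' @param genome a `toy_genome`.
#' @return data.frame: name, chrom, strand, pre_start, pre_end, mat_start,
#'   mat_end, first_nt (all 0-based half-open).
#' @export
mirna_catalog <- function(genome) {
  t <- genome$truth[genome$truth$kind %in% c("known", "noise"), ]
  data.frame(name = t$name, chrom = t$chrom, strand = t$strand,
             pre_start = t$pre_start, pre_end = t$pre_end,
             mat_start = t$mat_start, mat_end = t$mat_end,
             first_nt = ifelse(t$strand == "+", t$pre_start, t$pre_end - 1L),
             stringsAsFactors = FALSE)
}
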