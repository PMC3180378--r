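## Novel miRNA prediction from unannotated mapped tags: excise candidate
## windows with flanking sequence, fold them by weighted base-pair
## maximisation, and apply hairpin / Dicer-site / mfe acceptance criteria.

#' Fold an RNA/DNA sequence by weighted base-pair maximisation
#'
#' Computes the maximum-weight nested secondary structure by dynamic
#' programming with pair weights GC 3, AU 2, GU 1 and a minimum hairpin
#' loop of 3 unpaired bases.  The reported `mfe` is the negated total pair
#' weight (declared score units, not thermodynamic kcal/mol).  Traceback
#' is deterministic: unpaired positions are preferred on ties, then the
#' pairing with the smallest outer index.
#'
#' @param sequence a single ACGT/ACGU string, 40-400 nt (shorter inputs
#'   are allowed for `check_length = FALSE`, used by small oracles).
#' @param check_length enforce the 40-400 nt contract (default TRUE).
#' @return object of class `fold_result`: list with `structure`
#'   (dot-bracket), `mfe`, and `pairs` (two-column matrix of 1-based
#'   paired indices, i < j).
#' @export
fold_rna <- function(sequence, check_length = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(chartr("U", "T", sequence))
  if (!grepl("^[ACGT]*$", sequence))
    stop("sequence must be ACGU/ACGT")
  n <- nchar(sequence)
  if (check_length && (n < 40L || n > 400L))
    stop("sequence length must lie in [40, 400], got ", n)
  r <- .fold_nussinov(sequence)
  structure(list(structure = r$structure, mfe = -r$score,
                 pairs = r$pairs, sequence = sequence),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  cat("mfe:", x$mfe, "(", nrow(x$pairs), "pairs )\n")
  invisible(x)
}

#' Excise candidate precursor windows around unannotated tag loci
#'
#' Overlapping unannotated tag hits on the same strand are merged into
#' loci; each locus yields two windows: the locus as putative 5' arm
#' (extended `flank_down` bases 3' of it) and as putative 3' arm (extended
#' `flank_up` bases 5' of it).  Windows are clipped at chromosome ends and
#' flagged when clipped.
#'
#' @param ann an `annotated_tags` object (its `unann` tags are used), or a
#'   hits data.frame of unannotated tags.
#' @param genome a `toy_genome` or named character vector of sequences.
#' @param flank_up,flank_down flank lengths in bases (default 150).
#' @param sample restrict supporting tags to those with nonzero count in
#'   this sample (default: any sample).
#' @param min_support drop loci supported by fewer reads (default 3).
#' @return data.frame of candidate windows: locus coordinates, window
#'   coordinates, `arm` ("5p"/"3p"), `clipped`, and a `locus_id` shared by
#'   the two windows of one locus.
#' @export
extract_candidate_loci <- function(ann, genome, flank_up = 150L,
                                   flank_down = 150L, sample = NULL,
                                   min_support = 3L) {
  stopifnot(flank_up >= 0, flank_down >= 0)
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes
            else genome
  weights <- NULL
  hits <- if (inherits(ann, "annotated_tags")) {
    h <- attr(ann, "hits")
    keep_seq <- ann$sequence[ann$category == "unann"]
    if (!is.null(sample)) {
      keep_seq <- intersect(keep_seq,
                            ann$sequence[ann[[sample]] > 0])
    }
    h <- h[h$sequence %in% keep_seq, , drop = FALSE]
    if (!is.null(sample))
      weights <- ann[[sample]][match(h$sequence, ann$sequence)]
    h
  } else ann
  if (nrow(hits) == 0L)
    return(data.frame(locus_id = integer(0), chrom = character(0),
                      locus_start = integer(0), locus_end = integer(0),
                      strand = character(0), window_start = integer(0),
                      window_end = integer(0), arm = character(0),
                      clipped = logical(0), support = integer(0)))
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start + 1L, hits$end),
                               strand = hits$strand)
  red <- GenomicRanges::reduce(gr, ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(gr, red)
  if (is.null(weights)) weights <- rep(1L, nrow(hits))
  support <- as.integer(tapply(weights[S4Vectors::queryHits(ov)],
                               factor(S4Vectors::subjectHits(ov),
                                      levels = seq_along(red)),
                               sum, default = 0L))
  loci <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                     start = GenomicRanges::start(red) - 1L,
                     end = GenomicRanges::end(red),
                     strand = as.character(GenomicRanges::strand(red)),
                     support = support, stringsAsFactors = FALSE)
  loci <- loci[loci$support >= min_support | min_support <= 1L, ,
               drop = FALSE]
  if (nrow(loci) == 0L) loci <- loci[0, ]
  out <- list()
  for (i in seq_len(nrow(loci))) {
    L <- loci[i, ]
    clen <- nchar(chroms[[L$chrom]])
    ## 5' arm: extend 3' of the locus; 3' arm: extend 5' of it (in
    ## transcript orientation, i.e. swapped on the minus strand)
    w5 <- if (L$strand == "+") c(L$start, L$end + flank_down)
          else c(L$start - flank_down, L$end)
    w3 <- if (L$strand == "+") c(L$start - flank_up, L$end)
          else c(L$start, L$end + flank_up)
    for (arm in c("5p", "3p")) {
      w <- if (arm == "5p") w5 else w3
      clipped <- w[1] < 0 || w[2] > clen
      w[1] <- max(w[1], 0L); w[2] <- min(w[2], clen)
      out[[length(out) + 1L]] <- data.frame(
        locus_id = i, chrom = L$chrom, locus_start = L$start,
        locus_end = L$end, strand = L$strand,
        window_start = as.integer(w[1]), window_end = as.integer(w[2]),
        arm = arm, clipped = clipped, support = L$support,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

default_hairpin_thresholds <- function() {
  list(mfe_max = -18, min_stem_pairs = 16L, dicer_frac = 0.9,
       mature_len = c(18L, 26L), min_loop_dist = 2L, min_support = 3L)
}

#' Evaluate a candidate hairpin against miRNA precursor criteria
#'
#' A candidate is accepted only if all of the following hold, checked in
#' order (the first failure is recorded as the rejection reason):
#' (a) `mfe <= mfe_max`; (b) at least `min_stem_pairs` base pairs between
#' the mature arm and the opposite arm; (c) the mature tag lies entirely
#' on one arm — no pairing within the mature itself, essentially all its
#' partners on one side — and ends at least `min_loop_dist` nt before the
#' terminal loop; (d) Dicer-site consistency: at least `dicer_frac` of
#' supporting reads share one 5' start; (e) mature length 18-26 nt.
#'
#' @param fold a [fold_rna()] result for the window sequence (transcript
#'   orientation).
#' @param mature transcript-relative 0-based half-open interval of the
#'   mature tag within the window, `c(start, end)`.
#' @param support_starts integer vector of supporting-read 5' start
#'   positions (any consistent coordinate system).
#' @param support_counts read counts parallel to `support_starts`.
#' @param thresholds list as from `default_hairpin_thresholds()`.
#' @return list with `accepted`, `reason` (NA when accepted), and the
#'   measured `stem_pairs`, `loop_dist`, `dicer_frac`, `mfe`.
#' @export
evaluate_hairpin <- function(fold, mature, support_starts, support_counts,
                             thresholds = default_hairpin_thresholds()) {
  th <- utils::modifyList(default_hairpin_thresholds(), thresholds)
  ms <- mature[1] + 1L; me <- mature[2]        # 1-based inclusive
  p <- fold$pairs
  in_mat <- function(i) i >= ms & i <= me
  meas <- list(mfe = fold$mfe, stem_pairs = 0L, loop_dist = NA_integer_,
               dicer_frac = NA_real_)
  fail <- function(reason)
    c(list(accepted = FALSE, reason = reason), meas)

  if (fold$mfe > th$mfe_max) return(fail("mfe"))

  if (nrow(p)) {
    m1 <- in_mat(p[, 1]); m2 <- in_mat(p[, 2])
    self <- m1 & m2
    right <- m1 & !m2      # mature position pairs with a partner 3' of it
    left <- m2 & !m1       # partner 5' of the mature
    nl <- sum(left); nr <- sum(right)
  } else {
    self <- logical(0); left <- logical(0); right <- logical(0)
    nl <- 0L; nr <- 0L
  }
  meas$stem_pairs <- max(nl, nr)
  if (meas$stem_pairs < th$min_stem_pairs) return(fail("stem"))

  if (sum(self) > 0L || min(nl, nr) > 2L) return(fail("arm"))
  ## distance of the mature from the terminal loop of its stem
  if (nr >= nl) {
    m_in <- max(p[right, 1]); p_in <- p[right, 2][which.max(p[right, 1])]
    inner <- p[p[, 1] > m_in & p[, 2] < p_in, , drop = FALSE]
    i_h <- if (nrow(inner)) max(inner[, 1]) else m_in
    meas$loop_dist <- i_h - me
  } else {
    m_in <- min(p[left, 2]); p_in <- p[left, 1][which.min(p[left, 2])]
    inner <- p[p[, 1] > p_in & p[, 2] < m_in, , drop = FALSE]
    j_h <- if (nrow(inner)) min(inner[, 2]) else m_in
    meas$loop_dist <- ms - j_h
  }
  if (meas$loop_dist < th$min_loop_dist) return(fail("arm"))

  tot <- sum(support_counts)
  meas$dicer_frac <- if (tot > 0)
    max(tapply(support_counts, support_starts, sum)) / tot else 0
  if (meas$dicer_frac < th$dicer_frac) return(fail("dicer"))

  mlen <- me - ms + 1L
  if (mlen < th$mature_len[1] || mlen > th$mature_len[2])
    return(fail("mature_length"))

  c(list(accepted = TRUE, reason = NA_character_), meas)
}

#' Call novel miRNAs from unannotated tags
#'
#' For each sample, merges that sample's unannotated mapped tag loci,
#' excises 5'-arm and 3'-arm candidate windows, folds them and applies
#' [evaluate_hairpin()]; a locus is accepted when either window passes.
#' The shared list keeps loci accepted in every sample (same strand,
#' overlapping by at least one base).
#'
#' @param ann an `annotated_tags` object covering all samples.
#' @param genome a `toy_genome`.
#' @param samples character vector of sample names (default: all).
#' @param thresholds acceptance thresholds
#'   (see `default_hairpin_thresholds()`).
#' @param flank_up,flank_down excision flanks (default 150 nt).
#' @return object of class `novel_mirna_calls`: list with `per_sample`
#'   (named list of accepted-locus data.frames with hairpin metrics) and
#'   `shared` (loci accepted in every sample).
#' @export
call_novel_mirnas <- function(ann, genome, samples = NULL,
                              thresholds = default_hairpin_thresholds(),
                              flank_up = 150L, flank_down = 150L) {
  stopifnot(inherits(ann, "annotated_tags"))
  all_samples <- setdiff(names(ann),
                         c("sequence", "n_hits", "chrom", "start", "end",
                           "strand", "category", "assigned_mirna"))
  samples <- samples %||% all_samples
  hits <- attr(ann, "hits")
  per_sample <- list()
  for (s in samples) {
    cand <- extract_candidate_loci(ann, genome, flank_up, flank_down,
                                   sample = s,
                                   min_support = thresholds$min_support
                                   %||% 3L)
    acc <- list()
    for (lid in unique(cand$locus_id)) {
      wins <- cand[cand$locus_id == lid, ]
      res <- evaluate_locus(wins, ann, hits, genome, s, thresholds)
      if (!is.null(res)) acc[[length(acc) + 1L]] <- res
    }
    per_sample[[s]] <- if (length(acc)) do.call(rbind, acc)
      else empty_novel_df()
  }
  shared <- shared_loci(per_sample)
  structure(list(per_sample = per_sample, shared = shared,
                 thresholds = thresholds),
            class = "novel_mirna_calls")
}

empty_novel_df <- function() {
  data.frame(chrom = character(0), strand = character(0),
             pre_start = integer(0), pre_end = integer(0),
             mat_start = integer(0), mat_end = integer(0),
             arm = character(0), mfe = numeric(0),
             stem_pairs = integer(0), dicer_frac = numeric(0),
             support = integer(0), stringsAsFactors = FALSE)
}

## Evaluate one merged locus (both windows) for one sample; returns an
## accepted-locus row or NULL.
evaluate_locus <- function(wins, ann, hits, genome, sample, thresholds) {
  chroms <- genome$chromosomes
  L <- wins[1, ]
  ## supporting tags: unann tags of this sample hitting the locus
  sup_seq <- ann$sequence[ann$category == "unann" & ann[[sample]] > 0]
  h <- hits[hits$sequence %in% sup_seq & hits$chrom == L$chrom &
              hits$strand == L$strand & hits$start < L$locus_end &
              hits$end > L$locus_start, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  counts <- ann[[sample]][match(h$sequence, ann$sequence)]
  ## 5' start in transcript orientation
  starts5 <- if (L$strand == "+") h$start else h$end
  top <- which.max(counts)
  mat_g <- c(h$start[top], h$end[top])

  for (k in seq_len(nrow(wins))) {
    W <- wins[k, ]
    wseq <- substr(chroms[[W$chrom]], W$window_start + 1L, W$window_end)
    if (W$strand == "-") wseq <- revcomp(wseq)
    n <- nchar(wseq)
    if (n < 40L || n > 400L) next
    ## mature interval in window/transcript coordinates
    mat_t <- if (W$strand == "+")
      c(mat_g[1] - W$window_start, mat_g[2] - W$window_start)
    else c(W$window_end - mat_g[2], W$window_end - mat_g[1])
    if (mat_t[1] < 0 || mat_t[2] > n) next
    fold <- fold_rna(wseq)
    v <- evaluate_hairpin(fold, mat_t, starts5, counts, thresholds)
    if (isTRUE(v$accepted)) {
      return(data.frame(chrom = W$chrom, strand = W$strand,
                        pre_start = W$window_start, pre_end = W$window_end,
                        mat_start = mat_g[1], mat_end = mat_g[2],
                        arm = W$arm, mfe = v$mfe,
                        stem_pairs = v$stem_pairs,
                        dicer_frac = v$dicer_frac,
                        support = sum(counts), stringsAsFactors = FALSE))
    }
  }
  NULL
}

shared_loci <- function(per_sample) {
  if (length(per_sample) == 0L) return(empty_novel_df())
  base <- per_sample[[1]]
  if (length(per_sample) == 1L || nrow(base) == 0L) return(base)
  keep <- rep(TRUE, nrow(base))
  bgr <- GenomicRanges::GRanges(base$chrom,
                                IRanges::IRanges(base$pre_start + 1L,
                                                 base$pre_end),
                                strand = base$strand)
  for (other in per_sample[-1]) {
    if (nrow(other) == 0L) return(empty_novel_df())
    ogr <- GenomicRanges::GRanges(other$chrom,
                                  IRanges::IRanges(other$pre_start + 1L,
                                                   other$pre_end),
                                  strand = other$strand)
    ov <- GenomicRanges::countOverlaps(bgr, ogr, ignore.strand = FALSE)
    keep <- keep & ov > 0
  }
  base[keep, , drop = FALSE]
}

#' @export
print.novel_mirna_calls <- function(x, ...) {
  ns <- vapply(x$per_sample, nrow, 0L)
  cat("Novel miRNA calls:",
      paste(names(ns), ns, sep = "=", collapse = ", "),
      "; shared:", nrow(x$shared), "\n")
  invisible(x)
}

#' Write novel-miRNA call outputs
#'
#' Writes the candidate/accepted table as TSV and the accepted loci as a
#' BED6 track.
#'
#' @param calls a `novel_mirna_calls` object.
#' @param prefix output path prefix.
#' @export
write_novel_calls <- function(calls, prefix) {
  for (s in names(calls$per_sample))
    write.table(calls$per_sample[[s]],
                paste0(prefix, ".", s, ".tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  sh <- calls$shared
  write.table(sh, paste0(prefix, ".shared.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(sh)) {
    bed <- data.frame(sh$chrom, sh$pre_start, sh$pre_end,
                      paste0("novel-", seq_len(nrow(sh))), 0, sh$strand)
    write.table(bed, paste0(prefix, ".shared.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(prefix)
}
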