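## Quantification and comparison: TPM normalisation, Poisson random-bin
## noise filtering, 10-kb genomic cluster grouping, two-library
## differential expression and sample-level hierarchical clustering.

#' Normalise a count matrix to tags per million clean reads (TPM)
#'
#' `TPM = count / clean_total * 1e6`, exactly, per cell.
#'
#' @param counts numeric matrix, miRNAs x samples.
#' @param clean_totals named vector of per-sample clean read totals
#'   (names matching the count columns); all must be positive.
#' @param positions optional data.frame (`name`, `chrom`, `strand`,
#'   `first_nt`) locating each row's precursor first nucleotide, e.g. from
#'   [mirna_catalog()].
#' @return object of class `expression_matrix`: list with `counts`, `tpm`,
#'   `clean_totals`, `positions`.
#' @export
normalize_tpm <- function(counts, clean_totals, positions = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("count columns must be named")
  ct <- clean_totals[colnames(counts)]
  if (any(is.na(ct))) stop("clean_totals missing for some samples")
  if (any(ct <= 0)) stop("clean totals must be positive")
  tpm <- sweep(counts, 2, ct, "/") * 1e6
  if (!is.null(positions)) {
    positions <- positions[match(rownames(counts), positions$name), ,
                           drop = FALSE]
  }
  structure(list(counts = counts, tpm = tpm,
                 clean_totals = setNames(as.numeric(ct), colnames(counts)),
                 positions = positions),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$counts), "miRNAs x",
      ncol(x$counts), "samples\n")
  cat("  clean totals:",
      paste(names(x$clean_totals), x$clean_totals, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Smallest count exceeding a Poisson background at a tail probability
#'
#' Returns the smallest integer `c*` with `P(X >= c*) < p_crit` for
#' `X ~ Poisson(lambda)`.
#'
#' @param lambda background rate (mean reads per bin).
#' @param p_crit tail probability criterion (default 1e-4).
#' @return integer threshold count.
#' @export
poisson_count_threshold <- function(lambda, p_crit = 1e-4) {
  stopifnot(lambda >= 0, p_crit > 0, p_crit < 1)
  cc <- 1L
  while (ppois(cc - 1L, lambda, lower.tail = FALSE) >= p_crit)
    cc <- cc + 1L
  cc
}

#' Filter sporadically expressed miRNAs by a Poisson random-bin simulation
#'
#' Samples `n_bins_per_chrom` random `bin_len`-bp bins on every chromosome,
#' counts mapped reads starting in each bin, and takes the mean bin count
#' as the per-sample background rate lambda.  The count threshold `c*` is
#' the smallest count with upper-tail Poisson probability below `p_crit`;
#' its TPM equivalent is combined with the `tpm_floor` (the larger of the
#' two applies).  A miRNA is retained if it reaches the threshold in at
#' least one sample.
#'
#' @param em an [normalize_tpm()] `expression_matrix`.
#' @param genome a `toy_genome` or named character vector of sequences
#'   (for chromosome names and lengths).
#' @param read_positions data.frame of mapped read start positions with
#'   per-sample read counts: columns `chrom`, `start`, then one count
#'   column per sample.
#' @param n_bins_per_chrom random bins per chromosome (default 10,000; the
#'   procedure this emulates used 10,000 bins on each of 21 chromosomes).
#' @param bin_len bin width in bp (default 50).
#' @param p_crit Poisson tail criterion (default 1e-4).
#' @param tpm_floor minimum TPM treated as true expression (default 3).
#' @return list with `em` (filtered `expression_matrix`), `report`
#'   (per-sample lambda, `c_star`, TPM threshold) and `kept` (logical per
#'   input row).
#' @export
poisson_noise_filter <- function(em, genome, read_positions,
                                 n_bins_per_chrom = 10000L, bin_len = 50L,
                                 p_crit = 1e-4, tpm_floor = 3) {
  stopifnot(inherits(em, "expression_matrix"))
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes
            else genome
  clen <- nchar(chroms)
  if (any(clen < bin_len)) stop("chromosome shorter than bin_len")
  samples <- colnames(em$counts)
  report <- data.frame(sample = samples, lambda = NA_real_,
                       c_star = NA_integer_, tpm_threshold = NA_real_,
                       stringsAsFactors = FALSE)
  keep <- matrix(FALSE, nrow(em$tpm), length(samples),
                 dimnames = list(rownames(em$tpm), samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    total_bins <- 0L
    total_reads_in_bins <- 0
    for (ci in seq_along(chroms)) {
      ch <- names(chroms)[ci]
      starts <- floor(runif(n_bins_per_chrom) * (clen[ci] - bin_len + 1))
      rp <- read_positions[read_positions$chrom == ch, , drop = FALSE]
      if (nrow(rp)) {
        ## a read starting at r falls in every bin whose start lies in
        ## (r - bin_len, r]; summing those covers equals summing bin counts
        bs <- sort(starts)
        left <- findInterval(rp$start - bin_len + 1 - 1e-9, bs) + 1L
        right <- findInterval(rp$start, bs)
        n_cover <- pmax(right - left + 1L, 0L)
        total_reads_in_bins <- total_reads_in_bins +
          sum(rp[[s]] * n_cover)
      }
      total_bins <- total_bins + n_bins_per_chrom
    }
    lambda <- total_reads_in_bins / total_bins
    c_star <- poisson_count_threshold(lambda, p_crit)
    tpm_eq <- c_star / em$clean_totals[s] * 1e6
    thr <- max(tpm_floor, tpm_eq)
    report$lambda[si] <- lambda
    report$c_star[si] <- c_star
    report$tpm_threshold[si] <- thr
    keep[, si] <- em$tpm[, s] >= thr
  }
  kept <- rowSums(keep) > 0
  fem <- em
  fem$counts <- em$counts[kept, , drop = FALSE]
  fem$tpm <- em$tpm[kept, , drop = FALSE]
  if (!is.null(em$positions))
    fem$positions <- em$positions[kept, , drop = FALSE]
  list(em = fem, report = report, kept = kept)
}

#' Group miRNAs into genomic clusters by the 10-kb rule
#'
#' Single-linkage chaining along each chromosome: rows sorted by
#' precursor first-nucleotide position are joined while consecutive
#' first nucleotides are at most `max_gap` bases apart (inclusive), and
#' maximal chains are emitted.  Rows without positions become flagged
#' singletons.
#'
#' @param em an `expression_matrix` with `positions`, or a data.frame with
#'   `name`, `chrom`, `first_nt`.
#' @param max_gap maximum first-nucleotide distance joining consecutive
#'   miRNAs (default 10,000, i.e. "within 10 kb" read inclusively).
#' @return data.frame, one row per cluster: `cluster`, `chrom`, `members`
#'   (comma-joined, position-ordered), `n`, `span_start`, `span_end`,
#'   per-sample summed TPM (when expression is available), ranked by
#'   total summed TPM.
#' @export
group_clusters <- function(em, max_gap = 10000L) {
  if (inherits(em, "expression_matrix")) {
    pos <- em$positions
    if (is.null(pos)) stop("expression matrix has no positions")
    tpm <- em$tpm
  } else {
    pos <- em
    tpm <- NULL
  }
  known <- !is.na(pos$first_nt) & !is.na(pos$chrom)
  out <- list()
  cl_id <- 0L
  for (ch in unique(pos$chrom[known])) {
    sub <- pos[known & pos$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$first_nt, sub$name), , drop = FALSE]
    gap_new <- c(TRUE, diff(sub$first_nt) > max_gap)
    grp <- cumsum(gap_new)
    for (g in unique(grp)) {
      m <- sub[grp == g, , drop = FALSE]
      cl_id <- cl_id + 1L
      out[[cl_id]] <- data.frame(
        cluster = cl_id, chrom = ch,
        members = paste(m$name, collapse = ","), n = nrow(m),
        span_start = min(m$first_nt), span_end = max(m$first_nt),
        positioned = TRUE, stringsAsFactors = FALSE)
    }
  }
  for (nm in pos$name[!known]) {
    cl_id <- cl_id + 1L
    out[[cl_id]] <- data.frame(cluster = cl_id, chrom = NA_character_,
                               members = nm, n = 1L,
                               span_start = NA_integer_,
                               span_end = NA_integer_,
                               positioned = FALSE, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (!is.null(tpm)) {
    for (s in colnames(tpm)) {
      res[[paste0("tpm_", s)]] <- vapply(strsplit(res$members, ","),
        function(mm) sum(tpm[rownames(tpm) %in% mm, s]), 0)
    }
    tot <- rowSums(res[, paste0("tpm_", colnames(tpm)), drop = FALSE])
    res <- res[order(-tot), , drop = FALSE]
    res$rank <- seq_len(nrow(res))
  }
  rownames(res) <- NULL
  res
}

#' Exact conditional test for two sequencing libraries
#'
#' Compares one miRNA's counts in two libraries of (possibly different)
#' clean totals: conditional on the summed count, the count in library A
#' is binomial with probability `nA / (nA + nB)` under the null of equal
#' relative expression.  This is the exact two-library Poisson comparison
#' to which the classic two-library (Audic-Claverie-type) test is
#' asymptotically equivalent, and it is exactly antisymmetric in the two
#' libraries.
#'
#' @param xa,xb counts in libraries A and B.
#' @param na,nb clean totals of libraries A and B.
#' @return two-sided p-value.
#' @export
two_library_test <- function(xa, xb, na, nb) {
  stopifnot(length(xa) == length(xb))
  p <- na / (na + nb)
  vapply(seq_along(xa), function(i) {
    if (xa[i] + xb[i] == 0) return(1)
    binom.test(xa[i], xa[i] + xb[i], p)$p.value
  }, 0)
}

#' Differential expression between two libraries
#'
#' Rows are pre-filtered to TPM above `min_tpm` in at least one of the two
#' samples; `log2_ratio = log2((TPM_A + pc) / (TPM_B + pc))`; p-values
#' from [two_library_test()]; a miRNA is flagged up/down when the fold
#' change exceeds `fc_threshold` (i.e. |log2 ratio| > log2(fc)) and
#' `p < alpha`.
#'
#' @param em an `expression_matrix`.
#' @param sample_a,sample_b the two samples to compare.
#' @param min_tpm expression floor for inclusion (default 3 TPM).
#' @param fc_threshold fold-change threshold (default 2).
#' @param alpha significance threshold (default 0.05).
#' @param pseudocount pseudocount in TPM units for the log ratio
#'   (default 0.5, applied when either TPM is zero).
#' @return object of class `de_result`: data.frame with counts, TPMs,
#'   `log2_ratio`, `raw_ratio`, `p_value` and `flag` (up/down/ns).
#' @export
differential_expression <- function(em, sample_a, sample_b, min_tpm = 3,
                                    fc_threshold = 2, alpha = 0.05,
                                    pseudocount = 0.5) {
  stopifnot(inherits(em, "expression_matrix"))
  for (s in c(sample_a, sample_b))
    if (!s %in% colnames(em$tpm)) stop("unknown sample '", s, "'")
  ta <- em$tpm[, sample_a]; tb <- em$tpm[, sample_b]
  keep <- ta > min_tpm | tb > min_tpm
  ta <- ta[keep]; tb <- tb[keep]
  ca <- em$counts[keep, sample_a]; cb <- em$counts[keep, sample_b]
  pc <- ifelse(ta == 0 | tb == 0, pseudocount, 0)
  lr <- log2((ta + pc) / (tb + pc))
  pv <- two_library_test(ca, cb, em$clean_totals[sample_a],
                         em$clean_totals[sample_b])
  lfc <- log2(fc_threshold)
  flag <- ifelse(pv < alpha & lr > lfc, "up",
                 ifelse(pv < alpha & lr < -lfc, "down", "ns"))
  structure(data.frame(mirna = rownames(em$tpm)[keep],
                       count_a = ca, count_b = cb,
                       tpm_a = ta, tpm_b = tb,
                       log2_ratio = lr,
                       raw_ratio = ifelse(tb > 0, ta / tb, Inf),
                       p_value = pv, flag = flag,
                       stringsAsFactors = FALSE, row.names = NULL),
            samples = c(sample_a, sample_b),
            class = c("de_result", "data.frame"))
}

#' Average-linkage hierarchical clustering of sample expression profiles
#'
#' Distance between samples is `1 - Pearson correlation` of their
#' `log2(TPM + 1)` profiles; linkage is average ("UPGMA").  Tie handling
#' follows sample order (the order of the matrix columns).
#'
#' @param em an `expression_matrix`.
#' @param samples samples to include (default all; at least 2).
#' @return an [stats::hclust] object.
#' @export
hierarchical_clustering <- function(em, samples = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  samples <- samples %||% colnames(em$tpm)
  if (length(samples) < 2L) stop("need at least 2 samples")
  m <- log2(em$tpm[, samples, drop = FALSE] + 1)
  d <- as.dist(1 - cor(m))
  hclust(d, method = "average")
}
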