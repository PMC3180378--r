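## X-chromosome-inactivation inference from chromosome-wide miRNA dosage:
## per-miRNA log2 ratios against a male-median baseline, position-ordered
## moving averages, and a rank-test caller with chromosome 1 as control.

#' Collect a chromosome's miRNAs from an expression matrix
#'
#' Rows located on `chrom`, sorted by precursor first-nucleotide position;
#' rows with zero counts in every sample are excluded.
#'
#' @param em an `expression_matrix` with positions.
#' @param chrom chromosome name.
#' @return the row names, position-ordered; positions in
#'   `attr(, "first_nt")`.
#' @export
collect_chromosome_mirnas <- function(em, chrom) {
  stopifnot(inherits(em, "expression_matrix"))
  pos <- em$positions
  if (is.null(pos)) stop("expression matrix has no positions")
  if (!chrom %in% pos$chrom) stop("unknown chromosome '", chrom, "'")
  sel <- pos$chrom == chrom & rowSums(em$counts) > 0
  sub <- pos[sel, , drop = FALSE]
  o <- order(sub$first_nt, sub$name)
  structure(sub$name[o], first_nt = sub$first_nt[o])
}

#' Male-baseline expression for one chromosome
#'
#' The per-miRNA median TPM over the male samples; miRNAs whose baseline
#' is zero are excluded (flagged in `attr(, "excluded")`) because no
#' meaningful ratio exists for them.
#'
#' @param em an `expression_matrix`.
#' @param male_samples character vector of male sample names (>= 1).
#' @param chrom chromosome name.
#' @return named numeric vector of baselines (only miRNAs with positive
#'   baseline).
#' @export
male_baseline <- function(em, male_samples, chrom) {
  stopifnot(inherits(em, "expression_matrix"))
  if (length(male_samples) < 1L) stop("need at least one male sample")
  if (!all(male_samples %in% colnames(em$tpm)))
    stop("unknown male sample(s)")
  mir <- collect_chromosome_mirnas(em, chrom)
  b <- apply(em$tpm[mir, male_samples, drop = FALSE], 1, median)
  excluded <- names(b)[b == 0]
  b <- b[b > 0]
  structure(b, excluded = excluded)
}

#' Centered moving average with fixed-width windows
#'
#' Interior positions get the usual centered window; near the series ends
#' the window is anchored inside the series so it keeps its width (when
#' the window equals the series length every position therefore averages
#' the whole series).  Windows larger than the series are shrunk with a
#' warning.
#'
#' @param x numeric series.
#' @param window odd window size >= 1.
#' @return numeric vector of the same length.
#' @export
moving_average <- function(x, window = 5L) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > n) {
    window <- if (n %% 2L == 1L) n else max(n - 1L, 1L)
    warning("window larger than series; shrinking to ", window)
  }
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    a <- min(max(i - h, 1L), n - window + 1L)
    mean(x[a:(a + window - 1L)])
  }, 0)
}

#' Chromosome-wise relative expression profile of one sample
#'
#' Per-miRNA `log2((TPM + pc) / (baseline + pc))` in position order, with
#' a centered moving average (window truncated at the chromosome ends).
#'
#' @param em an `expression_matrix`.
#' @param sample sample name.
#' @param baseline a [male_baseline()] vector for the same chromosome.
#' @param chrom chromosome name.
#' @param window odd moving-average window in miRNAs (default 5).
#' @param pseudocount TPM pseudocount shared with the expression module
#'   (default 0.5, applied when either term is zero).
#' @return object of class `chromosome_profile`: data.frame with `mirna`,
#'   `first_nt`, `tpm`, `baseline`, `log2_ratio`, `moving_average`;
#'   attributes `sample` and `chrom`.
#' @export
relative_profile <- function(em, sample, baseline, chrom, window = 5L,
                             pseudocount = 0.5) {
  stopifnot(inherits(em, "expression_matrix"))
  mir <- collect_chromosome_mirnas(em, chrom)
  keep <- mir %in% names(baseline)
  mir <- mir[keep]
  fnt <- attr(mir, "first_nt") %||%
    em$positions$first_nt[match(mir, em$positions$name)]
  tpm <- em$tpm[mir, sample]
  b <- baseline[mir]
  pc <- ifelse(tpm == 0 | b == 0, pseudocount, 0)
  lr <- log2((tpm + pc) / (b + pc))
  ma <- moving_average(lr, window)
  structure(data.frame(mirna = mir, first_nt = fnt, tpm = tpm,
                       baseline = b, log2_ratio = lr,
                       moving_average = ma, row.names = NULL,
                       stringsAsFactors = FALSE),
            sample = sample, chrom = chrom,
            class = c("chromosome_profile", "data.frame"))
}

#' @export
plot.chromosome_profile <- function(x, ...) {
  graphics::plot(x$first_nt, x$log2_ratio, pch = 16, col = "grey50",
                 xlab = paste0(attr(x, "chrom"), " position (bp)"),
                 ylab = "log2 ratio vs male baseline",
                 main = attr(x, "sample"), ...)
  graphics::lines(x$first_nt, x$moving_average, col = "firebrick",
                  lwd = 2)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Call X-inactivation status from chromosome-wide miRNA dosage
#'
#' For each test (female) sample, the X-chromosome log2 ratios are
#' compared with the pooled reference samples' X log2 ratios by a
#' two-sided rank test (Mann-Whitney); the identical comparison on
#' chromosome 1 serves as a library-artifact control.  A chromosome is
#' considered dosage-elevated only when the rank test is significant
#' *and* the shift is biologically meaningful (elevation above
#' `elevation_min`), which keeps tiny-but-significant rank shifts from
#' driving calls.  Calls: `two_active_X` when X is elevated and the chr1
#' control is clean; `one_active_X` when X is not elevated and the
#' control is clean; otherwise `indeterminate` (including any sample
#' whose chr1 control itself shifts, the signature of a global scaling
#' artifact, and chromosomes with fewer than 3 informative miRNAs).
#'
#' @param em an `expression_matrix` with positions.
#' @param test_samples female samples to call.
#' @param reference_samples samples defining the reference dosage: the
#'   male samples plus any known one-active-X females.
#' @param male_samples samples used for the median baseline (default: the
#'   reference samples).
#' @param chrom test chromosome (default "chrX").
#' @param control_chrom control chromosome (default "chr1").
#' @param alpha rank-test significance threshold (default 0.05).
#' @param elevation_min minimum X elevation (log2 units, default 0.5,
#'   about 1.4-fold) for a two-active-X call.
#' @param window moving-average window (default 5).
#' @return object of class `xci_report`: data.frame with one row per test
#'   sample (`elevation`, `p_value`, `control_p_value`, `control_shift`,
#'   `call`, `reason`); profiles in `attr(, "profiles")`.
#' @export
call_xci <- function(em, test_samples, reference_samples,
                     male_samples = NULL, chrom = "chrX",
                     control_chrom = "chr1", alpha = 0.05,
                     elevation_min = 0.5, window = 5L) {
  stopifnot(inherits(em, "expression_matrix"))
  if (length(reference_samples) < 1L) stop("need reference samples")
  male_samples <- male_samples %||% reference_samples
  bx <- male_baseline(em, male_samples, chrom)
  b1 <- male_baseline(em, male_samples, control_chrom)
  prof <- function(s, ch, b) relative_profile(em, s, b, ch, window)
  ref_x <- unlist(lapply(reference_samples,
                         function(s) prof(s, chrom, bx)$log2_ratio))
  ref_1 <- unlist(lapply(reference_samples,
                         function(s) prof(s, control_chrom,
                                          b1)$log2_ratio))
  profiles <- list()
  rows <- list()
  for (s in test_samples) {
    px <- prof(s, chrom, bx)
    p1 <- prof(s, control_chrom, b1)
    profiles[[s]] <- list(x = px, control = p1)
    if (nrow(px) < 3L) {
      rows[[s]] <- data.frame(sample = s, elevation = NA_real_,
                              p_value = NA_real_,
                              control_p_value = NA_real_,
                              control_shift = NA_real_,
                              call = "indeterminate",
                              reason = "fewer than 3 X-linked miRNAs",
                              stringsAsFactors = FALSE)
      next
    }
    elevation <- median(px$log2_ratio) - median(p1$log2_ratio)
    pv <- suppressWarnings(
      wilcox.test(px$log2_ratio, ref_x, exact = FALSE)$p.value)
    ctrl_shift <- median(p1$log2_ratio) - median(ref_1)
    pv1 <- suppressWarnings(
      wilcox.test(p1$log2_ratio, ref_1, exact = FALSE)$p.value)
    ctrl_bad <- is.finite(pv1) && pv1 < alpha &&
      abs(ctrl_shift) > elevation_min
    x_elev <- is.finite(pv) && pv < alpha && elevation > elevation_min
    call <- if (ctrl_bad) "indeterminate"
            else if (x_elev) "two_active_X"
            else "one_active_X"
    reason <- if (ctrl_bad) "chr1 control shifted (library artifact?)"
              else NA_character_
    rows[[s]] <- data.frame(sample = s, elevation = elevation,
                            p_value = pv, control_p_value = pv1,
                            control_shift = ctrl_shift, call = call,
                            reason = reason, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            profiles = profiles, chrom = chrom,
            control_chrom = control_chrom,
            class = c("xci_report", "data.frame"))
}

#' @export
print.xci_report <- function(x, ...) {
  cat("XCI report (", attr(x, "chrom"), " vs ", attr(x, "control_chrom"),
      " control)\n", sep = "")
  df <- as.data.frame(x)
  df$elevation <- round(df$elevation, 3)
  df$p_value <- signif(df$p_value, 3)
  df$control_p_value <- signif(df$control_p_value, 3)
  df$control_shift <- round(df$control_shift, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
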