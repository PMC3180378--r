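## Read cleaning: 3' adaptor trimming, contaminant / length / quality
## filters, and collapsing clean reads into unique sequence tags.

#' Trim the 3' adaptor from raw reads
#'
#' Scans each read left to right for the first position where a prefix of
#' the adaptor (at least `min_overlap` bases long, allowing one mismatch
#' per 10 aligned bases by default) matches the remainder of the read.
#' Everything 5' of that position is the insert.  Reads without a
#' detectable adaptor, or containing an N, are flagged contaminant; the
#' function flags and never fails on biological input.
#'
#' @param reads character vector of raw reads.
#' @param quals optional character vector of Phred+33 quality strings,
#'   trimmed alongside the reads.
#' @param adaptor 3' adaptor sequence.
#' @param min_overlap minimum visible adaptor prefix (default 6).
#' @param mismatch_per10 allowed mismatches per 10 aligned adaptor bases
#'   (default 1; 0 forces exact matching).
#' @return data.frame with `insert`, `quality` (NA-free only when `quals`
#'   given) and logical `contaminant`.
#' @export
trim_adaptor <- function(reads, quals = NULL, adaptor,
                         min_overlap = 6L, mismatch_per10 = 1L) {
  stopifnot(nchar(adaptor) >= 1, min_overlap >= 1)
  if (length(reads) == 0L)
    return(data.frame(insert = character(0), quality = character(0),
                      contaminant = logical(0)))
  pos <- .adaptor_positions(toupper(reads), toupper(adaptor),
                            as.integer(min_overlap),
                            as.integer(mismatch_per10))
  has_n <- grepl("N", reads, fixed = TRUE)
  contaminant <- pos == 0L | has_n
  insert <- ifelse(contaminant, NA_character_,
                   substr(reads, 1L, pmax(pos - 1L, 0L)))
  quality <- if (is.null(quals)) NA_character_
             else ifelse(contaminant, NA_character_,
                         substr(quals, 1L, pmax(pos - 1L, 0L)))
  data.frame(insert = insert, quality = quality,
             contaminant = contaminant, stringsAsFactors = FALSE)
}

#' Clean a raw small RNA library
#'
#' Applies [trim_adaptor()], then removes inserts shorter than `min_len`,
#' longer than `max_len`, or with mean Phred quality below `min_qual`.
#' Bookkeeping is exact: `clean_total = raw_total - removed_contaminant -
#' removed_too_small - removed_too_long - removed_low_quality`.
#'
#' @param x path to a FASTQ file (Phred+33) or a `sim_library`.
#' @param adaptor 3' adaptor sequence.
#' @param min_len,max_len retained insert-length window (default 18-30 nt).
#' @param min_qual minimum mean Phred quality (default 20).
#' @param sample sample name; defaults to the file name or library sample.
#' @param min_overlap,mismatch_per10 passed to [trim_adaptor()].
#' @return an object of class `clean_read_set`: list with `sample`,
#'   `reads` (character vector of clean inserts) and `counters`.
#' @export
make_clean_reads <- function(x, adaptor, min_len = 18L, max_len = 30L,
                             min_qual = 20, sample = NULL,
                             min_overlap = 6L, mismatch_per10 = 1L) {
  if (inherits(x, "sim_library")) {
    if (is.null(x$reads))
      stop("library was simulated with make_reads = FALSE")
    reads <- x$reads; quals <- x$quals
    sample <- sample %||% x$sample
  } else {
    fq <- read_fastq(x)
    reads <- fq$reads; quals <- fq$quals
    sample <- sample %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(x))
  }
  n <- length(reads)
  if (n == 0L) {
    counters <- list(raw_total = 0L, adaptor_trimmed = 0L,
                     removed_contaminant = 0L, removed_too_small = 0L,
                     removed_too_long = 0L, removed_low_quality = 0L,
                     clean_total = 0L)
    return(structure(list(sample = sample, reads = character(0),
                          counters = counters), class = "clean_read_set"))
  }
  tr <- trim_adaptor(reads, quals, adaptor, min_overlap, mismatch_per10)
  ilen <- ifelse(tr$contaminant, NA_integer_, nchar(tr$insert))
  meanq <- rep(NA_real_, n)
  ok_len <- !tr$contaminant & ilen >= min_len & ilen <= max_len
  if (any(ok_len))
    meanq[ok_len] <- vapply(tr$quality[ok_len],
                            function(q) mean(utf8ToInt(q)) - 33, 0,
                            USE.NAMES = FALSE)
  status <- ifelse(tr$contaminant, "contaminant",
            ifelse(ilen < min_len, "too_small",
            ifelse(ilen > max_len, "too_long",
            ifelse(meanq < min_qual, "low_quality", "clean"))))
  counters <- list(
    raw_total = n,
    adaptor_trimmed = sum(!tr$contaminant),
    removed_contaminant = sum(status == "contaminant"),
    removed_too_small = sum(status == "too_small"),
    removed_too_long = sum(status == "too_long"),
    removed_low_quality = sum(status == "low_quality"),
    clean_total = sum(status == "clean"))
  structure(list(sample = sample,
                 reads = tr$insert[status == "clean"],
                 counters = counters),
            class = "clean_read_set")
}

#' @export
print.clean_read_set <- function(x, ...) {
  cat("Clean read set '", x$sample, "'\n", sep = "")
  c <- x$counters
  cat(sprintf("  raw %d -> clean %d (contaminant %d, <min %d, >max %d, low-qual %d)\n",
              c$raw_total, c$clean_total, c$removed_contaminant,
              c$removed_too_small, c$removed_too_long,
              c$removed_low_quality))
  invisible(x)
}

#' Collapse clean reads into unique sequence tags
#'
#' An exact multiset collapse: each unique sequence becomes one tag, with
#' one read-count column per sample.  Per-sample counts sum to that
#' sample's `clean_total`.
#'
#' @param ... `clean_read_set` objects (or a single list of them).
#' @return an object of class `tag_set`: data.frame with `sequence` and
#'   one integer column per sample; `attr(, "clean_totals")` carries the
#'   per-sample clean totals.
#' @export
collapse_tags <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "clean_read_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, TRUE, "clean_read_set")))
  samples <- vapply(sets, function(x) x$sample, "")
  if (anyDuplicated(samples)) stop("duplicate sample names")
  seqs <- sort(unique(unlist(lapply(sets, function(x) x$reads))))
  df <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (s in sets) {
    cnt <- integer(length(seqs))
    if (length(s$reads)) {
      tab <- table(factor(s$reads, levels = seqs))
      cnt <- as.integer(tab)
    }
    df[[s$sample]] <- cnt
  }
  totals <- setNames(vapply(sets, function(x) x$counters$clean_total, 0),
                     samples)
  structure(df, clean_totals = totals,
            class = c("tag_set", "data.frame"))
}

tag_samples <- function(tags) setdiff(names(tags), "sequence")

#' Read-length histogram of a sample's clean reads
#'
#' Tag lengths weighted by the sample's tag counts; the values sum to the
#' sample's clean total.
#'
#' @param tags a `tag_set`.
#' @param sample sample name.
#' @return named integer vector, names are read lengths.
#' @export
length_histogram <- function(tags, sample) {
  stopifnot(inherits(tags, "tag_set"))
  if (!sample %in% tag_samples(tags))
    stop("unknown sample '", sample, "'")
  cnt <- tags[[sample]]
  keep <- cnt > 0
  if (!any(keep)) return(setNames(integer(0), character(0)))
  lens <- nchar(tags$sequence[keep])
  tab <- tapply(cnt[keep], lens, sum)
  setNames(as.integer(tab), names(tab))
}
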