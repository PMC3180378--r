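## Readers and writers for the standard formats at the package boundary.
## Internal coordinates are 0-based half-open; GFF3 is 1-based closed and
## BED 0-based half-open, with conversion handled by rtracklayer/GRanges.

#' Write / read a toy genome as FASTA
#'
#' @param genome a `toy_genome` (or any named character vector of
#'   chromosome sequences for writing).
#' @param path file path.
#' @return `read_genome_fasta` returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "toy_genome")) genome$chromosomes else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write annotation features as GFF3 or BED6
#'
#' @param features data.frame with chrom/start/end/strand/category/name
#'   (0-based half-open), e.g. `toy_genome$features`.
#' @param path output path.
#' @export
write_features_gff3 <- function(features, path) {
  gr <- features_to_granges(features)
  S4Vectors::mcols(gr)$type <- features$category
  S4Vectors::mcols(gr)$ID <- features$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_features_gff3
#' @export
write_features_bed <- function(features, path) {
  gr <- features_to_granges(features)
  S4Vectors::mcols(gr) <- NULL
  ## BED has no type column; carry the category inside the name field
  names(gr) <- paste0(features$category, "|", features$name)
  S4Vectors::mcols(gr)$score <- 0
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read annotation features from GFF3 or BED
#'
#' Categories are taken from the GFF3 `type` column or, for BED, parsed
#' from the `<category>|<name>` convention used by [write_features_bed()].
#'
#' @param path input path.
#' @return features data.frame in internal 0-based half-open coordinates.
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  nm <- if (!is.null(md$ID)) as.character(md$ID)
        else if (!is.null(md$name)) as.character(md$name)
        else paste0("feature-", seq_along(gr))
  cat <- if (!is.null(md$type)) as.character(md$type)
         else sub("\\|.*$", "", nm)
  nm <- sub("^[^|]*\\|", "", nm)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             category = cat, name = nm, stringsAsFactors = FALSE)
}

#' Write a simulated library as FASTQ (Phred+33)
#'
#' @param lib a `sim_library`.
#' @param path output path.
#' @export
write_fastq <- function(lib, path) {
  stopifnot(inherits(lib, "sim_library"))
  if (is.null(lib$reads))
    stop("library was simulated with make_reads = FALSE")
  x <- Biostrings::DNAStringSet(lib$reads)
  names(x) <- sprintf("%s_read_%d", lib$sample, seq_along(x))
  q <- Biostrings::PhredQuality(lib$quals)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

## Internal FASTQ reader; returns reads + quality strings.
read_fastq <- function(path) {
  if (file.size(path) %in% c(0L, NA_integer_))
    return(list(reads = character(0), quals = character(0)))
  n_lines <- length(readLines(path, warn = FALSE, skipNul = TRUE))
  if (n_lines %% 4L != 0L)
    stop("malformed FASTQ in '", path, "': truncated record ",
         n_lines %/% 4L + 1L, call. = FALSE)
  res <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e)
      stop("malformed FASTQ in '", path, "': ", conditionMessage(e),
           call. = FALSE))
  list(reads = as.character(res),
       quals = as.character(S4Vectors::mcols(res)$qualities))
}

#' Write / read a sequence-tag table as TSV
#'
#' One row per unique tag sequence, one count column per sample; the
#' per-sample clean totals travel in a `# clean_total:` header line.
#'
#' @param tags a `tag_set` from [collapse_tags()].
#' @param path file path.
#' @return `read_tag_table` returns a `tag_set`.
#' @export
write_tag_table <- function(tags, path) {
  stopifnot(inherits(tags, "tag_set"))
  con <- file(path, "w")
  on.exit(close(con))
  ct <- attr(tags, "clean_totals")
  writeLines(paste0("# clean_total: ",
                    paste(names(ct), ct, sep = "=", collapse = "\t")), con)
  write.table(tags, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_table
#' @export
read_tag_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  ct_str <- sub("^# clean_total: ", "", hdr)
  parts <- strsplit(strsplit(ct_str, "\t")[[1]], "=")
  ct <- setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                 vapply(parts, `[`, "", 1L))
  structure(df, clean_totals = ct, class = c("tag_set", "data.frame"))
}

#' Write preprocessing counters as JSON
#'
#' @param clean a `clean_read_set` (or list of them).
#' @param path file path.
#' @export
write_counters_json <- function(clean, path) {
  if (inherits(clean, "clean_read_set")) clean <- list(clean)
  out <- lapply(clean, function(x)
    c(list(sample = x$sample), x$counters))
  names(out) <- vapply(clean, function(x) x$sample, "")
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
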