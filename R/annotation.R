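## Exact genomic mapping of sequence tags and priority-ruled annotation.
## Every tag resolves to exactly one category under the total order
## rRNA_genbank > rRNA_rfam > known_miRNA > repeat > exon > intron; mapped
## but feature-free tags (and unmapped tags) are 'unann'.

#' Map sequence tags to a genome by exact matching
#'
#' Reports every exact occurrence of each tag on both strands (a minus
#' strand hit means the reverse complement of the genome matches the tag).
#' Tags containing characters other than ACGT are skipped with a warning.
#'
#' @param tags a `tag_set` or character vector of tag sequences.
#' @param genome a `toy_genome` or named character vector of chromosome
#'   sequences.
#' @return data.frame of hits: `sequence`, `chrom`, `start` (0-based),
#'   `end` (half-open), `strand`.  Attribute `n_skipped` counts non-ACGT
#'   tags.
#' @export
map_tags <- function(tags, genome) {
  seqs <- if (inherits(tags, "tag_set")) tags$sequence
          else as.character(tags)
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes
            else genome
  valid <- grepl("^[ACGT]+$", seqs)
  if (any(!valid))
    warning(sum(!valid), " tag(s) skipped: non-ACGT characters")
  vseq <- unique(seqs[valid])
  out <- list()
  subjects <- lapply(chroms, Biostrings::DNAString)
  for (strand in c("+", "-")) {
    query <- if (strand == "+") vseq else revcomp(vseq)
    for (w in unique(nchar(query))) {
      sel <- which(nchar(query) == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(query[sel]))
      for (ch in names(chroms)) {
        m <- Biostrings::matchPDict(pd, subjects[[ch]])
        starts <- Biostrings::startIndex(m)
        nh <- lengths(starts)
        if (sum(nh) == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          sequence = rep(vseq[sel], nh),
          chrom = ch,
          start = unlist(starts[nh > 0]) - 1L,
          end = unlist(starts[nh > 0]) - 1L + w,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(out)) do.call(rbind, out)
          else data.frame(sequence = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  attr(hits, "n_skipped") <- sum(!valid)
  hits
}

#' Resolve the annotation category of one tag from its genomic hits
#'
#' Collects the categories of every feature overlapping any hit (at least
#' one shared base, strand-blind) and returns the highest-priority one;
#' a tag with no overlapping feature is `unann`.
#'
#' @param hits data.frame with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open) — the hits of a single tag.
#' @param features features data.frame (chrom/start/end/strand/category).
#' @return a single category string.
#' @export
resolve_category <- function(hits, features) {
  if (nrow(hits) == 0L) return("unann")
  cats <- character(0)
  for (i in seq_len(nrow(hits))) {
    ov <- features$chrom == hits$chrom[i] &
      features$start < hits$end[i] & hits$start[i] < features$end
    cats <- c(cats, features$category[ov])
  }
  if (length(cats) == 0L) return("unann")
  CATEGORY_LEVELS[min(category_rank(cats))]
}

#' Annotate a tag set against a genome
#'
#' Maps every tag exactly ([map_tags()]), resolves one category per tag by
#' the priority rule, and assigns known-miRNA tags to a catalog entry:
#' a same-strand hit overlapping a precursor interval, preferring hits
#' within 3 nt of the annotated mature arm, then the entry whose mature
#' start is closest to the tag start (ties broken by name).
#'
#' @param tags a `tag_set`.
#' @param genome a `toy_genome` (or named character vector of sequences,
#'   in which case `features` and `catalog` must be supplied).
#' @param features features data.frame; defaults to `genome$features`.
#' @param catalog known-miRNA catalog; defaults to [mirna_catalog()].
#' @param mature_slack tolerated 5'/3' offset beyond the mature arm for
#'   catalog assignment (default 3 nt).
#' @return an `annotated_tags` data.frame: the tag columns plus `n_hits`,
#'   `chrom`, `start`, `end`, `strand` (first hit), `category` and
#'   `assigned_mirna`; the full hit table travels in `attr(, "hits")`.
#' @export
annotate_tags <- function(tags, genome, features = NULL, catalog = NULL,
                          mature_slack = 3L) {
  stopifnot(inherits(tags, "tag_set"))
  if (inherits(genome, "toy_genome")) {
    features <- features %||% genome$features
    catalog <- catalog %||% mirna_catalog(genome)
  }
  if (is.null(features)) stop("features required")
  hits <- map_tags(tags, genome)
  n <- nrow(tags)
  category <- rep("unann", n)
  assigned <- rep(NA_character_, n)
  n_hits <- integer(n)
  first <- data.frame(chrom = rep(NA_character_, n), start = NA_integer_,
                      end = NA_integer_, strand = NA_character_,
                      stringsAsFactors = FALSE)
  if (nrow(hits) > 0) {
    tag_idx <- match(hits$sequence, tags$sequence)
    n_hits <- tabulate(tag_idx, nbins = n)
    fo <- order(tag_idx, hits$chrom, hits$start)
    fidx <- fo[!duplicated(tag_idx[fo])]
    first[tag_idx[fidx], ] <- hits[fidx, c("chrom", "start", "end",
                                           "strand")]

    hgr <- GenomicRanges::GRanges(hits$chrom,
                                  IRanges::IRanges(hits$start + 1L,
                                                   hits$end),
                                  strand = hits$strand)
    fgr <- features_to_granges(features)
    ov <- GenomicRanges::findOverlaps(hgr, fgr, ignore.strand = TRUE)
    if (length(ov)) {
      ti <- tag_idx[S4Vectors::queryHits(ov)]
      rk <- category_rank(features$category[S4Vectors::subjectHits(ov)])
      best <- tapply(rk, ti, min)
      category[as.integer(names(best))] <- CATEGORY_LEVELS[best]
    }

    if (!is.null(catalog) && nrow(catalog) > 0) {
      km <- which(category == "known_miRNA")
      if (length(km)) {
        cgr <- GenomicRanges::GRanges(catalog$chrom,
                                      IRanges::IRanges(catalog$pre_start + 1L,
                                                       catalog$pre_end),
                                      strand = catalog$strand)
        keep <- tag_idx %in% km
        sub <- hits[keep, ]
        sub_ti <- tag_idx[keep]
        sgr <- GenomicRanges::GRanges(sub$chrom,
                                      IRanges::IRanges(sub$start + 1L,
                                                       sub$end),
                                      strand = sub$strand)
        mov <- GenomicRanges::findOverlaps(sgr, cgr, ignore.strand = FALSE)
        if (length(mov)) {
          qi <- S4Vectors::queryHits(mov); si <- S4Vectors::subjectHits(mov)
          within_mature <- sub$start[qi] >= catalog$mat_start[si] -
            mature_slack & sub$end[qi] <= catalog$mat_end[si] + mature_slack
          cand <- data.frame(tag = sub_ti[qi], mir = catalog$name[si],
                             pref = !within_mature,
                             dist = abs(sub$start[qi] -
                                          catalog$mat_start[si]),
                             stringsAsFactors = FALSE)
          cand <- cand[order(cand$tag, cand$pref, cand$dist, cand$mir), ]
          cand <- cand[!duplicated(cand$tag), ]
          assigned[cand$tag] <- cand$mir
        }
      }
    }
  }
  out <- cbind(tags, n_hits = n_hits, first,
               category = category, assigned_mirna = assigned)
  ## a known_miRNA tag always carries an assignment: fall back to the
  ## nearest same-chromosome catalog entry if strand-specific overlap
  ## found none (possible for star-arm fragments seen antisense)
  miss <- if (is.null(catalog)) integer(0)
          else which(out$category == "known_miRNA" &
                       is.na(out$assigned_mirna))
  for (i in miss) {
    samec <- catalog[catalog$chrom == out$chrom[i], ]
    if (nrow(samec)) {
      d <- abs(samec$mat_start - out$start[i])
      pick <- samec$name[order(d, samec$name)][1]
      out$assigned_mirna[i] <- pick
    }
  }
  structure(out, clean_totals = attr(tags, "clean_totals"), hits = hits,
            class = c("annotated_tags", "data.frame"))
}

#' Known-miRNA count matrix from annotated tags
#'
#' Adds each known-miRNA tag's per-sample counts to its assigned catalog
#' entry.  Rows are catalog entries with at least one read in at least one
#' sample.
#'
#' @param ann an `annotated_tags` object.
#' @param catalog the catalog used for annotation (for row order).
#' @return integer matrix, miRNAs x samples.
#' @export
quantify_known <- function(ann, catalog) {
  stopifnot(inherits(ann, "annotated_tags"))
  samples <- setdiff(names(ann), c("sequence", "n_hits", "chrom", "start",
                                   "end", "strand", "category",
                                   "assigned_mirna"))
  km <- ann[ann$category == "known_miRNA" & !is.na(ann$assigned_mirna), ]
  mat <- matrix(0L, nrow = nrow(catalog), ncol = length(samples),
                dimnames = list(catalog$name, samples))
  for (s in samples) {
    if (nrow(km))
      mat[, s] <- as.integer(tapply(km[[s]],
                                    factor(km$assigned_mirna,
                                           levels = catalog$name),
                                    sum, default = 0L))
  }
  mat[rowSums(mat) > 0, , drop = FALSE]
}

#' Per-category read proportions for one sample
#'
#' @param ann an `annotated_tags` object.
#' @param sample sample name.
#' @return list with `counts` (reads per category, all seven categories),
#'   `prop_clean` (proportions of clean reads; sums to 1) and
#'   `prop_mapped` (proportions of mapped reads).
#' @export
category_summary <- function(ann, sample) {
  stopifnot(inherits(ann, "annotated_tags"))
  if (!sample %in% names(ann)) stop("unknown sample '", sample, "'")
  cnt <- ann[[sample]]
  cat_f <- factor(ann$category, levels = CATEGORY_LEVELS)
  counts <- tapply(cnt, cat_f, sum, default = 0L)
  total <- sum(cnt)
  mapped <- sum(cnt[ann$n_hits > 0])
  list(counts = counts,
       prop_clean = if (total > 0) counts / total else counts * NA,
       prop_mapped = if (mapped > 0)
         tapply(cnt[ann$n_hits > 0], cat_f[ann$n_hits > 0], sum,
                default = 0L) / mapped
       else counts * NA)
}
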