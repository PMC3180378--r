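## End-to-end convenience wrapper: raw libraries in, annotated tags,
## expression matrix, clusters, novel calls and (optionally) an XCI
## report out.

#' Run the small RNA-seq pipeline on a set of libraries
#'
#' Cleans each library ([make_clean_reads()]), collapses reads into tags,
#' annotates them against the genome, quantifies known miRNAs, normalises
#' to TPM, applies the Poisson noise filter, groups genomic clusters and,
#' when requested, calls novel miRNAs and X-inactivation status.
#'
#' @param genome a `toy_genome`.
#' @param libraries named list of FASTQ paths or `sim_library` objects.
#' @param adaptor 3' adaptor (default: the genome config's adaptor).
#' @param call_novel run the novel-miRNA caller (default TRUE).
#' @param xci_test,xci_reference sample names for [call_xci()]; the XCI
#'   step runs when both are given.
#' @param min_qual,min_len,max_len read-cleaning parameters.
#' @param noise_filter apply [poisson_noise_filter()] (default TRUE).
#' @return list with `clean`, `tags`, `annotated`, `counts`, `em` (raw
#'   TPM), `filtered` (noise-filtered expression + report), `clusters`,
#'   `novel`, `xci` (NULL when not run).
#' @export
run_pipeline <- function(genome, libraries, adaptor = NULL,
                         call_novel = TRUE, xci_test = NULL,
                         xci_reference = NULL, min_qual = 20,
                         min_len = 18L, max_len = 30L,
                         noise_filter = TRUE) {
  stopifnot(inherits(genome, "toy_genome"))
  adaptor <- adaptor %||% genome$config$adaptor_seq
  clean <- lapply(names(libraries), function(nm)
    make_clean_reads(libraries[[nm]], adaptor, min_len, max_len,
                     min_qual, sample = nm))
  tags <- collapse_tags(clean)
  ann <- annotate_tags(tags, genome)
  catalog <- mirna_catalog(genome)
  counts <- quantify_known(ann, catalog)
  positions <- data.frame(name = catalog$name, chrom = catalog$chrom,
                          strand = catalog$strand,
                          first_nt = catalog$first_nt,
                          stringsAsFactors = FALSE)
  em <- normalize_tpm(counts, attr(tags, "clean_totals"), positions)
  filtered <- NULL
  if (noise_filter) {
    hits <- attr(ann, "hits")
    first_hit <- hits[!duplicated(hits$sequence), , drop = FALSE]
    rp <- data.frame(chrom = first_hit$chrom, start = first_hit$start,
                     stringsAsFactors = FALSE)
    for (s in colnames(counts))
      rp[[s]] <- ann[[s]][match(first_hit$sequence, ann$sequence)]
    filtered <- poisson_noise_filter(em, genome, rp)
  }
  active_em <- if (noise_filter) filtered$em else em
  clusters <- group_clusters(active_em)
  novel <- if (call_novel) call_novel_mirnas(ann, genome) else NULL
  xci <- NULL
  if (!is.null(xci_test) && !is.null(xci_reference))
    xci <- call_xci(active_em, xci_test, xci_reference)
  list(clean = setNames(clean, names(libraries)), tags = tags,
       annotated = ann, counts = counts, em = em, filtered = filtered,
       clusters = clusters, novel = novel, xci = xci)
}
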