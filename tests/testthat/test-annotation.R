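test_that("map_tags finds planted substrings on both strands", {
  chroms <- c(chrA = paste0(strrep("A", 100), "ACGTACGTACGTACGTACGTAC",
                            strrep("T", 100)))
  tag <- "ACGTACGTACGTACGTACGTAC"
  hits <- map_tags(tag, chroms)
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$chrom == "chrA" & plus$start == 100))

  ## a tag and its reverse complement planted once each -> two hits on
  ## opposite strands
  chroms2 <- c(chrB = paste0("GGGGG", "AATTCCGGATATCCGGAAGG", "GGGGG",
                             revcomp("AATTCCGGATATCCGGAAGG"), "GGGGG"))
  h2 <- map_tags("AATTCCGGATATCCGGAAGG", chroms2)
  expect_identical(nrow(h2), 2L)
  expect_setequal(h2$strand, c("+", "-"))

  expect_warning(h3 <- map_tags(c("ACGTN", "AACCGGTTAACCGGTTAA"),
                                chroms2), "non-ACGT")
})

test_that("exact mapping agrees with a naive scan oracle", {
  cfg <- sim_config(n_autosomes = 1L, chrom_length = 48000L,
                    n_mirnas_per_chrom = 2L, n_clustered_groups = 0L,
                    n_novel_mirnas = 1L, n_noise_mirnas = 1L,
                    n_decoys = 1L, n_other_rna = 1L, seed = 5L)
  g <- generate_toy_genome(cfg)        # 2 x 48 kb genome, < 100 kb
  set.seed(31)
  tags <- c(g$truth$mature_seq[1:4],
            replicate(30, paste(sample(c("A", "C", "G", "T"), 19, TRUE),
                                collapse = "")),
            ## substrings of the genome at random spots
            vapply(1:15, function(i) {
              ch <- sample(names(g$chromosomes), 1)
              p <- sample(47000, 1)
              substr(g$chromosomes[[ch]], p, p + 21)
            }, ""))
  tags <- unique(tags)
  got <- map_tags(tags, g)
  want <- oracle_scan_hits(tags, g$chromosomes)
  key <- function(d) sort(paste(d$sequence, d$chrom, d$start, d$strand))
  expect_identical(key(got), key(want))
})

test_that("priority resolution follows the declared total order", {
  feats <- data.frame(
    chrom = "c", start = c(100, 120), end = c(160, 180),
    strand = "+", category = c("known_miRNA", "exon"),
    name = c("m", "e"), stringsAsFactors = FALSE)
  hit <- data.frame(chrom = "c", start = 130, end = 152, strand = "+",
                    stringsAsFactors = FALSE)
  expect_identical(resolve_category(hit, feats), "known_miRNA")

  feats$category <- c("rRNA_rfam", "known_miRNA")
  expect_identical(resolve_category(hit, feats), "rRNA_rfam")

  none <- data.frame(chrom = "c", start = 5000, end = 5022, strand = "+")
  expect_identical(resolve_category(none, feats), "unann")
})

test_that("priority resolution matches a rank-max oracle on random fixtures", {
  set.seed(77)
  cats <- c("rRNA_genbank", "rRNA_rfam", "known_miRNA", "repeat",
            "exon", "intron")
  for (case in 1:1000) {
    nf <- sample(0:5, 1)
    feats <- data.frame(
      chrom = sample(c("c1", "c2"), max(nf, 1), TRUE),
      start = sample(0:400, max(nf, 1), TRUE),
      strand = "+", category = sample(cats, max(nf, 1), TRUE),
      name = "f", stringsAsFactors = FALSE)[seq_len(nf), , drop = FALSE]
    feats$end <- feats$start + sample(10:80, nf, TRUE)
    nh <- sample(1:3, 1)
    hits <- data.frame(chrom = sample(c("c1", "c2"), nh, TRUE),
                       start = sample(0:450, nh, TRUE),
                       strand = "+", stringsAsFactors = FALSE)
    hits$end <- hits$start + 22L
    expect_identical(resolve_category(hits, feats),
                     oracle_priority(hits, feats))
  }
})

test_that("known-miRNA counts equal planted truth in error-free libraries", {
  cfg <- sim_config(frac_noise = 0, seed = 9L)
  g <- generate_toy_genome(cfg)
  lib <- simulate_library(g, "S", "male")
  cl <- make_clean_reads(lib, cfg$adaptor_seq)
  tags <- collapse_tags(cl)
  ann <- annotate_tags(tags, g)
  counts <- quantify_known(ann, mirna_catalog(g))
  truth <- lib$truth_counts[lib$truth_counts$kind %in%
                              c("known", "noise"), ]
  truth <- truth[truth$true_count > 0, ]
  expect_setequal(rownames(counts), truth$name)
  expect_identical(counts[truth$name, "S"],
                   setNames(truth$true_count, truth$name))
})

test_that("catalog entries without reads are absent from the matrix", {
  pipe <- fix_pipeline()
  counts <- pipe$counts
  expect_true(all(rowSums(counts) > 0))
})

test_that("category proportions reproduce a constructed 60/15/25 split", {
  g <- fix_genome()
  t <- g$truth
  known <- t[t$kind == "known", ][1, ]
  rrna <- g$features[g$features$category == "rRNA_genbank", ][1, ]
  rseq <- substr(g$chromosomes[[rrna$chrom]], rrna$start + 1,
                 rrna$start + 22)
  ## 60 miRNA reads, 15 other-annotated, 25 unannotated
  unmappable <- strrep("ACGTT", 5)
  reads <- c(rep(known$mature_seq, 60), rep(rseq, 15),
             rep(unmappable, 25))
  cl <- structure(list(sample = "fx", reads = reads,
                       counters = list(clean_total = 100L)),
                  class = "clean_read_set")
  ann <- annotate_tags(collapse_tags(cl), g)
  cs <- category_summary(ann, "fx")
  expect_equal(unname(cs$prop_clean["known_miRNA"]), 0.60)
  expect_equal(unname(cs$prop_clean["rRNA_genbank"]), 0.15)
  expect_equal(unname(cs$prop_clean["unann"]), 0.25)
  expect_equal(sum(cs$prop_clean), 1)
})

test_that("category read counts conserve the clean total per sample", {
  pipe <- fix_pipeline()
  ann <- pipe$annotated
  for (s in c("Pa2.2", "Pa3", "IVF-M1", "IVF-M2")) {
    cs <- category_summary(ann, s)
    expect_identical(as.integer(sum(cs$counts)),
                     pipe$clean[[s]]$counters$clean_total)
    expect_equal(sum(cs$prop_clean), 1)
  }
})

test_that("annotation is invariant under reverse-complementing the genome", {
  cfg <- sim_config(n_autosomes = 1L, chrom_length = 48000L,
                    n_mirnas_per_chrom = 2L, n_clustered_groups = 0L,
                    n_novel_mirnas = 1L, n_noise_mirnas = 0L,
                    n_decoys = 0L, n_other_rna = 1L,
                    read_depth = 5000L, seed = 13L)
  g <- generate_toy_genome(cfg)
  lib <- simulate_library(g, "S", "male")
  tags <- collapse_tags(make_clean_reads(lib, cfg$adaptor_seq))
  ann1 <- annotate_tags(tags, g)

  L <- nchar(g$chromosomes[[1]])
  flipped <- g
  flipped$chromosomes[] <- revcomp(g$chromosomes)
  f <- g$features
  flipped$features$start <- L - f$end
  flipped$features$end <- L - f$start
  flipped$features$strand <- ifelse(f$strand == "+", "-", "+")
  tr <- g$truth
  for (col in c("pre", "mat", "star")) {
    flipped$truth[[paste0(col, "_start")]] <- L - tr[[paste0(col, "_end")]]
    flipped$truth[[paste0(col, "_end")]] <- L - tr[[paste0(col, "_start")]]
  }
  flipped$truth$strand <- ifelse(tr$strand == "+", "-", "+")
  ann2 <- annotate_tags(tags, flipped)
  expect_identical(ann1$category, ann2$category)
  expect_identical(ann1$n_hits, ann2$n_hits)
})
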