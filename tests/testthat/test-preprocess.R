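ADAPTOR <- "TCGTATGCCGTCTTCTGCTTG"

test_that("trim_adaptor recovers inserts and flags adaptor-less reads", {
  insert <- "ACGTACGTACGTACGTACGTAC"          # 22 nt
  read <- paste0(insert, ADAPTOR)
  tr <- trim_adaptor(read, NULL, ADAPTOR)
  expect_false(tr$contaminant)
  expect_identical(tr$insert, insert)

  tr0 <- trim_adaptor(ADAPTOR, NULL, ADAPTOR)  # read is adaptor only
  expect_false(tr0$contaminant)
  expect_identical(nchar(tr0$insert), 0L)

  trc <- trim_adaptor(strrep("A", 35), NULL, ADAPTOR)
  expect_true(trc$contaminant)
  trn <- trim_adaptor(paste0("ACGN", substr(read, 5, 35)), NULL, ADAPTOR)
  expect_true(trn$contaminant)
  ## output is never longer than the input
  reads <- c(read, substr(read, 1, 30), ADAPTOR)
  tra <- trim_adaptor(reads, NULL, ADAPTOR)
  expect_true(all(is.na(tra$insert) |
                    nchar(tra$insert) <= nchar(reads)))
})

test_that("planted inserts are recovered exactly with exact matching", {
  g <- fix_genome()
  lib <- fix_libraries()[["IVF-M1"]]
  tr <- trim_adaptor(lib$reads[1:1000], lib$quals[1:1000],
                     ADAPTOR, mismatch_per10 = 0L)
  mat_seqs <- g$truth$mature_seq
  ok <- !tr$contaminant & nchar(tr$insert) >= 18
  ## the non-contaminant reads at the head of the library are planted
  ## mature sequences; every recovered insert must equal one of them
  expect_true(all(tr$insert[ok] %in% mat_seqs))
})

test_that("make_clean_reads books every raw read into exactly one bin", {
  good <- paste0(c("ACGTACGTACGTACGTACGTAC", "GGGTTTCCCAAAGGGTTTCCCA",
                   "ACACACACACACACACACAC", "TGTGTGTGTGTGTGTGTGTGT",
                   "AAACCCGGGTTTAAACCCGGGT", "CATCATCATCATCATCATCA"),
                 ADAPTOR)
  contam <- c(strrep("G", 35), strrep("C", 35))
  short <- paste0("ACGTACGTACGTACGTA", ADAPTOR)       # 17-nt insert
  lowq <- paste0("ACGTACGTACGTACGTACGTCA", ADAPTOR)
  reads <- c(good, contam, short, lowq)
  reads <- substr(reads, 1, 35)
  quals <- c(rep(phred_string(38, 35), 9), phred_string(5, 35))
  lib <- manual_library(reads, quals)
  cl <- make_clean_reads(lib, ADAPTOR)
  cc <- cl$counters
  expect_identical(cc$raw_total, 10L)
  expect_identical(cc$clean_total, 6L)
  expect_identical(cc$removed_contaminant, 2L)
  expect_identical(cc$removed_too_small, 1L)
  expect_identical(cc$removed_low_quality, 1L)
  expect_identical(cc$removed_too_long, 0L)
  expect_identical(cc$clean_total,
                   cc$raw_total - cc$removed_contaminant -
                     cc$removed_too_small - cc$removed_too_long -
                     cc$removed_low_quality)
})

test_that("empty and malformed FASTQ inputs are handled", {
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  cl <- make_clean_reads(empty, ADAPTOR)
  expect_identical(cl$counters$raw_total, 0L)
  expect_identical(cl$counters$clean_total, 0L)

  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad)
  expect_error(make_clean_reads(bad, ADAPTOR), "record")
})

test_that("contaminant removal rate matches the simulated fraction", {
  cfg <- sim_config(frac_contaminant = 0.1, read_depth = 50000L,
                    seed = 3L)
  g <- generate_toy_genome(cfg)
  lib <- simulate_library(g, "c", "male")
  cl <- make_clean_reads(lib, cfg$adaptor_seq)
  rate <- cl$counters$removed_contaminant / cl$counters$raw_total
  se <- sqrt(0.1 * 0.9 / cl$counters$raw_total)
  expect_lt(abs(rate - 0.1), 3 * se + 0.002)
})

test_that("collapse_tags is an exact multiset collapse", {
  s1 <- structure(list(sample = "S1",
                       reads = c("AAAATTTTCCCCGGGGAA", "AAAATTTTCCCCGGGGAA",
                                 "CCCCGGGGAAAATTTTCC"),
                       counters = list(clean_total = 3L)),
                  class = "clean_read_set")
  s2 <- structure(list(sample = "S2",
                       reads = "CCCCGGGGAAAATTTTCC",
                       counters = list(clean_total = 1L)),
                  class = "clean_read_set")
  tags <- collapse_tags(s1, s2)
  expect_identical(nrow(tags), 2L)
  a <- tags[tags$sequence == "AAAATTTTCCCCGGGGAA", ]
  expect_identical(c(a$S1, a$S2), c(2L, 0L))
  b <- tags[tags$sequence == "CCCCGGGGAAAATTTTCC", ]
  expect_identical(c(b$S1, b$S2), c(1L, 1L))

  ## random reads: counts agree with a sort-and-count oracle and conserve
  set.seed(21)
  reads <- random_pool <- replicate(200, paste(sample(c("A","C","G","T"),
                                                      20, TRUE),
                                               collapse = ""))
  draws <- sample(random_pool, 10000, replace = TRUE)
  s3 <- structure(list(sample = "S3", reads = draws,
                       counters = list(clean_total = 10000L)),
                  class = "clean_read_set")
  tags3 <- collapse_tags(s3)
  expect_identical(sum(tags3$S3), 10000L)
  oracle <- table(sort(draws))
  expect_identical(setNames(tags3$S3, tags3$sequence)[names(oracle)],
                   setNames(as.integer(oracle), names(oracle)))
})

test_that("cleaning is idempotent on already-clean inserts", {
  pipe <- fix_pipeline()
  clean1 <- pipe$clean[["Pa2.2"]]
  re_reads <- paste0(head(clean1$reads, 2000), ADAPTOR)
  re_reads <- substr(re_reads, 1, 35)
  lib <- manual_library(re_reads, rep(phred_string(38, 35),
                                      length(re_reads)))
  cl2 <- make_clean_reads(lib, ADAPTOR)
  expect_identical(cl2$counters$clean_total, length(re_reads))
  expect_identical(cl2$reads, head(clean1$reads, 2000))
})

test_that("length histogram is count-weighted, conserved, and peaks at 22-23", {
  tags <- structure(data.frame(sequence = c(strrep("AG", 11),
                                            paste0(strrep("CT", 11), "A")),
                               S = c(5L, 3L), stringsAsFactors = FALSE),
                    clean_totals = c(S = 8), class = c("tag_set",
                                                       "data.frame"))
  h <- length_histogram(tags, "S")
  expect_identical(h, setNames(c(5L, 3L), c("22", "23")))
  expect_error(length_histogram(tags, "nope"), "unknown sample")

  pipe <- fix_pipeline()
  hist <- length_histogram(pipe$tags, "Pa3")
  expect_identical(sum(hist),
                   pipe$clean[["Pa3"]]$counters$clean_total)
  expect_true(names(hist)[which.max(hist)] %in% c("22", "23"))

  empty <- structure(data.frame(sequence = character(0),
                                S = integer(0)),
                     clean_totals = c(S = 0),
                     class = c("tag_set", "data.frame"))
  expect_length(length_histogram(empty, "S"), 0)
})
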