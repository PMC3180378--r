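test_that("TPM normalisation applies the exact formula", {
  counts <- matrix(c(5L, 0L, 12L, 7L), 2,
                   dimnames = list(c("a", "b"), c("S1", "S2")))
  em <- normalize_tpm(counts, c(S1 = 1e6, S2 = 2e6))
  expect_equal(em$tpm["a", "S1"], 5)
  expect_equal(em$tpm["b", "S1"], 0)
  expect_equal(em$tpm["a", "S2"], 6)
  expect_error(normalize_tpm(counts, c(S1 = 0, S2 = 1)), "positive")

  ## exactness against rational arithmetic on random integers
  set.seed(3)
  c2 <- matrix(sample(0:5000, 200, TRUE), 50,
               dimnames = list(paste0("m", 1:50), paste0("s", 1:4)))
  totals <- setNames(sample(1e5:1e6, 4), paste0("s", 1:4))
  em2 <- normalize_tpm(c2, totals)
  for (j in 1:4)
    expect_equal(em2$tpm[, j], c2[, j] / totals[[j]] * 1e6)

  ## normalising a whole tag table conserves a million per sample
  pipe <- fix_pipeline()
  tags <- pipe$tags
  tagm <- as.matrix(tags[, c("Pa2.2", "Pa3"), drop = FALSE])
  rownames(tagm) <- tags$sequence
  emt <- normalize_tpm(tagm, attr(tags, "clean_totals")[c("Pa2.2", "Pa3")])
  expect_equal(unname(colSums(emt$tpm)), c(1e6, 1e6))
})

test_that("Poisson threshold count matches the direct tail-sum oracle", {
  for (lam in c(0.1, 0.5, 1, 5, 20))
    expect_equal(poisson_count_threshold(lam),
                     oracle_poisson_cstar(lam))
  ## empty background: a single read is already above noise
  expect_identical(poisson_count_threshold(0), 1L)
})

test_that("noise filter keeps expressed miRNAs and drops sporadic ones", {
  pipe <- fix_pipeline()
  g <- fix_genome()
  flt <- pipe$filtered
  truth <- g$truth
  expressed <- truth$name[truth$kind == "known"]
  noise <- truth$name[truth$kind == "noise"]
  kept <- rownames(flt$em$counts)
  in_matrix <- rownames(pipe$em$counts)
  expect_true(all(expressed[expressed %in% in_matrix] %in% kept))
  noise_in <- noise[noise %in% in_matrix]
  expect_gte(mean(!noise_in %in% kept), 0.95)
  expect_true(all(flt$report$tpm_threshold >= 3))
})

test_that("cluster grouping honours the inclusive 10-kb boundary", {
  pos <- data.frame(name = c("a", "b"), chrom = "c1",
                    first_nt = c(0L, 9999L), stringsAsFactors = FALSE)
  cl <- group_clusters(pos)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n, 2L)

  pos$first_nt <- c(0L, 10001L)
  cl2 <- group_clusters(pos)
  expect_identical(nrow(cl2), 2L)
  expect_true(all(cl2$n == 1L))

  pos$first_nt <- c(0L, 10000L)   # exactly 10 kb joins
  expect_identical(group_clusters(pos)$n, 2L)
})

test_that("cluster partition equals a union-find oracle, order-invariantly", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    pos <- data.frame(name = paste0("m", 1:n),
                      chrom = sample(c("c1", "c2", "cX"), n, TRUE),
                      first_nt = sample(0:60000, n),
                      stringsAsFactors = FALSE)
    cl <- group_clusters(pos)
    ## partition: every miRNA in exactly one cluster
    members <- unlist(strsplit(cl$members, ","))
    expect_setequal(members, pos$name)
    expect_identical(anyDuplicated(members), 0L)
    ## same partition as the oracle
    want <- oracle_clusters(pos)
    got <- integer(n)
    for (k in seq_len(nrow(cl)))
      got[match(strsplit(cl$members[k], ",")[[1]], pos$name)] <- k
    for (grp in split(seq_len(n), want))
      expect_identical(length(unique(got[grp])), 1L)
    for (grp in split(seq_len(n), got))
      expect_identical(length(unique(want[grp])), 1L)
    ## row order must not matter
    perm <- sample(n)
    cl_p <- group_clusters(pos[perm, ])
    expect_setequal(cl$members, cl_p$members)
  }
})

test_that("two-library p-values match pmf enumeration and are antisymmetric", {
  set.seed(14)
  for (i in 1:50) {
    xa <- sample(0:60, 1); xb <- sample(0:60, 1)
    na <- sample(1e5:2e5, 1); nb <- sample(1e5:2e5, 1)
    p1 <- two_library_test(xa, xb, na, nb)
    expect_equal(p1, oracle_two_library_p(xa, xb, na, nb),
                 tolerance = 1e-8)
    expect_equal(p1, two_library_test(xb, xa, nb, na), tolerance = 1e-12)
  }
})

test_that("differential expression flags follow fold change and p-value", {
  counts <- matrix(c(400L, 100L, 100L, 100L), 2, byrow = TRUE,
                   dimnames = list(c("m1", "m2"), c("A", "B")))
  em <- normalize_tpm(counts * 100L, c(A = 1e6, B = 1e6))
  de <- differential_expression(em, "A", "B")
  expect_equal(de$log2_ratio[de$mirna == "m1"], 2)
  expect_identical(de$flag[de$mirna == "m1"], "up")
  expect_equal(de$log2_ratio[de$mirna == "m2"], 0)
  expect_identical(de$flag[de$mirna == "m2"], "ns")

  ## antisymmetry: swapping samples negates ratios, swaps flags
  de_rev <- differential_expression(em, "B", "A")
  expect_equal(de_rev$log2_ratio, -de$log2_ratio)
  expect_equal(de_rev$p_value, de$p_value)
  expect_identical(de_rev$flag[de$flag == "up"], "down")
})

test_that("null libraries stay unflagged and 4-fold shifts are caught", {
  set.seed(15)
  n <- 500L
  lam <- rlnorm(n, log(120), 0.8)
  na <- nb <- 1e6
  null_a <- rpois(n, lam); null_b <- rpois(n, lam)
  counts <- cbind(A = null_a, B = null_b)
  rownames(counts) <- paste0("m", 1:n)
  em <- normalize_tpm(counts, c(A = na, B = nb))
  de <- differential_expression(em, "A", "B")
  flag_rate <- mean(de$flag != "ns")
  se <- sqrt(0.05 * 0.95 / nrow(de))
  expect_lte(flag_rate, 0.05 + 3 * se)

  ## power: true 4-fold at >= 50 counts
  lam2 <- pmax(rlnorm(n, log(150), 0.5), 55)
  up_a <- rpois(n, 4 * lam2); up_b <- rpois(n, lam2)
  c2 <- cbind(A = up_a, B = up_b); rownames(c2) <- paste0("u", 1:n)
  em2 <- normalize_tpm(c2, c(A = na, B = nb))
  de2 <- differential_expression(em2, "A", "B")
  at_depth <- de2[de2$count_b >= 50, ]
  expect_gte(mean(at_depth$flag == "up"), 0.95)
})

test_that("hierarchical clustering pairs resampled replicates first", {
  set.seed(16)
  n <- 300L
  base <- rlnorm(n, log(200), 1)
  shift <- base; shift[1:50] <- shift[1:50] * 4
  counts <- cbind(A = rpois(n, base), A2 = rpois(n, base),
                  B = rpois(n, shift), B2 = rpois(n, shift))
  rownames(counts) <- paste0("m", 1:n)
  em <- normalize_tpm(counts, setNames(rep(1e6, 4), colnames(counts)))
  hc <- hierarchical_clustering(em)
  merges <- hc$merge
  first_pairs <- lapply(seq_len(nrow(merges)), function(i)
    if (all(merges[i, ] < 0)) sort(hc$labels[-merges[i, ]]) else NULL)
  first_pairs <- Filter(Negate(is.null), first_pairs)
  expect_true(any(vapply(first_pairs, identical, TRUE, c("A", "A2"))))
  expect_true(any(vapply(first_pairs, identical, TRUE, c("B", "B2"))))

  ## identical samples merge at distance zero
  em2 <- normalize_tpm(cbind(X = counts[, "A"], Y = counts[, "A"]),
                       c(X = 1e6, Y = 1e6))
  hc2 <- hierarchical_clustering(em2)
  expect_equal(hc2$height[1], 0)
  expect_error(hierarchical_clustering(em, samples = "A"), "at least 2")
})
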