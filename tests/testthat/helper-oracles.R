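# Independent brute-force oracles.  Each one re-derives a quantity by the
# most naive correct method available, sharing no code with the package
# implementation it checks.

# --- exact mapping: scan every position of every chromosome -------------
oracle_scan_hits <- function(tags, chroms) {
  out <- list()
  for (tag in tags) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tag else oracle_revcomp(tag)
      for (ch in names(chroms)) {
        s <- chroms[[ch]]
        # position-by-position rescan so overlapping occurrences count too
        starts <- integer(0)
        from <- 1L
        while (TRUE) {
          hit <- regexpr(q, substr(s, from, nchar(s)), fixed = TRUE)
          if (hit == -1L) break
          starts <- c(starts, from + hit - 1L)
          from <- from + hit
        }
        for (st in starts)
          out[[length(out) + 1L]] <- data.frame(
            sequence = tag, chrom = ch, start = st - 1L,
            end = st - 1L + nchar(tag), strand = strand,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  do.call(rbind, out)
}

oracle_revcomp <- function(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")

# --- priority annotation: enumerate all overlaps, take the max rank -----
oracle_priority <- function(hits, features) {
  ranks <- c(rRNA_genbank = 1, rRNA_rfam = 2, known_miRNA = 3,
             `repeat` = 4, exon = 5, intron = 6)
  found <- character(0)
  for (i in seq_len(nrow(hits))) {
    for (j in seq_len(nrow(features))) {
      if (hits$chrom[i] == features$chrom[j] &&
          max(hits$start[i], features$start[j]) <
            min(hits$end[i], features$end[j]))
        found <- c(found, features$category[j])
    }
  }
  if (!length(found)) return("unann")
  names(ranks)[ranks == min(ranks[found])]
}

# --- secondary structure scoring ----------------------------------------
oracle_pair_score <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(3)
  if (key %in% c("AT", "TA", "AU", "UA")) return(2)
  if (key %in% c("GT", "TG", "GU", "UG")) return(1)
  0
}

# top-down recursion with memoisation (same recurrence family as any
# nested-structure optimiser, written independently in R)
oracle_fold_score <- function(seq) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(s)
  memo <- new.env(parent = emptyenv())
  best <- function(i, j) {
    if (j - i < 4) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- best(i, j - 1)
    for (k in i:(j - 4)) {
      w <- oracle_pair_score(s[k], s[j])
      if (w == 0) next
      left <- if (k > i) best(i, k - 1) else 0
      inner <- if (k + 1 <= j - 1) best(k + 1, j - 1) else 0
      v <- max(v, left + inner + w)
    }
    memo[[key]] <- v
    v
  }
  if (n < 2) return(0)
  best(1, n)
}

# full enumeration of every nested pairing (exponential; n <= ~16)
oracle_enumerate_score <- function(seq) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(s)
  recurse <- function(positions) {
    if (length(positions) == 0) return(0)
    i <- positions[1]
    rest <- positions[-1]
    best <- recurse(rest)                      # i unpaired
    for (j in rest) {
      if (j - i < 4) next
      w <- oracle_pair_score(s[i], s[j])
      if (w == 0) next
      inside <- rest[rest > i & rest < j]
      outside <- rest[rest > j]
      best <- max(best, w + recurse(inside) + recurse(outside))
    }
    best
  }
  recurse(seq_len(n))
}

# --- Poisson tail threshold by direct summation -------------------------
oracle_poisson_cstar <- function(lambda, p_crit = 1e-4) {
  upper_tail <- function(cc) {
    # P(X >= cc) summed term by term
    k <- cc
    term <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
    total <- 0
    while (term > 1e-300 || k < cc + 10) {
      total <- total + term
      k <- k + 1
      term <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
      if (k > cc + 1000) break
    }
    total
  }
  cc <- 1
  while (upper_tail(cc) >= p_crit) cc <- cc + 1
  cc
}

# --- cluster partition via union-find on the chain-adjacency graph ------
oracle_clusters <- function(pos, max_gap = 10000) {
  parent <- seq_len(nrow(pos))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) parent[find(i)] <<- find(j)
  for (ch in unique(pos$chrom)) {
    idx <- which(pos$chrom == ch)
    idx <- idx[order(pos$first_nt[idx])]
    if (length(idx) < 2) next
    for (k in 2:length(idx)) {
      if (pos$first_nt[idx[k]] - pos$first_nt[idx[k - 1]] <= max_gap)
        union(idx[k], idx[k - 1])
    }
  }
  vapply(seq_len(nrow(pos)), find, 0L)
}

# --- exact conditional two-library p-value by pmf enumeration -----------
oracle_two_library_p <- function(xa, xb, na, nb) {
  n <- xa + xb
  if (n == 0) return(1)
  p <- na / (na + nb)
  pmf <- vapply(0:n, function(k)
    exp(lchoose(n, k) + k * log(p) + (n - k) * log(1 - p)), 0)
  obs <- pmf[xa + 1]
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}
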