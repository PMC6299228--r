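# Independent brute-force oracles and fixture builders used across the suite.
# These deliberately avoid the code paths they validate.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
rand_protein_seq <- function(n) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# Plain fixed-string motif search: the union of substring searches over the
# full expansion of the motif. Returns sorted "offset/strand" keys.
oracle_motif_hits <- function(sequence, motif, both_strands = FALSE) {
  words <- expand_motif(motif, limit = 1e4)
  find_all <- function(s, w) {
    out <- integer()
    p <- 1L
    repeat {
      i <- regexpr(w, substr(s, p, nchar(s)), fixed = TRUE)
      if (i == -1L) break
      out <- c(out, p + i - 2L)  # 0-based
      p <- p + i                 # continue one past the match start (overlaps)
    }
    out
  }
  keys <- character()
  for (w in words) {
    off <- find_all(sequence, w)
    if (length(off)) keys <- c(keys, paste0(off, "/+"))
  }
  if (both_strands) {
    rc <- revcomp(sequence)
    n <- nchar(sequence)
    L <- nchar(words[1])
    for (w in words) {
      off <- find_all(rc, w)
      if (length(off)) keys <- c(keys, paste0(n - off - L, "/-"))
    }
  }
  sort(keys)
}

scan_keys <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  sort(paste0(hits$offset, "/", hits$strand))
}

# Exhaustive union-find over all >= cutoff pairs (single linkage).
oracle_union_find <- function(values, cutoff) {
  labels <- rownames(values)
  parent <- seq_along(labels)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n <- length(labels)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && values[i, j] >= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(roots, unique(roots)), labels)
}

# Exhaustive three-state global alignment oracle (Needleman-Wunsch with
# affine gaps costing open + L*ext, terminal gaps penalized). Returns the
# optimal score and the set of percent identities over *all* optimal
# alignments (identity can differ between co-optimal alignments).
oracle_global_identity <- function(a, b, open = 10, ext = 0.5) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (n > 0) for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 1) * ext
  if (m > 0) for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 1) * ext
  if (n > 0 && m > 0) for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[av[i - 1], bv[j - 1]]
    M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                   Y[i - 1, j] - open - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                   Y[i, j - 1] - ext)
  }
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])

  tol <- 1e-9
  idents <- numeric()
  rec <- function(i, j, state, matches, len) {
    if (i == 0L && j == 0L) {
      if (state == "M") idents <<- c(idents, 100 * matches / len)
      return(invisible())
    }
    v <- switch(state, M = M[i + 1, j + 1], X = X[i + 1, j + 1], Y = Y[i + 1, j + 1])
    if (state == "M") {
      s <- S[av[i], bv[j]]
      mt <- matches + (av[i] == bv[j])
      for (p in c("M", "X", "Y")) {
        pv <- switch(p, M = M[i, j], X = X[i, j], Y = Y[i, j])
        if (abs(pv + s - v) < tol) rec(i - 1L, j - 1L, p, mt, len + 1L)
      }
    } else if (state == "X") {
      if (i == 0L) return(invisible())
      if (i == 1L && j == 0L && abs(v + open + ext) < tol)
        return(rec(0L, 0L, "M", matches, len + 1L))
      for (p in c("M", "X", "Y")) {
        cost <- if (p == "X") ext else open + ext
        pv <- switch(p, M = M[i, j + 1], X = X[i, j + 1], Y = Y[i, j + 1])
        if (abs(pv - cost - v) < tol) rec(i - 1L, j, p, matches, len + 1L)
      }
    } else {
      if (j == 0L) return(invisible())
      if (j == 1L && i == 0L && abs(v + open + ext) < tol)
        return(rec(0L, 0L, "M", matches, len + 1L))
      for (p in c("M", "X", "Y")) {
        cost <- if (p == "Y") ext else open + ext
        pv <- switch(p, M = M[i + 1, j], X = X[i + 1, j], Y = Y[i + 1, j])
        if (abs(pv - cost - v) < tol) rec(i, j - 1L, p, matches, len + 1L)
      }
    }
    invisible()
  }
  for (st in c("M", "X", "Y")) {
    v <- switch(st, M = M[n + 1, m + 1], X = X[n + 1, m + 1], Y = Y[n + 1, m + 1])
    if (abs(v - best) < tol) rec(n, m, st, 0L, 0L)
  }
  list(score = best, identities = sort(unique(round(idents, 9))))
}

# Random additive case: a random unrooted binary tree with known branch
# lengths plus the exact patristic distance matrix it induces.
oracle_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

# Small handcrafted two-contig genome fixture (GenBank text) with three CDS:
# a plus-strand gene (ctgA 10..27, "MKGFH"), a minus-strand gene (ctgA
# complement(40..57), "MPFKG" on the minus strand) and a plus-strand gene on
# the second contig (ctgB 4..21, "MDDRR"). Coordinates laid out by hand.
tiny_fixture_seqs <- function() {
  ctgA <- paste0("ACGTACGTC",                     # 1..9
                 "ATGAAAGGTTTTCATTAA",            # 10..27  + strand CDS
                 "ACGTACGTACGT",                  # 28..39
                 revcomp("ATGCCCTTTAAAGGGTAA"),   # 40..57  - strand CDS
                 "ACG")                           # 58..60
  ctgB <- paste0("AAA", "ATGGATGATCGTCGTTGA", "ACGTACGTA")
  c(ctgA = ctgA, ctgB = ctgB)
}

origin_lines <- function(seq) {
  pos <- seq(1L, nchar(seq), by = 60L)
  vapply(pos, function(p) {
    blk <- substr(seq, p, min(p + 59L, nchar(seq)))
    tens <- substring(blk, seq(1L, nchar(blk), 10L),
                      pmin(seq(10L, nchar(blk) + 9L, 10L), nchar(blk)))
    sprintf("%9d %s", p, tolower(paste(tens, collapse = " ")))
  }, character(1))
}

write_tiny_genbank <- function(path) {
  s <- tiny_fixture_seqs()
  writeLines(c(
    sprintf("LOCUS       ctgA              %d bp    DNA     linear   BCT 01-JAN-2026", nchar(s[["ctgA"]])),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(s[["ctgA"]])),
    "     CDS             10..27",
    "                     /locus_tag=\"gA1\"",
    "                     /product=\"hypothetical protein\"",
    "     CDS             complement(40..57)",
    "                     /locus_tag=\"gA2\"",
    "                     /product=\"membrane protein\"",
    "ORIGIN",
    origin_lines(s[["ctgA"]]),
    "//",
    sprintf("LOCUS       ctgB              %d bp    DNA     linear   BCT 01-JAN-2026", nchar(s[["ctgB"]])),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(s[["ctgB"]])),
    "     CDS             4..21",
    "                     /locus_tag=\"gB1\"",
    "                     /product=\"putative oxidoreductase\"",
    "ORIGIN",
    origin_lines(s[["ctgB"]]),
    "//"), path)
}

write_tiny_gff3_fasta <- function(gff, fasta) {
  s <- tiny_fixture_seqs()
  writeLines(c(
    "##gff-version 3",
    sprintf("##sequence-region ctgA 1 %d", nchar(s[["ctgA"]])),
    sprintf("##sequence-region ctgB 1 %d", nchar(s[["ctgB"]])),
    "ctgA\ttest\tCDS\t10\t27\t.\t+\t0\tID=gA1;locus_tag=gA1;product=hypothetical protein",
    "ctgA\ttest\tCDS\t40\t57\t.\t-\t0\tID=gA2;locus_tag=gA2;product=membrane protein",
    "ctgB\ttest\tCDS\t4\t21\t.\t+\t0\tID=gB1;locus_tag=gB1;product=putative oxidoreductase"),
    gff)
  writeLines(c(">ctgA", s[["ctgA"]], ">ctgB", s[["ctgB"]]), fasta)
}
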