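test_that("pairwise identity matches hand values and the exhaustive alignment oracle", {
  expect_equal(pairwise_identity("MKLVAANNNW", "MKLVAANNNW"), 100)
  expect_equal(pairwise_identity("AAAAAAAAAA", "AAAAAAAAAC"), 90)
  # exhaustive-DP oracle on short peptides; co-optimal alignments may differ
  # in identity, so the implementation must land inside the optimal set
  cases <- list(c("HEAGAWGHEE", "PAWHEAE"), c("MKWVTF", "MKWTF"),
                c("GATTACA", "GCATGCA"), c("CCCHHHKR", "CCHHKR"))
  for (cs in cases) {
    oracle <- oracle_global_identity(cs[1], cs[2])
    expect_true(any(abs(pairwise_identity(cs[1], cs[2]) - oracle$identities) < 1e-9),
                info = paste(cs, collapse = "/"))
  }
  # symmetry on random pairs
  set.seed(12)
  for (k in 1:5) {
    a <- rand_protein_seq(40); b <- rand_protein_seq(35)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("identity matrix is symmetric with a 100 diagonal", {
  set.seed(13)
  seqs <- stats::setNames(vapply(1:4, function(i) rand_protein_seq(30), ""),
                          paste0("s", 1:4))
  im <- identity_matrix(seqs)
  expect_equal(diag(im$values), stats::setNames(rep(100, 4), names(seqs)))
  expect_lt(max(abs(im$values - t(im$values))), 1e-9)
})

test_that("ortholog grouping is single linkage and matches brute-force union-find", {
  labs <- c("A", "B", "C")
  m <- matrix(c(100, 95, 85, 95, 100, 92, 85, 92, 100), 3, 3,
              dimnames = list(labs, labs))
  og <- ortholog_groups(m, cutoff = 90)
  expect_equal(length(unique(og$assignment)), 1L)  # chained via B
  og2 <- ortholog_groups(m, cutoff = 96)
  expect_equal(length(unique(og2$assignment)), 3L)
  # random matrices vs the exhaustive oracle
  set.seed(7)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    v <- matrix(stats::runif(n * n, 0, 100), n, n)
    v <- (v + t(v)) / 2; diag(v) <- 100
    dimnames(v) <- list(paste0("t", 1:n), paste0("t", 1:n))
    for (cutoff in c(50, 90)) {
      got <- ortholog_groups(v, cutoff)$assignment
      want <- oracle_union_find(v, cutoff)
      # same partition (group ids may be permuted)
      expect_equal(outer(got, got, `==`), outer(want, want, `==`))
    }
  }
})

test_that("raising the cutoff never merges groups and lowering never splits", {
  set.seed(8)
  n <- 7
  v <- matrix(stats::runif(n * n, 0, 100), n, n)
  v <- (v + t(v)) / 2; diag(v) <- 100
  dimnames(v) <- list(paste0("t", 1:n), paste0("t", 1:n))
  cuts <- c(20, 40, 60, 80, 95)
  parts <- lapply(cuts, function(ct) ortholog_groups(v, ct)$assignment)
  for (i in seq_len(length(cuts) - 1)) {
    lo <- parts[[i]]; hi <- parts[[i + 1]]
    # refinement: same group at the higher cutoff implies same group lower
    expect_true(all(outer(hi, hi, `==`)[outer(lo, lo, `!=`)] == FALSE))
  }
})

test_that("column filtering keeps exactly the covered columns and is idempotent", {
  msa <- rd_msa(c("r1", "r2", "r3"), c("AAB", "A-A", "X-C"))
  f <- filter_columns(msa, 0.60)
  expect_equal(f$rows, c("AB", "AA", "XC"))  # col2 has 1/3 coverage, dropped
  # X counts as ambiguous: "A,A,X" has 2/3 coverage and survives at 0.60
  msa2 <- rd_msa(c("a", "b", "c"), c("A", "A", "X"))
  expect_equal(filter_columns(msa2, 0.60)$rows, c("A", "A", "X"))
  # seeded random alignments vs independent per-column tally
  set.seed(14)
  for (k in 1:5) {
    rows <- vapply(1:10, function(i)
      paste(sample(c("A", "R", "N", "-", "X"), 200, replace = TRUE,
                   prob = c(0.3, 0.25, 0.2, 0.15, 0.1)), collapse = ""), "")
    msa3 <- rd_msa(paste0("q", 1:10), rows)
    got <- filter_columns(msa3, 0.60)
    mat <- do.call(rbind, strsplit(rows, ""))
    keep <- which(apply(mat, 2, function(cc) sum(!cc %in% c("-", "X"))) / 10 >= 0.60)
    want <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
    expect_equal(got$rows, unname(want))
    expect_equal(filter_columns(got, 0.60)$rows, got$rows)  # idempotent
  }
  expect_warning(filter_columns(rd_msa(c("a", "b"), c("-A", "A-")), 0.9), "no alignment column")
})

test_that("p and Poisson distances follow their closed forms over comparable columns", {
  msa <- rd_msa(c("a", "b"), c("AAAAAAAAAA", "AAAAAAAACC"))
  expect_equal(distance_matrix(msa, "p")["a", "b"], 0.2)
  expect_equal(distance_matrix(msa, "poisson")["a", "b"], -log(0.8))
  msa2 <- rd_msa(c("a", "b"), c("AAAA", "AAAA"))
  expect_equal(distance_matrix(msa2, "p")["a", "b"], 0)
  # gap/X columns are excluded from the comparable set
  msa3 <- rd_msa(c("a", "b"), c("AC-AX", "ACCAA"))
  expect_equal(distance_matrix(msa3, "p")["a", "b"], 0)
  expect_error(distance_matrix(rd_msa(c("a", "b"), c("A-", "-A")), "p"),
               "no comparable")
})

test_that("neighbor joining reproduces two- and three-taxon closed forms", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))
  labs <- c("A", "B", "C")
  d3 <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
               dimnames = list(labs, labs))
  t3 <- nj_tree(d3)
  D <- ape::cophenetic.phylo(t3)[labs, labs]
  expect_equal(D, d3, tolerance = 1e-12)
  br <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(br["A"]), (0.3 + 0.5 - 0.6) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("neighbor joining recovers additive trees exactly (distances and topology)", {
  set.seed(3)
  for (k in 1:12) {
    case <- oracle_additive_case(sample(4:8, 1))
    tree <- nj_tree(case$d)
    D <- ape::cophenetic.phylo(tree)[rownames(case$d), colnames(case$d)]
    expect_lt(max(abs(D - case$d)), 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tree), case$tree)), 0)
    # independent cross-check against ape's NJ on the same matrix
    ref <- ape::nj(stats::as.dist(case$d))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tree), ape::unroot(ref))), 0)
  }
})

test_that("neighbor joining is deterministic under ties", {
  labs <- paste0("t", 1:5)
  d <- matrix(1, 5, 5, dimnames = list(labs, labs)); diag(d) <- 0
  t1 <- ape::write.tree(nj_tree(d))
  t2 <- ape::write.tree(nj_tree(d))
  expect_identical(t1, t2)
  # equidistant taxa: every pairwise patristic distance is still 1
  D <- ape::cophenetic.phylo(nj_tree(d))[labs, labs]
  expect_lt(max(abs(D - d)), 1e-9)
})

test_that("Newick round trip preserves topology and branch lengths", {
  set.seed(9)
  case <- oracle_additive_case(6)
  tree <- nj_tree(case$d)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, nwk)
  back <- read_newick(nwk)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back), ape::unroot(tree))), 0)
  D1 <- ape::cophenetic.phylo(tree); D2 <- ape::cophenetic.phylo(back)
  expect_lt(max(abs(D1[rownames(D2), colnames(D2)] - D2)), 1e-10)
  fixed <- ape::read.tree(text = "(A:0.1,B:0.1,(C:0.1,D:0.1):0.05);")
  expect_equal(length(fixed$tip.label), 4L)
})

test_that("aligned FASTA reader enforces equal lengths and names offenders", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "MKLV-", ">s2", "MKLVA", ">s3", "MKL"), fa)
  expect_error(read_alignment_fasta(fa), "s3")
  writeLines(c(">s1 desc", "MKLV-", ">s2", "MKLVA"), fa)
  msa <- read_alignment_fasta(fa)
  expect_equal(msa$labels, c("s1", "s2"))
  expect_equal(msa$rows, c("MKLV-", "MKLVA"))
})

test_that("clade assignment uses nearest reference, reports ties and monophyly", {
  # handcrafted tree: q1 sits at zero distance from ref_a (clade c1)
  tree <- ape::read.tree(text = "((ref_a:0.0,q1:0.0):0.2,(ref_b:0.1,q2:0.3):0.2,ref_c:0.5);")
  refs <- c(ref_a = "c1", ref_b = "c2", ref_c = "c3")
  ac <- assign_clades(tree, refs)
  expect_equal(unname(ac$assignment["q1"]), "c1")
  expect_equal(unname(ac$assignment["q2"]), "c2")
  expect_true(all(ac$monophyletic))
  # exact tie between two clades -> ambiguous
  tie <- ape::read.tree(text = "(ref_a:0.1,ref_b:0.1,q:0.1);")
  act <- assign_clades(tie, c(ref_a = "c1", ref_b = "c2"))
  expect_equal(unname(act$assignment["q"]), "ambiguous")
  # non-monophyletic references warn but still assign
  nm <- ape::read.tree(text = "((ref_a:0.1,ref_b:0.1):0.1,(ref_a2:0.1,q:0.1):0.1,x:0.2);")
  expect_warning(acn <- assign_clades(nm, c(ref_a = "c1", ref_a2 = "c1", ref_b = "c2")),
                 "not monophyletic")
  expect_equal(unname(acn$assignment["q"]), "c1")
  expect_error(assign_clades(tree, c(ghost = "c9")), "ghost")
})
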