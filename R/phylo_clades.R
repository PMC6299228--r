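# Pairwise identity, ortholog grouping, alignment column filtering, distance
# matrices, neighbor-joining trees and reference-based clade assignment.
#
# Trees are ape "phylo" objects (unrooted, trifurcating root); Newick I/O is
# delegated to ape. The NJ implementation is in-package because the pipeline
# requires bit-deterministic output: ties in the Q matrix are broken on the
# lexicographically smallest leaf-label pair and negative branch-length
# estimates are clamped to zero with the deficit moved to the sister branch.

#' Read a protein multiple sequence alignment from aligned FASTA
#'
#' @param path Path to the aligned FASTA file.
#' @return Object of class `rd_msa`: list with `labels` and `rows` (equal
#'   length aligned strings; residues, X and the gap character '-').
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  labels <- sub("\\s.*$", "", names(ss))
  rows <- toupper(as.character(ss))
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) {
    ragged <- labels[widths != widths[1]]
    stop("ragged alignment: record(s) ", paste(ragged, collapse = ", "),
         " differ in length from the first record")
  }
  rd_msa(labels, unname(rows))
}

#' Construct a validated alignment object
#'
#' @param labels Unique sequence labels.
#' @param rows Equal-length aligned amino-acid strings.
#' @return Object of class `rd_msa`.
#' @export
rd_msa <- function(labels, rows) {
  stopifnot(length(labels) == length(rows))
  if (anyDuplicated(labels)) stop("alignment labels must be unique")
  if (length(unique(nchar(rows))) > 1L) stop("alignment rows must have equal length")
  structure(list(labels = as.character(labels), rows = toupper(as.character(rows))),
            class = "rd_msa")
}

#' @export
print.rd_msa <- function(x, ...) {
  cat(sprintf("<rd_msa> %d sequence(s) x %d column(s)\n",
              length(x$labels), if (length(x$rows)) nchar(x$rows[1]) else 0L))
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
}

#' Global-alignment percent identity of two protein sequences
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with gap opening 10 and
#' gap extension 0.5 (a gap of length L costs 10 + 0.5 L); identity is
#' 100 x matches / alignment length, with gap columns (including terminal
#' overhangs) counted in the denominator. Symmetric by construction.
#'
#' @param a,b Amino-acid strings.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
  100 * Biostrings::nmatch(pa) / alen
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Pairwise percent-identity matrix
#'
#' @param seqs Named character vector of protein sequences.
#' @return Object of class `rd_identity`: list with `labels` and `values`
#'   (symmetric percent-identity matrix, diagonal 100).
#' @export
identity_matrix <- function(seqs) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      v <- pairwise_identity(seqs[[i]], seqs[[j]])
      m[i, j] <- v; m[j, i] <- v
    }
  }
  structure(list(labels = names(seqs), values = m), class = "rd_identity")
}

#' Ortholog groups at an identity cutoff
#'
#' Groups are the connected components of the graph whose edges join label
#' pairs with identity >= `cutoff` (single linkage): a sequence joins a group
#' when it clears the cutoff to any member. Group ids are dense integers in
#' order of first appearance.
#'
#' @param m An `rd_identity` object or a symmetric percent-identity matrix
#'   with dimnames.
#' @param cutoff Percent identity cutoff (default 90, the community RDase A
#'   ortholog-group convention).
#' @return List with `cutoff` and `assignment` (named integer vector).
#' @export
ortholog_groups <- function(m, cutoff = 90) {
  v <- if (inherits(m, "rd_identity")) m$values else as.matrix(m)
  if (is.null(dimnames(v)[[1]])) stop("identity matrix must carry labels")
  adj <- v >= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  ids <- match(memb, unique(memb))
  list(cutoff = cutoff, assignment = stats::setNames(as.integer(ids), rownames(v)))
}

#' Filter alignment columns by site coverage
#'
#' Retains exactly the columns where the fraction of rows carrying an
#' unambiguous, non-gap residue (not '-' and not X) is at least
#' `min_coverage`. Row order and labels are preserved; the operation is
#' idempotent.
#'
#' @param msa An `rd_msa`.
#' @param min_coverage Minimum site coverage fraction (default 0.60).
#' @return Filtered `rd_msa`; a warning is emitted when no column survives.
#' @export
filter_columns <- function(msa, min_coverage = 0.60) {
  stopifnot(inherits(msa, "rd_msa"))
  m <- msa_matrix(msa)
  ok <- matrix(!(m %in% c("-", "X")), nrow = nrow(m))
  keep <- colMeans(ok) >= min_coverage
  if (!any(keep)) {
    warning("no alignment column reaches the coverage threshold")
    return(rd_msa(msa$labels, rep("", length(msa$labels))))
  }
  kept <- m[, keep, drop = FALSE]
  rd_msa(msa$labels, apply(kept, 1L, paste, collapse = ""))
}

#' Pairwise distances from a filtered alignment
#'
#' The p-distance of a pair is the mismatch fraction over columns where both
#' rows carry an unambiguous, non-gap residue; the Poisson correction is
#' -ln(1 - p).
#'
#' @param msa An `rd_msa` (typically after [filter_columns()]).
#' @param correction `"p"` or `"poisson"`.
#' @return Symmetric labelled distance matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  m <- msa_matrix(msa)
  ok <- matrix(!(m %in% c("-", "X")), nrow = nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(msa$labels, msa$labels))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    comp <- ok[i, ] & ok[j, ]
    if (!any(comp))
      stop(sprintf("no comparable columns between '%s' and '%s'",
                   msa$labels[i], msa$labels[j]))
    p <- mean(m[i, comp] != m[j, comp])
    if (correction == "poisson") {
      if (p >= 1)
        stop(sprintf("saturated pair '%s'/'%s': p-distance 1 has no Poisson correction",
                     msa$labels[i], msa$labels[j]))
      p <- -log(1 - p)
    }
    d[i, j] <- p; d[j, i] <- p
  }
  d
}

format_brlen <- function(x) sprintf("%.15g", x)

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the standard Q criterion and two-point
#' branch-length formulas. Output is bit-deterministic: Q ties are broken on
#' the lexicographically smallest (sorted) leaf-label pair, where each active
#' node is keyed by the smallest leaf label in its subtree; negative branch
#' lengths are clamped to zero with the deficit added to the sister branch so
#' the joined pair's path length is preserved.
#'
#' @param d Symmetric non-negative distance matrix with labels (matrix or
#'   `dist`).
#' @return Unrooted `phylo` tree (trifurcating root for >= 3 taxa).
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  labels <- rownames(m)
  if (is.null(labels)) stop("distance matrix must carry labels")
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa")
  if (any(m < 0)) stop("distances must be non-negative")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
  diag(m) <- 0

  if (n == 2L) {
    h <- m[1, 2] / 2
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1], format_brlen(h),
                   labels[2], format_brlen(h))
    return(ape::read.tree(text = nwk))
  }

  reps <- labels                       # newick representation per active node
  keys <- labels                       # smallest leaf label per active node
  act <- m

  while (nrow(act) > 3L) {
    r <- nrow(act)
    rs <- rowSums(act)
    q <- (r - 2) * act - outer(rs, rs, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1L, function(ij) {
      kk <- sort(c(keys[ij[1]], keys[ij[2]]))
      paste(kk[1], kk[2], sep = "\r")
    })
    sel <- cand[order(pk)[1], ]
    i <- sel[1]; j <- sel[2]
    dij <- act[i, j]
    vi <- 0.5 * dij + (rs[i] - rs[j]) / (2 * (r - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newrep <- sprintf("(%s:%s,%s:%s)", reps[i], format_brlen(vi),
                      reps[j], format_brlen(vj))
    newkey <- min(keys[i], keys[j])
    du <- 0.5 * (act[i, ] + act[j, ] - dij)
    keep <- setdiff(seq_len(r), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
    reps <- c(reps[keep], newrep)
    keys <- c(keys[keep], newkey)
  }

  dab <- act[1, 2]; dac <- act[1, 3]; dbc <- act[2, 3]
  v <- c((dab + dac - dbc) / 2, (dab + dbc - dac) / 2, (dac + dbc - dab) / 2)
  v <- pmax(v, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 reps[1], format_brlen(v[1]), reps[2], format_brlen(v[2]),
                 reps[3], format_brlen(v[3]))
  ape::read.tree(text = nwk)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a tree as Newick
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

# Do the given tips form a split (unrooted monophyly) on the tree?
is_split <- function(tree, tips) {
  nt <- length(tree$tip.label)
  if (length(tips) <= 1L || length(tips) >= nt - 1L) return(TRUE)
  out <- setdiff(tree$tip.label, tips)
  rooted <- ape::root(tree, outgroup = out[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}

#' Assign query leaves to reference clades
#'
#' Each leaf not named in `reference_clades` is assigned the clade of its
#' nearest reference leaf by patristic distance; exact ties between different
#' clades yield `"ambiguous"`. The (unrooted) monophyly of each reference
#' clade on the tree is checked and reported; a non-monophyletic reference
#' clade triggers a warning but assignment proceeds.
#'
#' @param tree A `phylo` tree containing all reference leaves.
#' @param reference_clades Named character vector: leaf label -> clade id.
#' @return List with `assignment` (named character vector over query leaves)
#'   and `monophyletic` (named logical vector over clades).
#' @export
assign_clades <- function(tree, reference_clades) {
  miss <- setdiff(names(reference_clades), tree$tip.label)
  if (length(miss) > 0L)
    stop("reference leaf label(s) absent from tree: ", paste(miss, collapse = ", "))
  D <- ape::cophenetic.phylo(tree)
  queries <- setdiff(tree$tip.label, names(reference_clades))
  assignment <- stats::setNames(character(length(queries)), queries)
  for (q in queries) {
    dr <- D[q, names(reference_clades)]
    nearest <- which(dr <= min(dr) + 1e-12)
    clades <- unique(unname(reference_clades[names(dr)[nearest]]))
    assignment[q] <- if (length(clades) > 1L) "ambiguous" else clades
  }
  clade_ids <- unique(unname(reference_clades))
  mono <- stats::setNames(logical(length(clade_ids)), clade_ids)
  for (cl in clade_ids)
    mono[cl] <- is_split(tree, names(reference_clades)[reference_clades == cl])
  if (any(!mono))
    warning("reference clade(s) not monophyletic on the tree: ",
            paste(names(mono)[!mono], collapse = ", "))
  list(assignment = assignment, monophyletic = mono)
}
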