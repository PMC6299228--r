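# Degenerate sequence motifs: protein motifs with X wildcards and nucleotide
# motifs with IUPAC one-letter codes. Motifs compile to per-position symbol
# sets; scanning reports every overlapping occurrence. An N (nucleotide) or X
# (protein) in the *scanned* sequence matches no motif position -- an
# ambiguous symbol can never certify a motif.

IUPAC_NUC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

motif_symbol_sets <- function(pattern, alphabet) {
  cs <- chars(toupper(pattern))
  if (alphabet == "nucleotide") {
    ok <- cs %in% names(IUPAC_NUC)
    if (any(!ok)) {
      i <- which(!ok)[1]
      stop(sprintf("illegal nucleotide motif symbol '%s' at position %d", cs[i], i))
    }
    lapply(cs, function(s) IUPAC_NUC[[s]])
  } else if (alphabet == "protein") {
    ok <- cs %in% c(AA20, "X")
    if (any(!ok)) {
      i <- which(!ok)[1]
      stop(sprintf("illegal protein motif symbol '%s' at position %d", cs[i], i))
    }
    lapply(cs, function(s) if (s == "X") AA20 else s)
  } else stop("alphabet must be 'protein' or 'nucleotide'")
}

#' Compile a degenerate sequence motif
#'
#' Validates the pattern against its alphabet and precomputes the regular
#' expression used by [scan_motif()] together with the motif degeneracy (the
#' product of per-position option counts).
#'
#' @param name Motif name.
#' @param pattern Motif string. Protein alphabet: the 20 standard residues
#'   plus the wildcard X. Nucleotide alphabet: IUPAC codes
#'   A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return An object of class `rd_motif` with fields `name`, `pattern`,
#'   `alphabet`, `length`, `degeneracy` and `regex`.
#' @export
compile_motif <- function(name, pattern, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(pattern)) stop("motif pattern must be non-empty")
  sets <- motif_symbol_sets(pattern, alphabet)
  regex <- paste(vapply(sets, function(s) paste0("[", paste(s, collapse = ""), "]"),
                        character(1)), collapse = "")
  structure(list(name = name, pattern = toupper(pattern), alphabet = alphabet,
                 length = length(sets), degeneracy = prod(lengths(sets)),
                 sets = sets, regex = regex),
            class = "rd_motif")
}

#' @export
print.rd_motif <- function(x, ...) {
  cat(sprintf("<rd_motif> %s (%s): %s, degeneracy %g\n",
              x$name, x$alphabet, x$pattern, x$degeneracy))
  invisible(x)
}

validate_scan_sequence <- function(sequence, alphabet) {
  allowed <- if (alphabet == "nucleotide") c(DNA_BASES, "N") else c(AA20, "X")
  bad <- bad_symbols(sequence, allowed)
  if (nrow(bad) > 0L)
    stop(sprintf("scanned sequence contains symbol '%s' (position %d) outside the %s alphabet",
                 bad$symbol[1], bad$position[1], alphabet))
}

scan_one_strand <- function(sequence, motif) {
  if (nchar(sequence) < motif$length) return(integer())
  m <- gregexpr(paste0("(?=", motif$regex, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  as.integer(m)
}

#' Scan a sequence for all overlapping motif occurrences
#'
#' Reports every overlapping match in ascending offset order. With
#' `both_strands = TRUE` (nucleotide motifs only) the reverse complement is
#' scanned as well and minus-strand hits are reported with their offset
#' mapped to the forward coordinate of the match start; the `matched` string
#' is the concrete sequence as read on the minus strand.
#'
#' @param sequence Sequence to scan (uppercased internally).
#' @param motif An `rd_motif` from [compile_motif()].
#' @param both_strands Also scan the reverse complement (nucleotide only).
#' @param sequence_id Identifier copied into the result.
#' @return data.frame with columns `sequence_id`, `offset` (0-based match
#'   start), `strand` and `matched`.
#' @export
scan_motif <- function(sequence, motif, both_strands = FALSE, sequence_id = "seq") {
  stopifnot(inherits(motif, "rd_motif"))
  sequence <- toupper(sequence)
  validate_scan_sequence(sequence, motif$alphabet)
  if (both_strands && motif$alphabet != "nucleotide")
    stop("both_strands scanning applies to nucleotide motifs only")

  plen <- motif$length
  pos <- scan_one_strand(sequence, motif)
  out <- data.frame(sequence_id = rep(sequence_id, length(pos)),
                    offset = pos - 1L,
                    strand = rep("+", length(pos)),
                    matched = if (length(pos)) substring(sequence, pos, pos + plen - 1L) else character(),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- revcomp(sequence)
    n <- nchar(sequence)
    pos2 <- scan_one_strand(rc, motif)
    if (length(pos2) > 0L) {
      out2 <- data.frame(sequence_id = rep(sequence_id, length(pos2)),
                         offset = n - (pos2 - 1L) - plen,
                         strand = rep("-", length(pos2)),
                         matched = substring(rc, pos2, pos2 + plen - 1L),
                         stringsAsFactors = FALSE)
      out <- rbind(out, out2)
    }
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand a degenerate motif into all concrete strings it denotes
#'
#' Used as the brute-force oracle for [scan_motif()]: scanning equals the
#' union of plain substring searches over the expansion. Refuses motifs whose
#' degeneracy exceeds `limit`.
#'
#' @param motif An `rd_motif`.
#' @param limit Maximum degeneracy to expand.
#' @return Sorted character vector of concrete strings.
#' @export
expand_motif <- function(motif, limit = 10000) {
  stopifnot(inherits(motif, "rd_motif"))
  if (motif$degeneracy > limit)
    stop(sprintf("motif '%s' denotes %.0f concrete strings, above the expansion limit of %.0f",
                 motif$name, motif$degeneracy, limit))
  out <- ""
  for (s in motif$sets) out <- as.vector(outer(out, s, paste0))
  sort(out)
}

#' Built-in motif registry
#'
#' The motifs used throughout the screening pipeline:
#' \describe{
#'   \item{tat}{RRXFXK — twin-arginine (Tat) export signal, protein.}
#'   \item{fes_long}{CXXCXXCXXXCP — first iron-sulfur cluster binding motif, protein.}
#'   \item{fes_short}{CXXCXXXCP — second iron-sulfur cluster binding motif, protein.}
#'   \item{sigma54_core}{YTGGCACGRNNNTTGC — sigma-54 (-24/-12) promoter element, nucleotide; the default used in promoter scans.}
#'   \item{sigma54_extended}{YTGGCACGRNNNTTGCW — 17-mer variant with a degenerate trailing W.}
#' }
#'
#' @return Named list of compiled `rd_motif` objects.
#' @export
motif_registry <- function() {
  list(
    tat = compile_motif("tat", "RRXFXK", "protein"),
    fes_long = compile_motif("fes_long", "CXXCXXCXXXCP", "protein"),
    fes_short = compile_motif("fes_short", "CXXCXXXCP", "protein"),
    sigma54_core = compile_motif("sigma54_core", "YTGGCACGRNNNTTGC", "nucleotide"),
    sigma54_extended = compile_motif("sigma54_extended", "YTGGCACGRNNNTTGCW", "nucleotide"))
}
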