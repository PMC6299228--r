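# Genome container and I/O: GenBank flat files, GFF3+FASTA pairs, CDS
# translation and upstream (promoter) window extraction.
#
# Coordinates are 1-based inclusive everywhere, the native convention of both
# GenBank and GFF3; no half-open conversion happens internally.

GENOME_FEATURE_COLS <- c("contig_id", "start", "end", "strand",
                         "locus_tag", "product", "translation", "phase")

#' Construct a validated genome object
#'
#' A genome is a set of named contig sequences plus a table of stranded,
#' 1-based-inclusive gene (CDS) features. Validation enforces the container
#' invariants: sequences restricted to A/C/G/T/N, features inside their
#' contig, unique locus tags, translations drawn from the 20 standard
#' residues plus X, and features sorted by (contig, start).
#'
#' @param genome_id Identifier for the genome (character scalar).
#' @param contigs Named character vector of nucleotide sequences.
#' @param features data.frame with columns `contig_id`, `start`, `end`,
#'   `strand` ("+"/"-"), `locus_tag`, `product`, `translation` (NA allowed),
#'   and optionally `phase`.
#' @return An object of class `rd_genome`: a list with elements `genome_id`,
#'   `contigs` and `features`.
#' @export
rd_genome <- function(genome_id, contigs, features) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  contigs <- vapply(contigs, toupper, character(1))
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == ""))
    stop("contigs must be a named character vector")
  for (id in names(contigs)) {
    bad <- bad_symbols(contigs[[id]], c(DNA_BASES, "N"))
    if (nrow(bad) > 0L)
      stop(sprintf(
        "contig '%s' contains unsupported nucleotide code(s) %s at position(s) %s; only A/C/G/T/N are accepted",
        id, paste(unique(bad$symbol), collapse = ","),
        paste(utils::head(bad$position, 5L), collapse = ",")))
  }

  if (is.null(features) || nrow(features) == 0L) {
    features <- data.frame(contig_id = character(), start = integer(),
                           end = integer(), strand = character(),
                           locus_tag = character(), product = character(),
                           translation = character(), phase = character(),
                           stringsAsFactors = FALSE)
  }
  if (!"phase" %in% names(features)) features$phase <- NA_character_
  features <- features[, GENOME_FEATURE_COLS]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  for (col in c("contig_id", "strand", "locus_tag", "product", "translation", "phase"))
    features[[col]] <- as.character(features[[col]])

  if (nrow(features) > 0L) {
    if (any(!features$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'")
    if (any(features$start < 1L) || any(features$start > features$end))
      stop("feature coordinates must satisfy 1 <= start <= end")
    miss <- setdiff(unique(features$contig_id), names(contigs))
    if (length(miss) > 0L)
      stop("features reference unknown contig(s): ", paste(miss, collapse = ", "))
    clen <- nchar(contigs)[features$contig_id]
    if (any(features$end > clen)) {
      off <- features$locus_tag[features$end > clen]
      stop("feature(s) extend beyond contig bounds: ", paste(off, collapse = ", "))
    }
    if (anyDuplicated(features$locus_tag))
      stop("duplicate locus_tag(s): ",
           paste(unique(features$locus_tag[duplicated(features$locus_tag)]), collapse = ", "))
    tr <- features$translation
    for (i in which(!is.na(tr))) {
      aa <- sub("\\*$", "", tr[i])
      bad <- bad_symbols(aa, c(AA20, "X"))
      if (nrow(bad) > 0L)
        stop(sprintf("translation of '%s' contains illegal residue '%s' at position %d",
                     features$locus_tag[i], bad$symbol[1], bad$position[1]))
      features$translation[i] <- aa
    }
    features <- features[order(features$contig_id, features$start,
                               features$end, features$locus_tag), , drop = FALSE]
    rownames(features) <- NULL
  }

  structure(list(genome_id = genome_id, contigs = contigs, features = features),
            class = "rd_genome")
}

#' @export
print.rd_genome <- function(x, ...) {
  cat(sprintf("<rd_genome> %s: %d contig(s), %d bp, %d CDS feature(s)\n",
              x$genome_id, length(x$contigs), sum(nchar(x$contigs)),
              nrow(x$features)))
  invisible(x)
}

# Resolve a feature argument (locus_tag string, or a one-row data.frame /
# list carrying a locus_tag) to the stored feature row.
resolve_feature <- function(genome, feature) {
  if (is.character(feature) && length(feature) == 1L) {
    tag <- feature
  } else if (!is.null(feature$locus_tag)) {
    tag <- as.character(feature$locus_tag[1])
  } else stop("feature must be a locus_tag or an object with a locus_tag field")
  i <- match(tag, genome$features$locus_tag)
  if (is.na(i)) stop("locus_tag not found in genome: ", tag)
  as.list(genome$features[i, ])
}

#' Look up a gene feature by locus tag
#'
#' @param genome An `rd_genome`.
#' @param locus_tag Locus tag of the feature.
#' @return The feature as a named list.
#' @export
genome_feature <- function(genome, locus_tag) resolve_feature(genome, locus_tag)

## ---------------------------------------------------------------------------
## GenBank flat-file I/O (minimal subset: LOCUS / FEATURES with simple CDS
## locations / ORIGIN). Compound (join/order) locations are rejected: the
## package targets bacterial single-exon CDS only.
## ---------------------------------------------------------------------------

#' Read an annotated genome from a GenBank flat file
#'
#' Parses a (possibly multi-record) GenBank flat file, keeping one feature per
#' CDS. `/locus_tag`, `/product` and `/translation` qualifiers are captured
#' when present; records become contigs. Only simple `start..end` and
#' `complement(start..end)` locations are supported.
#'
#' @param path Path to the GenBank file.
#' @return An [rd_genome()] object.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty GenBank file: ", path)
  ends <- which(trimws(lines) == "//")
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  contigs <- character()
  feats <- list()
  n_cds <- 0L
  for (r in seq_along(starts)) {
    rl <- lines[starts[r]:ends[r]]
    rl <- rl[trimws(rl) != "//"]
    if (all(trimws(rl) == "")) next
    line0 <- starts[r]
    locus_i <- which(startsWith(rl, "LOCUS"))
    if (length(locus_i) == 0L)
      stop(sprintf("malformed GenBank record starting at line %d: missing LOCUS line", line0))
    toks <- strsplit(trimws(rl[locus_i[1]]), "\\s+")[[1]]
    if (length(toks) < 2L)
      stop(sprintf("malformed LOCUS line at line %d", line0 + locus_i[1] - 1L))
    contig_id <- toks[2]

    origin_i <- which(startsWith(rl, "ORIGIN"))
    seq <- ""
    if (length(origin_i) > 0L) {
      sl <- rl[(origin_i[1] + 1L):length(rl)]
      seq <- toupper(gsub("[0-9 \t]", "", paste(sl, collapse = "")))
    }
    contigs[contig_id] <- seq

    feat_i <- which(startsWith(rl, "FEATURES"))
    if (length(feat_i) == 0L) next
    last <- if (length(origin_i) > 0L) origin_i[1] - 1L else length(rl)
    fl <- rl[(feat_i[1] + 1L):last]
    fl_line0 <- line0 + feat_i[1]

    # Feature table: a new feature has its key in columns 6-20; qualifier and
    # continuation lines are indented to column 22.
    is_new <- grepl("^ {5}\\S", fl)
    idx <- which(is_new)
    for (k in seq_along(idx)) {
      hdr <- fl[idx[k]]
      key <- sub("^ {5}(\\S+).*$", "\\1", hdr)
      if (key != "CDS") next
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(fl)
      body <- fl[idx[k]:to]
      lineno <- fl_line0 + idx[k] - 1L

      loc <- trimws(sub("^ {5}\\S+\\s*", "", body[1]))
      # location may wrap; qualifier lines start with '/'
      j <- 2L
      while (j <= length(body) && !grepl("^\\s*/", body[j])) {
        loc <- paste0(loc, trimws(body[j])); j <- j + 1L
      }
      loc <- gsub("[<>]", "", loc)
      if (grepl("join|order", loc))
        stop(sprintf("compound CDS location not supported (line %d): %s", lineno, loc))
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      locnum <- sub("^complement\\((.*)\\)$", "\\1", loc)
      m <- regmatches(locnum, regexec("^(\\d+)\\.\\.(\\d+)$", locnum))[[1]]
      if (length(m) != 3L) {
        m1 <- regmatches(locnum, regexec("^(\\d+)$", locnum))[[1]]
        if (length(m1) == 2L) m <- c(m1[1], m1[2], m1[2])
        else stop(sprintf("cannot parse CDS location at line %d: %s", lineno, loc))
      }

      # Qualifiers: split the remaining lines into /name=value chunks.
      quals <- list()
      cur <- NULL
      for (q in body[seq.int(j, length.out = max(0L, length(body) - j + 1L))]) {
        qt <- trimws(q)
        if (startsWith(qt, "/")) {
          if (!is.null(cur)) quals[[length(quals) + 1L]] <- cur
          cur <- qt
        } else if (!is.null(cur)) cur <- c(cur, qt)
      }
      if (!is.null(cur)) quals[[length(quals) + 1L]] <- cur
      qv <- list()
      for (qq in quals) {
        first <- sub("^/", "", qq[1])
        eq <- regexpr("=", first, fixed = TRUE)
        if (eq == -1L) { qv[[first]] <- TRUE; next }
        name <- substr(first, 1L, eq - 1L)
        val <- c(substr(first, eq + 1L, nchar(first)), qq[-1])
        val <- if (name == "translation") paste(val, collapse = "") else paste(val, collapse = " ")
        qv[[name]] <- gsub("\"", "", val)
      }

      n_cds <- n_cds + 1L
      feats[[length(feats) + 1L]] <- data.frame(
        contig_id = contig_id,
        start = as.integer(m[2]), end = as.integer(m[3]), strand = strand,
        locus_tag = qv$locus_tag %||% qv$gene %||% sprintf("cds_%04d", n_cds),
        product = qv$product %||% NA_character_,
        translation = qv$translation %||% NA_character_,
        phase = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (n_cds == 0L) warning("no CDS features found in ", path)
  features <- if (length(feats) > 0L) do.call(rbind, feats) else NULL
  rd_genome(tools::file_path_sans_ext(basename(path)), contigs, features)
}

wrap_qualifier <- function(name, value, width = 58L) {
  txt <- sprintf("/%s=\"%s\"", name, value)
  out <- character()
  while (nchar(txt) > width) {
    out <- c(out, substr(txt, 1L, width))
    txt <- substr(txt, width + 1L, nchar(txt))
  }
  paste0(strrep(" ", 21L), c(out, txt))
}

#' Write a genome as a GenBank flat file
#'
#' Emits one record per contig with simple CDS features; the inverse of
#' [read_genbank()] for the subset of GenBank this package uses.
#'
#' @param genome An `rd_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cid in names(genome$contigs)) {
    seq <- genome$contigs[[cid]]
    writeLines(sprintf("LOCUS       %-17s %d bp    DNA     linear   BCT 01-JAN-2026",
                       cid, nchar(seq)), con)
    writeLines(sprintf("DEFINITION  %s contig %s.", genome$genome_id, cid), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", nchar(seq)), con)
    ff <- genome$features[genome$features$contig_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(ff))) {
      loc <- sprintf("%d..%d", ff$start[i], ff$end[i])
      if (ff$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(wrap_qualifier("locus_tag", ff$locus_tag[i]), con)
      if (!is.na(ff$product[i]))
        writeLines(wrap_qualifier("product", ff$product[i]), con)
      if (!is.na(ff$translation[i]))
        writeLines(wrap_qualifier("translation", ff$translation[i]), con)
    }
    writeLines("ORIGIN", con)
    if (nchar(seq) > 0L) {
      pos <- seq(1L, nchar(seq), by = 60L)
      for (p in pos) {
        blk <- substr(seq, p, min(p + 59L, nchar(seq)))
        tens <- substring(blk, seq(1L, nchar(blk), 10L),
                          pmin(seq(10L, nchar(blk) + 9L, 10L), nchar(blk)))
        writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## GFF3 + FASTA
## ---------------------------------------------------------------------------

#' Read an annotated genome from a GFF3 + FASTA pair
#'
#' CDS records in the GFF3 are matched against the FASTA contigs; GFF3
#' 1-based inclusive coordinates are preserved unchanged. The `locus_tag`
#' attribute is used when present, falling back to `ID`. The phase column is
#' recorded but never used for feature extent.
#'
#' @param gff Path to the GFF3 file.
#' @param fasta Path to the contig FASTA file.
#' @return An [rd_genome()] object.
#' @export
read_gff3_fasta <- function(gff, fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff)
  df <- as.data.frame(gr)
  df <- df[as.character(df$type) == "CDS", , drop = FALSE]
  if (nrow(df) == 0L) warning("no CDS features found in ", gff)
  miss <- setdiff(unique(as.character(df$seqnames)), names(seqs))
  if (length(miss) > 0L)
    stop("GFF3 seqid(s) absent from FASTA: ", paste(miss, collapse = ", "))

  get_attr <- function(col) {
    if (col %in% names(df)) as.character(df[[col]]) else rep(NA_character_, nrow(df))
  }
  locus <- get_attr("locus_tag")
  id <- get_attr("ID")
  locus[is.na(locus)] <- id[is.na(locus)]
  strand <- as.character(df$strand)
  if (any(!strand %in% c("+", "-")))
    stop("GFF3 CDS records must be stranded (+/-)")
  features <- data.frame(
    contig_id = as.character(df$seqnames),
    start = df$start, end = df$end, strand = strand,
    locus_tag = locus, product = get_attr("product"),
    translation = get_attr("translation"),
    phase = get_attr("phase"), stringsAsFactors = FALSE)
  rd_genome(tools::file_path_sans_ext(basename(fasta)),
            stats::setNames(as.character(seqs), names(seqs)), features)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x
}

#' Write a genome as a GFF3 + FASTA pair
#'
#' @param genome An `rd_genome`.
#' @param gff Output GFF3 path.
#' @param fasta Output FASTA path.
#' @return Invisibly, `c(gff, fasta)`.
#' @export
write_gff3_fasta <- function(genome, gff, fasta) {
  lines <- "##gff-version 3"
  for (cid in names(genome$contigs))
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", cid, nchar(genome$contigs[[cid]])))
  ff <- genome$features
  for (i in seq_len(nrow(ff))) {
    attrs <- sprintf("ID=%s;locus_tag=%s", gff3_escape(ff$locus_tag[i]),
                     gff3_escape(ff$locus_tag[i]))
    if (!is.na(ff$product[i]))
      attrs <- paste0(attrs, ";product=", gff3_escape(ff$product[i]))
    lines <- c(lines, paste(ff$contig_id[i], "dehaloscout", "CDS",
                            ff$start[i], ff$end[i], ".", ff$strand[i], "0",
                            attrs, sep = "\t"))
  }
  writeLines(lines, gff)
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, fasta, width = 70L)
  invisible(c(gff, fasta))
}

## ---------------------------------------------------------------------------
## Translation and upstream windows
## ---------------------------------------------------------------------------

# NCBI translation table 11 alternative initiation codons.
TABLE11_STARTS <- c("ATG", "GTG", "TTG", "CTG", "ATT", "ATC", "ATA")

#' Translate a CDS feature with the bacterial genetic code
#'
#' Returns the stored `/translation` verbatim when present (trailing stop
#' stripped). Otherwise the coding sequence is extracted (reverse-complemented
#' for minus-strand features) and translated with NCBI table 11; an
#' alternative initiation codon at position 1 is rendered as M and a trailing
#' stop is removed. Ambiguous (N-containing) codons translate to X.
#'
#' @param genome An `rd_genome`.
#' @param feature Locus tag or feature row.
#' @return Amino-acid string.
#' @export
translate_cds <- function(genome, feature) {
  f <- resolve_feature(genome, feature)
  if (!is.na(f$translation)) return(sub("\\*$", "", f$translation))
  s <- substr(genome$contigs[[f$contig_id]], f$start, f$end)
  if (f$strand == "-") s <- revcomp(s)
  n <- nchar(s)
  if (n %% 3L != 0L)
    stop(sprintf("CDS length of '%s' (%d bp) is not divisible by 3", f$locus_tag, n))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(s),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
  aav <- chars(aa)
  if (aav[length(aav)] == "*") aav <- aav[-length(aav)]
  stops <- which(aav == "*")
  if (length(stops) > 0L)
    stop(sprintf("internal stop codon in '%s' at codon position %d",
                 f$locus_tag, stops[1]))
  if (substr(s, 1L, 3L) %in% TABLE11_STARTS) aav[1] <- "M"
  paste(aav, collapse = "")
}

#' Extract the upstream (promoter) window of a gene
#'
#' Returns up to `max_bp` of sequence immediately 5' of the start codon in
#' the gene's reading orientation (reverse-complemented for minus-strand
#' genes), truncated at the contig edge. Genome-frame coordinates of the
#' window are reported alongside.
#'
#' @param genome An `rd_genome`.
#' @param feature Locus tag or feature row.
#' @param max_bp Maximum window size in bp (>= 1).
#' @return A list with `sequence` (oriented 5'->3' towards the start codon),
#'   `contig_id`, `start`, `end` (genome frame, NA when empty) and `strand`.
#' @export
upstream_region <- function(genome, feature, max_bp) {
  stopifnot(is.numeric(max_bp), max_bp >= 1)
  f <- resolve_feature(genome, feature)
  ctg <- genome$contigs[[f$contig_id]]
  if (f$strand == "+") {
    e <- f$start - 1L
    s <- max(1L, f$start - as.integer(max_bp))
    if (e < s)
      return(list(sequence = "", contig_id = f$contig_id,
                  start = NA_integer_, end = NA_integer_, strand = "+"))
    list(sequence = substr(ctg, s, e), contig_id = f$contig_id,
         start = s, end = e, strand = "+")
  } else {
    s <- f$end + 1L
    e <- min(nchar(ctg), f$end + as.integer(max_bp))
    if (e < s)
      return(list(sequence = "", contig_id = f$contig_id,
                  start = NA_integer_, end = NA_integer_, strand = "-"))
    list(sequence = revcomp(substr(ctg, s, e)), contig_id = f$contig_id,
         start = s, end = e, strand = "-")
  }
}

#' Reverse-complement an entire genome
#'
#' Mirrors every contig and flips feature strands/coordinates accordingly.
#' Screening results must be invariant under this transformation (up to
#' coordinate mirroring), which the test suite exploits.
#'
#' @param genome An `rd_genome`.
#' @return The mirrored `rd_genome`.
#' @export
revcomp_genome <- function(genome) {
  contigs <- vapply(genome$contigs, revcomp, character(1))
  ff <- genome$features
  if (nrow(ff) > 0L) {
    L <- nchar(genome$contigs)[ff$contig_id]
    s <- L - ff$end + 1L
    e <- L - ff$start + 1L
    ff$start <- as.integer(s)
    ff$end <- as.integer(e)
    ff$strand <- ifelse(ff$strand == "+", "-", "+")
  }
  rd_genome(genome$genome_id, contigs, ff)
}
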