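# Candidate RDase A calling and gene-cluster characterization.
#
# A respiratory reductive dehalogenase operon typically encodes the catalytic
# subunit (RDase A, with a twin-arginine export signal and two Fe-S cluster
# binding motifs), a small hydrophobic membrane anchor (RDase B) immediately
# downstream, and often a sigma-54-dependent transcriptional activator (bEBP)
# nearby, with a sigma-54 -24/-12 element in the operon promoter.

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

RDASE_B_KEYWORDS <- c("reductive dehalogenase", "anchoring", "rdhb", "membrane")
BEBP_KEYWORDS <- c("sigma-54", "sigma 54", "rpon", "fis family")

# Count sliding windows of the given width whose mean Kyte-Doolittle
# hydropathy reaches `threshold`. X residues score 0.
hydropathy_windows <- function(protein, width = 19L, threshold = 1.6) {
  aa <- chars(toupper(protein))
  v <- unname(KD_SCALE[aa])
  v[is.na(v)] <- 0
  n <- length(v)
  if (n < width) return(0L)
  cs <- cumsum(c(0, v))
  means <- (cs[(width + 1L):(n + 1L)] - cs[1:(n - width + 1L)]) / width
  sum(means >= threshold)
}

#' Find the twin-arginine (Tat) export signal near the N terminus
#'
#' Returns the first RRXFXK match whose 0-based start offset is below
#' `window`, or NULL when absent. The N-terminal restriction reflects the
#' biology: the Tat signal is part of the export leader peptide.
#'
#' @param protein Amino-acid string.
#' @param window Number of N-terminal residues searched (default 45).
#' @return One-row hit data.frame (as from [scan_motif()]) or NULL.
#' @export
find_tat_signal <- function(protein, window = 45L) {
  stopifnot(nzchar(protein))
  hits <- scan_motif(protein, compile_motif("tat", "RRXFXK", "protein"),
                     sequence_id = "protein")
  hits <- hits[hits$offset < window, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  hits[1L, , drop = FALSE]
}

#' Find the two iron-sulfur cluster binding motifs
#'
#' Reports the first occurrence of each of CXXCXXCXXXCP (`fes_long`) and
#' CXXCXXXCP (`fes_short`) anywhere in the sequence; overlapping occurrences
#' are reported independently (note that any long-motif instance contains a
#' short-motif instance at offset +3).
#'
#' @param protein Amino-acid string.
#' @return List with elements `fes_long` and `fes_short`, each a one-row hit
#'   data.frame or NULL.
#' @export
find_fes_motifs <- function(protein) {
  stopifnot(nzchar(protein))
  reg <- motif_registry()
  first_hit <- function(m) {
    h <- scan_motif(protein, m, sequence_id = "protein")
    if (nrow(h) == 0L) NULL else h[1L, , drop = FALSE]
  }
  list(fes_long = first_hit(reg$fes_long), fes_short = first_hit(reg$fes_short))
}

#' Read an external domain-hit table
#'
#' TSV with columns `locus_tag`, `domain_id`, `score` (hmmscan-style summary).
#' Rows whose `domain_id` is pfam13486 / PF13486 (case-insensitive) mark genes
#' carrying the reductive dehalogenase subunit domain.
#'
#' @param path Path to the TSV file.
#' @return data.frame with the three columns.
#' @export
read_domain_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus_tag", "domain_id")
  if (!all(need %in% names(df)))
    stop("domain table must have columns locus_tag and domain_id")
  df
}

domain_hit_tags <- function(domain_table, genome) {
  if (is.null(domain_table)) return(character())
  df <- if (is.character(domain_table)) read_domain_table(domain_table) else domain_table
  unknown <- setdiff(unique(df$locus_tag), genome$features$locus_tag)
  if (length(unknown) > 0L)
    stop("domain table references unknown locus_tag(s): ",
         paste(unknown, collapse = ", "))
  hit <- tolower(df$domain_id) %in% c("pfam13486", "pf13486")
  unique(df$locus_tag[hit])
}

# Protein sequence for a feature, or NA when it cannot be obtained
# (e.g. CDS length not divisible by 3 on a malformed annotation).
feature_protein <- function(genome, feature) {
  tryCatch(translate_cds(genome, feature), error = function(e) NA_character_)
}

#' Call candidate RDase A genes in a genome
#'
#' A gene is called when (a) it is listed with the reductive dehalogenase
#' domain in an external domain-hit table, or (b) both Fe-S cluster binding
#' motifs are present in its protein and the protein length lies within
#' `[min_len, max_len]`. The Tat signal is recorded as evidence but never
#' required (it is absent from a substantial fraction of genuine RDase As,
#' which are then cytoplasmic candidates).
#'
#' @param genome An `rd_genome`.
#' @param domain_table Optional path to, or data.frame of, a domain-hit table
#'   (see [read_domain_table()]).
#' @param min_len,max_len Protein length bounds for motif-based calls
#'   (defaults 250 and 750 aa).
#' @param require_both_fes Require both Fe-S motifs for a motif-based call
#'   (default TRUE); set FALSE to accept either one for sensitivity studies.
#' @param tat_window N-terminal window for the Tat signal (residues).
#' @return data.frame with one row per candidate, ordered by genome
#'   coordinate: locus/coordinates, `protein_length`, motif evidence offsets
#'   (`tat_offset`, `fes_long_offset`, `fes_short_offset`; NA when absent),
#'   `external_domain_hit` and `call_basis` (motif/external/both). The policy
#'   parameters are attached as the `"policy"` attribute.
#' @export
call_rdase_candidates <- function(genome, domain_table = NULL,
                                  min_len = 250L, max_len = 750L,
                                  require_both_fes = TRUE, tat_window = 45L) {
  ext_tags <- domain_hit_tags(domain_table, genome)
  ff <- genome$features
  rows <- list()
  for (i in seq_len(nrow(ff))) {
    tag <- ff$locus_tag[i]
    prot <- feature_protein(genome, tag)
    external <- tag %in% ext_tags
    tat <- fes <- NULL
    plen <- NA_integer_
    motif_call <- FALSE
    if (!is.na(prot) && nzchar(prot)) {
      plen <- nchar(prot)
      tat <- find_tat_signal(prot, tat_window)
      fes <- find_fes_motifs(prot)
      fes_ok <- if (require_both_fes) {
        !is.null(fes$fes_long) && !is.null(fes$fes_short)
      } else {
        !is.null(fes$fes_long) || !is.null(fes$fes_short)
      }
      motif_call <- fes_ok && plen >= min_len && plen <= max_len
    }
    if (!motif_call && !external) next
    rows[[length(rows) + 1L]] <- data.frame(
      locus_tag = tag, contig_id = ff$contig_id[i],
      start = ff$start[i], end = ff$end[i], strand = ff$strand[i],
      protein_length = plen,
      tat_offset = if (is.null(tat)) NA_integer_ else tat$offset,
      fes_long_offset = if (is.null(fes) || is.null(fes$fes_long)) NA_integer_ else fes$fes_long$offset,
      fes_short_offset = if (is.null(fes) || is.null(fes$fes_short)) NA_integer_ else fes$fes_short$offset,
      external_domain_hit = external,
      call_basis = if (motif_call && external) "both" else if (external) "external" else "motif",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(locus_tag = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character(),
               protein_length = integer(), tat_offset = integer(),
               fes_long_offset = integer(), fes_short_offset = integer(),
               external_domain_hit = logical(), call_basis = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$contig_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "policy") <- list(min_len = min_len, max_len = max_len,
                              require_both_fes = require_both_fes,
                              tat_window = tat_window)
  out
}

# Index of a locus tag among the (sorted) features of its contig; returns
# list(feats = contig features, idx = index).
contig_neighborhood <- function(genome, locus_tag) {
  f <- resolve_feature(genome, locus_tag)
  feats <- genome$features[genome$features$contig_id == f$contig_id, , drop = FALSE]
  rownames(feats) <- NULL
  list(feats = feats, idx = match(f$locus_tag, feats$locus_tag), anchor = f)
}

#' Locate the RDase B membrane-anchor gene near a candidate
#'
#' Searches up to `gene_window` genes on each side of the candidate on the
#' same contig. A gene qualifies as RDase B if (i) its product annotation
#' matches the RDase B keyword list and the protein is small
#' (<= `max_len` aa), or (ii) by the hydropathy heuristic: protein
#' <= `max_len` aa with at least `min_windows` sliding windows of
#' `kd_window` residues whose mean Kyte-Doolittle hydropathy reaches
#' `kd_threshold` (a putative membrane anchor). The heuristic thresholds are
#' echoed in the result. Position is classified relative to the candidate's
#' reading orientation (downstream = 3' of RDase A); when two genes qualify,
#' the nearest wins and at equal distance downstream wins.
#'
#' @param genome An `rd_genome`.
#' @param candidate Candidate locus tag (or a candidate row).
#' @param gene_window Genes searched each side (default 3).
#' @param keywords Product keyword list (matched case-insensitively).
#' @param max_len Maximum RDase B protein length in aa (default 130).
#' @param kd_window,kd_threshold,min_windows Hydropathy heuristic parameters.
#' @return List: `status` ("downstream"/"upstream"/"absent"), `locus_tag`,
#'   `gene_distance` (intervening genes), `bp_gap`, `rule`
#'   ("annotation"/"hydropathy"), and `parameters`.
#' @export
locate_rdase_b <- function(genome, candidate, gene_window = 3L,
                           keywords = RDASE_B_KEYWORDS, max_len = 130L,
                           kd_window = 19L, kd_threshold = 1.6,
                           min_windows = 2L) {
  nb <- contig_neighborhood(genome, candidate)
  feats <- nb$feats; ci <- nb$idx
  params <- list(gene_window = gene_window, max_len = max_len,
                 kd_window = kd_window, kd_threshold = kd_threshold,
                 min_windows = min_windows)
  js <- setdiff(seq(max(1L, ci - gene_window), min(nrow(feats), ci + gene_window)), ci)
  found <- list()
  for (j in js) {
    prot <- feature_protein(genome, feats$locus_tag[j])
    if (is.na(prot)) next
    plen <- nchar(prot)
    if (plen > max_len) next
    prod <- tolower(feats$product[j] %||% "")
    kw <- !is.na(feats$product[j]) &&
      any(vapply(keywords, function(k) grepl(k, prod, fixed = TRUE), logical(1)))
    hyd <- hydropathy_windows(prot, kd_window, kd_threshold) >= min_windows
    if (!kw && !hyd) next
    downstream <- if (nb$anchor$strand == "+") j > ci else j < ci
    bp_gap <- if (j > ci) feats$start[j] - feats$end[ci] - 1L else feats$start[ci] - feats$end[j] - 1L
    found[[length(found) + 1L]] <- list(
      locus_tag = feats$locus_tag[j],
      status = if (downstream) "downstream" else "upstream",
      gene_distance = abs(j - ci) - 1L, bp_gap = bp_gap,
      rule = if (kw) "annotation" else "hydropathy")
  }
  if (length(found) == 0L)
    return(list(status = "absent", locus_tag = NA_character_,
                gene_distance = NA_integer_, bp_gap = NA_integer_,
                rule = NA_character_, parameters = params))
  dist <- vapply(found, function(x) x$gene_distance, integer(1))
  down <- vapply(found, function(x) x$status == "downstream", logical(1))
  best <- order(dist, !down)[1]
  c(found[[best]], list(parameters = params))
}

#' Locate regulator genes near a candidate
#'
#' Within `gene_window` genes on each side, reports sigma-54-dependent
#' transcriptional activator (bEBP) genes -- by product annotation keyword,
#' or by the auxiliary GAFTGA heuristic (the invariant hexapeptide of the
#' bEBP AAA+ domain; heuristic calls are labelled as such in the `basis`
#' column) -- and flags MarR and CRP/FNR family regulators by annotation.
#'
#' @param genome An `rd_genome`.
#' @param candidate Candidate locus tag (or candidate row).
#' @param gene_window Genes searched each side (default 5).
#' @return List: `bebp` (data.frame locus_tag/basis), `marr_flag`,
#'   `crp_fnr_flag`, `parameters`.
#' @export
locate_regulators <- function(genome, candidate, gene_window = 5L) {
  nb <- contig_neighborhood(genome, candidate)
  feats <- nb$feats; ci <- nb$idx
  js <- setdiff(seq(max(1L, ci - gene_window), min(nrow(feats), ci + gene_window)), ci)
  bebp <- data.frame(locus_tag = character(), basis = character(),
                     stringsAsFactors = FALSE)
  marr <- FALSE; crp_fnr <- FALSE
  for (j in js) {
    prod <- tolower(feats$product[j] %||% "")
    if (is.na(feats$product[j])) prod <- ""
    kw <- any(vapply(BEBP_KEYWORDS, function(k) grepl(k, prod, fixed = TRUE), logical(1)))
    gaftga <- FALSE
    if (!kw) {
      prot <- feature_protein(genome, feats$locus_tag[j])
      gaftga <- !is.na(prot) && grepl("GAFTGA", prot, fixed = TRUE)
    }
    if (kw || gaftga)
      bebp <- rbind(bebp, data.frame(
        locus_tag = feats$locus_tag[j],
        basis = if (kw) "annotation" else "gaftga_heuristic",
        stringsAsFactors = FALSE))
    if (grepl("marr", prod, fixed = TRUE)) marr <- TRUE
    if (grepl("crp", prod, fixed = TRUE) || grepl("fnr", prod, fixed = TRUE) ||
        grepl("cyclic amp", prod, fixed = TRUE)) crp_fnr <- TRUE
  }
  list(bebp = bebp, marr_flag = marr, crp_fnr_flag = crp_fnr,
       parameters = list(gene_window = gene_window))
}

#' First gene of the operon containing a gene
#'
#' The operon is approximated as the maximal run of adjacent same-strand
#' genes (in sorted feature order) containing the anchor; the first gene is
#' the run's 5'-most member in reading orientation.
#'
#' @param genome An `rd_genome`.
#' @param feature Locus tag or feature row of the anchor gene.
#' @return The first gene's feature as a named list.
#' @export
operon_first_gene <- function(genome, feature) {
  nb <- contig_neighborhood(genome, feature)
  feats <- nb$feats; k <- nb$idx
  st <- feats$strand[k]
  if (st == "+") {
    while (k > 1L && feats$strand[k - 1L] == st) k <- k - 1L
  } else {
    while (k < nrow(feats) && feats$strand[k + 1L] == st) k <- k + 1L
  }
  as.list(feats[k, ])
}

#' Scan the promoter of an operon's first gene for sigma-54 elements
#'
#' Runs the sigma54_core motif (YTGGCACGRNNNTTGC) over the upstream window of
#' the given gene. By default only the coding-strand window is scanned (the
#' -24/-12 element is oriented with transcription); `both_strands = TRUE`
#' also scans the opposite strand. Hits are reported both as offsets relative
#' to the start codon (negative; -120 means the site starts 120 bp before the
#' first coding base) and as genome-frame coordinates.
#'
#' @param genome An `rd_genome`.
#' @param first_gene Locus tag or feature row of the operon's 5'-most gene.
#' @param max_bp Promoter window size in bp (default 500).
#' @param both_strands Scan both strands of the window (default FALSE).
#' @param motif Compiled nucleotide motif (default the registry sigma54_core).
#' @return data.frame: `offset_from_start`, `contig_id`, `genome_start`,
#'   `genome_end`, `genome_strand`, `matched`.
#' @export
scan_sigma54_promoter <- function(genome, first_gene, max_bp = 500L,
                                  both_strands = FALSE, motif = NULL) {
  if (is.null(motif)) motif <- motif_registry()$sigma54_core
  f <- resolve_feature(genome, first_gene)
  up <- upstream_region(genome, f, max_bp)
  empty <- data.frame(offset_from_start = integer(), contig_id = character(),
                      genome_start = integer(), genome_end = integer(),
                      genome_strand = character(), matched = character(),
                      stringsAsFactors = FALSE)
  L <- nchar(up$sequence)
  if (L < motif$length) return(empty)
  hits <- scan_motif(up$sequence, motif, both_strands = both_strands,
                     sequence_id = f$locus_tag)
  if (nrow(hits) == 0L) return(empty)
  w <- motif$length
  if (f$strand == "+") {
    gs <- f$start - L + hits$offset
    ge <- gs + w - 1L
    gstrand <- ifelse(hits$strand == "+", "+", "-")
  } else {
    ge <- f$end + L - hits$offset
    gs <- ge - w + 1L
    gstrand <- ifelse(hits$strand == "+", "-", "+")
  }
  data.frame(offset_from_start = hits$offset - L, contig_id = f$contig_id,
             genome_start = as.integer(gs), genome_end = as.integer(ge),
             genome_strand = gstrand, matched = hits$matched,
             stringsAsFactors = FALSE)
}

#' Build the full cluster report for one candidate
#'
#' Aggregates RDase B localization, nearby regulators, the sigma-54 promoter
#' scan of the operon's first gene, the annotated gene list spanning the
#' search window, and the predicted protein localization (periplasmic
#' candidate when the Tat signal is present, cytoplasmic candidate when it is
#' absent).
#'
#' @param genome An `rd_genome`.
#' @param candidate One row of the [call_rdase_candidates()] result (or a
#'   locus tag, in which case the motif evidence is recomputed).
#' @param gene_window_b Window for RDase B search (genes, default 3).
#' @param gene_window_reg Window for regulator search (genes, default 5).
#' @param promoter_bp Promoter window (bp, default 500).
#' @param both_strands Scan both promoter strands (default FALSE).
#' @return Object of class `rd_cluster_report`.
#' @export
build_cluster_report <- function(genome, candidate, gene_window_b = 3L,
                                 gene_window_reg = 5L, promoter_bp = 500L,
                                 both_strands = FALSE) {
  if (is.character(candidate)) {
    f <- resolve_feature(genome, candidate)
    prot <- feature_protein(genome, candidate)
    tat <- if (!is.na(prot)) find_tat_signal(prot) else NULL
    candidate <- data.frame(
      locus_tag = f$locus_tag, contig_id = f$contig_id, start = f$start,
      end = f$end, strand = f$strand,
      protein_length = if (is.na(prot)) NA_integer_ else nchar(prot),
      tat_offset = if (is.null(tat)) NA_integer_ else tat$offset,
      stringsAsFactors = FALSE)
  }
  tag <- candidate$locus_tag[1]
  b <- locate_rdase_b(genome, tag, gene_window = gene_window_b)
  regs <- locate_regulators(genome, tag, gene_window = gene_window_reg)
  first <- operon_first_gene(genome, tag)
  sites <- scan_sigma54_promoter(genome, first, max_bp = promoter_bp,
                                 both_strands = both_strands)
  nb <- contig_neighborhood(genome, tag)
  w <- max(gene_window_b, gene_window_reg)
  span <- seq(max(1L, nb$idx - w), min(nrow(nb$feats), nb$idx + w))
  structure(list(
    candidate = candidate[1L, , drop = FALSE],
    rdase_b = b, bebp = regs$bebp,
    marr_flag = regs$marr_flag, crp_fnr_flag = regs$crp_fnr_flag,
    first_gene = first$locus_tag, sigma54_sites = sites,
    cluster_genes = nb$feats[span, c("locus_tag", "start", "end", "strand", "product")],
    predicted_localization = if (is.na(candidate$tat_offset[1]))
      "cytoplasmic-candidate" else "periplasmic-candidate",
    parameters = list(gene_window_b = gene_window_b,
                      gene_window_reg = gene_window_reg,
                      promoter_bp = promoter_bp, both_strands = both_strands)),
    class = "rd_cluster_report")
}

#' @export
print.rd_cluster_report <- function(x, ...) {
  cat(sprintf("<rd_cluster_report> %s (%s)\n", x$candidate$locus_tag,
              x$predicted_localization))
  cat(sprintf("  RDase B: %s", x$rdase_b$status))
  if (x$rdase_b$status != "absent")
    cat(sprintf(" (%s, %d intervening gene(s), rule %s)",
                x$rdase_b$locus_tag, x$rdase_b$gene_distance, x$rdase_b$rule))
  cat("\n")
  cat(sprintf("  bEBP gene(s): %s\n",
              if (nrow(x$bebp) == 0L) "none" else paste(x$bebp$locus_tag, collapse = ", ")))
  cat(sprintf("  MarR: %s, CRP/FNR: %s\n", x$marr_flag, x$crp_fnr_flag))
  cat(sprintf("  sigma-54 sites upstream of %s: %d\n", x$first_gene,
              nrow(x$sigma54_sites)))
  invisible(x)
}

#' Survey a set of genomes for RDase gene clusters
#'
#' Runs candidate calling and cluster characterization over each genome and
#' summarizes per genome plus an aggregate line (fraction of genomes with at
#' least one candidate, candidate totals, Tat-positive, RDase-B-associated
#' and bEBP-associated cluster counts).
#'
#' @param genomes List of `rd_genome` objects.
#' @param domain_tables Optional named list (by genome_id) of domain tables.
#' @param ... Passed to [call_rdase_candidates()] and
#'   [build_cluster_report()] (policy and window parameters).
#' @return List with `rows` (per-genome data.frame), `aggregate` (list) and
#'   `reports` (list of per-candidate `rd_cluster_report`s, by genome).
#' @export
survey_genomes <- function(genomes, domain_tables = NULL, ...) {
  dots <- list(...)
  call_args <- dots[names(dots) %in% names(formals(call_rdase_candidates))]
  rep_args <- dots[names(dots) %in% names(formals(build_cluster_report))]
  rows <- list(); reports <- list()
  for (g in genomes) {
    dt <- if (!is.null(domain_tables)) domain_tables[[g$genome_id]] else NULL
    cand <- do.call(call_rdase_candidates,
                    c(list(genome = g, domain_table = dt), call_args))
    reps <- lapply(seq_len(nrow(cand)), function(i)
      do.call(build_cluster_report,
              c(list(genome = g, candidate = cand[i, , drop = FALSE]), rep_args)))
    reports[[g$genome_id]] <- reps
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = g$genome_id,
      n_genes = nrow(g$features),
      n_rdase_a = nrow(cand),
      has_rdase_a = nrow(cand) >= 1L,
      n_tat_positive = sum(!is.na(cand$tat_offset)),
      n_with_rdase_b = sum(vapply(reps, function(r) r$rdase_b$status != "absent", logical(1))),
      n_bebp_near = sum(vapply(reps, function(r) nrow(r$bebp), integer(1))),
      n_clusters_with_bebp = sum(vapply(reps, function(r) nrow(r$bebp) > 0L, logical(1))),
      n_sigma54_sites = sum(vapply(reps, function(r) nrow(r$sigma54_sites), integer(1))),
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  aggregate <- list(
    n_genomes = nrow(rows),
    fraction_with_candidate = mean(rows$has_rdase_a),
    total_candidates = sum(rows$n_rdase_a),
    total_tat_positive = sum(rows$n_tat_positive),
    total_rdase_b_associated = sum(rows$n_with_rdase_b),
    total_bebp_associated = sum(rows$n_clusters_with_bebp),
    total_bebp_genes = sum(rows$n_bebp_near))
  list(rows = rows, aggregate = aggregate, reports = reports)
}
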