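# Seeded generators: annotated genomes with planted RDase operons and decoys
# (plus a ground-truth table), sequential first-order debromination kinetics,
# and qPCR runs with known fold changes. These supply the planted truth the
# screening and physiology modules are validated against.
#
# All generators are deterministic under a fixed seed. Background sequences
# are rejection-sampled so that they contain no registry-motif matches (and
# no GAFTGA), and whole genomes are re-drawn in a bounded loop if a sigma54
# element appears anywhere outside the planted sites, making planted truth
# exact by construction.

set_gen_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
}

random_protein <- function(len) {
  c("M", sample(AA20, len - 1L, replace = TRUE))
}

protein_motif_counts <- function(protein) {
  reg <- motif_registry()
  c(tat = nrow(scan_motif(protein, reg$tat)),
    fes_long = nrow(scan_motif(protein, reg$fes_long)),
    fes_short = nrow(scan_motif(protein, reg$fes_short)),
    gaftga = as.integer(grepl("GAFTGA", protein, fixed = TRUE)))
}

# Background protein free of every registry protein motif and of GAFTGA.
clean_protein <- function(len, max_tries = 200L) {
  for (k in seq_len(max_tries)) {
    p <- paste(random_protein(len), collapse = "")
    if (all(protein_motif_counts(p) == 0L)) return(p)
  }
  stop("failed to sample a motif-free background protein")
}

# First (alphabetical) codon per residue under NCBI table 11; deterministic
# back-translation so the same protein always yields the same DNA.
codon_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc11 <- Biostrings::getGeneticCode("11")
      tab <- split(names(gc11), unname(gc11))
      cache <<- vapply(tab, function(x) sort(x)[1], character(1))
    }
    cache
  }
})

back_translate <- function(protein) {
  cm <- codon_map()
  paste0(paste(cm[chars(protein)], collapse = ""), "TAA")
}

#' Generate a synthetic RDase A protein with planted motifs
#'
#' Random background residues (rejection-sampled to be free of all registry
#' motifs) with the requested motif instances planted at non-overlapping
#' positions: a concrete RRxFxK within the first 45 residues when
#' `include_tat`, and concrete CxxCxxCxxxCP / CxxCxxxCP instances per
#' `include_fes`. Note that any long Fe-S instance inherently contains a
#' short-motif match at offset +3, so `"long_only"` still produces a short
#' hit; `"short_only"` and `"none"` are verified free of long matches.
#'
#' @param length Protein length in aa (>= 120).
#' @param include_tat Plant the Tat signal (default TRUE).
#' @param include_fes One of "both", "long_only", "short_only", "none".
#' @param seed Optional integer seed.
#' @return List: `protein`, plus 0-based `tat_offset`, `fes_long_offset`,
#'   `fes_short_offset` (NA when not planted).
#' @export
gen_rdase_protein <- function(length = 450L, include_tat = TRUE,
                              include_fes = c("both", "long_only", "short_only", "none"),
                              seed = NULL) {
  include_fes <- match.arg(include_fes)
  stopifnot(length >= 120L)
  set_gen_seed(seed)
  for (try in 1:200) {
    aa <- random_protein(length)
    tat_pos <- NA_integer_; long_pos <- NA_integer_; short_pos <- NA_integer_
    if (include_tat) {
      tat_pos <- sample(2:min(30L, length - 6L), 1L)
      aa[tat_pos:(tat_pos + 5L)] <-
        c("R", "R", sample(AA20, 1L), "F", sample(AA20, 1L), "K")
    }
    lo <- max(40L, round(length * 0.25))
    if (include_fes %in% c("both", "long_only")) {
      long_pos <- sample(lo:(lo + 30L), 1L)
      aa[long_pos:(long_pos + 11L)] <-
        c("C", sample(AA20, 2L, TRUE), "C", sample(AA20, 2L, TRUE),
          "C", sample(AA20, 3L, TRUE), "C", "P")
    }
    if (include_fes %in% c("both", "short_only")) {
      so <- if (is.na(long_pos)) lo else long_pos + 40L
      if (so + 20L > length) so <- length - 20L
      short_pos <- sample(so:(so + 10L), 1L)
      aa[short_pos:(short_pos + 8L)] <-
        c("C", sample(AA20, 2L, TRUE), "C", sample(AA20, 3L, TRUE), "C", "P")
    }
    p <- paste(aa, collapse = "")
    counts <- protein_motif_counts(p)
    tat_ok <- if (include_tat) !is.null(find_tat_signal(p)) else is.null(find_tat_signal(p))
    fes_ok <- switch(include_fes,
      both = counts[["fes_long"]] >= 1L && counts[["fes_short"]] >= 1L,
      long_only = counts[["fes_long"]] >= 1L,
      short_only = counts[["fes_long"]] == 0L && counts[["fes_short"]] >= 1L,
      none = counts[["fes_long"]] == 0L && counts[["fes_short"]] == 0L)
    if (tat_ok && fes_ok && counts[["gaftga"]] == 0L)
      return(list(protein = p,
                  tat_offset = if (include_tat) tat_pos - 1L else NA_integer_,
                  fes_long_offset = if (!is.na(long_pos)) long_pos - 1L else NA_integer_,
                  fes_short_offset = if (!is.na(short_pos)) short_pos - 1L else NA_integer_))
  }
  stop("failed to generate RDase protein satisfying the motif constraints")
}

# Small hydrophobic membrane-anchor protein: satisfies the Kyte-Doolittle
# heuristic (>= 2 windows of 19 residues with mean >= 1.6) and is free of
# registry motifs.
gen_rdase_b_protein <- function(length = 90L) {
  hydro <- c("I", "V", "L", "F", "C", "M", "A")
  for (try in 1:200) {
    body <- ifelse(stats::runif(length - 1L) < 0.85,
                   sample(hydro, length - 1L, replace = TRUE),
                   sample(AA20, length - 1L, replace = TRUE))
    p <- paste(c("M", body), collapse = "")
    if (hydropathy_windows(p) >= 2L && all(protein_motif_counts(p) == 0L))
      return(p)
  }
  stop("failed to generate RDase B protein")
}

# sigma-54 activator protein: motif-free background with the invariant
# GAFTGA hexapeptide planted mid-sequence.
gen_bebp_protein <- function(length = 400L) {
  p <- chars(clean_protein(length))
  pos <- round(length / 2)
  p[pos:(pos + 5L)] <- c("G", "A", "F", "T", "G", "A")
  paste(p, collapse = "")
}

# Random intergenic DNA free of sigma54_core matches on either strand.
clean_intergenic <- function(len, max_tries = 100L) {
  if (len <= 0L) return("")
  m <- motif_registry()$sigma54_core
  for (k in seq_len(max_tries)) {
    s <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    if (nrow(scan_motif(s, m, both_strands = TRUE)) == 0L) return(s)
  }
  stop("failed to sample sigma54-free intergenic sequence")
}

# A concrete instance of the sigma54 -24/-12 element.
concrete_sigma54 <- function() {
  paste0(sample(c("C", "T"), 1L), "TGGCACG", sample(c("A", "G"), 1L),
         paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = ""), "TTGC")
}

flip <- function(strand) ifelse(strand == "+", "-", "+")

#' Default operon architecture sampler
#'
#' Draws one operon specification from the study-condition mix: Tat signal
#' present with probability 0.5 (about half of surveyed RDase As carry it);
#' RDase B downstream / upstream / absent with probabilities 0.8 / 0.1 / 0.1
#' (downstream is the rule, upstream the rare exception); bEBP adjacent /
#' within-window / absent 0.6 / 0.2 / 0.2; a sigma-54 element present with
#' probability 0.85 at 40-300 bp upstream of the operon's first gene; RDase A
#' length 300-600 aa; random strand.
#'
#' @return List: the operon specification.
#' @export
sample_operon_spec <- function() {
  list(include_tat = stats::runif(1) < 0.5,
       include_fes = "both",
       rdase_b = sample(c("downstream", "upstream", "absent"), 1L,
                        prob = c(0.8, 0.1, 0.1)),
       bebp = sample(c("adjacent", "within_window", "absent"), 1L,
                     prob = c(0.6, 0.2, 0.2)),
       sigma54_offset = if (stats::runif(1) < 0.85) sample(40:300, 1L) else NA_integer_,
       rdase_length = sample(300:600, 1L),
       strand = sample(c("+", "-"), 1L))
}

# Build one operon block on the local + orientation, then mirror if the spec
# asks for the - strand. Returns the block sequence, local features (1-based
# within the block), and local truth (sigma54 site coordinates etc.).
build_operon_block <- function(spec, intergenic_range) {
  stopifnot(is.na(spec$sigma54_offset) || spec$sigma54_offset >= 16L)
  rd <- gen_rdase_protein(spec$rdase_length, spec$include_tat, spec$include_fes)
  genes <- list(list(role = "rdase_a", protein = rd$protein,
                     product = "reductive dehalogenase alpha subunit",
                     strand = "+"))
  if (spec$rdase_b == "downstream") {
    genes <- c(genes, list(list(role = "rdase_b", protein = gen_rdase_b_protein(),
                                product = "reductive dehalogenase anchoring protein RdhB",
                                strand = "+")))
  } else if (spec$rdase_b == "upstream") {
    genes <- c(list(list(role = "rdase_b", protein = gen_rdase_b_protein(),
                         product = "reductive dehalogenase anchoring protein RdhB",
                         strand = "+")), genes)
  }
  if (spec$bebp == "within_window") {
    genes <- c(genes, list(list(role = "spacer", protein = clean_protein(sample(150:250, 1L)),
                                product = "hypothetical protein", strand = "-")))
  }
  if (spec$bebp %in% c("adjacent", "within_window")) {
    genes <- c(genes, list(list(role = "bebp", protein = gen_bebp_protein(),
                                product = "sigma-54 dependent transcriptional regulator",
                                strand = "-")))
  }

  # promoter region: random sigma54-free DNA with the concrete site planted
  # so that its first base sits spec$sigma54_offset bp before the start codon
  off <- spec$sigma54_offset
  lp <- max(if (is.na(off)) 0L else off, 16L) +
    sample(intergenic_range[1]:intergenic_range[2], 1L)
  promoter <- clean_intergenic(lp)
  site_local <- NULL
  if (!is.na(off)) {
    for (k in 1:50) {
      site <- concrete_sigma54()
      cand <- paste0(substr(promoter, 1L, lp - off), site,
                     substr(promoter, lp - off + 17L, lp))
      hits <- scan_motif(cand, motif_registry()$sigma54_core, both_strands = TRUE)
      if (nrow(hits) == 1L && hits$offset == lp - off && hits$strand == "+") {
        promoter <- cand
        site_local <- c(start = lp - off + 1L, end = lp - off + 16L)
        break
      }
    }
    if (is.null(site_local)) stop("failed to plant a unique sigma54 site")
  }

  seqs <- promoter
  feats <- list()
  pos <- nchar(promoter)
  for (g in genes) {
    dna <- back_translate(g$protein)
    if (g$strand == "-") dna <- revcomp(dna)
    feats[[length(feats) + 1L]] <- list(
      role = g$role, start = pos + 1L, end = pos + nchar(dna),
      strand = g$strand, product = g$product, protein = g$protein)
    seqs <- c(seqs, dna)
    pos <- pos + nchar(dna)
    ig <- clean_intergenic(sample(intergenic_range[1]:intergenic_range[2], 1L))
    seqs <- c(seqs, ig)
    pos <- pos + nchar(ig)
  }
  block <- paste(seqs, collapse = "")
  bl <- nchar(block)

  if (spec$strand == "-") {
    block <- revcomp(block)
    feats <- lapply(feats, function(f) {
      new <- f
      new$start <- bl - f$end + 1L
      new$end <- bl - f$start + 1L
      new$strand <- flip(f$strand)
      new
    })
    feats <- feats[order(vapply(feats, function(f) f$start, integer(1)))]
    if (!is.null(site_local))
      site_local <- c(start = bl - site_local[["end"]] + 1L,
                      end = bl - site_local[["start"]] + 1L)
  }

  list(sequence = block, features = feats, sigma54_local = site_local,
       spec = spec)
}

#' Generate a synthetic annotated genome with planted RDase operons
#'
#' Assembles contigs from background genes (motif-free by rejection
#' sampling), decoy genes (exactly one Fe-S motif, or broken motifs), and
#' operon blocks built per specification: RDase A with the requested motifs,
#' optional RDase B downstream or upstream, optional sigma-54 activator
#' (bEBP) gene adjacent or within the window (placed divergently, on the
#' opposite strand), and a concrete sigma-54 element planted at the stated
#' offset upstream of the operon's first gene. The genes flanking an operon
#' block are forced onto the opposite strand so the operon's same-strand run
#' is exactly the planted operon. A truth table accompanies the genome.
#'
#' @param genome_id Genome identifier (also the locus-tag prefix).
#' @param n_contigs Number of contigs (default 2).
#' @param n_operons Number of planted operons (default: drawn from 1-3).
#' @param operon_specs Optional list of specs as from [sample_operon_spec()];
#'   overrides `n_operons`.
#' @param n_decoys Number of decoy genes (default 5).
#' @param n_background Number of background genes (default 50).
#' @param intergenic_range Uniform bounds for intergenic spacer lengths (bp).
#' @param seed Optional integer seed (fixed seed => byte-identical output).
#' @return List with `genome` (an `rd_genome`) and `truth` (list with
#'   data.frames `operons` and `decoys`).
#' @export
gen_genome <- function(genome_id = "syngenome", n_contigs = 2L,
                       n_operons = NULL, operon_specs = NULL, n_decoys = 5L,
                       n_background = 50L, intergenic_range = c(50L, 300L),
                       seed = NULL) {
  set_gen_seed(seed)
  for (attempt in 1:25) {
    res <- try(gen_genome_once(genome_id, n_contigs, n_operons, operon_specs,
                               n_decoys, n_background, intergenic_range),
               silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
  }
  stop("failed to assemble a clean synthetic genome: ",
       attr(res, "condition")$message)
}

gen_genome_once <- function(genome_id, n_contigs, n_operons, operon_specs,
                            n_decoys, n_background, intergenic_range) {
  if (is.null(operon_specs)) {
    if (is.null(n_operons)) n_operons <- sample(1:3, 1L)
    operon_specs <- replicate(n_operons, sample_operon_spec(), simplify = FALSE)
  }
  n_operons <- length(operon_specs)

  units <- list()
  for (i in seq_len(n_background))
    units[[length(units) + 1L]] <- list(
      kind = "background", protein = clean_protein(sample(150:300, 1L)),
      product = "hypothetical protein", strand = sample(c("+", "-"), 1L))
  for (i in seq_len(n_decoys)) {
    fes_mode <- if (i %% 2L == 1L) "short_only" else "none"
    dp <- gen_rdase_protein(sample(250:600, 1L),
                            include_tat = stats::runif(1) < 0.5,
                            include_fes = fes_mode)
    units[[length(units) + 1L]] <- list(
      kind = "decoy", protein = dp$protein,
      product = "putative oxidoreductase", strand = sample(c("+", "-"), 1L),
      fes_mode = fes_mode)
  }
  units <- units[sample(length(units))]

  blocks <- lapply(operon_specs, build_operon_block,
                   intergenic_range = intergenic_range)

  # insertion slots: spread operons over the unit list, >= 6 units apart and
  # never at the very start of a contig
  n_units <- length(units)
  slot_ok <- FALSE
  for (k in 1:50) {
    slots <- sort(sample(seq(3L, n_units - 1L), n_operons))
    if (n_operons <= 1L || min(diff(slots)) >= 6L) { slot_ok <- TRUE; break }
  }
  if (!slot_ok) stop("could not space operon blocks")

  # force the units flanking each block onto the opposite strand of its operon
  for (b in seq_len(n_operons)) {
    op_strand <- blocks[[b]]$spec$strand
    units[[slots[b]]]$strand <- flip(op_strand)       # unit before the block
    if (slots[b] + 1L <= n_units)
      units[[slots[b] + 1L]]$strand <- flip(op_strand) # unit after the block
  }

  # contig assignment: split the unit sequence into n_contigs stretches
  cut_pts <- unique(round(seq(0L, n_units, length.out = n_contigs + 1L)))
  contig_of_unit <- cut(seq_len(n_units), cut_pts, labels = FALSE)

  contigs <- character()
  feat_rows <- list()
  op_truth <- list()
  decoy_truth <- list()
  tag_counter <- 0L
  next_tag <- function() {
    tag_counter <<- tag_counter + 1L
    sprintf("%s_%04d", genome_id, tag_counter)
  }

  for (ci in seq_len(max(contig_of_unit))) {
    contig_id <- sprintf("%s_c%d", genome_id, ci)
    pieces <- clean_intergenic(sample(intergenic_range[1]:intergenic_range[2], 1L))
    pos <- nchar(pieces)
    for (u in which(contig_of_unit == ci)) {
      unit <- units[[u]]
      dna <- back_translate(unit$protein)
      if (unit$strand == "-") dna <- revcomp(dna)
      tag <- next_tag()
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        contig_id = contig_id, start = pos + 1L, end = pos + nchar(dna),
        strand = unit$strand, locus_tag = tag, product = unit$product,
        translation = unit$protein, phase = NA_character_,
        stringsAsFactors = FALSE)
      if (unit$kind == "decoy")
        decoy_truth[[length(decoy_truth) + 1L]] <- data.frame(
          locus_tag = tag, fes_mode = unit$fes_mode, stringsAsFactors = FALSE)
      pieces <- c(pieces, dna)
      pos <- pos + nchar(dna)

      b <- match(u, slots)
      if (!is.na(b)) {
        blk <- blocks[[b]]
        ig <- clean_intergenic(sample(intergenic_range[1]:intergenic_range[2], 1L))
        pieces <- c(pieces, ig)
        pos <- pos + nchar(ig)
        block_off <- pos
        tags <- list()
        for (f in blk$features) {
          tag <- next_tag()
          tags[[f$role]] <- tag
          feat_rows[[length(feat_rows) + 1L]] <- data.frame(
            contig_id = contig_id, start = block_off + f$start,
            end = block_off + f$end, strand = f$strand, locus_tag = tag,
            product = f$product, translation = f$protein,
            phase = NA_character_, stringsAsFactors = FALSE)
        }
        spec <- blk$spec
        site <- blk$sigma54_local
        op_truth[[length(op_truth) + 1L]] <- data.frame(
          rdase_locus = tags$rdase_a, contig_id = contig_id,
          strand = spec$strand, include_tat = spec$include_tat,
          rdase_b_class = spec$rdase_b,
          rdase_b_locus = tags$rdase_b %||% NA_character_,
          bebp_class = spec$bebp,
          bebp_locus = tags$bebp %||% NA_character_,
          first_gene_locus = if (spec$rdase_b == "upstream") tags$rdase_b else tags$rdase_a,
          sigma54_present = !is.na(spec$sigma54_offset),
          sigma54_offset = if (is.na(spec$sigma54_offset)) NA_integer_ else -spec$sigma54_offset,
          sigma54_start = if (is.null(site)) NA_integer_ else block_off + site[["start"]],
          sigma54_end = if (is.null(site)) NA_integer_ else block_off + site[["end"]],
          rdase_length = spec$rdase_length, stringsAsFactors = FALSE)
        pieces <- c(pieces, blk$sequence)
        pos <- pos + nchar(blk$sequence)
      }
      ig <- clean_intergenic(sample(intergenic_range[1]:intergenic_range[2], 1L))
      pieces <- c(pieces, ig)
      pos <- pos + nchar(ig)
    }
    contigs[contig_id] <- paste(pieces, collapse = "")
  }

  genome <- rd_genome(genome_id, contigs,
                      do.call(rbind, feat_rows))
  truth <- list(
    operons = if (length(op_truth)) do.call(rbind, op_truth) else NULL,
    decoys = if (length(decoy_truth)) do.call(rbind, decoy_truth) else NULL)

  # purity: the only sigma54 matches anywhere in the genome must be the
  # planted sites (checked on both strands)
  m54 <- motif_registry()$sigma54_core
  planted <- if (is.null(truth$operons)) integer() else
    stats::na.omit(truth$operons$sigma54_start)
  planted_ctg <- if (is.null(truth$operons)) character() else
    truth$operons$contig_id[!is.na(truth$operons$sigma54_start)]
  found <- character()
  for (cid in names(contigs)) {
    h <- scan_motif(contigs[[cid]], m54, both_strands = TRUE, sequence_id = cid)
    if (nrow(h) > 0L)
      found <- c(found, paste(cid, h$offset + 1L))
  }
  # a planted site on a - strand operon sits on the reverse strand of the
  # contig, but the both-strands scan reports forward coordinates either way
  expected <- if (length(planted)) paste(planted_ctg, planted) else character()
  if (!setequal(found, expected))
    stop("stray sigma54 match in background sequence")

  list(genome = genome, truth = truth)
}

#' Generate a set of synthetic genomes
#'
#' @param n Number of genomes.
#' @param seed Base seed; genome i uses seed `seed + i - 1`.
#' @param ... Passed to [gen_genome()].
#' @return List of `gen_genome()` results.
#' @export
gen_genomes <- function(n, seed = 1L, ...) {
  lapply(seq_len(n), function(i)
    gen_genome(genome_id = sprintf("syn%03d", i), seed = seed + i - 1L, ...))
}

#' Simulate a sequential debromination time series
#'
#' Closed-form sequential first-order kinetics for parent -> mono-bromophenol
#' -> phenol (e.g. 2,6-DBP -> 2-BP -> phenol): the parent decays as
#' `c0 e^(-k1 t)`, the intermediate is
#' `c0 k1/(k2-k1) (e^(-k1 t) - e^(-k2 t))`, and phenol is the balance, so the
#' ring total is conserved exactly before noise. Gaussian noise (sd
#' `noise_sd` µM) is added per species and timepoint, then clipped at zero.
#' The rate law is a fixture-realism choice, not an inference about the
#' organisms.
#'
#' @param k1,k2 First-order rate constants (per hour, k1 != k2).
#' @param c0 Initial parent concentration (µM; default 200, the study's
#'   feeding level).
#' @param times Sampling times (hours).
#' @param noise_sd Gaussian noise sd (µM; 0 = noiseless).
#' @param volume_L Culture volume (litres; default 0.02).
#' @param parent,intermediate,product Species names.
#' @param seed Optional integer seed.
#' @return An `rd_timeseries`.
#' @export
gen_timeseries <- function(k1, k2, c0 = 200, times = seq(0, 72, by = 4),
                           noise_sd = 0, volume_L = 0.02,
                           parent = "2,6-DBP", intermediate = "2-BP",
                           product = "phenol", seed = NULL) {
  stopifnot(k1 > 0, k2 > 0)
  if (k1 == k2) stop("k1 and k2 must differ (limit form not implemented)")
  set_gen_seed(seed)
  a <- c0 * exp(-k1 * times)
  b <- c0 * k1 / (k2 - k1) * (exp(-k1 * times) - exp(-k2 * times))
  p <- c0 - a - b
  sp <- stats::setNames(list(a, b, p), c(parent, intermediate, product))
  if (noise_sd > 0)
    sp <- lapply(sp, function(x) pmax(0, x + stats::rnorm(length(x), 0, noise_sd)))
  dehal_timeseries(times, sp, volume_L)
}

#' Simulate a qPCR run with a known fold change
#'
#' Standards lie exactly on the line `Cq = slope log10(q) + intercept` (one
#' line per gene); sample Cq values are generated from the true quantities --
#' target induced at `true_fold` times the control level, the 16S reference
#' constant across conditions -- with optional Gaussian Cq noise. The design
#' mirrors the study: 3 biological replicates, each assayed in technical
#' duplicate.
#'
#' @param true_fold True induced/control fold change.
#' @param slope Standard-curve slope (negative; default -log10(2)^-1 =
#'   -3.3219, i.e. 100 percent efficiency).
#' @param intercept_target,intercept_ref Curve intercepts for the target and
#'   16S genes.
#' @param cq_noise_sd Gaussian Cq noise sd (0 = noiseless).
#' @param n_bio,n_tech Biological and technical replicate counts.
#' @param control_qty,ref_qty True relative quantities of the control target
#'   and the reference gene.
#' @param seed Optional integer seed.
#' @return List with `run` (an `rd_qpcr_run`) and `truth` (the generator
#'   parameters).
#' @export
gen_qpcr <- function(true_fold, slope = -1 / log10(2), intercept_target = 30,
                     intercept_ref = 14, cq_noise_sd = 0, n_bio = 3L,
                     n_tech = 2L, control_qty = 0.01, ref_qty = 1,
                     seed = NULL) {
  stopifnot(slope < 0, true_fold > 0)
  set_gen_seed(seed)
  lq <- seq(2, -2, by = -1)
  standards <- rbind(
    data.frame(gene = "rdhA", log10_qty = lq, cq = slope * lq + intercept_target),
    data.frame(gene = "16S", log10_qty = lq, cq = slope * lq + intercept_ref))
  qty <- list(rdhA = c(control = control_qty, induced = control_qty * true_fold),
              `16S` = c(control = ref_qty, induced = ref_qty))
  icept <- c(rdhA = intercept_target, `16S` = intercept_ref)
  samples <- expand.grid(gene = c("rdhA", "16S"),
                         condition = c("control", "induced"),
                         bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech),
                         stringsAsFactors = FALSE)
  samples$cq <- slope * log10(mapply(function(g, cond) qty[[g]][[cond]],
                                     samples$gene, samples$condition)) +
    icept[samples$gene]
  if (cq_noise_sd > 0)
    samples$cq <- samples$cq + stats::rnorm(nrow(samples), 0, cq_noise_sd)
  run <- qpcr_run(standards, samples, target_gene = "rdhA", reference_gene = "16S")
  list(run = run, truth = list(true_fold = true_fold, slope = slope,
                               cq_noise_sd = cq_noise_sd))
}
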