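# A small deterministic genome with one planted operon plus a decoy, reused
# across several blocks.
screen_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- list(include_tat = TRUE, include_fes = "both",
                   rdase_b = "downstream", bebp = "adjacent",
                   sigma54_offset = 120L, rdase_length = 400L, strand = "+")
      cache <<- gen_genome(genome_id = "fix", operon_specs = list(spec),
                           n_decoys = 2, n_background = 20, seed = 404)
    }
    cache
  }
})

test_that("Tat signal detection is restricted to the N-terminal window", {
  expect_equal(find_tat_signal("MSRRDFLKA")$offset, 2L)
  far <- paste0(strrep("A", 200), "RRDFLK")
  expect_null(find_tat_signal(far))
  expect_equal(find_tat_signal(far, window = 250)$offset, 200L)
  expect_null(find_tat_signal("MKKKAAAA"))
})

test_that("Fe-S motif detection needs the full spacing including the terminal proline", {
  p1 <- paste0(strrep("A", 30), "CAACAACAAACP", strrep("A", 30))
  h1 <- find_fes_motifs(p1)
  expect_equal(h1$fes_long$offset, 30L)
  # the long instance nests a short instance at +3
  expect_equal(h1$fes_short$offset, 33L)
  p2 <- paste0(strrep("A", 30), "CAACAAACP", strrep("A", 30))
  h2 <- find_fes_motifs(p2)
  expect_null(h2$fes_long)
  expect_equal(h2$fes_short$offset, 30L)
  h3 <- find_fes_motifs(paste0(strrep("A", 30), "CAACAACAAACA"))
  expect_null(h3$fes_long)
  expect_null(h3$fes_short)
})

test_that("candidate calling follows the motif policy, length bounds and domain table", {
  res <- screen_fixture()
  g <- res$genome
  truth <- res$truth
  cand <- call_rdase_candidates(g)
  expect_equal(cand$locus_tag, truth$operons$rdase_locus)
  expect_equal(cand$call_basis, "motif")
  expect_false(is.na(cand$tat_offset))
  # domain table adds the decoy as an external call
  decoy <- truth$decoys$locus_tag[1]
  dt <- data.frame(locus_tag = decoy, domain_id = "PF13486", score = 55.2)
  cand2 <- call_rdase_candidates(g, domain_table = dt)
  expect_setequal(cand2$locus_tag, c(truth$operons$rdase_locus, decoy))
  expect_equal(cand2$call_basis[cand2$locus_tag == decoy], "external")
  # unknown locus tags in the table are an error
  expect_error(call_rdase_candidates(g, domain_table = data.frame(
    locus_tag = "nope_0001", domain_id = "pfam13486", score = 1)), "nope_0001")
  # length bound excludes an oversized protein
  big <- gen_rdase_protein(900, include_tat = FALSE, include_fes = "both", seed = 5)
  gb <- rd_genome("big", c(c1 = paste0(rand_dna(30), dehaloscout:::back_translate(big$protein), rand_dna(30))),
                  data.frame(contig_id = "c1", start = 31,
                             end = 30 + 3 * (nchar(big$protein) + 1), strand = "+",
                             locus_tag = "big_1", product = "x",
                             translation = big$protein))
  expect_equal(nrow(call_rdase_candidates(gb)), 0L)
  expect_equal(nrow(call_rdase_candidates(gb, max_len = 1000)), 1L)
})

test_that("RDase B localization reports position class, distance and rule", {
  res <- screen_fixture()
  tr <- res$truth$operons
  b <- locate_rdase_b(res$genome, tr$rdase_locus)
  expect_equal(b$status, "downstream")
  expect_equal(b$locus_tag, tr$rdase_b_locus)
  expect_equal(b$gene_distance, 0L)
  expect_equal(b$rule, "annotation")
  # upstream arrangement (the rarer architecture)
  spec_up <- list(include_tat = FALSE, include_fes = "both", rdase_b = "upstream",
                  bebp = "absent", sigma54_offset = 60L, rdase_length = 350L,
                  strand = "+")
  res_up <- gen_genome(genome_id = "up", operon_specs = list(spec_up),
                       n_decoys = 1, n_background = 15, seed = 405)
  b_up <- locate_rdase_b(res_up$genome, res_up$truth$operons$rdase_locus)
  expect_equal(b_up$status, "upstream")
  # no small hydrophobic gene in the window -> absent
  spec_no <- modifyList(spec_up, list(rdase_b = "absent"))
  res_no <- gen_genome(genome_id = "nob", operon_specs = list(spec_no),
                       n_decoys = 1, n_background = 15, seed = 406)
  expect_equal(locate_rdase_b(res_no$genome, res_no$truth$operons$rdase_locus)$status,
               "absent")
})

test_that("hydropathy heuristic fires on an unannotated small hydrophobic gene", {
  res <- screen_fixture()
  g <- res$genome
  tr <- res$truth$operons
  # strip the annotation so only the Kyte-Doolittle rule can identify it
  i <- match(tr$rdase_b_locus, g$features$locus_tag)
  g$features$product[i] <- "hypothetical protein"
  b <- locate_rdase_b(g, tr$rdase_locus)
  expect_equal(b$locus_tag, tr$rdase_b_locus)
  expect_equal(b$rule, "hydropathy")
})

test_that("regulator search finds bEBPs by annotation or GAFTGA and flags MarR/CRP-FNR", {
  res <- screen_fixture()
  g <- res$genome
  tr <- res$truth$operons
  regs <- locate_regulators(g, tr$rdase_locus)
  expect_equal(regs$bebp$locus_tag, tr$bebp_locus)
  expect_equal(regs$bebp$basis, "annotation")
  expect_false(regs$marr_flag)
  expect_false(regs$crp_fnr_flag)
  # strip the annotation: the GAFTGA heuristic still finds it, labelled as such
  i <- match(tr$bebp_locus, g$features$locus_tag)
  g$features$product[i] <- "hypothetical protein"
  regs2 <- locate_regulators(g, tr$rdase_locus)
  expect_equal(regs2$bebp$locus_tag, tr$bebp_locus)
  expect_equal(regs2$bebp$basis, "gaftga_heuristic")
  # MarR annotation in the window flips the flag
  g$features$product[i] <- "MarR family transcriptional regulator"
  expect_true(locate_regulators(g, tr$rdase_locus)$marr_flag)
})

test_that("sigma-54 promoter scan maps hits to start-codon offsets and genome coordinates", {
  res <- screen_fixture()
  tr <- res$truth$operons
  first <- operon_first_gene(res$genome, tr$rdase_locus)
  expect_equal(first$locus_tag, tr$first_gene_locus)
  sites <- scan_sigma54_promoter(res$genome, first)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$offset_from_start, tr$sigma54_offset)
  expect_equal(sites$genome_start, tr$sigma54_start)
  expect_equal(sites$genome_end, tr$sigma54_end)
  # the hit sequence really is at those genome coordinates
  planted <- substr(res$genome$contigs[[sites$contig_id]],
                    sites$genome_start, sites$genome_end)
  expect_equal(planted, sites$matched)
  # a window too small to reach the site finds nothing
  expect_equal(nrow(scan_sigma54_promoter(res$genome, first, max_bp = 20)), 0L)
  # all-A promoter has no hits
  g2 <- rd_genome("p", c(c1 = paste0(strrep("A", 600), "ATGAAATAA")),
                  data.frame(contig_id = "c1", start = 601, end = 609,
                             strand = "+", locus_tag = "g", product = NA,
                             translation = NA))
  expect_equal(nrow(scan_sigma54_promoter(g2, "g")), 0L)
})

test_that("cluster report aggregates evidence and predicts localization from Tat", {
  res <- screen_fixture()
  tr <- res$truth$operons
  rep <- build_cluster_report(res$genome, tr$rdase_locus)
  expect_s3_class(rep, "rd_cluster_report")
  expect_equal(rep$predicted_localization, "periplasmic-candidate")
  expect_equal(rep$rdase_b$status, "downstream")
  expect_equal(rep$bebp$locus_tag, tr$bebp_locus)
  expect_equal(nrow(rep$sigma54_sites), 1L)
  expect_true(tr$rdase_locus %in% rep$cluster_genes$locus_tag)
  # a Tat-less candidate is a cytoplasmic candidate
  spec_nt <- list(include_tat = FALSE, include_fes = "both", rdase_b = "downstream",
                  bebp = "absent", sigma54_offset = NA_integer_,
                  rdase_length = 350L, strand = "-")
  res_nt <- gen_genome(genome_id = "nt", operon_specs = list(spec_nt),
                       n_decoys = 1, n_background = 15, seed = 407)
  rep_nt <- build_cluster_report(res_nt$genome, res_nt$truth$operons$rdase_locus)
  expect_equal(rep_nt$predicted_localization, "cytoplasmic-candidate")
  expect_equal(nrow(rep_nt$sigma54_sites), 0L)
})

test_that("enlarging windows never removes a previously reported finding", {
  res <- screen_fixture()
  tr <- res$truth$operons
  b3 <- locate_rdase_b(res$genome, tr$rdase_locus, gene_window = 3)
  b6 <- locate_rdase_b(res$genome, tr$rdase_locus, gene_window = 6)
  expect_equal(b6$locus_tag, b3$locus_tag)
  r5 <- locate_regulators(res$genome, tr$rdase_locus, gene_window = 5)
  r8 <- locate_regulators(res$genome, tr$rdase_locus, gene_window = 8)
  expect_true(all(r5$bebp$locus_tag %in% r8$bebp$locus_tag))
  first <- operon_first_gene(res$genome, tr$rdase_locus)
  s300 <- scan_sigma54_promoter(res$genome, first, max_bp = 300)
  s500 <- scan_sigma54_promoter(res$genome, first, max_bp = 500)
  expect_true(all(s300$genome_start %in% s500$genome_start))
})

test_that("screening is invariant under genome reverse complement", {
  res <- gen_genome(genome_id = "inv", seed = 31)
  g <- res$genome
  rc <- revcomp_genome(g)
  cand <- call_rdase_candidates(g)
  cand_rc <- call_rdase_candidates(rc)
  expect_setequal(cand_rc$locus_tag, cand$locus_tag)
  for (tag in cand$locus_tag) {
    r1 <- build_cluster_report(g, tag)
    r2 <- build_cluster_report(rc, tag)
    expect_equal(r2$rdase_b$status, r1$rdase_b$status)
    expect_equal(r2$rdase_b$locus_tag, r1$rdase_b$locus_tag)
    expect_setequal(r2$bebp$locus_tag, r1$bebp$locus_tag)
    expect_equal(r2$sigma54_sites$offset_from_start, r1$sigma54_sites$offset_from_start)
    # genome coordinates mirror: start <-> L - end + 1
    L <- nchar(g$contigs[[r1$candidate$contig_id]])
    expect_equal(sort(r2$sigma54_sites$genome_start),
                 sort(L - r1$sigma54_sites$genome_end + 1L))
  }
})

test_that("survey aggregates per-genome rows and the planted fraction", {
  specs <- list(list(include_tat = TRUE, include_fes = "both",
                     rdase_b = "downstream", bebp = "adjacent",
                     sigma54_offset = 100L, rdase_length = 400L, strand = "+"))
  genomes <- c(
    lapply(1:3, function(i) gen_genome(sprintf("pos%d", i), operon_specs = specs,
                                       n_background = 12, n_decoys = 1,
                                       seed = 500 + i)$genome),
    lapply(1:7, function(i) gen_genome(sprintf("neg%d", i), operon_specs = list(),
                                       n_background = 12, n_decoys = 1,
                                       seed = 600 + i)$genome))
  sv <- survey_genomes(genomes)
  expect_equal(nrow(sv$rows), 10L)
  expect_equal(sv$aggregate$fraction_with_candidate, 0.3)
  expect_equal(sv$aggregate$total_candidates, 3L)
  expect_equal(sv$aggregate$total_tat_positive, 3L)
  expect_equal(sv$aggregate$total_rdase_b_associated, 3L)
  expect_equal(sv$aggregate$total_bebp_associated, 3L)
  expect_true(all(sv$rows$has_rdase_a == (sv$rows$n_rdase_a >= 1)))
})
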