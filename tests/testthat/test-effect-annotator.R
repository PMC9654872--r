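test_that("codon_position follows the 1-based CDS convention", {
  expect_identical(codon_position(1234), 1L)
  expect_identical(codon_position(701), 2L)
  expect_identical(codon_position(1722), 3L)
  expect_identical(codon_position(1:6), c(1L, 2L, 3L, 1L, 2L, 3L))
  expect_error(codon_position(0), "positive")
  expect_error(codon_position(-3), "positive")
})

test_that("apply_edit reproduces the canonical editing outcomes", {
  stop <- apply_edit("CGA", 1)
  expect_identical(stop[c("alt_codon", "ref_aa", "alt_aa", "effect")],
                   list(alt_codon = "TGA", ref_aa = "R", alt_aa = "X",
                        effect = "stop_gain"))
  start <- apply_edit("ACG", 2, codon_index = 1)
  expect_identical(start[c("alt_codon", "ref_aa", "alt_aa", "effect")],
                   list(alt_codon = "ATG", ref_aa = "T", alt_aa = "M",
                        effect = "start_gain"))
  # the same edit mid-gene is an ordinary missense change
  expect_identical(apply_edit("ACG", 2, codon_index = 7)$effect, "missense")
  syn <- apply_edit("ATC", 3)
  expect_identical(syn$alt_codon, "ATT")
  expect_identical(syn$effect, "synonymous")
  expect_error(apply_edit("ATG", 1), "no C at position")
})

test_that("apply_edit agrees with a brute-force oracle over 64 codons x 3 positions", {
  codons <- names(GENETIC_CODE_ORACLE)
  n_checked <- 0L
  for (codon in codons) {
    for (pos in 1:3) {
      if (substr(codon, pos, pos) != "C") next
      got <- apply_edit(codon, pos, codon_index = 5L)
      alt <- codon
      substr(alt, pos, pos) <- "T"
      ref_aa <- unname(GENETIC_CODE_ORACLE[codon])
      alt_aa <- unname(GENETIC_CODE_ORACLE[alt])
      expect_identical(got$alt_codon, alt)
      expect_identical(got$ref_aa, ref_aa)
      expect_identical(got$alt_aa, alt_aa)
      expected_effect <-
        if (ref_aa == alt_aa) "synonymous"
        else if (alt_aa == "X") "stop_gain"
        else "missense"
      expect_identical(got$effect, expected_effect)
      n_checked <- n_checked + 1L
    }
  }
  expect_identical(n_checked, 48L)  # 16 codons per position carry a C
})

test_that("stop loss is unreachable by C-to-U editing", {
  stops <- names(GENETIC_CODE_ORACLE)[GENETIC_CODE_ORACLE == "X"]
  expect_false(any(grepl("C", stops)))
})

test_that("edit_achievable distinguishes single and joint codon edits", {
  expect_true(edit_achievable("S", "L", 2))   # TCA -> TTA
  expect_true(edit_achievable("H", "Y", 1))   # CAC -> TAC
  expect_false(edit_achievable("P", "L", 1))  # CCx -> TCx is Ser
  expect_true(edit_achievable("P", "L", c(1, 2)))   # CCA -> TTA
  expect_true(edit_achievable("P", "F", c(1, 2)))   # CCT -> TTT
  expect_false(edit_achievable("P", "H", 2))  # His needs A at position 2
  expect_false(edit_achievable("S", "L", 1))  # no Ser codon has C at pos 1
})

test_that("locate maps genome positions to spliced CDS coordinates", {
  plus <- gene_model("p", "CDS", "+", cbind(100, 199), complete = FALSE)
  minus <- gene_model("m", "CDS", "-", cbind(100, 199), complete = FALSE)
  expect_identical(locate(100, list(plus))$local_pos, 1L)
  expect_identical(locate(199, list(minus))$local_pos, 1L)
  expect_identical(locate(100, list(minus))$local_pos, 100L)
  two <- gene_model("t", "CDS", "+", rbind(c(100, 129), c(200, 229)),
                    complete = TRUE)
  expect_identical(locate(200, list(two))$local_pos, 31L)
  expect_identical(nrow(locate(150, list(two))), 0L)  # in the gap
  # overlapping genes: all memberships reported
  both <- locate(150, list(plus, minus))
  expect_identical(nrow(both), 2L)
})

test_that("locate and transcript_sequence agree on random synthetic genes", {
  truth <- simulate_organelle(simulation_config(seed = 11, n_sites = 20,
                                                n_genes = 6))
  gseq <- strsplit(truth$genome[[1]], "")[[1]]
  for (g in truth$genes) {
    tx <- transcript_sequence(truth$genome, g)
    for (cds_pos in sort(sample(nchar(tx), 25))) {
      gp <- orgedit:::cds_to_genome(g, cds_pos)
      hit <- locate(gp, list(g))
      expect_identical(hit$local_pos, as.integer(cds_pos))
      base <- gseq[gp]
      if (g$strand == "-") base <- oracle_revcomp(base)
      expect_identical(substr(tx, cds_pos, cds_pos), base)
    }
  }
})

test_that("annotate_sites derives full records and routes noncoding hits", {
  set.seed(3)
  # transcript with a CGA codon at codon 3 -> stop gain when edited at cds 7
  tx <- paste0("ATG", "GCT", "CGA", "TCA", "TAA")
  for (strand in c("+", "-")) {
    eg <- embed_gene(tx, strand, offset = 20, gene_id = "gS",
                     complete = TRUE)
    gp <- orgedit:::cds_to_genome(eg$gene, 7L)
    ann <- annotate_sites(data.frame(genome_pos = gp, ref_base = "C"),
                          eg$genome, list(eg$gene))
    expect_identical(ann$sites$effect, "stop_gain")
    expect_identical(ann$sites$cds_pos, 7L)
    expect_identical(ann$sites$ref_codon, "CGA")
    expect_identical(ann$sites$alt_codon, "TGA")
  }
  eg <- embed_gene(tx, "+", offset = 20, gene_id = "gS", complete = TRUE)
  # intergenic candidate goes to the noncoding report
  ann <- annotate_sites(data.frame(genome_pos = 3L), eg$genome,
                        list(eg$gene))
  expect_identical(nrow(ann$sites), 0L)
  expect_identical(ann$noncoding$feature_class, "intergenic")
  # reference mismatch is an error, not a silent fix
  gp_a <- orgedit:::cds_to_genome(eg$gene, 1L)  # an A, not C
  expect_error(annotate_sites(data.frame(genome_pos = gp_a, ref_base = "C"),
                              eg$genome, list(eg$gene)),
               "reference mismatch|not an editable C")
})

test_that("annotate_sites reports overlapping-gene claims without choosing", {
  genome <- c(g = paste0(strrep("A", 10), "ATGCCTCCATAA", strrep("A", 10)))
  g1 <- gene_model("g1", "CDS", "+", cbind(11, 22), complete = TRUE)
  g2 <- gene_model("g2", "CDS", "+", cbind(14, 22), complete = TRUE)
  ann <- annotate_sites(data.frame(genome_pos = 15L), genome, list(g1, g2))
  expect_identical(nrow(ann$sites), 2L)  # one row per membership
  expect_identical(nrow(ann$ambiguous), 1L)
  expect_match(ann$ambiguous$gene_ids, "g1,g2")
})

test_that("check_against_table is reflexive and flags injected faults", {
  cp <- tea_sites("chloroplast")
  self <- check_against_table(cp, cp)
  expect_identical(unname(self$summary["n_matched"]), 38L)
  expect_identical(unname(self$summary["n_field_mismatch"]), 0L)
  corrupted <- cp
  corrupted$codon_position[5] <- (corrupted$codon_position[5] %% 3L) + 1L
  rep <- check_against_table(corrupted, cp)
  expect_identical(unname(rep$summary["n_field_mismatch"]), 1L)
})
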