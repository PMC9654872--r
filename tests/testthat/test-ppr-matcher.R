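motif_df <- function(pid, seqs, classes = NULL) {
  if (is.null(classes)) classes <- rep("P", length(seqs))
  data.frame(protein_id = pid, motif_index = seq_along(seqs),
             motif_class = classes, motif_sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("extract_codes pulls residues 2, 5 and last in N-to-C order", {
  m35 <- paste0("VTYTT", paste(rep("L", 29), collapse = ""), "D")  # 35 aa
  codes <- extract_codes(motif_df("p1", m35))
  expect_identical(codes$res2, "T")
  expect_identical(codes$res5, "T")
  expect_identical(codes$res_last, "D")

  two <- extract_codes(motif_df("p1", c("VTYTTXXXXN", "ASQWENNNND")))
  expect_identical(two$motif_index, 1:2)
  expect_identical(two$res_last, c("N", "D"))

  expect_error(extract_codes(motif_df("p1", "VTYT")), "shorter than 5")
  expect_error(extract_codes(motif_df("p1", "VTYTTL", classes = "Z")),
               "unknown PPR motif class")
})

test_that("code tables validate probability vectors", {
  bad <- data.frame(res2 = "A", res5 = "B", res_last = "C",
                    pA = 0.5, pC = 0.5, pG = 0.5, pU = 0.5)
  expect_error(code_table(bad), "sum to 1")
  expect_error(code_table(bad[0, ]), "empty")
  ct <- synthetic_code_table()
  expect_s3_class(ct, "ppr_code_table")
  expect_true(all(abs(rowSums(ct[, c("pA", "pC", "pG", "pU")]) - 1) < 1e-9))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(ct, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(as.data.frame(read_code_table(f)), as.data.frame(ct),
               tolerance = 1e-12)
})

test_that("build_pwm maps codes to columns with triple/pair/single fallback", {
  ct <- code_table(data.frame(
    res2 = c("F", NA, NA), res5 = c("T", "S", NA),
    res_last = c("N", "N", "D"),
    pA = c(0.97, 0.05, 0.10), pC = c(0.01, 0.85, 0.10),
    pG = c(0.01, 0.05, 0.70), pU = c(0.01, 0.05, 0.10)))
  # triple hit, pseudocount 0: column equals the stored vector
  m_tri <- paste0("XF", "XX", "T", "XXXX", "N")   # res2=F res5=T last=N
  pwm <- build_pwm(extract_codes(motif_df("p", m_tri)), ct, pseudocount = 0)
  expect_equal(unname(pwm$probs[, 1]), c(0.97, 0.01, 0.01, 0.01))
  # unknown triple falls back to the (res5, res_last) pair
  m_pair <- paste0("XQ", "XX", "S", "XXXX", "N")
  pwm <- build_pwm(extract_codes(motif_df("p", m_pair)), ct, pseudocount = 0)
  expect_equal(unname(pwm$probs[, 1]), c(0.05, 0.85, 0.05, 0.05))
  # unknown pair falls back to the last-residue single
  m_single <- paste0("XQ", "XX", "Q", "XXXX", "D")
  pwm <- build_pwm(extract_codes(motif_df("p", m_single)), ct,
                   pseudocount = 0)
  expect_equal(unname(pwm$probs[, 1]), c(0.10, 0.10, 0.70, 0.10))
  # nothing matches: background
  m_bg <- paste0("XQ", "XX", "Q", "XXXX", "Q")
  pwm <- build_pwm(extract_codes(motif_df("p", m_bg)), ct, pseudocount = 0)
  expect_equal(unname(pwm$probs[, 1]), rep(0.25, 4))
})

test_that("build_pwm assembles multi-motif matrices and skips E/DYW motifs", {
  ct <- synthetic_code_table()
  # five motifs spelling A,C,G,U,A via the synthetic triples, with a DYW
  # tail that must contribute no column
  spell <- list(c("T", "N"), c("S", "N"), c("T", "D"), c("S", "D"),
                c("T", "N"))
  seqs <- vapply(spell, function(rr) {
    paste0("XF", "XX", rr[1], "XXXX", rr[2])
  }, "")
  df <- motif_df("p5", c(seqs, "ADYWDYWDYW"),
                 classes = c("P", "L", "S", "P", "L", "DYW"))
  pwm <- build_pwm(extract_codes(df), ct, pseudocount = 0)
  expect_identical(pwm$length, 5L)
  hand <- cbind(c(0.97, 0.01, 0.01, 0.01), c(0.01, 0.97, 0.01, 0.01),
                c(0.01, 0.01, 0.97, 0.01), c(0.01, 0.01, 0.01, 0.97),
                c(0.97, 0.01, 0.01, 0.01))
  expect_equal(unname(pwm$probs), hand)
  # proteins without any nucleotide-specifying motif are rejected
  expect_error(build_pwm(extract_codes(motif_df("p", "ADYWDYWDYW",
                                                classes = "DYW")), ct),
               "no nucleotide-specifying")
})

test_that("PWM columns stay normalized for any pseudocount", {
  ct <- synthetic_code_table()
  df <- extract_codes(motif_df("p", c("XFXXTXXXXN", "XFXXSXXXXD")))
  for (pc in c(0, 1e-6, 0.01, 0.5, 5)) {
    pwm <- build_pwm(df, ct, pseudocount = pc)
    expect_true(all(abs(colSums(pwm$probs) - 1) < 1e-9))
  }
})

test_that("pwm_pvalue has the exact closed-form corners", {
  hot3 <- one_hot_pwm("ACG")
  maxscore <- sum(apply(hot3$logodds, 2, max))
  expect_equal(pwm_pvalue(hot3, maxscore), 0.015625)  # (1/4)^3
  expect_equal(pwm_pvalue(hot3, -Inf), 1)
  set.seed(31)
  rnd <- random_pwm(5)
  minscore <- sum(apply(rnd$logodds, 2, min))
  expect_equal(pwm_pvalue(rnd, minscore), 1)
  expect_equal(pwm_pvalue(rnd, sum(apply(rnd$logodds, 2, max)) + 1), 0)
})

test_that("p-values are monotone non-increasing in score", {
  set.seed(5)
  pwm <- random_pwm(6)
  scores <- sort(runif(25, -12, 12))
  p <- vapply(scores, function(s) pwm_pvalue(pwm, s), 1)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("DP p-values match exhaustive enumeration for random PWMs", {
  set.seed(61)
  for (L in c(3, 6)) {
    pwm <- random_pwm(L)
    en <- enum_scores(pwm)
    for (s in sample(en$scores, 8)) {
      p_dp <- pwm_pvalue(pwm, s)
      # sandwich within the lattice perturbation L * granularity
      eps <- L * 1e-3
      expect_lte(p_dp, sum(en$probs[en$scores >= s - eps]) + 1e-12)
      expect_gte(p_dp, sum(en$probs[en$scores >= s + eps]) - 1e-12)
    }
  }
})

test_that("scan_window finds consensus matches with counting-argument p-values", {
  hot <- one_hot_pwm("ACGT")
  window <- paste0("TTTTT", "ACGT", "TTTTTTTT")
  hits <- scan_window(hot, window, threshold_p = 1e-2)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$offset, 5L)
  expect_equal(hits$p_value, 0.25^4)
  expect_identical(hits$matched_seq, "ACGT")

  # uniform PWM scores 0 bits everywhere with p = 1: no hits below 1
  unif <- structure(list(protein_id = "u", length = 3,
                         probs = matrix(0.25, 4, 3,
                                        dimnames = list(c("A", "C", "G", "U"),
                                                        NULL)),
                         logodds = matrix(0, 4, 3), pseudocount = 0,
                         background = c(A = 0.25, C = 0.25, G = 0.25,
                                        U = 0.25)),
                    class = "pwm_model")
  expect_identical(nrow(scan_window(unif, "ACGTACGT", threshold_p = 0.5)), 0L)
  all_hits <- scan_window(unif, "ACGTACGT", threshold_p = 1)
  expect_true(all(all_hits$score == 0) && all(all_hits$p_value == 1))

  expect_error(scan_window(hot, "ACG"), "shorter than PWM length")
  expect_error(scan_window(hot, "ACGTNN"), "non-ACGT")
})

test_that("one-hot hit counts equal exact string-match counts", {
  set.seed(14)
  for (i in 1:5) {
    L <- sample(3:6, 1)
    consensus <- random_dna(L)
    hot <- one_hot_pwm(consensus)
    window <- random_dna(51)
    hits <- scan_window(hot, window, threshold_p = 0.25^L)
    matches <- gregexpr(consensus, window, fixed = TRUE)[[1]]
    # gregexpr misses overlapping occurrences; count by hand instead
    n_occ <- sum(vapply(1:(51 - L + 1), function(o) {
      substr(window, o, o + L - 1) == consensus
    }, NA))
    expect_identical(nrow(hits), n_occ)
  }
})

test_that("background-sequence hit rate calibrates to the p-value threshold", {
  set.seed(71)
  pwm <- random_pwm(5)
  n <- 3000
  t <- 0.05
  hits <- 0L
  seqs <- vapply(seq_len(n), function(i) random_dna(5), "")
  for (s in seqs) {
    hit <- scan_window(pwm, s, threshold_p = t)
    hits <- hits + (nrow(hit) > 0L)
  }
  rate <- hits / n
  expect_lt(abs(rate - t), 0.015)
})

test_that("predict_interactions recovers constructed positives and handles edge cases", {
  cfg <- simulation_config(seed = 23, n_sites = 12, n_ppr_positive = 4,
                           n_ppr_decoy = 0)
  truth <- simulate_organelle(cfg)
  ppr <- simulate_ppr(truth)
  res <- predict_interactions(ppr$motifs, synthetic_code_table(),
                              truth$sites, truth$genome, truth$genes,
                              threshold_p = 1e-4)
  got <- paste(res$interactions$protein_id, res$interactions$target_id)
  want <- paste(ppr$truth$protein_id, ppr$truth$target_id)
  expect_true(all(want %in% got))  # every planted pair recovered
  # with no decoys, only positive proteins appear
  expect_true(all(grepl("^pprP", res$interactions$protein_id)))
  expect_true(all(res$interactions$p_value <= 1e-4))
  expect_true(all(c("q_value", "offset", "score") %in%
                    names(res$interactions)))

  empty <- predict_interactions(ppr$motifs[0, ], synthetic_code_table(),
                                truth$sites, truth$genome, truth$genes)
  expect_identical(nrow(empty$interactions), 0L)
  expect_identical(sum(empty$summary$n_proteins), 0L)
})

test_that("interaction summary bins per-protein target counts", {
  cfg <- simulation_config(seed = 29, n_sites = 10, n_ppr_positive = 3,
                           n_ppr_decoy = 2)
  truth <- simulate_organelle(cfg)
  ppr <- simulate_ppr(truth)
  res <- predict_interactions(ppr$motifs, synthetic_code_table(),
                              truth$sites, truth$genome, truth$genes,
                              threshold_p = 1e-4)
  expect_identical(res$summary$targets, c("1", "2", "3", "4", ">=5"))
  expect_identical(sum(res$summary$n_proteins),
                   length(unique(res$interactions$protein_id)))
  expect_equal(sum(res$summary$proportion), 1)
})
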