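#' Configuration for the synthetic organelle generator
#'
#' All randomness in the generator flows from `seed`; the companion
#' samplers ([simulate_pileups()], [simulate_peaks()], [simulate_ppr()])
#' derive their own seeds deterministically from it, so every artefact is
#' byte-identical across runs of the same configuration.
#'
#' Defaults emulate the study design the pipeline is built around: a
#' handful of organellar genes on both strands, planted C-to-U sites
#' skewed towards codon positions 1 and 2 in the proportions observed in
#' validated catalogues (57:116:4), site-level editing extents spanning
#' low to complete, six samples contrasting two high-, two mid- and two
#' low-editing profiles, and amplicon-scale read coverage.
#'
#' @param seed integer seed.
#' @param genome_length genome size in nt.
#' @param n_genes number of CDS gene models to carve out.
#' @param p_two_segments probability a gene is split into two segments
#'   (splice-junction exercise).
#' @param strand_mix fraction of genes on the minus strand.
#' @param n_sites number of planted C-to-U sites.
#' @param codon_position_weights sampling weights for codon positions
#'   1/2/3 of planted sites.
#' @param levels candidate per-site base editing levels.
#' @param n_samples number of samples.
#' @param sample_profile per-sample multiplier applied to the base level
#'   (clipped to \[0, 1\]).
#' @param dna_coverage,rna_coverage per-position read depth.
#' @param sequencing_error_rate per-read probability of a uniformly wrong
#'   base call.
#' @param peak_noise_cv coefficient of variation of the multiplicative
#'   chromatogram peak noise.
#' @param n_ppr_positive,n_ppr_decoy PPR proteins constructed to match
#'   planted windows / drawn at random.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 30000L,
                              n_genes = 12L,
                              p_two_segments = 0.3,
                              strand_mix = 0.5,
                              n_sites = 50L,
                              codon_position_weights = c(57, 116, 4) / 177,
                              levels = c(0.1, 0.3, 0.5, 0.8, 1.0),
                              n_samples = 6L,
                              sample_profile = c(1, 1, 0.6, 0.6, 0.3, 0.3),
                              dna_coverage = 100L,
                              rna_coverage = 100L,
                              sequencing_error_rate = 0.001,
                              peak_noise_cv = 0.05,
                              n_ppr_positive = 5L,
                              n_ppr_decoy = 5L) {
  stopifnot(seed == floor(seed), genome_length > 0, n_genes >= 1,
            p_two_segments >= 0, p_two_segments <= 1,
            strand_mix >= 0, strand_mix <= 1, n_sites >= 0,
            length(codon_position_weights) == 3L,
            all(codon_position_weights >= 0),
            sum(codon_position_weights) > 0,
            all(levels >= 0 & levels <= 1),
            n_samples >= 1, length(sample_profile) == n_samples,
            dna_coverage >= 1, rna_coverage >= 1,
            sequencing_error_rate >= 0, sequencing_error_rate < 1,
            peak_noise_cv >= 0, n_ppr_positive >= 0, n_ppr_decoy >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

#' Simulate a synthetic organelle genome with planted editing sites
#'
#' Generates an i.i.d.-uniform genome with `n_genes` intact ORFs
#' (ATG ... stop, no internal stop codons) carved out on both strands,
#' optionally split into two segments by an intervening spacer, then
#' plants `n_sites` C-to-U sites on transcript C positions sampled
#' according to `codon_position_weights`, each with a base editing level
#' drawn from `levels` and per-sample true levels
#' `pmin(1, base * sample_profile)`.
#'
#' @param config a [simulation_config()].
#' @return object of class `truth_set`: list with `genome` (named
#'   character), `genes` (list of [gene_model()]), `sites` (a
#'   [site_table()] with provenance `"simulated"` and a `base_level`
#'   column), `levels` (site x sample matrix of true levels), `config`.
#' @export
simulate_organelle <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  genome <- sample(DNA_BASES, config$genome_length, replace = TRUE)
  genes <- vector("list", config$n_genes)
  cursor <- 201L
  for (i in seq_len(config$n_genes)) {
    n_codons <- sample(80:150, 1L)
    strand <- if (runif(1) < config$strand_mix) "-" else "+"
    two_seg <- runif(1) < config$p_two_segments
    cds <- paste0("ATG",
                  paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    len <- nchar(cds)
    spacer <- if (two_seg) sample(60:200, 1L) else 0L
    footprint <- len + spacer
    if (cursor + footprint + 200L > config$genome_length) {
      stop("infeasible config: genome_length ", config$genome_length,
           " too small for ", config$n_genes, " genes (ran out at gene ",
           i, ")")
    }
    split_at <- if (two_seg) 3L * sample(10:(n_codons - 10L), 1L) else len
    part1 <- substr(cds, 1L, split_at)
    part2 <- if (two_seg) substr(cds, split_at + 1L, len) else ""
    if (strand == "+") {
      s1 <- cursor; e1 <- cursor + nchar(part1) - 1L
      genome[s1:e1] <- strsplit(part1, "")[[1L]]
      segs <- cbind(s1, e1)
      if (two_seg) {
        s2 <- e1 + spacer + 1L; e2 <- s2 + nchar(part2) - 1L
        genome[s2:e2] <- strsplit(part2, "")[[1L]]
        segs <- rbind(segs, cbind(s2, e2))
      }
    } else {
      # transcription runs right to left: first transcript part occupies
      # the higher-coordinate segment
      if (two_seg) {
        s2 <- cursor; e2 <- cursor + nchar(part2) - 1L
        genome[s2:e2] <- strsplit(revcomp(part2), "")[[1L]]
        s1 <- e2 + spacer + 1L; e1 <- s1 + nchar(part1) - 1L
        genome[s1:e1] <- strsplit(revcomp(part1), "")[[1L]]
        segs <- rbind(cbind(s1, e1), cbind(s2, e2))
      } else {
        s1 <- cursor; e1 <- cursor + len - 1L
        genome[s1:e1] <- strsplit(revcomp(cds), "")[[1L]]
        segs <- cbind(s1, e1)
      }
    }
    genes[[i]] <- gene_model(sprintf("g%02d", i), "CDS", strand, segs,
                             complete = TRUE, seqid = "synth_organelle")
    cursor <- cursor + footprint + sample(100:300, 1L)
  }
  genome <- setNames(paste(genome, collapse = ""), "synth_organelle")

  # pool of editable C positions (transcript coordinates)
  pool <- do.call(rbind, lapply(genes, function(g) {
    tx <- transcript_sequence(genome, g)
    pos <- which(strsplit(tx, "")[[1L]] == "C")
    if (!length(pos)) return(NULL)
    data.frame(gene_id = g$gene_id, cds_pos = pos,
               codon_position = codon_position(pos),
               stringsAsFactors = FALSE)
  }))
  if (config$n_sites > nrow(pool)) {
    stop("infeasible config: ", config$n_sites,
         " sites requested but only ", nrow(pool), " editable C positions")
  }
  w <- config$codon_position_weights[pool$codon_position]
  pick <- sample(nrow(pool), config$n_sites, prob = w)
  picked <- pool[sort(pick), , drop = FALSE]
  by_id <- setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  rows <- lapply(seq_len(nrow(picked)), function(i) {
    g <- by_id[[picked$gene_id[i]]]
    tx <- transcript_sequence(genome, g)
    cds_pos <- picked$cds_pos[i]
    ci <- (cds_pos + 2L) %/% 3L
    cp <- codon_position(cds_pos)
    ref_codon <- substr(tx, (ci - 1L) * 3L + 1L, ci * 3L)
    ed <- apply_edit(ref_codon, cp, codon_index = ci)
    data.frame(organelle = "chloroplast", gene_id = g$gene_id,
               genome_pos = cds_to_genome(g, cds_pos), cds_pos = cds_pos,
               ref_base = "C", alt_base = "T", codon_index = ci,
               codon_position = cp, ref_codon = ref_codon,
               alt_codon = ed$alt_codon, ref_aa = ed$ref_aa,
               alt_aa = ed$alt_aa, effect = ed$effect,
               stringsAsFactors = FALSE)
  })
  sites_df <- do.call(rbind, rows)
  sites_df$base_level <- sample(config$levels, nrow(sites_df),
                                replace = TRUE)
  sites <- site_table(sites_df, provenance = "simulated",
                      organelle = "chloroplast")
  levels <- outer(sites$base_level, config$sample_profile,
                  function(b, f) pmin(1, b * f))
  dimnames(levels) <- list(paste(sites$gene_id, sites$cds_pos, sep = ":"),
                           sprintf("S%d", seq_len(config$n_samples)))
  structure(list(genome = genome, genes = genes, sites = sites,
                 levels = levels, config = config),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(paste0("<truth_set> genome %d nt, %d genes, %d planted ",
                     "sites, %d samples (seed %d)\n"),
              nchar(x$genome), length(x$genes), nrow(x$sites),
              ncol(x$levels), x$config$seed))
  invisible(x)
}

# per-read error model: observed base = true base w.p. 1-e, else uniform
# over the other three; returns multinomial counts over A,C,G,T (reference
# strand)
.read_counts <- function(n, p_true, error_rate) {
  p_obs <- p_true * (1 - error_rate) + (sum(p_true) - p_true) * error_rate / 3
  drop(rmultinom(1L, n, p_obs))
}

#' Simulate DNA/RNA pileups for one sample
#'
#' One [call_from_pileups()]-ready row per genic genome position. DNA
#' reads follow the genome base; RNA reads at planted sites show the
#' edited base (transcript T, reference-strand complement for minus-strand
#' genes) with the site's true level for the sample. Both channels apply
#' the per-read uniform sequencing-error model.
#'
#' @param truth a [simulate_organelle()] truth set.
#' @param sample_index which sample's levels to use.
#' @return pileup data frame sorted by `genome_pos`.
#' @export
simulate_pileups <- function(truth, sample_index = 1L) {
  stopifnot(inherits(truth, "truth_set"),
            sample_index >= 1L, sample_index <= ncol(truth$levels))
  cfg <- truth$config
  set.seed((cfg$seed + 104729L * as.integer(sample_index)) %%
             .Machine$integer.max)
  gseq <- strsplit(truth$genome[[1L]], "")[[1L]]
  site_key <- paste(truth$sites$gene_id, truth$sites$genome_pos)
  rows <- list()
  for (g in truth$genes) {
    pos <- unlist(lapply(seq_len(nrow(g$segments)), function(i) {
      g$segments[i, 1L]:g$segments[i, 2L]
    }))
    for (p in pos) {
      true_base <- gseq[p]
      p_dna <- setNames(as.numeric(DNA_BASES == true_base), DNA_BASES)
      dna <- .read_counts(cfg$dna_coverage, p_dna, cfg$sequencing_error_rate)
      si <- match(paste(g$gene_id, p), site_key)
      if (!is.na(si)) {
        lvl <- truth$levels[si, sample_index]
        # transcript C -> T; on the reference strand of a minus gene the
        # edited base reads as A replacing G
        alt_ref <- if (g$strand == "+") "T" else "A"
        p_rna <- setNames(as.numeric(DNA_BASES == true_base) * (1 - lvl),
                          DNA_BASES)
        p_rna[alt_ref] <- p_rna[alt_ref] + lvl
      } else {
        p_rna <- setNames(as.numeric(DNA_BASES == true_base), DNA_BASES)
      }
      rna <- .read_counts(cfg$rna_coverage, p_rna, cfg$sequencing_error_rate)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_pos = p, dA = dna[[1L]], dC = dna[[2L]], dG = dna[[3L]],
        dT = dna[[4L]], rA = rna[[1L]], rC = rna[[2L]], rG = rna[[3L]],
        rT = rna[[4L]], strand = g$strand, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$genome_pos), , drop = FALSE]
}

#' Simulate chromatogram peak heights for all sites and samples
#'
#' `h_T = level * (1 + eps)`, `h_C = (1 - level) * (1 + eps')` with
#' independent Gaussian multiplicative noise of coefficient of variation
#' `peak_noise_cv`, truncated at zero. A and G peaks are zero.
#'
#' @param truth a [simulate_organelle()] truth set.
#' @return data frame with `site`, `sample`, `h_A`, `h_C`, `h_G`, `h_T`
#'   and the `true_level` used.
#' @export
simulate_peaks <- function(truth) {
  stopifnot(inherits(truth, "truth_set"))
  cfg <- truth$config
  set.seed((cfg$seed + 31337L) %% .Machine$integer.max)
  grid <- expand.grid(site = rownames(truth$levels),
                      sample = colnames(truth$levels),
                      stringsAsFactors = FALSE)
  lvl <- truth$levels[cbind(match(grid$site, rownames(truth$levels)),
                            match(grid$sample, colnames(truth$levels)))]
  n <- nrow(grid)
  f1 <- pmax(0, 1 + rnorm(n, 0, cfg$peak_noise_cv))
  f2 <- pmax(0, 1 + rnorm(n, 0, cfg$peak_noise_cv))
  data.frame(grid, h_A = 0, h_C = (1 - lvl) * f2, h_G = 0,
             h_T = lvl * f1, true_level = lvl, stringsAsFactors = FALSE)
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Simulate PPR proteins matched to planted sites, plus decoys
#'
#' Positive proteins are built to recognise a 7-12-nt subwindow of a
#' planted site's centered 51-base window (at least 7 motifs, so that a
#' perfect match can reach the conventional 1e-4 scan p-value; the best
#' achievable exact p-value of a length-L matrix is 4^-L): for every
#' base of the
#' subwindow a motif is emitted whose recognition code maps, in the given
#' code table, to a preference vector concentrating at least 0.9 on that
#' base. Decoy proteins draw their codes uniformly from the table's
#' triple rows. Motif classes cycle through P/L/S.
#'
#' @param truth a [simulate_organelle()] truth set.
#' @param codes a [code_table()] in which every base has a triple code
#'   with probability >= 0.9 (see [synthetic_code_table()]).
#' @return list with `motifs` (PPR motif data frame, input to
#'   [extract_codes()]) and `truth` (intended protein/target pairs with
#'   subwindow offsets).
#' @export
simulate_ppr <- function(truth, codes = synthetic_code_table()) {
  stopifnot(inherits(truth, "truth_set"), inherits(codes, "ppr_code_table"))
  cfg <- truth$config
  set.seed((cfg$seed + 7919L) %% .Machine$integer.max)
  tri <- codes[!is.na(codes$res2) & !is.na(codes$res5), , drop = FALSE]
  pcols <- c("pA", "pC", "pG", "pU")
  best_for <- lapply(RNA_BASES, function(b) {
    ix <- which(tri[[paste0("p", b)]] >= 0.9)
    if (!length(ix)) stop("insufficient code table: no triple code with ",
                          "probability >= 0.9 for base ", b)
    ix[1L]
  })
  names(best_for) <- RNA_BASES
  windows <- export_windows(truth$sites, truth$genome, truth$genes,
                            mode = "centered51", truncate = TRUE)
  names(windows) <- sub(" truncated$", "", names(windows))
  full <- windows[nchar(windows) == 51L]
  if (cfg$n_ppr_positive > length(full)) {
    stop("infeasible config: not enough full-length site windows for ",
         cfg$n_ppr_positive, " positive proteins")
  }
  motif_row <- function(pid, idx, code_row) {
    cls <- c("P", "L", "S")[((idx - 1L) %% 3L) + 1L]
    aa <- sample(AA_ALPHABET, 35L, replace = TRUE)
    aa[2L] <- code_row$res2
    aa[5L] <- code_row$res5
    aa[35L] <- code_row$res_last
    data.frame(protein_id = pid, motif_index = idx, motif_class = cls,
               motif_sequence = paste(aa, collapse = ""),
               stringsAsFactors = FALSE)
  }
  motifs <- list(); truth_rows <- list()
  targets <- sample(names(full), cfg$n_ppr_positive)
  for (k in seq_len(cfg$n_ppr_positive)) {
    win <- full[[targets[k]]]
    len <- sample(7:12, 1L)
    off <- sample(0:(51L - len), 1L)
    sub <- substr(win, off + 1L, off + len)
    sub_rna <- chartr("T", "U", sub)
    pid <- sprintf("pprP%02d", k)
    for (j in seq_len(len)) {
      b <- substr(sub_rna, j, j)
      motifs[[length(motifs) + 1L]] <-
        motif_row(pid, j, tri[best_for[[b]], , drop = FALSE])
    }
    truth_rows[[length(truth_rows) + 1L]] <-
      data.frame(protein_id = pid, target_id = targets[k], offset = off,
                 subwindow = sub, stringsAsFactors = FALSE)
  }
  for (k in seq_len(cfg$n_ppr_decoy)) {
    pid <- sprintf("pprD%02d", k)
    len <- sample(7:12, 1L)
    picks <- sample(nrow(tri), len, replace = TRUE)
    for (j in seq_len(len)) {
      motifs[[length(motifs) + 1L]] <-
        motif_row(pid, j, tri[picks[j], , drop = FALSE])
    }
  }
  motifs_df <- if (length(motifs)) do.call(rbind, motifs) else
    data.frame(protein_id = character(), motif_index = integer(),
               motif_class = character(), motif_sequence = character())
  truth_df <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(protein_id = character(), target_id = character(),
               offset = integer(), subwindow = character())
  list(motifs = motifs_df, truth = truth_df)
}
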