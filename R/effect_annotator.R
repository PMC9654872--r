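#' Codon position of a spliced-CDS coordinate
#'
#' Position within the codon (1, 2 or 3) of the 1-based position `cds_pos`
#' in a spliced coding sequence whose first base is position 1 of the start
#' codon: `((cds_pos - 1) mod 3) + 1`.
#'
#' @param cds_pos integer vector of 1-based CDS positions.
#' @return integer vector of codon positions in 1..3.
#' @export
#' @examples
#' codon_position(c(1234, 701, 1722))
codon_position <- function(cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (anyNA(cds_pos) || any(cds_pos < 1L)) {
    stop("cds_pos must be a positive integer")
  }
  ((cds_pos - 1L) %% 3L) + 1L
}

#' Translate codons under the standard genetic code
#'
#' Plant plastid and mitochondrial coding sequences use the standard code;
#' stop codons are rendered `"X"` to match the `R>X` notation of validated
#' site catalogues.
#'
#' @param codon character vector of trinucleotides over A/C/G/T (U accepted).
#' @return character vector of one-letter amino acids, `"X"` for stop.
#' @export
translate_codon <- function(codon) {
  codon <- chartr("u", "T", chartr("U", "T", toupper(codon)))
  if (any(nchar(codon) != 3L) || any(grepl("[^ACGT]", codon))) {
    stop("codons must be trinucleotides over A/C/G/T")
  }
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  aa[aa == "*"] <- "X"
  aa
}

# Effect taxonomy from an amino-acid pair; start_gain needs the alt codon
# and codon index, stop_gain needs only the pair. stop_loss is
# unreachable for C-to-U (no stop codon contains C).
classify_effect <- function(ref_aa, alt_aa, alt_codon = NA_character_,
                            codon_index = NA_integer_) {
  n <- max(length(ref_aa), length(alt_aa))
  alt_codon <- rep_len(alt_codon, n)
  codon_index <- rep_len(codon_index, n)
  eff <- ifelse(ref_aa == alt_aa, "synonymous",
                ifelse(alt_aa == "X" & ref_aa != "X", "stop_gain", "missense"))
  start <- !is.na(alt_codon) & alt_codon == "ATG" &
    !is.na(codon_index) & codon_index == 1L
  eff[start] <- "start_gain"
  eff
}

#' Apply a C-to-U edit to a codon
#'
#' Replaces the C at `codon_position` with T, translates both codons under
#' the standard genetic code and classifies the consequence:
#' `stop_gain` when the edit creates a termination codon (e.g. CGA to UGA),
#' `start_gain` when it creates AUG in the first codon (ACG to AUG),
#' `synonymous` when the amino acid is unchanged, otherwise `missense`.
#'
#' @param ref_codon trinucleotide with C at `codon_position`.
#' @param codon_position 1, 2 or 3.
#' @param codon_index 1-based codon number (needed to flag start gains).
#' @return list with `alt_codon`, `ref_aa`, `alt_aa`, `effect`.
#' @export
#' @examples
#' apply_edit("CGA", 1)          # stop gain
#' apply_edit("ACG", 2, codon_index = 1)  # start gain
apply_edit <- function(ref_codon, codon_position, codon_index = NA_integer_) {
  ref_codon <- toupper(ref_codon)
  stopifnot(length(ref_codon) == 1L, codon_position %in% 1:3)
  if (substr(ref_codon, codon_position, codon_position) != "C") {
    stop("codon ", ref_codon, " has no C at position ", codon_position,
         ": not an editable codon")
  }
  alt_codon <- ref_codon
  substr(alt_codon, codon_position, codon_position) <- "T"
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  effect <- classify_effect(ref_aa, alt_aa, alt_codon, codon_index)
  list(alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
       effect = effect)
}

#' Is an amino-acid transition achievable by C-to-U editing?
#'
#' Brute-force search over all 64 codons for one carrying C at every
#' position in `edited_positions` whose image after editing those C's to T
#' translates to the stated amino-acid pair. With the default single
#' position this tests achievability by one edit; passing several
#' positions models codons that carry more than one validated site, where
#' published catalogues print the jointly edited outcome on each row.
#'
#' @param ref_aa,alt_aa one-letter amino acids (`"X"` = stop).
#' @param edited_positions integer vector of codon positions (subset of 1:3).
#' @return logical.
#' @export
edit_achievable <- function(ref_aa, alt_aa, edited_positions) {
  edited_positions <- sort(unique(as.integer(edited_positions)))
  stopifnot(all(edited_positions %in% 1:3))
  codons <- names(Biostrings::GENETIC_CODE)
  for (c0 in codons) {
    if (!all(substring(c0, edited_positions, edited_positions) == "C")) next
    c1 <- c0
    for (p in edited_positions) substr(c1, p, p) <- "T"
    if (translate_codon(c0) == ref_aa && translate_codon(c1) == alt_aa) {
      return(TRUE)
    }
  }
  FALSE
}

#' Locate a genome position within gene models
#'
#' Returns every feature containing the position (organelle genomes can
#' hold overlapping ORFs; no precedence is applied). CDS hits report the
#' 1-based position in the spliced coding sequence counted in transcription
#' order across segments; tRNA/rRNA hits report the feature-local position.
#' Zero rows means intergenic.
#'
#' @param genome_pos single 1-based genome coordinate.
#' @param genes list of [gene_model()] objects.
#' @return data frame with `gene_id`, `feature_class`, `strand`, `local_pos`.
#' @export
locate <- function(genome_pos, genes) {
  stopifnot(length(genome_pos) == 1L, genome_pos >= 1L)
  hits <- lapply(genes, function(g) {
    lens <- g$segments[, 2L] - g$segments[, 1L] + 1L
    off <- c(0L, cumsum(lens))
    for (i in seq_len(nrow(g$segments))) {
      s <- g$segments[i, 1L]; e <- g$segments[i, 2L]
      if (genome_pos >= s && genome_pos <= e) {
        local <- if (g$strand == "+") genome_pos - s + 1L else e - genome_pos + 1L
        return(data.frame(gene_id = g$gene_id,
                          feature_class = g$feature_class,
                          strand = g$strand,
                          local_pos = as.integer(off[i] + local),
                          stringsAsFactors = FALSE))
      }
    }
    NULL
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), feature_class = character(),
                      strand = character(), local_pos = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Annotate candidate editing sites against gene models
#'
#' Maps each candidate genome position onto the gene models, derives the
#' CDS position, codon, amino-acid change and effect class for coding
#' candidates, and reports tRNA/rRNA/intergenic candidates separately.
#' Positions claimed by more than one gene are annotated once per
#' membership and listed in the `ambiguous` report; no silent choice is
#' made. A candidate whose transcript-strand reference base does not match
#' the genome raises a reference-mismatch error.
#'
#' @param candidates data frame with `genome_pos` and optionally
#'   `ref_base`, `alt_base` (transcript strand), `editing_freq`,
#'   `dna_cov`, `rna_cov`.
#' @param genome genome sequence (see [transcript_sequence()]).
#' @param genes list of [gene_model()] objects.
#' @param organelle label for the output table.
#' @return list with `sites` (a [site_table()] of coding candidates),
#'   `noncoding` (data frame) and `ambiguous` (data frame of multi-gene
#'   claims).
#' @export
annotate_sites <- function(candidates, genome, genes,
                           organelle = NA_character_) {
  stopifnot(is.data.frame(candidates), "genome_pos" %in% names(candidates))
  by_id <- setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  coding <- list(); noncoding <- list(); ambiguous <- list()
  for (i in seq_len(nrow(candidates))) {
    pos <- candidates$genome_pos[i]
    hit <- locate(pos, genes)
    cds_hits <- hit[hit$feature_class == "CDS", , drop = FALSE]
    if (nrow(hit) > 1L) {
      ambiguous[[length(ambiguous) + 1L]] <-
        data.frame(genome_pos = pos,
                   gene_ids = paste(hit$gene_id, collapse = ","),
                   stringsAsFactors = FALSE)
    }
    if (nrow(hit) == 0L) {
      noncoding[[length(noncoding) + 1L]] <-
        data.frame(genome_pos = pos, feature_class = "intergenic",
                   gene_id = NA_character_, local_pos = NA_integer_,
                   stringsAsFactors = FALSE)
      next
    }
    non_cds <- hit[hit$feature_class != "CDS", , drop = FALSE]
    if (nrow(non_cds)) {
      noncoding[[length(noncoding) + 1L]] <-
        data.frame(genome_pos = pos, feature_class = non_cds$feature_class,
                   gene_id = non_cds$gene_id, local_pos = non_cds$local_pos,
                   stringsAsFactors = FALSE)
    }
    for (j in seq_len(nrow(cds_hits))) {
      g <- by_id[[cds_hits$gene_id[j]]]
      cds_pos <- cds_hits$local_pos[j]
      tx <- transcript_sequence(genome, g)
      base <- substr(tx, cds_pos, cds_pos)
      if ("ref_base" %in% names(candidates) &&
          !is.na(candidates$ref_base[i]) && candidates$ref_base[i] != base) {
        stop("reference mismatch at genome position ", pos, " (gene ",
             g$gene_id, "): candidate ref '", candidates$ref_base[i],
             "' but transcript has '", base, "'")
      }
      if (base != "C") {
        stop("candidate at genome position ", pos, " (gene ", g$gene_id,
             "): transcript base is '", base, "', not an editable C")
      }
      ci <- (cds_pos + 2L) %/% 3L
      cp <- codon_position(cds_pos)
      ref_codon <- substr(tx, (ci - 1L) * 3L + 1L, ci * 3L)
      ed <- apply_edit(ref_codon, cp, codon_index = ci)
      row <- data.frame(
        organelle = organelle, gene_id = g$gene_id, genome_pos = pos,
        cds_pos = cds_pos, ref_base = "C", alt_base = "T",
        codon_index = ci, codon_position = cp,
        ref_codon = ref_codon, alt_codon = ed$alt_codon,
        ref_aa = ed$ref_aa, alt_aa = ed$alt_aa, effect = ed$effect,
        stringsAsFactors = FALSE)
      for (col in intersect(c("editing_freq", "dna_cov", "rna_cov"),
                            names(candidates))) {
        row[[col]] <- candidates[[col]][i]
      }
      coding[[length(coding) + 1L]] <- row
    }
  }
  sites <- if (length(coding)) {
    site_table(do.call(rbind, coding), provenance = "called",
               organelle = organelle)
  } else {
    site_table(data.frame(organelle = character(), gene_id = character(),
                          genome_pos = integer(), cds_pos = integer(),
                          ref_aa = character(), alt_aa = character(),
                          effect = character(), stringsAsFactors = FALSE),
               provenance = "called")
  }
  nc <- if (length(noncoding)) do.call(rbind, noncoding) else
    data.frame(genome_pos = integer(), feature_class = character(),
               gene_id = character(), local_pos = integer())
  amb <- if (length(ambiguous)) do.call(rbind, ambiguous) else
    data.frame(genome_pos = integer(), gene_ids = character())
  list(sites = sites, noncoding = nc, ambiguous = amb)
}

#' Compare an annotated site table against a reference table
#'
#' Rows are matched on `(gene_id, cds_pos)`; matched rows are compared on
#' codon position and amino-acid change. Purely a reporting operation.
#'
#' @param annotated,reference [site_table()] objects.
#' @return list with `rows` (per-row status data frame) and `summary`
#'   (named counts: reference rows, annotated rows, matched, mismatched
#'   fields, missed, spurious).
#' @export
check_against_table <- function(annotated, reference) {
  key <- function(x) paste(x$gene_id, x$cds_pos, sep = ":")
  ka <- key(annotated); kr <- key(reference)
  common <- intersect(ka, kr)
  ia <- match(common, ka); ir <- match(common, kr)
  rows <- data.frame(
    key = common,
    codon_position_match = annotated$codon_position[ia] ==
      reference$codon_position[ir],
    aa_change_match = annotated$ref_aa[ia] == reference$ref_aa[ir] &
      annotated$alt_aa[ia] == reference$alt_aa[ir],
    stringsAsFactors = FALSE)
  missed <- setdiff(kr, ka); spurious <- setdiff(ka, kr)
  summary <- c(n_reference = length(kr), n_annotated = length(ka),
               n_matched = length(common),
               n_field_mismatch = sum(!rows$codon_position_match |
                                        !rows$aa_change_match),
               n_missed = length(missed), n_spurious = length(spurious))
  list(rows = rows, summary = summary, missed = missed, spurious = spurious)
}

#' Internal-consistency report for a validated site catalogue
#'
#' For every row checks: (i) the printed codon position against the value
#' recomputed from the CDS coordinate; (ii) the printed amino-acid residue
#' number against `ceiling(cds_pos / 3)`; (iii) whether the printed
#' amino-acid transition is achievable by a single C-to-U at the printed
#' codon position ([edit_achievable()]); and (iv), where (iii) fails but
#' the codon hosts additional validated sites in the same table, whether
#' the transition is achievable by jointly editing all of the codon's
#' sites (catalogues print the fully edited outcome on each row of such
#' codons). Discrepancies are reported, never corrected.
#'
#' @param sites a [site_table()] loaded via [load_site_table()].
#' @return list with `rows` (per-row logical flags) and `summary` counts.
#' @export
check_table_consistency <- function(sites) {
  computed <- codon_position(sites$cds_pos)
  printed <- if ("codon_position_printed" %in% names(sites)) {
    sites$codon_position_printed
  } else sites$codon_position
  codon_formula_ok <- computed == printed
  aa_index_ok <- if ("aa_index_printed" %in% names(sites)) {
    sites$aa_index_printed == sites$codon_index
  } else rep(NA, nrow(sites))
  single <- mapply(edit_achievable, sites$ref_aa, sites$alt_aa, computed)
  codon_key <- paste(sites$gene_id, sites$codon_index, sep = ":")
  joint <- single
  for (i in which(!single)) {
    sibs <- which(codon_key == codon_key[i])
    pos <- unique(codon_position(sites$cds_pos[sibs]))
    if (length(pos) > 1L) {
      joint[i] <- edit_achievable(sites$ref_aa[i], sites$alt_aa[i], pos)
    }
  }
  rows <- data.frame(gene_id = sites$gene_id, cds_pos = sites$cds_pos,
                     codon_formula_ok = codon_formula_ok,
                     aa_index_ok = aa_index_ok,
                     single_edit_achievable = unname(single),
                     joint_edit_achievable = unname(joint),
                     stringsAsFactors = FALSE)
  list(rows = rows,
       summary = c(n = nrow(rows),
                   n_codon_formula_ok = sum(codon_formula_ok),
                   n_aa_index_ok = sum(aa_index_ok, na.rm = TRUE),
                   n_single_achievable = sum(single),
                   n_joint_achievable = sum(joint)))
}
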