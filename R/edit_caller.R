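#' Thresholds for the pileup-based editing-site caller
#'
#' The caller is a deliberately simple threshold filter over paired
#' DNA/RNA pileup evidence; thresholds are conservative defaults and fully
#' overridable. Note that organellar heteroplasmy cannot be distinguished
#' from editing by DNA/RNA comparison alone: the DNA homozygosity filter
#' (`max_dna_alt_fraction`) is the only guard, and calls carry the DNA
#' minor-allele fraction for downstream judgement.
#'
#' @param min_dna_cov minimum DNA coverage at a site.
#' @param min_rna_cov minimum RNA coverage.
#' @param min_edited_reads minimum number of edited (T) RNA reads.
#' @param min_editing_freq minimum T/(T+C) in RNA, in \[0, 1\].
#' @param max_dna_alt_fraction maximum non-C fraction tolerated in DNA
#'   (homozygosity filter), in \[0, 0.5).
#' @return object of class `caller_params`.
#' @export
caller_params <- function(min_dna_cov = 10, min_rna_cov = 10,
                          min_edited_reads = 3, min_editing_freq = 0.05,
                          max_dna_alt_fraction = 0.05) {
  stopifnot(min_dna_cov >= 0, min_rna_cov >= 0, min_edited_reads >= 0)
  if (min_editing_freq < 0 || min_editing_freq > 1) {
    stop("min_editing_freq must be in [0, 1]")
  }
  if (max_dna_alt_fraction < 0 || max_dna_alt_fraction >= 0.5) {
    stop("max_dna_alt_fraction must be in [0, 0.5)")
  }
  structure(list(min_dna_cov = min_dna_cov, min_rna_cov = min_rna_cov,
                 min_edited_reads = min_edited_reads,
                 min_editing_freq = min_editing_freq,
                 max_dna_alt_fraction = max_dna_alt_fraction),
            class = "caller_params")
}

#' Fold strand-specific base counts onto the transcript strand
#'
#' Pileup counts are recorded on the reference (+) strand; for a gene on
#' the minus strand the transcript-strand counts are the complement
#' (A and T swapped, C and G swapped).
#'
#' @param counts named numeric vector with entries A, C, G, T.
#' @param strand `"+"` or `"-"`; anything else is an error — the caller
#'   must not guess strand when applying the C/T test.
#' @return counts on the transcript strand.
#' @export
strand_fold <- function(counts, strand) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(counts)))
  if (identical(strand, "+")) return(counts[DNA_BASES])
  if (identical(strand, "-")) {
    return(setNames(counts[c("T", "G", "C", "A")], DNA_BASES))
  }
  stop("unknown strand '", strand, "': strand is required for the C/T test")
}

#' Call C-to-U sites from an aligned gDNA/cDNA sequence pair
#'
#' Mirrors amplicon validation: genomic-DNA and cDNA amplicons of the same
#' locus, already aligned on the transcript strand, are compared base by
#' base. Every position where the gDNA has C and the cDNA has T is a
#' C-to-U editing call (`editing_freq` 1 — Sanger consensus evidence);
#' every other mismatch is returned with `is_c_to_u = FALSE` so contrary
#' evidence is never hidden. Matching positions are omitted.
#'
#' @param gdna_seq,cdna_seq equal-length, gap-free aligned sequences on
#'   the transcript strand (U accepted in the cDNA).
#' @return data frame with `pos`, `ref_base`, `alt_base`, `is_c_to_u`,
#'   `editing_freq`.
#' @export
#' @examples
#' call_from_pair("ACG", "ATG")  # the classic start-gain edit
call_from_pair <- function(gdna_seq, cdna_seq) {
  g <- chartr("U", "T", toupper(gdna_seq))
  c_ <- chartr("U", "T", toupper(cdna_seq))
  if (nchar(g) != nchar(c_)) {
    stop("gDNA and cDNA sequences differ in length (", nchar(g), " vs ",
         nchar(c_), ")")
  }
  if (grepl("[-.]", g) || grepl("[-.]", c_)) {
    stop("gap characters found: sequences must be pre-aligned and ungapped")
  }
  gs <- strsplit(g, "")[[1L]]
  cs <- strsplit(c_, "")[[1L]]
  mism <- which(gs != cs)
  data.frame(pos = mism, ref_base = gs[mism], alt_base = cs[mism],
             is_c_to_u = gs[mism] == "C" & cs[mism] == "T",
             editing_freq = rep(1, length(mism)),
             stringsAsFactors = FALSE)
}

#' Call C-to-U editing sites from DNA/RNA pileup pairs
#'
#' A site is called when, on the transcript strand, (i) DNA coverage is at
#' least `min_dna_cov` with C the DNA majority base and a non-C fraction of
#' at most `max_dna_alt_fraction`, and (ii) RNA coverage is at least
#' `min_rna_cov` with at least `min_edited_reads` T reads and
#' `T/(T+C) >= min_editing_freq`. Other DNA/RNA differences passing the
#' coverage filters are retained in the `"non_canonical"` attribute of the
#' result rather than being silently dropped.
#'
#' @param pileups data frame sorted by `genome_pos` with columns
#'   `genome_pos`, `dA`, `dC`, `dG`, `dT`, `rA`, `rC`, `rG`, `rT`,
#'   `strand` (strand of the overlapping gene, `"+"` or `"-"`).
#' @param params a [caller_params()].
#' @return data frame of calls: `genome_pos`, `strand`, `ref_base`,
#'   `alt_base`, `editing_freq` (= T/(T+C) in RNA), `n_edited`,
#'   `dna_cov`, `rna_cov`, `dna_alt_fraction`, `is_c_to_u`.
#' @export
call_from_pileups <- function(pileups, params = caller_params()) {
  stopifnot(is.data.frame(pileups))
  need <- c("genome_pos", "dA", "dC", "dG", "dT", "rA", "rC", "rG", "rT",
            "strand")
  miss <- setdiff(need, names(pileups))
  if (length(miss)) stop("pileup table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.unsorted(pileups$genome_pos)) {
    stop("pileups must be sorted by genome_pos")
  }
  cnt <- as.matrix(pileups[, c("dA", "dC", "dG", "dT",
                               "rA", "rC", "rG", "rT")])
  if (any(cnt < 0) || any(cnt != floor(cnt))) {
    stop("pileup counts must be non-negative integers")
  }
  calls <- list(); noncanon <- list()
  for (i in seq_len(nrow(pileups))) {
    dna <- strand_fold(c(A = pileups$dA[i], C = pileups$dC[i],
                         G = pileups$dG[i], T = pileups$dT[i]),
                       pileups$strand[i])
    rna <- strand_fold(c(A = pileups$rA[i], C = pileups$rC[i],
                         G = pileups$rG[i], T = pileups$rT[i]),
                       pileups$strand[i])
    dcov <- sum(dna); rcov <- sum(rna)
    if (dcov < params$min_dna_cov || rcov < params$min_rna_cov) next
    dna_major <- DNA_BASES[which.max(dna)]
    alt_frac <- if (dcov > 0) 1 - dna[[dna_major]] / dcov else NA_real_
    if (dna_major == "C" && alt_frac <= params$max_dna_alt_fraction) {
      tc <- rna[["T"]] + rna[["C"]]
      freq <- if (tc > 0) rna[["T"]] / tc else 0
      if (rna[["T"]] >= params$min_edited_reads &&
          freq >= params$min_editing_freq) {
        calls[[length(calls) + 1L]] <- data.frame(
          genome_pos = pileups$genome_pos[i], strand = pileups$strand[i],
          ref_base = "C", alt_base = "T", editing_freq = freq,
          n_edited = unname(rna[["T"]]), dna_cov = dcov, rna_cov = rcov,
          dna_alt_fraction = unname(alt_frac), is_c_to_u = TRUE,
          stringsAsFactors = FALSE)
        next
      }
    }
    # secondary report: any non-reference RNA base passing the same
    # evidence thresholds at a homozygous DNA position
    alt_ok <- dna_major != "C" || alt_frac <= params$max_dna_alt_fraction
    if (alt_ok) {
      others <- setdiff(DNA_BASES, dna_major)
      for (b in others) {
        nb <- rna[[b]]
        denom <- nb + rna[[dna_major]]
        fb <- if (denom > 0) nb / denom else 0
        if (nb >= params$min_edited_reads && fb >= params$min_editing_freq &&
            1 - dna[[dna_major]] / dcov <= params$max_dna_alt_fraction) {
          noncanon[[length(noncanon) + 1L]] <- data.frame(
            genome_pos = pileups$genome_pos[i], strand = pileups$strand[i],
            ref_base = dna_major, alt_base = b, editing_freq = fb,
            n_edited = unname(nb), dna_cov = dcov, rna_cov = rcov,
            dna_alt_fraction = unname(1 - dna[[dna_major]] / dcov),
            is_c_to_u = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty <- data.frame(genome_pos = integer(), strand = character(),
                      ref_base = character(), alt_base = character(),
                      editing_freq = numeric(), n_edited = numeric(),
                      dna_cov = numeric(), rna_cov = numeric(),
                      dna_alt_fraction = numeric(), is_c_to_u = logical(),
                      stringsAsFactors = FALSE)
  out <- if (length(calls)) do.call(rbind, calls) else empty
  attr(out, "non_canonical") <-
    if (length(noncanon)) do.call(rbind, noncanon) else empty
  out
}

#' Read a DNA/RNA pileup table from TSV
#'
#' Columns: `genome_pos`, `dA..dT` (DNA base counts), `rA..rT` (RNA base
#' counts), `strand` — counts on the reference strand, strand of the
#' overlapping gene. A `sample_id` column is preserved when present.
#'
#' @param path TSV path.
#' @return data frame suitable for [call_from_pileups()].
#' @export
read_pileups <- function(path) {
  if (!file.exists(path)) stop("pileup table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_pos", "dA", "dC", "dG", "dT", "rA", "rC", "rG", "rT",
            "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pileup table '", path, "' lacks column(s): ",
                         paste(miss, collapse = ", "))
  num <- c("genome_pos", "dA", "dC", "dG", "dT", "rA", "rC", "rG", "rT")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("pileup table '", path, "': non-numeric value in column '", col,
           "' (row ", which(is.na(v))[1L], ")")
    }
    df[[col]] <- v
  }
  df
}

#' Write a pileup table to TSV
#' @param pileups pileup data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileups <- function(pileups, path) {
  write.table(pileups, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
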