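#' orgedit: C-to-U RNA editing analysis for plant organelle genomes
#'
#' Pipeline components: domain readers/writers and bundled validated-site
#' catalogues ([read_fasta()], [load_site_table()]), an editing-site caller
#' working from gDNA/cDNA pairs or DNA/RNA pileups ([call_from_pair()],
#' [call_from_pileups()]), codon-effect annotation ([annotate_sites()]),
#' flanking-base context profiling ([context_matrix()]), editing-level
#' quantification ([level_from_peaks()], [level_from_counts()]), PPR-code
#' PWM scanning ([build_pwm()], [scan_window()], [predict_interactions()])
#' and a seeded synthetic-data generator ([simulate_organelle()]).
#'
#' @keywords internal
#' @importFrom stats rbinom rmultinom rnorm runif setNames p.adjust qnorm
#' @importFrom utils read.delim write.table
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Resolve the sequence a gene model lives on from a (possibly multi-record)
# genome; gene models carry an optional seqid for multi-record genomes.
.genome_seq <- function(genome, gene = NULL) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (length(genome) == 1L) return(toupper(genome[[1L]]))
  sid <- if (!is.null(gene)) gene$seqid else NULL
  if (is.null(sid) || is.na(sid) || !sid %in% names(genome)) {
    stop("genome has ", length(genome),
         " records; gene model must carry a matching 'seqid'")
  }
  toupper(genome[[sid]])
}

#' Read a FASTA file of organelle genome sequences
#'
#' Sequences are upper-cased and restricted to the A/C/G/T/N alphabet;
#' record order is preserved and ids (first whitespace-delimited header
#' token) must be unique.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs)))) stop("FASTA record with empty header in '", path, "'")
  if (anyDuplicated(names(seqs))) {
    stop("duplicate FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) stop("empty sequence for record ",
                               names(seqs)[!nzchar(seqs)][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in record ", names(seqs)[bad][1L])
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Construct a gene model
#'
#' A stranded, possibly multi-segment CDS/tRNA/rRNA feature. Segments are
#' 1-based inclusive genome intervals listed in transcription order, i.e.
#' descending genome coordinate for minus-strand genes.
#'
#' @param gene_id feature identifier.
#' @param feature_class one of `"CDS"`, `"tRNA"`, `"rRNA"`.
#' @param strand `"+"` or `"-"`.
#' @param segments two-column matrix (start, end) in transcription order.
#' @param complete for CDS, whether the model is a complete ORF (total
#'   length then must be divisible by 3).
#' @param seqid optional sequence id for multi-record genomes.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, feature_class = c("CDS", "tRNA", "rRNA"),
                       strand, segments, complete = TRUE, seqid = NA_character_) {
  feature_class <- match.arg(feature_class)
  if (!strand %in% c("+", "-")) {
    stop("gene ", gene_id, ": unknown strand symbol '", strand, "'")
  }
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  if (nrow(segments) == 0L) stop("gene ", gene_id, ": no segments")
  if (any(segments[, 1L] > segments[, 2L])) {
    stop("gene ", gene_id, ": segment start > end")
  }
  if (any(segments < 1L)) stop("gene ", gene_id, ": segment coordinate < 1")
  if (nrow(segments) > 1L) {
    ord <- segments[order(segments[, 1L]), , drop = FALSE]
    if (any(ord[-nrow(ord), 2L] >= ord[-1L, 1L])) {
      stop("gene ", gene_id, ": overlapping segments")
    }
    # transcription order: ascending on +, descending on -
    asc <- all(diff(segments[, 1L]) > 0)
    desc <- all(diff(segments[, 1L]) < 0)
    if ((strand == "+" && !asc) || (strand == "-" && !desc)) {
      stop("gene ", gene_id, ": segments not in transcription order for strand ",
           strand)
    }
  }
  len <- sum(segments[, 2L] - segments[, 1L] + 1L)
  if (feature_class == "CDS" && isTRUE(complete) && len %% 3L != 0L) {
    stop("gene ", gene_id, ": complete CDS length ", len,
         " not divisible by 3")
  }
  structure(list(gene_id = gene_id, feature_class = feature_class,
                 strand = strand, segments = segments,
                 complete = isTRUE(complete), seqid = seqid),
            class = "gene_model")
}

#' Total feature length of a gene model
#' @param gene a [gene_model()].
#' @return integer length in nucleotides.
#' @export
feature_length <- function(gene) {
  sum(gene$segments[, 2L] - gene$segments[, 1L] + 1L)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s [%s, %s] %d segment(s), %d nt\n",
              x$gene_id, x$feature_class, x$strand,
              nrow(x$segments), feature_length(x)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' CDS, tRNA and rRNA features are retained; multi-segment CDS are grouped
#' by their `Parent` attribute (falling back to `ID`, then `gene_id`) and
#' segments are ordered 5' to 3' in transcription order.
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates).
#' @param complete whether CDS models are complete ORFs (length checked
#'   to be divisible by 3).
#' @return list of [gene_model()] objects.
#' @export
read_gff <- function(path, complete = TRUE) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "tRNA", "rRNA")
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no CDS/tRNA/rRNA features in '", path, "'")
  md <- S4Vectors::mcols(gr)
  key <- rep(NA_character_, length(gr))
  if ("Parent" %in% names(md)) {
    par <- as.character(S4Vectors::unstrsplit(md$Parent, sep = ","))
    key[nzchar(par)] <- par[nzchar(par)]
  }
  if ("ID" %in% names(md)) {
    id <- as.character(md$ID)
    fill <- is.na(key) & !is.na(id) & nzchar(id)
    key[fill] <- id[fill]
  }
  if (anyNA(key)) stop("GFF feature without Parent/ID attribute in '", path, "'")
  out <- lapply(split(seq_along(gr), key), function(ix) {
    sub <- gr[ix]
    strand <- unique(as.character(GenomicRanges::strand(sub)))
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      stop("gene ", key[ix[1L]], ": unknown or inconsistent strand symbol '",
           paste(strand, collapse = "/"), "'")
    }
    cls <- unique(as.character(sub$type))
    if (length(cls) != 1L) {
      stop("gene ", key[ix[1L]], ": mixed feature classes")
    }
    st <- GenomicRanges::start(sub)
    en <- GenomicRanges::end(sub)
    ord <- if (strand == "+") order(st) else order(st, decreasing = TRUE)
    gene_model(gene_id = key[ix[1L]], feature_class = cls, strand = strand,
               segments = cbind(st[ord], en[ord]), complete = complete,
               seqid = as.character(GenomicRanges::seqnames(sub))[1L])
  })
  unname(out)
}

#' Write gene models to a GFF3 file
#'
#' @param genes list of [gene_model()] objects.
#' @param path output path.
#' @param seqid sequence id used when gene models carry none.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path, seqid = "genome") {
  rows <- do.call(rbind, lapply(genes, function(g) {
    sid <- if (is.na(g$seqid)) seqid else g$seqid
    lens <- g$segments[, 2L] - g$segments[, 1L] + 1L
    phase <- if (g$feature_class == "CDS") {
      # bases to skip at each segment start to reach a codon boundary,
      # accumulated in transcription order
      as.integer((3L - (c(0L, cumsum(lens)[-length(lens)]) %% 3L)) %% 3L)
    } else {
      rep(NA_integer_, length(lens))
    }
    data.frame(seqid = sid, start = g$segments[, 1L], end = g$segments[, 2L],
               strand = g$strand, type = g$feature_class,
               id = paste0(g$gene_id, ".seg", seq_len(nrow(g$segments))),
               parent = g$gene_id, phase = phase, stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$seqid,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand)
  gr$type <- rows$type
  gr$phase <- rows$phase
  gr$ID <- rows$id
  gr$Parent <- rows$parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Spliced transcript-strand sequence of a gene model
#'
#' Segments are extracted from the genome, reverse-complemented for
#' minus-strand genes, and concatenated in transcription order, yielding
#' the mature (unedited) transcript sequence in DNA alphabet.
#'
#' @param genome a single sequence (character), a named character vector,
#'   or a `DNAStringSet`.
#' @param gene a [gene_model()].
#' @return single character string.
#' @export
transcript_sequence <- function(genome, gene) {
  seq <- .genome_seq(genome, gene)
  n <- nchar(seq)
  if (any(gene$segments[, 2L] > n)) {
    stop("gene ", gene$gene_id, ": segment out of genome bounds (genome ",
         n, " nt)")
  }
  parts <- substring(seq, gene$segments[, 1L], gene$segments[, 2L])
  if (gene$strand == "-") parts <- revcomp(parts)
  paste0(parts, collapse = "")
}

# Map a feature-local (transcript) position back to its genome coordinate.
cds_to_genome <- function(gene, cds_pos) {
  lens <- gene$segments[, 2L] - gene$segments[, 1L] + 1L
  if (cds_pos < 1L || cds_pos > sum(lens)) {
    stop("gene ", gene$gene_id, ": transcript position ", cds_pos,
         " out of bounds")
  }
  cum <- cumsum(lens)
  seg <- which(cds_pos <= cum)[1L]
  within <- cds_pos - (if (seg > 1L) cum[seg - 1L] else 0L)
  if (gene$strand == "+") {
    gene$segments[seg, 1L] + within - 1L
  } else {
    gene$segments[seg, 2L] - within + 1L
  }
}

# ---- site tables -----------------------------------------------------------

SITE_TABLE_COLUMNS <- c("organelle", "gene_id", "genome_pos", "cds_pos",
                        "ref_base", "alt_base", "codon_index",
                        "codon_position", "ref_aa", "alt_aa", "effect")

.provenances <- c("validated_chloroplast", "validated_mitochondrion",
                  "called", "simulated")

#' Construct a site table
#'
#' A site table is a data frame of C-to-U editing sites, one row per event,
#' with genome and spliced-CDS coordinates, codon bookkeeping and the
#' amino-acid consequence. `(gene_id, genome_pos)` pairs must be unique.
#'
#' @param df data frame carrying at least `gene_id`, `genome_pos`,
#'   `cds_pos`, `ref_aa`, `alt_aa`.
#' @param provenance where the rows came from: a bundled validated
#'   catalogue, the caller, or the simulator.
#' @param organelle organelle label applied when `df` has no
#'   `organelle` column.
#' @return data frame of class `site_table`.
#' @export
site_table <- function(df, provenance = c("called", "simulated",
                                          "validated_chloroplast",
                                          "validated_mitochondrion"),
                       organelle = NA_character_) {
  provenance <- match.arg(provenance)
  if (!"organelle" %in% names(df)) df$organelle <- rep(organelle, nrow(df))
  if (!"ref_base" %in% names(df)) df$ref_base <- rep("C", nrow(df))
  if (!"alt_base" %in% names(df)) df$alt_base <- rep("T", nrow(df))
  if (!"codon_index" %in% names(df)) df$codon_index <- (df$cds_pos + 2L) %/% 3L
  if (!"codon_position" %in% names(df)) {
    df$codon_position <- codon_position(df$cds_pos)
  }
  if (!"effect" %in% names(df)) {
    df$effect <- classify_effect(df$ref_aa, df$alt_aa,
                                 alt_codon = if ("alt_codon" %in% names(df))
                                   df$alt_codon else NA_character_,
                                 codon_index = df$codon_index)
  }
  missing <- setdiff(SITE_TABLE_COLUMNS, names(df))
  for (m in missing) df[[m]] <- NA
  if (any(df$ref_base != "C")) {
    stop("non-C reference base in site table (C-to-U events only)")
  }
  dup <- duplicated(df[, c("gene_id", "genome_pos")])
  if (any(dup)) {
    stop("duplicate (gene_id, genome_pos) in site table: ",
         paste0(df$gene_id[dup], ":", df$genome_pos[dup], collapse = ", "))
  }
  bad <- df$codon_position < 1L | df$codon_position > 3L
  if (any(bad, na.rm = TRUE)) stop("codon_position outside 1..3")
  front <- intersect(SITE_TABLE_COLUMNS, names(df))
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("site_table", "data.frame"))
}

#' Load a validated/called site table from TSV
#'
#' Expects the five catalogue columns `gene`, `genome_position`,
#' `edited_nucleotide` (e.g. `C701`: reference base plus 1-based position in
#' the spliced CDS), `amino_acid_change` (e.g. `S234>F234`) and
#' `position_in_codon`. The printed codon position is cross-checked against
#' `((cds_pos - 1) mod 3) + 1`; mismatches are recorded in the
#' `"codon_position_mismatches"` attribute, never silently fixed.
#'
#' @param path TSV file path.
#' @param provenance see [site_table()].
#' @return a [site_table()] with the extra columns `aa_index_printed`,
#'   `codon_position_printed` and (if present in the file)
#'   `inferred_strand`.
#' @export
load_site_table <- function(path, provenance = c("called", "simulated",
                                                 "validated_chloroplast",
                                                 "validated_mitochondrion")) {
  provenance <- match.arg(provenance)
  if (!file.exists(path)) stop("site table not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "genome_position", "edited_nucleotide",
            "amino_acid_change", "position_in_codon")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("site table '", path, "' lacks column(s): ",
                         paste(miss, collapse = ", "))
  m <- regmatches(raw$edited_nucleotide,
                  regexec("^([ACGT])([0-9]+)$", raw$edited_nucleotide))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("unparseable edited_nucleotide token '",
                     raw$edited_nucleotide[bad][1L], "' (row ",
                     which(bad)[1L], ")")
  ref_base <- vapply(m, `[`, "", 2L)
  if (any(ref_base != "C")) {
    stop("non-C edited nucleotide '", raw$edited_nucleotide[ref_base != "C"][1L],
         "': only C-to-U events are representable")
  }
  cds_pos <- as.integer(vapply(m, `[`, "", 3L))
  a <- regmatches(raw$amino_acid_change,
                  regexec("^([A-Z*])([0-9]+)\\s*(?:>|->)\\s*([A-Z*])([0-9]+)$",
                          raw$amino_acid_change))
  bad <- vapply(a, length, 1L) != 5L
  if (any(bad)) stop("unparseable amino_acid_change token '",
                     raw$amino_acid_change[bad][1L], "' (row ",
                     which(bad)[1L], ")")
  printed <- as.integer(raw$position_in_codon)
  if (any(is.na(printed) | printed < 1L | printed > 3L)) {
    stop("position_in_codon outside 1..3")
  }
  organelle <- switch(provenance,
                      validated_chloroplast = "chloroplast",
                      validated_mitochondrion = "mitochondrion",
                      NA_character_)
  df <- data.frame(
    organelle = organelle,
    gene_id = raw$gene,
    genome_pos = as.integer(gsub(",", "", raw$genome_position)),
    cds_pos = cds_pos,
    ref_base = ref_base,
    alt_base = "T",
    codon_index = (cds_pos + 2L) %/% 3L,
    codon_position = printed,
    ref_aa = vapply(a, `[`, "", 2L),
    alt_aa = vapply(a, `[`, "", 4L),
    aa_index_printed = as.integer(vapply(a, `[`, "", 3L)),
    codon_position_printed = printed,
    stringsAsFactors = FALSE)
  if ("inferred_strand" %in% names(raw)) df$inferred_strand <- raw$inferred_strand
  computed <- codon_position(cds_pos)
  mism <- which(computed != printed)
  out <- site_table(df, provenance = provenance, organelle = organelle)
  attr(out, "codon_position_mismatches") <-
    data.frame(row = mism, gene_id = df$gene_id[mism],
               cds_pos = df$cds_pos[mism],
               printed = printed[mism], computed = computed[mism])
  out
}

#' Write a site table to TSV
#'
#' Emits the five catalogue columns plus any computed columns present.
#'
#' @param sites a [site_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  out <- data.frame(
    gene = sites$gene_id,
    genome_position = sites$genome_pos,
    edited_nucleotide = paste0(sites$ref_base, sites$cds_pos),
    amino_acid_change = paste0(sites$ref_aa, sites$codon_index, ">",
                               sites$alt_aa, sites$codon_index),
    editing_type = "C>T",
    position_in_codon = sites$codon_position,
    stringsAsFactors = FALSE)
  extra <- intersect(c("inferred_strand", "effect", "ref_codon", "alt_codon",
                       "editing_freq", "dna_cov", "rna_cov"), names(sites))
  for (e in extra) out[[e]] <- sites[[e]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled validated editing-site catalogues for tea plant
#'
#' Machine-readable transcriptions of the published, experimentally
#' validated C-to-U editing-site catalogues for the tea plant
#' (*Camellia sinensis*): 38 chloroplast sites across 22 genes and 139
#' mitochondrial sites across 22 genes. The `inferred_strand` column is
#' derived from the trend of genome position against CDS position within
#' each multi-site gene and is metadata, not an assertion of the source.
#'
#' @param organelle which catalogue to load.
#' @return a [site_table()].
#' @export
#' @examples
#' nrow(tea_sites("chloroplast"))
tea_sites <- function(organelle = c("chloroplast", "mitochondrion")) {
  organelle <- match.arg(organelle)
  file <- switch(organelle,
                 chloroplast = "tea_chloroplast_sites.tsv",
                 mitochondrion = "tea_mitochondria_sites.tsv")
  prov <- switch(organelle,
                 chloroplast = "validated_chloroplast",
                 mitochondrion = "validated_mitochondrion")
  path <- system.file("extdata", file, package = "orgedit", mustWork = TRUE)
  load_site_table(path, provenance = prov)
}
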