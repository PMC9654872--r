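#' Extract a flanking window around an edited transcript position
#'
#' Windows are taken in transcript coordinates, so strand and splice
#' junctions are handled once: the window is a substring of the spliced
#' transcript-strand sequence. The edited base itself is included only
#' when `include_center = TRUE` (centered windows); upstream-only exports
#' exclude it.
#'
#' @param genome genome sequence (see [transcript_sequence()]).
#' @param gene a [gene_model()].
#' @param cds_pos 1-based position of the edited base in the spliced CDS.
#' @param upstream,downstream number of bases requested on each side.
#' @param include_center include the edited base itself.
#' @param truncate allow windows crossing the transcript ends to be
#'   clipped (flagged via the `"truncated"` attribute); otherwise an
#'   out-of-bounds window is an error.
#' @return character string with attributes `truncated` (logical) and
#'   `center_offset` (0-based offset of the edited base within the window,
#'   or -1 when the center is excluded).
#' @export
flanking_window <- function(genome, gene, cds_pos, upstream, downstream,
                            include_center = TRUE, truncate = FALSE) {
  tx <- transcript_sequence(genome, gene)
  n <- nchar(tx)
  if (cds_pos < 1L || cds_pos > n) {
    stop("gene ", gene$gene_id, ": cds_pos ", cds_pos,
         " outside transcript (", n, " nt)")
  }
  lo <- cds_pos - upstream
  hi <- cds_pos + downstream
  trunc <- lo < 1L || hi > n
  if (trunc && !truncate) {
    stop("gene ", gene$gene_id, ": window [", lo, ", ", hi,
         "] crosses transcript bounds (", n,
         " nt); pass truncate = TRUE to clip")
  }
  lo <- max(lo, 1L); hi <- min(hi, n)
  if (include_center) {
    out <- substr(tx, lo, hi)
    center <- cds_pos - lo
  } else {
    left <- if (cds_pos > lo) substr(tx, lo, cds_pos - 1L) else ""
    right <- if (hi > cds_pos) substr(tx, cds_pos + 1L, hi) else ""
    out <- paste0(left, right)
    center <- -1L
  }
  attr(out, "truncated") <- trunc
  attr(out, "center_offset") <- as.integer(center)
  out
}

#' Flanking-base frequency matrix around editing sites
#'
#' Per-position nucleotide frequencies at transcript positions -5..-1 and
#' +1..+5 relative to the edited C (position 0 excluded). Sites whose
#' window crosses a transcript end contribute only their available
#' positions; the denominator is tracked per column, so each row of the
#' returned matrix sums to 1 over the sites that cover it.
#'
#' @param sites a [site_table()] with `gene_id` and `cds_pos`.
#' @param genome genome sequence.
#' @param genes list of [gene_model()] objects.
#' @param flank half-width of the profiled window (default 5).
#' @return data frame with columns `position` (e.g. `"-5"`, `"+4"`),
#'   `A`, `C`, `G`, `T` (frequencies) and `n` (sites covering the
#'   position).
#' @export
context_matrix <- function(sites, genome, genes, flank = 5L) {
  if (nrow(sites) == 0L) stop("empty site set")
  by_id <- setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  offsets <- setdiff(seq(-flank, flank), 0L)
  counts <- matrix(0L, nrow = length(offsets), ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  txcache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(sites))) {
    gid <- sites$gene_id[i]
    g <- by_id[[gid]]
    if (is.null(g)) stop("site references unknown gene '", gid, "'")
    tx <- if (!is.null(txcache[[gid]])) txcache[[gid]] else {
      txcache[[gid]] <- transcript_sequence(genome, g)
    }
    n <- nchar(tx)
    for (k in seq_along(offsets)) {
      idx <- sites$cds_pos[i] + offsets[k]
      if (idx >= 1L && idx <= n) {
        b <- substr(tx, idx, idx)
        if (b %in% DNA_BASES) counts[k, b] <- counts[k, b] + 1L
      }
    }
  }
  n_col <- as.integer(rowSums(counts))
  freq <- counts / ifelse(n_col > 0L, n_col, 1L)
  data.frame(position = ifelse(offsets > 0, paste0("+", offsets),
                               as.character(offsets)),
             freq, n = n_col, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Export per-site sequence windows as FASTA
#'
#' `upstream25` exports the 25 bases upstream of each edited C (the input
#' convention of motif-discovery tools); `centered51` exports the 51-base
#' window from -25 to +25 including the edited base (the target-sequence
#' convention of PPR/PWM scanning). Record ids are `gene_id:cds_pos`;
#' truncated windows are flagged in the description.
#'
#' @param sites a [site_table()].
#' @param genome genome sequence.
#' @param genes list of [gene_model()] objects.
#' @param mode `"upstream25"` or `"centered51"`.
#' @param path optional FASTA output path.
#' @param truncate allow clipped windows near transcript ends.
#' @return named character vector of window sequences (names carry the
#'   `" truncated"` description suffix where applicable), invisibly when
#'   `path` is given.
#' @export
export_windows <- function(sites, genome, genes,
                           mode = c("upstream25", "centered51"),
                           path = NULL, truncate = TRUE) {
  mode <- match.arg(mode)
  by_id <- setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  up <- 25L
  down <- if (mode == "centered51") 25L else 0L
  center <- mode == "centered51"
  out <- character(nrow(sites))
  nm <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    g <- by_id[[sites$gene_id[i]]]
    if (is.null(g)) stop("site references unknown gene '", sites$gene_id[i], "'")
    w <- flanking_window(genome, g, sites$cds_pos[i], up, down,
                         include_center = center, truncate = truncate)
    id <- paste0(sites$gene_id[i], ":", sites$cds_pos[i])
    nm[i] <- if (isTRUE(attr(w, "truncated"))) paste(id, "truncated") else id
    out[i] <- as.character(w)
  }
  names(out) <- nm
  if (!is.null(path)) {
    write_fasta(out, path)
    return(invisible(out))
  }
  out
}
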