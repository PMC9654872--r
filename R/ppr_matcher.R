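#' @rdname build_pwm
#' @format NULL
PPR_NT_CLASSES <- c("P", "P1", "P2", "L", "L1", "L2", "S", "S1", "S2")

PPR_CLASSES <- c(PPR_NT_CLASSES, "E", "E+", "DYW")

RNA_BASES <- c("A", "C", "G", "U")

#' Extract PPR recognition codes from motif sequences
#'
#' Each ~35-residue PPR motif recognises one RNA base; the identity of the
#' second, fifth and last residues of the motif carries the recognition
#' code. This extracts the (residue-2, residue-5, last-residue) triple for
#' every motif, preserving N-to-C order.
#'
#' @param motifs data frame with columns `protein_id`, `motif_index`,
#'   `motif_class` (one of P/P1/P2/L/L1/L2/S/S1/S2/E/E+/DYW) and
#'   `motif_sequence` (amino acids, length >= 5).
#' @return data frame with `protein_id`, `motif_index`, `motif_class`,
#'   `res2`, `res5`, `res_last`, ordered by protein and motif index.
#' @export
extract_codes <- function(motifs) {
  stopifnot(is.data.frame(motifs),
            all(c("protein_id", "motif_index", "motif_class",
                  "motif_sequence") %in% names(motifs)))
  bad_class <- !motifs$motif_class %in% PPR_CLASSES
  if (any(bad_class)) {
    stop("unknown PPR motif class '", motifs$motif_class[bad_class][1L], "'")
  }
  seqs <- toupper(motifs$motif_sequence)
  short <- nchar(seqs) < 5L
  if (any(short)) {
    stop("PPR motif shorter than 5 residues (protein ",
         motifs$protein_id[short][1L], ", motif ",
         motifs$motif_index[short][1L], ")")
  }
  out <- data.frame(protein_id = motifs$protein_id,
                    motif_index = motifs$motif_index,
                    motif_class = motifs$motif_class,
                    res2 = substr(seqs, 2L, 2L),
                    res5 = substr(seqs, 5L, 5L),
                    res_last = substr(seqs, nchar(seqs), nchar(seqs)),
                    stringsAsFactors = FALSE)
  out[order(out$protein_id, out$motif_index), , drop = FALSE]
}

#' Construct or read a PPR code table
#'
#' Maps recognition codes to base-preference probability vectors over
#' A/C/G/U. Keys are the triple (res2, res5, res_last); rows with `res2`
#' empty define pair (res5, res_last) fallbacks and rows with both `res2`
#' and `res5` empty define single (res_last) fallbacks. Every vector must
#' sum to 1.
#'
#' @param df data frame with columns `res2`, `res5`, `res_last`, `pA`,
#'   `pC`, `pG`, `pU` (`res2`/`res5` may be `NA`/empty for fallback rows).
#' @return object of class `ppr_code_table`.
#' @export
code_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("res2", "res5", "res_last", "pA", "pC", "pG", "pU") %in%
                  names(df)))
  if (nrow(df) == 0L) stop("empty code table")
  for (col in c("res2", "res5")) {
    v <- as.character(df[[col]])
    v[!is.na(v) & (v == "" | v == "*" | v == ".")] <- NA_character_
    df[[col]] <- v
  }
  p <- as.matrix(df[, c("pA", "pC", "pG", "pU")])
  sums <- rowSums(p)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("code-table probability vector does not sum to 1 (row ",
         which(abs(sums - 1) > 1e-9)[1L], ")")
  }
  if (any(p < 0)) stop("negative probability in code table")
  structure(df, class = c("ppr_code_table", "data.frame"))
}

#' @rdname code_table
#' @param path TSV file with the columns above.
#' @export
read_code_table <- function(path) {
  if (!file.exists(path)) stop("code table not found: ", path)
  code_table(read.delim(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""),
                        colClasses = c(res2 = "character",
                                       res5 = "character",
                                       res_last = "character")))
}

#' A synthetic, fully invertible PPR code table
#'
#' Four triple codes (one strongly preferring each base, probability
#' 0.97), pair fallbacks at 0.90 and single fallbacks at 0.40. Used by the
#' simulator and tests; it is a synthetic stand-in, not a published code
#' dataset.
#'
#' @return a [code_table()].
#' @export
synthetic_code_table <- function() {
  tri <- function(r5, rl, base) {
    p <- setNames(rep(0.01, 4L), RNA_BASES); p[base] <- 0.97
    data.frame(res2 = "F", res5 = r5, res_last = rl,
               pA = p[["A"]], pC = p[["C"]], pG = p[["G"]], pU = p[["U"]],
               stringsAsFactors = FALSE)
  }
  pair <- function(r5, rl, base) {
    p <- setNames(rep(0.1 / 3, 4L), RNA_BASES); p[base] <- 0.90
    data.frame(res2 = NA_character_, res5 = r5, res_last = rl,
               pA = p[["A"]], pC = p[["C"]], pG = p[["G"]], pU = p[["U"]],
               stringsAsFactors = FALSE)
  }
  single <- function(rl, base) {
    p <- setNames(rep(0.2, 4L), RNA_BASES); p[base] <- 0.40
    data.frame(res2 = NA_character_, res5 = NA_character_, res_last = rl,
               pA = p[["A"]], pC = p[["C"]], pG = p[["G"]], pU = p[["U"]],
               stringsAsFactors = FALSE)
  }
  code_table(rbind(
    tri("T", "N", "A"), tri("T", "D", "G"), tri("S", "N", "C"),
    tri("S", "D", "U"),
    pair("T", "N", "A"), pair("T", "D", "G"), pair("S", "N", "C"),
    pair("S", "D", "U"),
    single("N", "A"), single("D", "G")))
}

# triple -> pair -> single -> background lookup of one motif's preference
.code_lookup <- function(codes, res2, res5, res_last, background) {
  pcols <- c("pA", "pC", "pG", "pU")
  hit <- which(!is.na(codes$res2) & codes$res2 == res2 &
                 !is.na(codes$res5) & codes$res5 == res5 &
                 codes$res_last == res_last)
  if (!length(hit)) {
    hit <- which(is.na(codes$res2) & !is.na(codes$res5) &
                   codes$res5 == res5 & codes$res_last == res_last)
  }
  if (!length(hit)) {
    hit <- which(is.na(codes$res2) & is.na(codes$res5) &
                   codes$res_last == res_last)
  }
  if (!length(hit)) return(setNames(background, RNA_BASES))
  setNames(as.numeric(codes[hit[1L], pcols]), RNA_BASES)
}

#' Build a base-preference PWM for a PPR protein
#'
#' Each nucleotide-specifying motif (P/L/S families) contributes one PWM
#' column in N-to-C order, which maps onto the target RNA 5' to 3'; E,
#' E+ and DYW motifs contribute no column. Each motif's preference vector
#' is looked up in the code table by triple, falling back to pair, then
#' single, then the background distribution. A pseudocount is added and
#' columns renormalised before taking base-2 log-odds against the
#' background.
#'
#' @param codes_df output of [extract_codes()] for one protein (or a
#'   subset of it; the `protein_id` must be unique).
#' @param codes a [code_table()].
#' @param pseudocount non-negative pseudocount added per base.
#' @param background background base probabilities (A/C/G/U), default
#'   uniform.
#' @return object of class `pwm_model`: list with `protein_id`, `length`,
#'   `probs` (4 x L), `logodds` (4 x L, bits), `pseudocount`,
#'   `background`.
#' @export
build_pwm <- function(codes_df, codes, pseudocount = 0.01,
                      background = rep(0.25, 4L)) {
  stopifnot(inherits(codes, "ppr_code_table"), pseudocount >= 0,
            length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  pid <- unique(codes_df$protein_id)
  if (length(pid) != 1L) stop("build_pwm expects motifs of one protein")
  nt <- codes_df[codes_df$motif_class %in% PPR_NT_CLASSES, , drop = FALSE]
  nt <- nt[order(nt$motif_index), , drop = FALSE]
  if (nrow(nt) == 0L) {
    stop("protein ", pid, " has no nucleotide-specifying (P/L/S) motif")
  }
  probs <- vapply(seq_len(nrow(nt)), function(i) {
    p <- .code_lookup(codes, nt$res2[i], nt$res5[i], nt$res_last[i],
                      background)
    p <- p + pseudocount
    p / sum(p)
  }, numeric(4L))
  rownames(probs) <- RNA_BASES
  logodds <- log2(probs / background)
  structure(list(protein_id = pid, length = ncol(probs), probs = probs,
                 logodds = logodds, pseudocount = pseudocount,
                 background = setNames(background, RNA_BASES)),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model> %s, %d position(s), pseudocount %g\n",
              x$protein_id, x$length, x$pseudocount))
  print(round(x$probs, 3))
  invisible(x)
}

# Integer score lattice and exact background score distribution.
# Scores are discretized to multiples of `granularity` bits; -Inf entries
# (possible at pseudocount 0) are tracked as a separate mass that can
# never reach a finite threshold.
.pwm_lattice <- function(pwm, granularity) {
  V <- round(pwm$logodds / granularity)
  storage.mode(V) <- "double"   # keeps -Inf representable
  V
}

.pwm_score_dist <- function(pwm, granularity) {
  V <- .pwm_lattice(pwm, granularity)
  bg <- as.numeric(pwm$background)
  offset <- 0
  dist <- 1
  p_ninf <- 0
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    fin <- is.finite(v)
    p_ninf <- p_ninf + sum(bg[!fin]) * sum(dist) +
      if (any(fin)) 0 else 0
    if (!any(fin)) {
      return(list(values = numeric(0), probs = numeric(0), p_ninf = 1))
    }
    vmin <- min(v[fin]); vmax <- max(v[fin])
    newlen <- length(dist) + (vmax - vmin)
    new <- numeric(newlen)
    for (b in which(fin)) {
      sh <- v[b] - vmin
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + bg[b] * dist
    }
    offset <- offset + vmin
    dist <- new
  }
  list(values = offset + seq_along(dist) - 1, probs = dist, p_ninf = p_ninf)
}

# Tail probability on the lattice: P(integer score >= t_int)
.pwm_tail_fun <- function(pwm, granularity) {
  d <- .pwm_score_dist(pwm, granularity)
  if (!length(d$values)) return(function(t_int) as.numeric(!is.finite(t_int)))
  tail <- rev(cumsum(rev(d$probs)))
  vmin <- d$values[1L]; vmax <- d$values[length(d$values)]
  function(t_int) {
    if (t_int == -Inf) return(1)
    if (t_int > vmax) return(0)
    if (t_int <= vmin) return(1 - d$p_ninf)
    tail[t_int - vmin + 1L]
  }
}

#' Exact PWM p-value by dynamic programming
#'
#' Probability that an i.i.d. background sequence of the PWM's length
#' attains a log-odds score at least `score`. Computed exactly on a
#' discretized score lattice: every log-odds entry is rounded to the
#' nearest multiple of `granularity` (bits) and the full distribution of
#' the lattice score is accumulated position by position. The
#' discretization perturbs any sequence's score by at most
#' `L * granularity / 2` bits, which bounds the error of the reported
#' tail probability; [scan_window()] scores queries on the same lattice,
#' making its p-values exact for the discretized matrix.
#'
#' @param pwm a [build_pwm()] model.
#' @param score threshold score in bits.
#' @param granularity lattice spacing in bits.
#' @return tail probability in \[0, 1\].
#' @export
#' @examples
#' # one-hot PWM of length 3, uniform background: p(max score) = (1/4)^3
pwm_pvalue <- function(pwm, score, granularity = 1e-3) {
  stopifnot(inherits(pwm, "pwm_model"), length(score) == 1L)
  if (is.nan(score)) stop("score must not be NaN")
  tailf <- .pwm_tail_fun(pwm, granularity)
  t_int <- if (score == -Inf) -Inf else round(score / granularity)
  tailf(t_int)
}

#' Scan a target window with a PPR PWM
#'
#' Scores every offset of the (forward-strand) window with the summed
#' per-position log-odds and attaches the exact background p-value of the
#' score (see [pwm_pvalue()]). Hits with `p_value <= threshold_p` are
#' returned sorted by p-value, ties broken by leftmost offset.
#'
#' @param pwm a [build_pwm()] model.
#' @param window target sequence over A/C/G/T/U (conventionally the
#'   51-base window from -25 to +25 around an edited site).
#' @param threshold_p report hits with p-value at most this.
#' @param granularity score-lattice spacing in bits.
#' @return data frame with `protein_id`, `offset` (0-based), `score`
#'   (bits), `p_value`, `matched_seq`.
#' @export
scan_window <- function(pwm, window, threshold_p = 1e-4,
                        granularity = 1e-3) {
  stopifnot(inherits(pwm, "pwm_model"))
  w <- chartr("U", "T", toupper(window))
  if (grepl("[^ACGT]", w)) stop("window contains non-ACGT/U characters")
  L <- pwm$length
  W <- nchar(w)
  if (W < L) stop("window (", W, " nt) shorter than PWM length ", L)
  base_idx <- match(strsplit(w, "")[[1L]], DNA_BASES)  # A,C,G,T == A,C,G,U
  V <- .pwm_lattice(pwm, granularity)
  tailf <- .pwm_tail_fun(pwm, granularity)
  offs <- 0:(W - L)
  score <- numeric(length(offs))
  s_int <- numeric(length(offs))
  for (k in seq_along(offs)) {
    idx <- cbind(base_idx[offs[k] + seq_len(L)], seq_len(L))
    score[k] <- sum(pwm$logodds[idx])
    s_int[k] <- sum(V[idx])
  }
  p <- vapply(s_int, function(t) tailf(if (is.finite(t)) t else -Inf),
              numeric(1L))
  keep <- which(p <= threshold_p)
  ko <- offs[keep]
  out <- data.frame(protein_id = rep(pwm$protein_id, length(ko)),
                    offset = ko, score = score[keep], p_value = p[keep],
                    matched_seq = substring(rep(w, length(ko)), ko + 1L,
                                            ko + L),
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$offset), , drop = FALSE]
}

#' Predict PPR-protein / editing-site interactions
#'
#' Builds a PWM per protein from its extracted codes, scans the 51-base
#' window centered on every editing site, and keeps the best (smallest
#' p-value) hit per protein/site pair that reaches `threshold_p`.
#' Benjamini-Hochberg q-values over all evaluated pairs are attached as an
#' auxiliary column; filtering uses the raw p-value. The summary bins
#' per-protein distinct-target counts as 1/2/3/4/>=5.
#'
#' @param motifs PPR motif data frame (see [extract_codes()]), any number
#'   of proteins.
#' @param codes a [code_table()].
#' @param sites a [site_table()].
#' @param genome genome sequence.
#' @param genes list of [gene_model()] objects.
#' @param threshold_p raw p-value threshold for reporting an interaction.
#' @param pseudocount,background,granularity passed to [build_pwm()] /
#'   [scan_window()].
#' @return list with `interactions` (protein_id, target_id, offset,
#'   score, p_value, q_value) and `summary` (per-bin protein counts and
#'   proportions).
#' @export
predict_interactions <- function(motifs, codes, sites, genome, genes,
                                 threshold_p = 1e-4, pseudocount = 0.01,
                                 background = rep(0.25, 4L),
                                 granularity = 1e-3) {
  empty <- data.frame(protein_id = character(), target_id = character(),
                      offset = integer(), score = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
  empty_summary <- data.frame(targets = c("1", "2", "3", "4", ">=5"),
                              n_proteins = 0L, proportion = NA_real_,
                              stringsAsFactors = FALSE)
  if (nrow(motifs) == 0L) {
    return(list(interactions = empty, summary = empty_summary))
  }
  codes_df <- extract_codes(motifs)
  windows <- export_windows(sites, genome, genes, mode = "centered51",
                            truncate = TRUE)
  names(windows) <- sub(" truncated$", "", names(windows))
  best <- list()
  for (pid in unique(codes_df$protein_id)) {
    pwm <- build_pwm(codes_df[codes_df$protein_id == pid, , drop = FALSE],
                     codes, pseudocount = pseudocount,
                     background = background)
    for (tid in names(windows)) {
      if (nchar(windows[[tid]]) < pwm$length) next
      hits <- scan_window(pwm, windows[[tid]], threshold_p = 1,
                          granularity = granularity)
      if (nrow(hits) == 0L) next
      top <- hits[1L, ]
      best[[length(best) + 1L]] <- data.frame(
        protein_id = pid, target_id = tid, offset = top$offset,
        score = top$score, p_value = top$p_value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(best)) return(list(interactions = empty,
                                 summary = empty_summary))
  all_best <- do.call(rbind, best)
  all_best$q_value <- p.adjust(all_best$p_value, method = "BH")
  kept <- all_best[all_best$p_value <= threshold_p, , drop = FALSE]
  kept <- kept[order(kept$p_value), , drop = FALSE]
  rownames(kept) <- NULL
  counts <- table(kept$protein_id)
  binned <- cut(as.integer(counts), breaks = c(0.5, 1.5, 2.5, 3.5, 4.5, Inf),
                labels = c("1", "2", "3", "4", ">=5"))
  tab <- table(binned)
  summary <- data.frame(targets = names(tab),
                        n_proteins = as.integer(tab),
                        proportion = if (length(counts))
                          as.numeric(tab) / length(counts) else NA_real_,
                        stringsAsFactors = FALSE)
  list(interactions = kept, summary = summary)
}
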