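# Hand-written standard genetic code (stop = X), independent of the
# implementation's translation path.
GENETIC_CODE_ORACLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "X", TAG = "X",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "X", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Embed a transcript into a random genome at a given offset, on either
# strand, as a single-segment CDS-style gene model.
embed_gene <- function(transcript, strand = "+", offset = 10L,
                       pad = 10L, gene_id = "gX", complete = FALSE) {
  left <- paste(sample(c("A", "C", "G", "T"), offset, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                 collapse = "")
  body <- if (strand == "+") transcript else oracle_revcomp(transcript)
  genome <- paste0(left, body, right)
  gene <- gene_model(gene_id, "CDS", strand,
                     cbind(offset + 1L, offset + nchar(transcript)),
                     complete = complete)
  list(genome = c(g = genome), gene = gene)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A random PWM model over A/C/G/U with uniform background.
random_pwm <- function(L, protein_id = "rnd") {
  p <- matrix(runif(4 * L), nrow = 4)
  p <- sweep(p, 2, colSums(p), "/")
  rownames(p) <- c("A", "C", "G", "U")
  structure(list(protein_id = protein_id, length = L, probs = p,
                 logodds = log2(p / 0.25), pseudocount = 0,
                 background = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)),
            class = "pwm_model")
}

# Exhaustive-enumeration tail probability oracle over all 4^L sequences,
# using floating-point scores (no lattice).
enum_tail <- function(pwm, score) {
  L <- pwm$length
  grids <- rep(list(1:4), L)
  combos <- as.matrix(expand.grid(grids))
  scores <- numeric(nrow(combos))
  probs <- numeric(nrow(combos)) + 1
  for (j in seq_len(L)) {
    scores <- scores + pwm$logodds[cbind(combos[, j], j)]
    probs <- probs * pwm$background[combos[, j]]
  }
  sum(probs[scores >= score])
}

# A deterministic one-hot PWM for a DNA consensus (U rows internally).
one_hot_pwm <- function(consensus) {
  L <- nchar(consensus)
  p <- matrix(0, nrow = 4, ncol = L,
              dimnames = list(c("A", "C", "G", "U"), NULL))
  for (j in seq_len(L)) {
    b <- chartr("T", "U", substr(consensus, j, j))
    p[b, j] <- 1
  }
  structure(list(protein_id = "hot", length = L, probs = p,
                 logodds = log2(p / 0.25), pseudocount = 0,
                 background = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)),
            class = "pwm_model")
}

# Exhaustive distribution of float scores with their background probs
enum_scores <- function(pwm) {
  L <- pwm$length
  combos <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(combos))
  probs <- numeric(nrow(combos)) + 1
  for (j in seq_len(L)) {
    scores <- scores + pwm$logodds[cbind(combos[, j], j)]
    probs <- probs * pwm$background[combos[, j]]
  }
  list(scores = scores, probs = unname(probs))
}
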