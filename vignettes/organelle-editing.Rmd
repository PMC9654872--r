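---
title: "Calling and characterising C-to-U RNA editing in plant organelles"
author: "orgedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterising C-to-U RNA editing in plant organelles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgedit)
```

## The biological problem

In plant chloroplasts and mitochondria, cytidines encoded in the genome
are deaminated to uridine in the transcript. These C-to-U events sit
mostly at the first or second codon position, where they change the
encoded amino acid, and occasionally create initiation (ACG→AUG) or
termination (CGA→UGA, CAA→UAA) codons. Editing extent varies between
sites, tissues and cultivars, and site recognition is carried out by
PLS-class pentatricopeptide-repeat (PPR) proteins whose tandem ~35-aa
motifs each bind one RNA base; the identities of a motif's 2nd, 5th and
last residues form an empirical "PPR code" mapping motifs to base
preferences.

`orgedit` implements the complete desk-side workflow around these
observations for the tea plant and for synthetic organelle data: calling
sites from paired DNA/RNA evidence, annotating their codon-level
consequence, profiling their sequence context, quantifying editing
levels, and predicting PPR/target interactions by PWM scanning. Two
validated site catalogues for tea (38 chloroplast and 139 mitochondrial
sites) ship with the package as TSV and anchor the consistency tests.

## Evidence model of the caller

The caller is deliberately a transparent threshold filter, not a
statistical genotyper. On the transcript strand, a site is called C-to-U
when:

* DNA coverage ≥ `min_dna_cov` (default 10), with C the DNA majority
  base and a non-C fraction ≤ `max_dna_alt_fraction` (default 0.05) —
  the homozygosity guard;
* RNA coverage ≥ `min_rna_cov` (default 10), with ≥ `min_edited_reads`
  (default 3) T reads and `T/(T+C)` ≥ `min_editing_freq` (default 0.05).

Counts from minus-strand genes are complement-folded
(`strand_fold()`) before the C/T test; a pileup row without a known
strand is an error rather than a guess. Every other DNA/RNA difference
passing the same evidence bar is retained in a secondary
"non-canonical mismatch" report: confirmed plant organellar editing is
overwhelmingly C-to-U, but contrary evidence is reported, not hidden.

Two caveats are inherent to the design. First, DNA/RNA comparison
cannot distinguish editing from heteroplasmy (coexisting organellar
genome variants); the DNA-purity filter is the only guard, and calls
carry the DNA minor-allele fraction so downstream analysis can judge.
Second, detection near the thresholds is stochastic: at true level
$\ell$ and RNA coverage $n$, the edited read count is
$\mathrm{Bin}(n, \ell)$, so a site with $\ell = 0.1$ at $n = 100$ falls
below the 5% observed-frequency floor with probability
$P(X \le 4) \approx 2.4\%$. Perfect recall is therefore only guaranteed
for levels bounded away from `min_editing_freq`; the test suite's
round-trip at coverage 100 documents exactly this behaviour (47/50
planted sites recovered at seed 1, all misses at level 0.1, zero false
positives).

## Coordinates, codons and effects

Genome coordinates are 1-based inclusive (GFF3 convention); CDS
coordinates are 1-based with position 1 the first base of the start
codon, so the codon position of CDS position $p$ is
$((p-1) \bmod 3) + 1$. Gene models are stranded and possibly
multi-segment, with segments stored in transcription order (descending
genome coordinate on the minus strand); `transcript_sequence()`
extracts, reverse-complements and concatenates them once, and all
window and context operations work in transcript coordinates thereafter.
Translation uses the standard genetic code for both organelles (plant
plastid and mitochondrial CDS use it), with stop rendered `X` to match
the `R>X` notation of the catalogues. The effect taxonomy is
synonymous / missense / stop_gain / start_gain; stop_loss is
representable but unreachable, because no stop codon contains a C — the
suite asserts this.

Overlapping genes are real in organelle genomes, so `locate()` and
`annotate_sites()` report *all* memberships of a position and list
multi-gene claims in an `ambiguous` report; no precedence is applied.

### Consistency checking of the bundled catalogues

`check_table_consistency()` recomputes each catalogue row's codon
position from its CDS coordinate (all 177 rows agree with the printed
column), compares the printed amino-acid residue number with
`ceiling(cds_pos/3)` (five rows disagree and are flagged), and asks, by
brute force over the 64 codons, whether the printed amino-acid
transition is achievable by a single C→U at the printed position. Eight
rows are not. Six of them sit in codons that carry a *second* validated
site (e.g. ccmB positions 475/476, both edited, CC→TT turning Pro into
Leu): there the catalogue prints the jointly edited outcome on each
row, and the checker's joint model — editing all of a codon's
catalogued sites at once — resolves them. The remaining two rows
(atpF C92 "P31>H31": His needs an A at codon position 2; ccmB C28
"S10>L10" at codon position 1: no serine codon has a C there) are
unreachable under any combination of C→U edits and are flagged as
printed-catalogue discrepancies. They are reported, never corrected.

## Sequence context and window exports

The context profile counts bases at transcript positions −5..−1 and
+1..+5 around each edited C (the edited position itself excluded).
Windows are taken on the transcript strand — editing factors bind the
transcript, and this handles strand and splice junctions in one place.
Sites whose window crosses a transcript end contribute only their
available positions, and the denominator is tracked per column, so each
row of the matrix sums to 1 over the sites that cover it.
`export_windows()` emits the two window dialects used by downstream
motif tools: the 25 bases upstream of the site (motif discovery input)
and the 51-base window from −25 to +25 (PPR/PWM target sequences). Motif
discovery itself (MEME-style) is out of scope; the package only
prepares its inputs.

## Editing levels

A site's editing level in a sample is the fraction of edited transcript
molecules, estimated either from the sequencing chromatogram of a cDNA
amplicon — the T peak height over the sum of C and T peak heights — or
from RNA read counts, $n_T/(n_T+n_C)$. Peak-based estimates carry no
interval (a single trace has no sampling model); count-based estimates
carry a Wilson 95% score interval, computed in closed form. The
peak statistic is scale-invariant, monotone in $h_T$ and bounded in
$[0,1]$, all asserted as properties. `level_table()` pivots
measurements into a site × sample matrix; the qualitative bins
(`<10%`, `~30%`, `~50%`, `>80%`, `~100%`) are narrative labels only and
never enter computation.

## PPR code, PWM and exact p-values

For each PLS protein, the nucleotide-specifying motifs (P/L/S families;
E, E+ and DYW contribute no column) are mapped through a code table to
base-preference vectors, in N-to-C order corresponding to target
5'→3'. Lookup falls back triple → pair (5th + last) → single (last) →
background. A pseudocount (default 0.01) is added and columns
renormalised; scores are base-2 log-odds against the background
(default uniform; optionally estimated from the scanned windows). No
fixed offset between the PWM and the edited C is imposed — the scan
over the 51-nt window discovers the offset.

The p-value of a score is the exact probability that an i.i.d.
background sequence of the PWM's length scores at least as high. It is
computed by dynamic programming over a discretized score lattice: each
log-odds entry is rounded to the nearest multiple of the granularity
$g$ (default $10^{-3}$ bits) and the full distribution of the lattice
score is convolved position by position, with $-\infty$ entries
(possible at pseudocount 0) tracked as a separate mass that can never
reach a finite threshold. Discretization perturbs any sequence's score
by at most $Lg/2$, which bounds the error of the reported tail;
`scan_window()` scores queries on the same lattice, so its p-values are
exact for the discretized matrix. The tests sandwich the DP against
exhaustive enumeration over all $4^L$ sequences for $L \le 8$ and check
that background sequences hit a threshold $t$ at empirical rate ≈ $t$.

One counting argument matters for experimental design: a length-$L$
one-hot-like matrix can never produce a p-value below $4^{-L}$, so at
the conventional reporting threshold $10^{-4}$ a recognisable target
needs $L \ge 7$ ($4^{-7} \approx 6\times 10^{-5}$). The synthetic PPR
generator therefore builds its guaranteed-recoverable positive proteins
from 7–12-nt subwindows.

`predict_interactions()` keeps the best hit per protein/site pair at
the raw-p threshold (default $10^{-4}$), attaches Benjamini–Hochberg
q-values as an auxiliary column (filtering uses raw p, matching common
single-scan practice), and summarises per-protein target counts in the
bins 1/2/3/4/≥5.

## The synthetic organelle generator

`simulate_organelle()` is first-class, tested code, and defines the
conditions under which every pipeline property is exercised:

* genome: i.i.d. uniform bases (a GC-skew knob is deliberately absent;
  uniform composition keeps the scan-calibration tests analytically
  clean), default 30 kb;
* genes: 12 intact ORFs (ATG … stop, no internal stops) of 80–150
  codons, half on the minus strand, 30% split into two segments by a
  60–200-nt spacer to exercise splice-aware coordinates;
* sites: 50 planted C-to-U events at codon positions drawn with weights
  57:116:4 — the partition observed across the 177 validated tea sites;
* levels: per-site base level from {0.1, 0.3, 0.5, 0.8, 1.0} (spanning
  barely-detectable to complete editing, as observed across cultivars),
  with six samples at profile multipliers (1, 1, 0.6, 0.6, 0.3, 0.3)
  emulating a high/mid/low cultivar contrast — labels are synthetic;
* reads: per-position DNA and RNA multinomial counts at coverage 100
  with a uniform per-read error model (default error 0.001);
* peaks: $h_T = \ell(1+\varepsilon)$, $h_C = (1-\ell)(1+\varepsilon')$
  with multiplicative Gaussian noise of CV 0.05, truncated at zero;
* PPR proteins: positives spelling a subwindow of a planted site's
  51-nt window through the code table, plus uniformly drawn decoys.

All randomness flows from the single config seed; the samplers derive
their own seeds deterministically from it, so outputs are byte-identical
across runs. What the generator does *not* emulate: real organellar
base composition (AT-rich), genome-wide coverage heterogeneity,
alignment and mapping artefacts, chromatogram base-calling, and
partially edited codons read in phase on single molecules. Passing the
synthetic suites therefore demonstrates the correctness of the
computations, not the field performance of the thresholds on real
sequencing data.

## Numerical and design choices

* Caller thresholds (10/10/3/0.05/0.05) are conservative conventions,
  not published values, and every one is overridable.
* PWM granularity $10^{-3}$ bits balances lattice size against the
  documented $Lg/2$ score-perturbation bound.
* Wilson intervals use the closed form without continuity correction.
* The code table ships as a replaceable TSV; the bundled
  `synthetic_code_table()` is a synthetic stand-in (filename and docs
  say so), and tests never hard-code published code-table values.
* Problem sizes in the test suite (30 kb genomes, 12 genes, 50 sites,
  coverage 100–10⁴, exhaustive PWM enumeration up to $L=8$, 2000-draw
  calibration) were chosen so the full suite runs in about a minute
  while keeping binomial/Monte-Carlo error well inside the asserted
  tolerances.

## Known limitations

Heteroplasmy and editing are not separable from DNA/RNA comparison;
reference-genome quality directly limits coordinate fidelity; the
catalogue strand column is inferred from coordinate trends and flagged
as such; PREP-style homology prediction, motif discovery, RNA/protein
structure prediction and read alignment are out of scope — the package
emits the sequences such tools consume.
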