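---
title: "Methods: in-silico neuropeptidome discovery and quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico neuropeptidome discovery and quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmine)
```

`pepmine` reconstructs a neuropeptidome from a nucleotide transcriptome:
translated homology mining, a three-criteria precursor screen, rule-based
prohormone maturation, family assignment, and the two statistical analyses
that typically accompany such catalogs (2^−ΔΔCt developmental profiling and
an arcsine/ANOVA settlement bioassay). This vignette explains each model,
its assumptions and parameters, and the design decisions behind them.

## Translated homology mining

Queries are curated reference peptides or precursors; subjects are the six
frame translations of each contig under the standard genetic code
(N-containing codons become `X`, stops `*`). Alignments never cross a stop:
each frame is segmented at `*` before alignment, mirroring how a translated
search treats reading-frame interruptions.

The aligner is an affine-gap Smith–Waterman (Gotoh) in compiled code. A gap
of length $L$ costs `gap_open` + $L \cdot$ `gap_extend` — the BLAST-style
convention — with BLOSUM62 and defaults open 11 / extend 1. The published
BLOSUM62 matrix is taken from Biostrings, with `*` rescored to −4 against
everything so a stop can never be profitable. Traceback is deterministic:
on ties a substitution is preferred over a gap in the query over a gap in
the subject, and the best-scoring cell with the smallest subject end (then
query end) wins. The same machinery with end-to-end boundary conditions
provides the Needleman–Wunsch global aligner used for family comparisons.
Both are verified against an independent dynamic-programming oracle and
against Biostrings' `pairwiseAlignment` in the test suite.

Hit significance uses the Karlin–Altschul form
$E = K m n e^{-\lambda S}$ with the published gapped BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$, where $m$ is the query length and $n$ the
total residue count of all frame translations. These statistics are
self-consistent within the package but are **not** calibrated to NCBI
BLAST: raw scores enter undiscounted for edge effects, so absolute
E-values from other tools are not comparable. Per query, hits with
$E < 0.01$ are kept, at most `top_k = 3`, sorted by ascending E-value with
a documented tie-break (raw score, subject start, query start, frame).
There is no heuristic word seeding: the search is exhaustive, which is
exact but quadratic — appropriate for the tens-of-thousands-of-contigs
scale this package targets, not for genome-scale databases.

## ORF selection and the precursor screen

For each mined transcript the best hit defines a candidate: the maximal
stop-to-stop segment of the hit's frame containing the hit span, trimmed
to the first Met upstream of the hit when one exists (candidates without
one are kept but flagged `no_start`, since transcriptome fragments often
truncate the 5' end).

A candidate passes the screen if it satisfies all three classical
neuropeptide precursor criteria:

1. **Signal peptide.** A transparent two-part heuristic in the spirit of
   von Heijne's rules, not a neural-network reimplementation: (i) some
   8-residue window within positions 2–30 contains ≥ 6 hydrophobic
   residues (A I L M F V W C); (ii) a cleavage position $c \in [10, 40]$
   satisfies the (−3,−1) small-residue rule — residues $c$ and $c-2$ both
   in {A G S C T V}. The reported end is the smallest such $c$ at or after
   the end of the best hydrophobic window; the score is that window's
   hydrophobic fraction. The heuristic is auditable and dependency-free;
   it trades the calibrated accuracy of learned models for transparency,
   which the synthetic benchmarks quantify (exact end recovery on
   generated signals).
2. **Processing sites** (below) — at least one accepted site after the
   signal.
3. **Length** strictly under 300 residues (a 300-residue protein fails).

## Cleavage rules and maturation

The site rules are an operational reading of the classical dibasic /
monobasic processing literature, each sub-rule independently toggleable:

- (a) dibasic `KR` and `RR` always accepted;
- (b) `RK` / `KK` only when enabled (`accept_RK`, `accept_KK`; default off);
- (c) monobasic `R` accepted only with another K/R at relative position
  −4, −6 or −8;
- (d) runs of ≥ 3 consecutive K/R collapse into one multibasic site at the
  run's last residue (so overlapping candidates resolve to the longest);
- (e) any site immediately followed by Pro is rejected.

Mature peptides are the maximal stretches strictly between the signal end,
the site residues and the precursor end; the basic residues themselves are
excised. Conservation is an invariant: signal + sites + segments always
reconstruct the precursor, property-tested on random precursors.

PTMs never touch stored coordinates: a terminal Gly is removed and flagged
as the amide donor (a lone `G` segment is left intact — a zero-length
peptide is not a peptide); an N-terminal Gln flags pyroglutamate (Glu too
with `pyroglu_E`); a Tyr is flagged sulfated when ≥ `sulfation_acidic_min`
(default 2) D/E residues fall within ±`sulfation_window` (default 5)
positions, a window heuristic standing in for curated sulfation
predictors. Reports render these as `pQ…` and `…-NH2` in a display field
only.

Families come from terminal motif patterns expressed in a small language
(`X` any residue, `[AB]` alternatives, `X(n)` repeats, trailing `a`
requiring amidation, with C/N/anywhere anchoring). The shipped defaults
cover the families with clean signatures — FGLamide A-type allatostatins,
W(X6)Wamide B-type, the C-type core with its usually-conserved Ala made
variable, sulfakinins generalized to Lys8 and Met6/Phe6 variants,
SIFamide, FXGXRamide tachykinin-related peptides, N-terminal NFDEIDR
orcokinins. Patterns are data (a TSV ships in `inst/extdata`), not code.
Peptides without a motif match inherit the family of the precursor's best
homology hit — the same dual motif/homology logic used in manual catalog
curation. Multiple alignment of family members uses a deterministic
star-progressive scheme around the best-summed-score centroid; it makes no
claim to ClustalW bit-compatibility, and figure-layout reproduction is out
of scope.

## The synthetic data model

All benchmarks run on generated data with known ground truth, because the
underlying raw measurements of such studies (reads, Ct values, counts) are
typically unpublished. The generators are pure functions of (spec, seed).

**Precursors** follow the canonical architecture: synthetic signal (Met +
charged residue + hydrophobic core from {L I F M W} + Ala-Leu-Ala), an
optional acidic spacer, and payload peptides joined by basic sites, with
Gly appended to amidated payloads. The signal construction deliberately
places the first (−3,−1)-compatible position exactly at the signal end, so
end recovery is exact; real signal peptides are messier, and the ≥ 95%
recovery benchmark should be read as a self-consistency check, not a
claim about biological signal-peptide accuracy. Every generated precursor
is self-validated at emission: the annotation rules must reproduce the
planted signal end, sites and mature peptides, so a payload that collides
with the cleavage rules is a generation-time error.

**The catalog** (`catalog_specs()`) is a fully synthetic 16-family
precursor set whose structural statistics mirror a published barnacle
neuropeptidome: 64 mature peptides in total, 22 A-type allatostatins, 10
B-type allatostatin isoforms, 4 tachykinin copies, 4 sulfakinins with the
reported Lys8 / Met6 / Phe6 variants, 11 orcokinins of exactly 14
residues, an insulin-like B–C–A chain precursor, and the printed PDH and
ASTC mature sequences as payloads. Only those printed mature sequences are
real; everything else is constructed. Two constructed details are worth
flagging: the catalog's orcokinin variants carry Pro8 so that rule (c)
leaves the 14-mers intact (the N-terminal motif fixes an Arg at position
7, which would otherwise be monobasic-eligible after a dibasic site), and
the count of 16 families reflects treating the calcitonin-like and
bursicon subunits as subfamily-level entries while omitting the weakest
unconfirmed family of the published table.

**Transcriptomes** back-translate precursors with uniform synonymous
codons (codon bias is immaterial to protein-space mining), plant an
in-frame stop directly 5' of the start codon so ORF recovery is exact, and
add i.i.d.-nucleotide decoys with matched length distribution and chosen
GC. Decoys carry no repeat structure; they measure false-positive control
under chance similarity only.

**Ct tables** model the reference gene as a batch-shifted constant and each
target as reference + baseline − log2(fold) + Gaussian noise (defaults:
3 batches × 3 replicates, noise sd 0.2 cycles, batch sd 0.5). The default
fold profile encodes the study conditions the package emulates: PDH
4-fold and SIFamide 6-fold up in cyprids, B-type allatostatin and
calcitonin-A ~3-fold up in late larval stages, tachykinin high in
nauplius VI and adults, insulin-like peptide down only in juveniles, and
the remaining genes flat across larval stages but down-regulated in
adults, with the juvenile stage as calibrator.

**Settlement counts** are Binomial(n, p) per well with n ~ 18–22 cyprids,
3 wells × 3 batches. The default scenario encodes strong 24-h inhibition
at 10 and 100 µmol/L (p = 0.15 / 0.05 vs 0.60 in both controls), a slight
non-significant trend at 1 µmol/L (0.58), and complete recovery by 48 h
(0.85 in every group — the no-difference condition the emulated experiment
reports). The 1 µmol/L value is deliberately a *small real* effect: the
emulated study reports a near-threshold p there, and the qualitative
contract (10/100 significant, 1 not, 48 h silent) should still hold in
≥ 90% of seeds under exact Tukey control.

## Quantitation models

`ddct()` pairs each target measurement with the reference measurement of
the same (stage, batch, replicate) cell — the pairing is configurable to
cell means — and computes ΔΔCt against the mean calibrator ΔCt per gene.
The per-stage `fold` is the geometric mean $2^{-\overline{\Delta\Delta
C_t}}$, so the calibrator is exactly 1 by construction; arithmetic
mean ± sd of per-replicate folds is also kept for plotting, since that is
what such figures conventionally show. Stage comparisons run on the
per-replicate log2 folds (−ΔΔCt): under Gaussian Ct noise the raw folds
are log-normal, and the log scale restores variance homogeneity for the
ANOVA (a raw-scale option remains). ANOVA and Tukey HSD are delegated to
`stats::aov`/`stats::TukeyHSD` and cross-checked in the tests against
sums-of-squares and studentized-range computations. Zero-variance input
yields an explicit degenerate result (NA F, no flags) rather than an
error. No amplification-efficiency correction is applied — the method is
plain 2^−ΔΔCt by design.

`settlement_analysis()` transforms well proportions by $y = \arcsin
\sqrt{p}$ (the classical variance-stabilizer for binomial proportions; at
n ≈ 20 it is adequate though mildly anticonservative at extreme
proportions), then per timepoint runs the same ANOVA/Tukey machinery
across {seawater control, vehicle control, doses}, reporting contrasts
against the seawater control with `ns`/`*`/`**`/`***` tiers.

## Numerical choices and limitations

- Problem sizes in the shipped tests: the end-to-end benchmark uses one
  planted precursor per family plus 500 decoys (~516 contigs); oracle
  comparisons run 500 random pairs up to 20 residues; conservation runs
  1,000 random precursors; the statistical contracts use 200 seeds.
  These sizes give stable pass/fail behaviour at interactive runtimes.
- Degenerate inputs are contracts, not crashes: empty frames translate to
  empty peptides, zero mined hits is a valid result, an all-equal ANOVA is
  flagged degenerate, `n_total = 0` wells are data errors.
- The mono-R rule looks upstream across element boundaries (including
  into sites and signal), which is deliberate — convertases see the
  precursor, not the annotation.
- Disulfide topology (insulin-like, bursicon, eclosion hormone families)
  is out of scope; cysteines are reported as sequence content only.
- Passing the planted-recovery suites demonstrates the pipeline is exact
  on data satisfying its own assumptions (clean ORFs, canonical sites,
  in-alphabet sequences). Real transcriptomes add frameshifts, assembly
  chimeras, non-canonical processing and signal peptides that violate the
  heuristic; expect recall below the synthetic benchmarks there, and
  treat the config toggles (site rules, sulfation window, length bound)
  as the first tuning surface.
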