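---
title: "Detecting and reconstructing ERV protein fossils: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and reconstructing ERV protein fossils: methods}
  %\VignetteEncoding{UTF-8}
---

# Overview

`ervfossils` implements a complete desk-scale pipeline for finding *protein
fossils* — genomic DNA segments descended from formerly protein-coding
sequence — inside decayed endogenous retroviruses (ERVs), and for
reconstructing the ancestral element they came from.  The pipeline has five
analysis stages plus a simulator that generates ground-truth data for all of
them:

1. **Parameter training** (`train`): estimate a 64×21 codon-versus-protein
   log-odds substitution matrix plus gap and frameshift penalties from
   diverged DNA/protein pairs.
2. **Frameshift-aware alignment** (`align_local`, `scan_genome`): local
   DNA-versus-protein alignment that tolerates reading-frame disruptions,
   with simple-repeat soft-masking and an empirically calibrated score
   threshold.
3. **Annotation overlap** (`parse_rm_out`, `assign_families`,
   `project_to_consensus`): relate fossil hits to RepeatMasker repeat-family
   annotations, detect hits spanning annotation gaps, and project hits onto
   repeat-consensus coordinates.
4. **Consensus reconstruction** (`select_for_reconstruction`, `refine`,
   `find_orfs`): iteratively infer an ancestral DNA sequence from selected
   fossil copies and search it for open reading frames.
5. **Phylogenetics** (`align_to_reference`, `maxalign_prune`, `nj_build`,
   `bootstrap`): infer the evolutionary tree of fossil copies with
   neighbor-joining on Jukes-Cantor distances and bootstrap supports.

# The alignment model

The aligner compares a DNA sequence to a protein by dynamic programming over
(DNA position, protein position).  Its states are:

* a **codon column**: consumes 3 nt and 1 residue, scored by the 64×21
  matrix `s(c, a)`;
* **frameshift columns**: consume 2 or 4 nt and 1 residue, charged a flat
  `frameshift_penalty` in addition to the substitution score.  The codon
  scored is always the last 3 nt ending at the current DNA position, so a
  2-nt column re-reads one nucleotide of the previous column and a 4-nt
  column skips one.  Only ±1-nt shifts are modelled; a ±2 shift is
  equivalent to a ∓1 shift combined with a different codon boundary choice;
* affine **deletions** (unaligned protein letters) and **insertions**
  (unaligned codons).

Alignment is local (score floor 0; alignments start and end on a regular
codon column) and both DNA strands are searched.  Traceback ties are broken
in the order match > 2-nt frameshift > 4-nt frameshift > deletion >
insertion, preferring the longer (leftmost-starting) alignment; this makes
output deterministic.  Codons containing `N` score 0 against everything,
as does the protein letter `X`.  Soft-masked (lowercase) codons have their
substitution score capped at 0, so masked simple repeats can be crossed but
never rewarded.  Percent identity is defined as the fraction of codon
columns whose standard-genetic-code translation equals the aligned residue;
gap columns are excluded.

The matrix's 21st protein letter is the stop symbol `*`: translated fossils
contain stops, so the matrix must score them.  The DP core is exact; its
optimum is verified in the tests against brute-force enumeration of every
monotone alignment on small instances.

# Training

`train` iterates: align every pair under the current parameters; drop
alignments above `max_pid` percent identity (near-identical pairs carry
almost no information about substitution rates — we interpret the identity
filter as a *maximum*); accumulate codon↔residue, gap-run and frameshift
counts with a +1 pseudocount per cell; rebuild scores as
`s(c,a) = round(log2(P(c,a)/(π(c)ρ(a)))/scale)` and re-derive the penalties
from event frequencies (`penalty = -log2(frequency)/scale`).  The scale is
set each round so the best translating-codon score is ≈15, and rounding is
half-away-from-zero.  Iteration stops when no score moves by ≥1 unit
(`tol`), normally within a handful of rounds.  The fixed starting point is
`seed_params()`: +5 for a codon aligned to its exact translation, −1
otherwise.  Training is validated by simulating pairs from a known
coding-decay model (uniform non-stop ancestral codons, per-site Jukes-Cantor
divergence) whose analytic joint distribution gives ground-truth scores.

# Score calibration

Rather than analytic Karlin-Altschul statistics, `score_threshold` aligns
shuffled DNA against shuffled protein, fits a Gumbel distribution to the
per-shuffle maximum scores by moment matching, and returns the smallest
score whose expected chance-hit count in the search space is below a target.
The scan default targets one chance alignment per 10⁹ bp — the usual
stringency for genome-wide fossil searches — which makes chance hits on a
desk-scale genome essentially impossible while leaving real fossils (which
score hundreds of units) untouched.  The calibration is seeded and exactly
reproducible.

# Simple-repeat masking

`mask_simple_repeats` runs, for every period *p* ≤ `period_max` (default 6),
a reset-at-zero running score over positions (+1 if a position matches the
letter *p* before it, −3 otherwise) and lowercases runs reaching `threshold`
(default 10, i.e. ten matching positions beyond background).  On random
sequence the expected match rate is 0.25, so the running score drifts down
and false masking is rare (<5% of positions, tested).  Masking is
idempotent and preserves existing lowercase.

# Genome scanning

`scan_genome` slides windows (default 10 kb, 2 kb overlap) over each
sequence, aligns both strands, merges duplicate hits from overlapping
windows and removes alignments whose DNA interval lies inside a strictly
higher-scoring one (redundancy culling).  Windowing is lossless for hits
shorter than the overlap; the tests verify windowed and whole-sequence scans
agree.

# Consensus reconstruction

Fossil copies whose alignments cover most of the query protein (fewer than
10 residues missing at the start and 30 at the end, by default) are
extracted with 200 bp flanks, oriented protein-forward, and fed to
`refine`.  Refinement seeds the consensus with the medoid segment (maximum
summed pairwise alignment score), then repeats: align every segment to the
consensus (ends-free affine DNA-DNA alignment, match +1, mismatch −1, gap
open 5, extend 1), stack letters on consensus columns, and call a new
consensus by per-column plurality.  Gaps win a column only when they
strictly outnumber the best letter; letter ties break alphabetically
(A<C<G<T); columns with non-gap support below `min_support` (default 3) are
dropped, which trims ragged flank-derived ends.  Insertion calling needs two
extra safeguards, because equivalent indel placements in tandem context
(e.g. a lost `TGC` in a `TGC·TGC` repeat, or an indel next to a
homopolymer) scatter otherwise-identical votes across adjacent slots:
insertions are first left-normalized (shifted to their leftmost equivalent
placement, as in VCF indel normalization), then votes are pooled over a
3-slot window; a new column block is inserted when the pooled voters form a
strict majority of the segments *covering* that site (so partially covered
flank regions are judged against their local coverage, not the full stack),
inserting the plurality string with lexicographic tie-break.  The iteration
is a fixpoint scheme: it stops when the consensus no longer changes
(typically 2–4 rounds) or after `max_iters`.  Mean segment-to-consensus
identity is non-decreasing across rounds (tested).

`find_orfs` reports maximal stop-free codon runs in all six frames —
stop-to-stop, *no start codon required*, the terminating stop excluded from
the interval.  Under this definition an ORF of length 3n encodes exactly n
residues; this is the only definition under which a 293-residue protein
corresponds to an 879-bp ORF, which the acceptance checks exercise.

# Phylogenetics

Copies longer than 300 bp (strictly) are aligned to a fixed reference — the
refined consensus, which keeps all rows in a common coordinate system
(segment insertions relative to the reference are discarded, mirroring
"keeplength" semantics).  Because rows with many gaps destroy complete
columns, a MaxAlign-style greedy pruner removes rows while doing so
increases alignment area (rows × gap-free columns), with ties broken by
label.  Distances use the Jukes-Cantor formula
d = −(3/4)·ln(1 − (4/3)p) with pairwise deletion (only shared non-gap
columns); pairs at p ≥ 3/4 are saturated and rejected.  `nj_build` is a
textbook neighbor-joining implementation — exact on additive matrices
(verified to 1e-9 against path-length matrices of random trees, and
cross-checked against an independent NJ implementation) — with Q-ties broken
by the lexicographically smallest pair of representative leaf labels, and
negative branch lengths clamped to 0.  `bootstrap` resamples columns with
replacement; replicate *i* draws its column indices from an RNG substream
derived from the master seed and *i* alone, which makes supports invariant
to input row order.  Support is the percentage of successful replicates
containing the same bipartition; replicates with saturated pairs are
skipped and counted.

# The simulator

`plant_copies` emulates the proliferation history the pipeline is designed
to untangle: an ancestral element (5′ LTR, protein ORF, gag-pol-env spacer,
identical 3′ LTR; defaults 400 + 879 + 1200 + 400 bp) decays along a
three-level tree — `n_clades` deep branches of `divergence`
substitutions/site (default 3 × 0.15, mirroring independent proliferations
in three host clades) each spawning a star of `n_copies_per_clade` copies on
shallow branches of `divergence/5`.  Decay applies per-site Jukes-Cantor
substitutions; indels at `indel_rate` events/site with geometric lengths
(p = 0.5, capped at 30 bp) of which `frameshift_fraction` (default 2/3, the
fraction of random lengths not divisible by 3) disrupt the frame; and, with
`truncation_prob` 0.3, loss of a uniform prefix or suffix of up to 40% of
the copy.  Copies land on random strands at random non-overlapping positions
in an i.i.d. background host (no host repeats, so every detected hit is
attributable to a planted copy).  The ancestor's ORF is built from uniform
non-stop codons and bounded by in-frame TAA stops, so its stop-to-stop
length is exactly the requested `orf_length_bp` and its translation is the
ground-truth query protein.  A fixed configuration seed makes the FASTA,
BED and Newick outputs byte-identical across runs.

What the simulator does *not* emulate: host repeat families, LTR
recombination, target-site duplications, LINE-mediated retrotransposition,
rate heterogeneity across sites, or large internal deletions (real elements
show multi-kb deletions; these can be approximated with truncations but are
not modelled as internal events).  Passing tests therefore demonstrate
correctness of the algorithms under a clean decay model, not performance on
real annotation noise or chimeric elements.

# Problem sizes and numerical choices

The bundled checks run at desk scale, chosen to finish in seconds while
leaving comfortable statistical margins: training on 2,000 codons across 20
pairs; scans of an 80-kb host with 15 planted copies; consensus
reconstruction from 15 copies of a ~1.2-kb element over 5 seeds; bootstrap
with 100 replicates on 15 taxa.  Score thresholds calibrate on 200 shuffles
of 3-kb DNA against 300-residue protein.  All randomness flows through
explicit seeds; integer score rounding is half-away-from-zero; the Gumbel
fit uses moment matching (scale = sd·√6/π, location = mean − γ·scale).

# Known limitations

* The aligner reports one alignment per DNA region per strand (greedy peak
  extraction before culling); overlapping same-region alignments to
  different protein parts are suppressed.
* `-m`-style seeding heuristics are not implemented; alignment is full DP,
  appropriate for genomes up to a few megabases, not for whole mammalian
  genomes.
* The consensus refiner assumes segments are pre-oriented; the selection
  step guarantees this for pipeline-internal use.
* Saturated distance pairs are excluded rather than capped, so extremely
  diverged copy sets can lose taxa before tree building.
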