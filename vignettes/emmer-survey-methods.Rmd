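---
title: "Methods: survey-sequence analysis of a synthetic tetraploid genome"
author: "emmerSurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey-sequence analysis of a synthetic tetraploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind each stage of the package, and what the synthetic
genome does and does not establish about behaviour on real data.

## Coordinates and determinism

All coordinates are 0-based half-open internally; GFF3 emission converts
to 1-based closed. Every stochastic routine takes a seed and runs inside
an RNG sandbox that restores the caller's random state, so a configuration
plus a seed yields byte-identical output (the end-to-end report is checked
for two-run byte identity). Stage-specific sub-seeds are derived
arithmetically from the user seed and stay below 2^31.

## The synthetic tetraploid and its ground truth

`generateGenome()` builds A/B subgenome chromosomes ("1A", "1B", ...) on an
i.i.d. uniform A/C/G/T background. Background structure is deliberately
unmodelled: none of the downstream summaries depends on background
composition, only on planted features.

* **Transposable elements.** Copies are drawn from a built-in
  seven-family library spanning Class I LTR retroelements (Copia, Gypsy),
  a LINE, a SINE, two Class II DNA transposons — a dominant CACTA family
  (named for the Triticeae "Jorge" family) and a Tc1/Mariner analogue —
  and an "undetermined LTR" class. Copies carry 1–5% point mutations and a
  20% chance of 5'-anchored truncation to 40–100% of length. The
  undetermined-LTR family is tilted ×1.8 in the A subgenome and ×0.9 in B
  so that an A-versus-B landscape contrast exists by construction. Copies
  are placed into free gaps until the per-chromosome base budget
  (`teFraction`, default 0.6) is met; the last copy is truncated to the
  remaining budget, so the genome-wide realised fraction lands within
  2 percentage points of the target. Placement margins (20 b between
  repeats) keep planted copies disjoint, which makes the per-chromosome
  true repeat fraction an exact interval-union computation.
* **Genes.** Two-exon genes (CDS length ~ Normal(2772, 250) b, floored at
  900 and rounded to codons; fixed 120-b GT..AG intron) are placed at
  identical positions on both homeologs of a pair — colinearity by
  construction — with the B copy diverged by 2% substitutions. Each
  homeolog pair shares one ortholog identifier per grass species
  (Brachypodium, rice, sorghum, barley), defining the true ortholog
  groups.
* **miRNA hairpins.** A 50-nt arm containing the mature at offset 10, an
  8-nt loop, and the arm's reverse complement. Free-standing hairpins are
  placed with a 220-b margin so the ±200-nt candidate precursor window
  stays repeat-free (truthfully high-confidence); TE-embedded hairpins are
  written inside a dedicated low-divergence (1%) CACTA copy at offset
  300, so the precursor window lies wholly inside the repeat (truthfully
  low-confidence). The mature catalogue couples one published mature
  sequence (the miR437 family mature) with seven fixed synthetic 21-mers.
* **lncRNAs and decoys.** lncRNA bodies are rejection-sampled to contain
  no six-frame ORF longer than 100 aa; half carry the exact reverse
  complement of a mature miRNA (a target-mimicry site recorded in the
  manifest). Decoys cycle through three removal designs — a 152-codon ORF,
  a simulated protein homology hit, and a 150-nt body — one per cascade
  stage.
* **SSRs and junctions.** Planted runs are flanked by guard bases chosen
  so the run cannot extend periodically into the background, keeping the
  manifest interval exact; two sub-threshold repeats are planted as
  negative controls. Every repeat-copy boundary with ≥ 30 assayable bases
  to the chromosome ends is recorded as a true ISBP junction.
* **Translocation.** One donor-arm tail (default: the last 50 kb of 2A)
  is appended to the acceptor (1B). The cut point is moved to the nearest
  feature boundary so no feature straddles it; all manifest coordinates
  are updated, and the breakpoints are recorded. Because the tail carries
  its repeat complement, per-chromosome repeat fractions shift while the
  genome-wide fraction is conserved — which is why the generator's
  repeat-fraction contract is genome-wide.

`fragmentIntoScaffolds()` cuts each chromosome into consecutive fragments
with lengths uniform on [0.5, 1.5] × the N50 target; the mass-median of
that distribution puts the realised N50 within 20% of the target. The
returned placements are the exact source intervals, which downstream
stages treat as the output of a read-mapping step.

**What the generator does not emulate:** sequencing reads and their error
profiles, amplification bias, nested/fragmented repeat insertions,
paralogous gene families, alternative splicing, and chimeric scaffolds.
Passing the parameter-recovery tests therefore demonstrates the
correctness of the downstream arithmetic under clean, disjoint features;
it does not establish calibration of, for example, the repeat masker on
heavily nested real Triticeae repeats.

## Super-scaffolding

Placements are reduced to one per query (highest score; ties to the
lexicographically smallest chromosome, then leftmost — a deterministic
convention, as the source procedure is silent on multi-mappers). Sorted
per chromosome, consecutive placements with reference gap 0 ≤ g < 50 merge
with exactly g Ns, preserving reference-projected length. A gap of
exactly 50 starts a new super-scaffold ("closer than" is strict). Members
on the minus strand are reverse-complemented so super-scaffolds read in
reference orientation. Overlapping placements (g < 0) are not merged by
default — the original behaviour is unstated — and a policy flag
(`mergeOverlapping = TRUE`) chains them with zero Ns instead.

## Repeat masking and landscapes

The masker is an exact 15-mer seed, diagonal-grouped, tolerance-extended
matcher — a desk-scale surrogate for a Smith–Waterman repeat masker. Seed
hits of an oriented library element on one alignment diagonal become a
candidate; the candidate window grows along the diagonal while its
mismatch fraction stays ≤ 0.1, is trimmed to end on exact matches, and is
reported if ≥ 50 b. Substitution-only extension means diverged copies with
indels would fragment; the planted copies are substitution-mutated, which
is the regime the masker is tested in. Externally produced GFF3/BED
annotations can be substituted at the same interface. Nested or
overlapping calls are resolved by longest-match priority (same-family
overlaps are unioned first), so per-family bases partition the masked
bases and family shares sum to one by construction.

## Orthology

Hit filtering applies the published per-species threshold triplets
verbatim (they live in `hitFilterProfiles()` and the pipeline
configuration, never inline). Best reciprocal hits rank by bit score with
deterministic tie-breaks (smaller e-value, then lexicographic subject id),
making the pair set one-to-one. Markov clustering runs on the
column-normalised weighted adjacency (edge weight −log10 e-value capped at
200) with expansion 2, configurable inflation (default 2.0), pruning at
1e-6, and convergence at max|ΔM| < 1e-9 or 100 iterations. Self-loops are
set to each node's maximum incident weight (1 for isolated nodes) — a
standard stabilisation; clusters are the connected components of the
converged non-zero structure, so disconnected components can never merge.
The test suite checks the sparse implementation against an independent
dense-matrix reference implementation on randomised graphs.

Two genuinely open points are resolved as follows:

* **Locus-occupancy evidence** counts chromosomes with ≥ 1 *filtered hit*
  from a wheat query to a group member, not ≥ 1 BRH. BRH is one-to-one
  per species pair by definition, so with two near-identical homeologous
  copies a BRH criterion would attribute every group to a single
  chromosome and the homeologous-only category would be empty by
  construction; hit-based evidence matches the "contigs associated with
  groups" framing of the analysis.
* **The gene-content estimator** converts per-chromosome conserved
  coverage to genes via the 2772-b mean CDS length:
  Σ size × fraction / 2772. An alternative locus-count estimator is
  available behind `method = "loci"`. Neither is claimed to be the exact
  arithmetic of the original survey, whose path from group counts to the
  genome-wide figure is unstated.

## miRNA annotation

The homology scan reports every ≤ 2-mismatch window on either strand
(substitutions only) and extends it by ±200 nt into a candidate
precursor, clipped at chromosome ends. Same-family candidates whose
precursors overlap reciprocally ≥ 50% are deduplicated (fewest
mismatches, then leftmost, plus strand first); note that any planted
hairpin legitimately yields a mirror-image minus-strand candidate — its
3' arm contains the mature's reverse complement — which the deduplication
collapses.

Hairpin evaluation maximises base pairing with a Nussinov dynamic program
(Rcpp; minimum loop 3, G:U allowed) and derives metrics from one optimal
traceback: the paired-mature fraction, whether any pair has both ends
inside the mature (the operational definition of "mature spans the
terminal loop"), and the size of the nested pair chain through the
outermost mature-involving pair (the stem arm). Pass requires ≥ 60%
mature bases paired, no loop-spanning, and ≥ 18 stem pairs. These
thresholds are explicit configuration values, not claims about the
original pipeline, whose structural criteria live in earlier
publications.

Confidence is low (LC) iff the precursor's TE overlap — the interval
union of repeat annotations intersected with the precursor, over its
length — strictly exceeds 0.5. Target scoring is a documented surrogate
for a web-service tool: per-position costs (mismatch 1.0, G:U 0.5, zero
for Watson–Crick) doubled at mature positions 2–13, reported at penalty
≤ 3.0, no gaps.

## The lncRNA cascade

Stages run in a fixed order (length > 200 strictly; six-frame complete
ATG..stop ORFs > 100 aa, with incomplete stop-free frames not counted and
the translation guarded against alternative-initiation-codon promotion;
homology screens at the published thresholds with "any passing hit
discards"; per-genome acceptance at coverage 1.0 and score ≥ 40; the
reverse-complement splice check, which discards a transcript only when
every intron signal reads CT-AC and the reverse complement encodes a
> 100-aa ORF; and the all-genome core intersection). Each stage emits
trace rows, so the final audit trail has exactly one removing stage per
removed transcript, and the homology screens are order-independent
because removal is a union of per-screen predicates. Coding-potential
labels from an external classifier can be injected as one more removal
screen; the offline default relies on the ORF rule alone.

## Markers

SSR detection reimplements the MISA defaults (mono 10, di 6, tri–hexa 5
minimum units; compound merge at interruptions < 100 b) on maximal
perfect whole-unit runs. Motifs are canonicalised to the minimal rotation
only — no reverse-complement collapsing — to keep reporting
strand-explicit for primer design. Non-primitive motifs (powers of a
shorter motif) are reported at the shorter length, and loci contained in a
longer-motif locus are suppressed. ISBP junctions are annotation state
changes (family→family at zero gap, family→unique, unique→family) with
≥ 30 assayable bases to each contig end; primer-quality scoring is out of
scope. Variant filtering is a plain predicate (depth, quality, optionally
biallelic) and the summary partitions survivors into SNPs and InDels, so
counts are conserved by construction.

## Synteny and translocation detection

Links are queries with a unique best placement in both genomes (tied best
scores exclude the query). Ribbons bin links by midpoint into window
pairs; bundling is strict (count > threshold), and midpoint binning keeps
Σ ribbon counts equal to the link count. The published rule operates at
> 200 links per 1-Mb window on a full genome; at the default toy scale
the pipeline uses 100-kb windows with a threshold of 5, preserving the
strict inequality. Bundled ribbons whose chromosome pair is absent from
the expected correspondence table are flagged; on the default conditions
the only flagged pair is the engineered donor/acceptor pair, with windows
within one bin of the recorded breakpoints.

## Problem sizes and degenerate inputs

The default study conditions are 2 homeologous pairs × 500 kb (scaled
down from 7 pairs at gigabase scale), 25 genes per chromosome, 16
hairpins, 12 lncRNAs, 12 decoys, 20 SSRs and a 50-kb translocation; unit
tests use a 4 × 60-kb genome. These sizes were chosen so that every
feature class is represented multiply per chromosome while a full
pipeline run remains a couple of minutes of CPU.

Degenerate inputs are handled explicitly: empty sequence sets are errors
for assembly statistics and empty libraries for masking; zero-length
features are errors for overlap fractions; empty placement or link sets
return empty results; an infeasible packing (features exceeding
chromosome capacity) aborts generation naming the overfull chromosome;
malformed variant records and gene models are errors carrying the
offending record.

## Known limitations

The masker does not model indel divergence or nested insertions; the
hairpin evaluator maximises pairing rather than free energy, so
thermodynamically marginal hairpins can pass; the target scorer is
ungapped; the cascade's organellar/ncRNA screens use configurable
defaults where the original thresholds are unstated; and the synthetic
genome's clean feature geometry makes recovery rates upper bounds on
real-data performance.
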