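---
title: "Clustering CCS reads for amplicon consensus and tiled assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering CCS reads for amplicon consensus and tiled assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes and why the
numerical choices are what they are. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` compute themselves.

## The data model

A SMRT instrument reads a circularised amplicon insert repeatedly; each pass
is a *subread*, and successive subreads alternate strand. All subreads of a
molecule share a `"<movie>/<zmw>"` identifier. Subreads are individually
poor (total per-base error on the order of 10-20%, insertion-leaning), but
the per-molecule circular consensus sequence (CCS) formed from them is good
enough that short fixed sequences — PCR primers, sample barcodes, padding —
can be located in it *exactly*. That observation carries the whole design:
demultiplexing and amplicon assignment are done on CCS reads by exact
substring matching, and all the error tolerance lives in the consensus
steps before and after.

## Pipeline stages and their assumptions

**CCS building** (`build_ccs`). Subreads are oriented against the longest
subread by Levenshtein distance (Myers bit-parallel, both strands), then
star-aligned to it with a banded unit-cost global alignment and reduced to
a per-column weighted majority. The consensus is recomputed against its own
output for up to 3 rounds (almost always a fixpoint in 2), which removes
the bias a single error-laden seed subread would otherwise imprint. The
*predicted accuracy* of a CCS read is the mean over consensus columns of
the fraction of subreads agreeing with the called base — a deliberate,
documented surrogate for vendor likelihood models, which are out of scope.
By this column definition a single-pass molecule scores 1.0, so the default
filter (minimum 1 pass, 0.90 predicted accuracy) never rejects single-pass
reads; this matches the permissive reads-of-insert settings appropriate for
clustering, where downstream exact matching provides the real specificity.

**Clustering** (`cluster_ccs`). One-level mode matches each amplicon's
forward primer in the first `search_space` bases and the reverse-complement
of its reverse primer in the last `search_space` bases (default 21 bp);
antisense is tested on the flipped read, sense first — a deterministic tie
rule for palindromic pathologies. Two-level mode prepends the sample
barcode (and, by default, the shared 5' padding, which sits outermost on
the synthesis oligo) to both primers and widens the window to 121 bp:
padding (5) + barcode (16) + primer (~20) plus slack. Matching is exact by
default; a Hamming `max_mismatch` knob exists for robustness experiments
but is off, because exact matching is what makes cluster membership
auditable. Reads matching no entry or more than one are set aside with
reasons (`no_match`, `ambiguous`) rather than guessed at — an ambiguous
molecule must never pollute a polishing cluster. The cost of this strictness
is known and accepted: a molecule whose CCS read has an error inside a
primer window is lost to clustering, which mostly affects very long
amplicons with few passes.

**Cluster polishing** (`polish_cluster`, `consensus_all`). Whitelisted raw
subreads are polished by deterministic iterative majority voting: orient all
subreads against the current template (initially the longest subread),
banded-align each, vote per column including insertions and deletions,
update, and stop at a fixpoint (zero edits) or `max_iters` (default 5).
This replaces likelihood-based polishers on purpose — the claim under test
is that *clustering* determines consensus quality, and a transparent
majority vote makes that attribution clean. Clusters with fewer than
`min_subreads` (default 100) whitelisted subreads are reported but not
emitted; set 0 to keep everything, as accuracy evaluation does. The filter
counts subreads after the optional `min_subread_length` filter (default 0),
a deliberate resolution of an ambiguity in how support should be counted.

**Tiled assembly** (`assemble_sample`). Emitted consensus sequences are
trimmed by `trim_bp` per end (the run-parameters default is the panel's
padding+barcode length, i.e. exactly the synthesis extension), then every
pair is tested for dovetail and containment overlaps on both strands by a
full overlap dynamic program (match +1, mismatch −2, gap −3). Edges need
`min_overlap` ≥ 40 bp and identity ≥ 0.94 — conventional small-assembler
values, config-exposed since nothing in the method depends on them finely.
Members are placed by breadth-first traversal from the longest sequence of
each component (contradictory placements are a hard assembly error), and
columns are voted: one voter keeps its base; two disagreeing voters write
`N`; three or more voters take the plurality base, and a plurality *tie*
also writes `N` — the conservative extension of the two-voter rule.
Contained members simply join the container's column votes. `N` runs are
exported as 0-based half-open BED intervals.

**Evaluation** (`align_and_report`, `bootstrap_experiment`). Consensus and
contig sequences are aligned locally to the reference (match +1, mismatch
−2, gap open −5, extend −2, both strands; `N` never matches) and reported
as `100·matches/alignment_columns` with mismatch and indel counts (bases
and events — the error decomposition defaults to bases, with an `"events"`
mode, since either reading of "insertions, deletions and single
nucleotides" is defensible). The bootstrap draws `d` CCS identifiers per
amplicon *with replacement* for `d` in a depth grid, replicated; a molecule
drawn twice contributes its subreads twice — the literal reading of
sampling with replacement. Each replicate's consensus set is assembled per
sample and an assembly's subread depth is the minimum over its member
clusters.

## The simulator and what it does not emulate

`simulate_library` generates: a random reference with optionally planted
homopolymer runs (length 8-12) at recorded positions; an end-to-end tiling
of amplicons with primers taken verbatim from amplicon ends; symmetric
per-sample barcodes with the shared 5' `GTTAG` padding outermost; and
multi-pass raw reads with alternating orientation. Pass counts follow
`1 + Poisson(mean − 1)` (mean 9 by default, matching typical multi-kb
amplicon libraries in long movies). The error model applies, per base,
exclusive substitution/deletion events and an independent insertion after
the base; inside homopolymer runs of length ≥ `run_min` the insertion rate
is raised by `homopolymer_ins_rate` and the inserted base repeats the run —
reproducing the systematic run-length inflation long-read chemistry shows.
Defaults are 3% substitution, 8% insertion, 4% deletion (15% total,
insertion-dominated); the tests mostly use a 2/5/3 profile (10% total).
`protect_ends` can keep a fixed number of template bases error-free at the
ends, which isolates clustering behaviour from end-window errors in
experiments.

Not modelled, deliberately: polymerase kinetics and per-base qualities
(qualities are a constant placeholder; nothing reads them), chimeras,
adapter dimers, or the SMRTbell adapter itself (subreads are emitted
already split, since the pipeline consumes subreads). Passing tests on this
simulator therefore demonstrate the pipeline's *bioinformatic* correctness
— clustering, voting, assembly rules, bookkeeping — not robustness to every
artefact of real libraries.

## Numerical choices

* **Alignment bands.** Star/polish alignments run in a diagonal band of
  half-width `band_frac` of the template length (0.15 for CCS, where
  subread divergence is ~2x the per-read error; 0.10 for polishing), with a
  32 bp floor and automatic widening to cover any length difference.
* **Column tie-breaks.** All consensus voting uses plurality over
  {A, C, G, T, gap} with ties preferring the current template's base, then
  A<C<G<T, gap last. An earlier variant that let gaps win only on strict
  majority and broke ties by fixed base order was measurably worse (it
  preserved spurious seed insertions), so the template-stable rule is used
  everywhere; it is equally deterministic.
* **Insertions between columns** are emitted only when a strict majority of
  spanning reads carries a non-empty insertion at that junction; the
  inserted string is the highest-weight one, ties to the lexicographically
  smallest.
* **Degenerate inputs.** Consensus of k identical sequences is that
  sequence for any k ≥ 1; polishing an emitted consensus against itself is
  a no-op; empty clusters, over-trimming, unwritable directories and
  whitelist/subread mismatches are hard, named errors.
* **Determinism.** Every stochastic component takes an explicit seed and
  restores the caller's RNG state; identical seeds give byte-identical
  FASTQ/TSV artifacts, and the bootstrap is reproducible end to end.

## Scale used in tests

The method targets 3-8 kb amplicons. The test suite and the acceptance
script exercise identical code paths at reduced length — 150-800 bp
amplicons, 2-8 amplicon tilings, up to 6 samples x 6 amplicons x depth 20
(720 molecules, ~6,500 subreads) and bootstrap grids of up to depths
1-40 x 25 replicates x 8 amplicons (8,000 consensus records) — sizes chosen
so the full suite runs in minutes on one CPU while keeping pass counts,
depths and error rates at the method's operating point. Polishing fidelity
is additionally checked at 3 kb (100 subreads at 10% error must reach
99.9% identity).

## Known limitations

* Exact end-window matching requires intact barcode+primer sequences in the
  CCS read; molecules whose consensus has an error there are dropped rather
  than rescued. For very long inserts with one or two passes this loses
  yield.
* The majority polisher has no base-quality model and no diploid phasing;
  it targets amplicons from homozygous material (allele phasing is out of
  scope).
* The assembler lays members at fixed offsets from pairwise overlaps; it is
  a tiling-path assembler, not a general repeat-resolving one, and indels
  inside an overlap shift the conflict column rather than being re-gapped.
* Systematic errors shared by a majority of molecules (e.g. PCR-era
  homopolymer duplications) are faithfully *kept* by majority voting — the
  bootstrap harness exists precisely to surface that depth cannot fix them.
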