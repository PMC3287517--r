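---
title: "Methods: multitag 454 amplicon analysis of endosymbiont communities"
author: "amplitag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multitag 454 amplicon analysis of endosymbiont communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameters and
design choices. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data-generating model

A multitag 454 amplicon run pools PCR products from several samples. Every
molecule carries, inside the Titanium adaptors,

```
key (TCAG, 4 bp) + MID (6 bp) + primer (18-20 bp) + insert (~450 bp 16S V1-V2)
```

on the A side and the reverse-complemented reverse tag on the B side. The
simulator (`simulate_community()`) draws, per read: a template by the
sample's configured relative abundances; an insert length from
`Normal(len_mean, len_sd)` clipped to `[100, template length]`; an
orientation (reverse with probability `rev_read_frac`); then builds the
tagged amplicon and applies noise. A truth table (read → sample, template,
orientation) accompanies the reads; there is no hidden state.

### Error model

454 error is dominated by homopolymer miscalls, not substitutions. The
model (`error_model()`) has two parts:

* a per-base substitution probability `sub_rate` (uniform over the three
  alternative bases), and
* a per-homopolymer-run indel probability `min(0.5, hp_indel_base *
  hp_scale^(k-1))` for a maximal run of length `k`; insertion and deletion
  of one base are equiprobable.

Defaults — `sub_rate = 0.004`, `hp_indel_base = 0.01`, `hp_scale = 1.6`,
`len_mean = 430`, `len_sd = 25`, `rev_read_frac = 0.5` — give reads of
roughly 460 bp total (insert + 30 bp tag, matching the platform's ~450 bp
amplicon reads) with about 2 substitutions and 4–5 homopolymer indels per
read, i.e. the error profile published for GS FLX Titanium chemistry, and a
run-length dependence that the test suite checks against the closed form
(a 6-base run at `hp_indel_base = 0.01, hp_scale = 2` mutates with
probability 0.32).

What the simulator does **not** emulate: flowgram-level signal, PCR chimera
formation, amplification bias between templates, and per-individual
substructure (the motivating study pooled 7 larvae per species equimolar;
the pooled library is what the sequencer saw, so profiles are per-sample).
Passing tests on simulated data therefore demonstrate correctness of the
algorithms under this error model, not robustness to chimeras or primer
bias in real libraries.

## Demultiplexing

"Accurate match" is read strictly: 0 mismatches in the 4-base key at
position 0 and in the 6-base MID at positions 4–9, in either orientation
(forward and reverse MIDs are distinct across all samples and orientations,
enforced at sample-sheet load, so assignment is never ambiguous). The
primer that follows is matched IUPAC-aware (the universal forward primer
`MGAGTTTGATCCTGGCTCAG` has a degenerate first base), by default with 0
mismatches (`primer_mismatches` is exposed). The quality gate is a mean
Phred threshold (default 20) plus an N-count cap (default 0) — the
filtering criterion behind "high quality reads" is not published, so both
knobs are explicit.

With ~30 tag bases per read and the default error model, roughly a third of
simulated reads fail the exact tag match and land in `UNASSIGNED`; the loss
is orientation- and template-independent (every read of a sample carries
the same tag), so composition estimates are unbiased. This mirrors the
sizeable raw-to-assembled read loss typical of published 454 surveys.

Reverse-orientation reads are reverse-complemented into forward frame on
output. A forward-frame reverse read has no 5' key+MID — its tag sits
reverse-complemented at the 3' end — so `assign_read()` also recognises
that 3' tail pattern. This makes demultiplexing idempotent on its own
output pools, which the test suite asserts.

Coordinates in all reported spans are 0-based half-open.

## WiMSeEx assembly

The algorithm is named for *window match seed extension*; its published
description consists of its parameters (minimum seed 200 bp, window 60 bp,
key + 20 primer bases for seed detection, 500 kb stop). The extension
mechanics are this package's reconstruction, and every choice is a flagged
default of `wimseex_params()`:

* **Seeding.** Seeds are reads of ≥ `min_seed_size` whose prefix matches
  key + MID + first `anchor_len_primer` primer bases (IUPAC-aware), longest
  first, id as tie-break. (The pool is per-tag, so requiring the MID is
  free; `anchor_mode = "mid"` drops the key requirement instead.)
* **Window matching.** The contig's terminal `window_size` bases must occur
  in the read with identity ≥ `min_window_identity` (default 1.0 — the most
  literal reading of "window match"), leftmost occurrence, and the read
  must extend past the contig's 3' end. Matching is delegated to
  Biostrings' pattern matching.
* **Extension.** One window-advance per round: the contig grows by at most
  `window_size` bases per round, each new column the majority base over all
  matched reads' overhang columns (N never outvotes a concrete base; ties
  give the IUPAC code). A read is consumed — exclusively — the first round
  it matches; overhangs from earlier rounds keep voting until exhausted.
  Extension is 3'-only: seeds begin at the amplicon's 5' anchor, so
  leftward extension is impossible by construction.
* **Containment consumption.** After extension, reads whose leading window
  occurs in the contig and whose full length fits inside it are consumed as
  supporting members. Without this, forward reads that are proper prefixes
  of the contig could never be consumed (they cannot *extend* it), would
  re-seed duplicate contigs, and per-template support could not equal the
  simulator's truth — which the zero-noise oracle tests require.
* **Polish.** The finished contig is re-voted column-by-column against a
  capped, evenly spaced subsample of its members (default 300; majority
  votes saturate far below that), using ends-free pairwise alignment so
  that member insertions/deletions vote too: a column with a strict gap
  majority is dropped, a junction where most covering members carry an
  insertion gains the majority base. This exists because the contig
  otherwise inherits the seed read's own errors (~6 per read at default
  noise), capping consensus identity near 98.7%; with polish, zero-noise
  contigs are byte-identical to the true amplicon and noisy contigs stay
  above 99% identity, which the suite asserts.
* **Budget.** "Stopped by reaching 500 kb sequence data" is read as a cap
  on the cumulative length of consumed reads, checked between seeds
  (`budget_mode = "contig_bases"` is the alternative reading). At the
  study's per-tag depths (6,000–8,600 reads ≈ 3–4 Mb) the budget is
  exhausted by the first, dominant contig — which is why OTU *abundance*
  is measured by re-mapping (below), not by assembler membership.
* Contigs below `min_support` (default 2) are discarded; at default noise
  these are almost exclusively single reads whose first window carries an
  error.

## OTUs and the abundance table

Per sample, contigs are clustered greedily around centroids in support
order at `identity ≥ 0.97` — the conventional 16S OTU radius; the value is
not published for this pipeline and is exposed (`identity`). The cluster
consensus is a support-weighted column vote of members projected onto the
centroid. The key+MID+primer prefix is then stripped (IUPAC-aware, with a
1-mismatch tolerance for residual consensus error), as is the
reverse-complemented reverse tag that fully extended contigs carry at
their 3' end.

Read counts per OTU come in two modes:

* `membership` (default of `make_otus()`): summed assembler support of the
  cluster's contigs;
* `remap`: every demultiplexed read of the sample is assigned to its best
  OTU by pairwise identity, requiring ≥ 0.90; percentages are then taken
  over the sample's total assigned reads.

The shipped demo pipeline uses `remap`, because under the 500 kb assembly
budget membership counts cover only the consumed fraction of a deep pool,
whereas an abundance table must account for every assigned read — note the
published per-species tables likewise sum to full per-tag read totals.
Reads below the mapping threshold (at default simulation settings, the
rare-template reads, whose templates never assemble within budget) remain
uncounted rows of nothing: they appear in the denominator, not in any OTU
row, which leaves the dominant percentage an honest estimate of the
configured dominance.

### Pairwise identity

All identity computations use one primitive (`pairwise_identity()`,
implemented in C++): ends-free (overlap) Needleman–Wunsch with match +1,
mismatch −1, gap open 2, gap extension 0.5. Identity is matches divided by
alignment columns **plus any unaligned remainder of the shorter sequence**.
The ends-free form is what read-versus-consensus comparison needs (a read
is a fragment of the amplicon; its unshared tag bases must not be
penalised), and the shorter-sequence correction prevents the degenerate
opposite — two unrelated sequences scoring high identity on a trivial
15 bp overlap. A sequence fully contained in a longer one is judged on its
own full length.

## Phylogenetic placement

The original study placed consensus sequences into a curated alignment of
260,000 reference 16S sequences. This module deliberately operates at desk
scale on user-supplied reference sets of tens of sequences — the same
algorithms, exhaustively and exactly:

* `distance_matrix()`: pairwise-deletion p-distance, with the Jukes–Cantor
  correction `−(3/4)·log(1 − 4p/3)` as the default model (`p ≥ 0.75` is
  flagged `NA` with a warning);
* `neighbor_joining()`: Saitou–Nei agglomeration; `Q` ties break to the
  smallest pair in matrix order; negative branch lengths are clamped to 0
  with the deficit moved to the sister branch (standard practice). NJ is
  exact on additive matrices, and the suite asserts topology (RF = 0) and
  path-length recovery to 1e-9 over random trees of 4–12 leaves;
* `fitch_score()`: small parsimony on binary trees, gaps and N as
  wildcards, vectorised over columns;
* `parsimony_place()`: the query is profile-aligned to the (degapped)
  majority consensus of the reference alignment, attached to *every* branch
  in turn and Fitch-scored — exhaustive branch evaluation replaces the
  original tool's proprietary insertion heuristics, which is feasible and
  exact at this scale. Ties go to the first branch in preorder; the full
  score list is returned for audit.

Newick I/O delegates to `ape`. The packaged reference set
(`synthetic_refs_16s.fasta`) is *synthetic* — three clades ("Rickettsia-
like", "Nardonella-like", "Neoehrlichia-like", ~3% within-clade divergence)
plus unrelated outgroups — standing in for the curated database that cannot
be redistributed; accessions are prefixed `SYN` to make this unmistakable.

## The demo configuration and problem sizes

`inst/extdata/demo_pipeline.yaml` encodes the four-species study design:
read depths 6,073 / 8,584 / 6,412 / 6,311 and dominant-OTU fractions
0.9083 / 0.9087 / 0.9916 / 0.9349 (the printed per-species values), default
error model, default WiMSeEx parameters, remap counting. Minor community
members are synthetic unrelated templates at 0.3–5% each; one template is
shared between two samples to emulate the published observation of the same
endosymbiont lineage appearing in several hosts. The acceptance script runs
this configuration end to end (a few minutes on one CPU); module tests use
smaller pools (150–1,000 reads) chosen to exercise the same code paths at
interactive speed. The per-seed subsample cap of 300 reads for polishing
and the identity thresholds above are the only scale-dependent constants.

## Numerical and degenerate-input conventions

* All randomness flows from a single seed; the pipeline derives per-stage
  seeds by hashing the stage name, so adding a stage never perturbs earlier
  stages' streams. Reruns are byte-identical (checksummed manifest).
* Majority-vote ties between concrete bases yield the IUPAC code of the
  tied set; a base beats N; a tie between base and gap keeps the base.
* Empty pools, empty clusters and unmatched reads are data (empty results
  or `UNASSIGNED`), not errors; malformed *files* are errors that name the
  offending line or record.
* Percentages are reported to two decimals, matching the field's table
  conventions; per-sample percentage columns sum to 100 ± 0.05 under
  membership counting.

## Known limitations

* The WiMSeEx internals are a reconstruction from the published parameter
  set; `min_window_identity`, `anchor_mode` and `budget_mode` expose the
  readings that cannot be settled from the original description.
* Whether the 500 kb stop was per tag or global is likewise unknowable;
  it is implemented per tag ("each assembly run").
* The consensus aligner is centroid-anchored, not a full multiple
  alignment; for the ≤ a-few-contigs clusters this pipeline produces the
  difference is immaterial, and an external aligner can be applied to the
  written FASTA intermediates if desired.
* Fitch parsimony requires binary trees; multifurcating references must be
  resolved first.
* Chimera detection, rarefaction and diversity statistics are out of
  scope.
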