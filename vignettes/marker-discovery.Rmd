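---
title: "Plastome marker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome marker discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastmark)
```

## The problem

Chloroplast genomes ("plastomes") are compact, largely colinear, and
maternally inherited, which makes them the molecule of choice for plant DNA
barcoding. Universal barcodes such as *matK* and *rbcL* amplify across
families but often carry too few polymorphisms to separate close species.
Given whole-plastome sequences for a group of interest, a better strategy is
comparative: align the plastomes, find the regions that are simultaneously
(a) variable enough to discriminate taxa and (b) bracketed by perfectly
conserved sequence where primers will match every member of the group.
plastmark implements that strategy as a reusable, fully testable pipeline.

## The two consensus tracks

Everything downstream is driven by two per-column tracks derived from the
alignment (`build_consensus_pair()`), both kept at full alignment length so
that SSRs, barcode blocks and primers share one coordinate frame:

* **best-base** — the majority base per column, with gaps and `N` excluded
  from the vote. Ties break in the fixed order A < C < G < T (the rule is
  arbitrary but deterministic; the sources are silent on ties). A column
  with no votes at all becomes `-`.
* **ambiguous** — an explicit base only where *every* row carries that same
  A/C/G/T base; any mismatch, gap or `N` makes the column ambiguous (`N`).
  Explicit columns are exactly the perfectly conserved ones, and they are
  the only sequence primers may be built from.

An `N` in an input row is treated as a mismatch, never as support: it
encodes base-calling uncertainty, not evidence of conservation.

**Divergence** of a region is defined once, for all filters, as the
fraction of its columns that are ambiguous. Gap-containing columns
therefore count as divergent. The alternative (pairwise average distance)
would not be computable from the consensus pair alone and would decouple
the divergence filter from the conservation track that the primer rules
use.

## Microsatellite (SSR) screen

`find_perfect_repeats()` reports maximal perfect tandem repeats on the
best-base track with unit length 2 or 3 and at least 4 complete units
(`min_units = 4`). Only complete units enter the reported span; runs never
cross a `-` column; homopolymers disguised as di-/tri-motifs (`AA`,
`AAA`) are rejected because mononucleotide runs are technically unreliable
markers. Motifs are canonicalized to their lexicographically smallest
rotation only — the consensus has a fixed strand, so no reverse-complement
collapsing is applied by default.

`screen_polymorphic()` then asks whether the repeat actually varies across
the aligned taxa: a locus is polymorphic when an ambiguous column lies
inside the repeat span or within `proximity = 4` bases of either edge.
Offsets are measured from the span boundary (inside = 0, adjacent = 1), so
the cutoff admits offsets 1–4 outside the repeat. This is the natural
reading of "within 4 bp"; it is monotone in `proximity` and exercised at
both sides of the boundary in the test suite.

## Barcode block scan

`scan_blocks()` slides a 300-column window (stride 1 by default) and
accepts a window when all four criteria hold:

| parameter | genus | family | meaning |
|---|---|---|---|
| `min_divergence` | 2% | 2% | enough variation to discriminate |
| `max_divergence` | 10% | 15% | still alignable / amplifiable |
| `min_flanked_snps` | 5 | 8 | well-behaved diagnostic sites |
| `max_ambiguous_run` | 7 | 7 | no long indels or dropouts |

A *flanked SNP* is an ambiguous column that (a) arises from a substitution
— every row carries an A/C/G/T base there — and (b) is bordered by
`flank_width = 5` perfectly conserved columns on each side. Indel- or
N-derived ambiguity counts toward divergence and ambiguous runs but never
toward the SNP count: a SNP is a substitution by definition. Flanks may
extend outside the window (the window boundary is an artifact of the scan)
but not outside the alignment.

Two numerical choices deserve note. First, all thresholds are
**inclusive** (≥ 2%, ≥ 5/8 SNPs, ≤ 10%/15%, ≤ 7): the source material
states the rules once as strict and once as inclusive bounds, and we
follow the inclusive phrasing; every bound is config-exposed. Second,
overlapping accepted windows are **merged** into one block spanning their
union, with `merged_from` recording the window count. The union's
statistics are reported but deliberately *not* re-filtered: the guarantee
attached to a block is that every constituent window passed, and the
acceptance suite re-verifies exactly that, per offset, with the public
interval operations.

## Primer design

Primers are drawn exclusively from explicit columns of the ambiguous
track, i.e. from sequence identical in every aligned taxon — the point of
the whole construction, since such primers are unbiased across the group.
Search geometry: forward placements start up to `max_search_flank = 300`
columns upstream of the target and no later than its last column; reverse
placements mirror this downstream. Placements inside the target are
legitimate (its conserved stretches are fair game); what matters is that
the amplicon covers at least one polymorphic column of the target, which
`design_pairs()` enforces. With a 300-bp block and a 100–280-bp product
window this is in fact the only workable geometry: an amplicon can never
contain a whole 300-bp block.

Defaults: product size 100–280 (as published), primer length 18–24, Tm
52–62 °C, GC 30–70%, maximum pair ΔTm 4 °C (standard Primer3 defaults,
which the published pipeline did not override). Melting temperatures use
the SantaLucia (1998) unified nearest-neighbor parameters with duplex
initiation terms, the symmetry correction for self-complementary oligos,
and the entropic salt correction `ΔS + 0.368 (n−1) ln[Na+]`, at 50 mM
monovalent salt and 0.25 µM total strand concentration; values are frozen
against an independent implementation in the tests. A Wallace-rule mode
exists for quick arithmetic only.

Ranking is a Primer3-style penalty: |Tm − optimum| for each oligo, excess
pair ΔTm beyond half the allowance, GC deviation beyond 0.4–0.6, and a
−0.5 bonus per 3′ G/C clamp; ties resolve to the leftmost forward
placement, then the shortest product, so output is deterministic. Two
engine-specific Primer3 knobs (`PRIMER_MAX_END_STABILITY`,
`PRIMER_LIBERAL_BASE`) have no direct analogue here; the built-in engine
instead applies a simple cross-dimer screen (reject any pair with a
complementarity run ≥ 8) and records its constraint-rejection histogram
when no pair survives. Candidate lists are capped at the best
`max_candidates = 200` per orientation before pairing; this keeps pairing
tractable and, because the cap is applied to penalty-sorted candidates,
it cannot exclude a pair that would have ranked in any reasonable top-k.

## Distance tree

`k80_distance()` implements the Kimura two-parameter distance
`d = −½ ln((1 − 2P − Q) √(1 − 2Q))` with pairwise deletion (columns with a
gap or `N` in either row are excluded for that pair only). Saturated pairs
(non-positive log argument) are flagged, never silently zeroed, and are a
hard error in tree building. `nj_tree()` delegates Saitou–Nei neighbor
joining to ape with taxa pre-sorted by id for deterministic tie-breaking;
negative NJ branch lengths are clamped to zero with a warning.
`bootstrap_support()` resamples alignment columns with replacement
(seeded), rebuilds the tree per replicate, and reports the percentage of
replicates containing each internal bipartition (default 50 replicates).

This is a deliberate, documented stand-in for full maximum-likelihood
inference: at five or six plastome-scale taxa the claim being tested is
topology plus support, for which distance NJ with bootstrap is adequate;
ML search, model selection and rate heterogeneity are out of scope.

## The synthetic family generator

`simulate_family()` exists so that every stage can be validated closed-loop
without downloads. Its default stated world is a five-taxon family on the
topology `(((Zof,Hco),Clo),(Aze,Aca))` with every branch at 0.001
substitutions/site — i.e. ~99% background identity, the conservation
regime in which plastome-family barcoding operates — over 20 kb under K80
with κ = 2, containing:

* two 600-bp perfectly conserved islands (rate multiplier 0);
* two 300-bp hypervariable blocks (rate ×10, giving realized divergence
  around 4–8%, inside the family window);
* two SSR loci planted as explicit per-taxon unit counts (`AT` at
  6/6/8/6/6 and `AAG` at 5/5/5/7/5), shorter taxa padded with aligned
  gaps as an aligner would emit them;
* one 9-bp single-taxon indel realized as gap columns.

SSR polymorphism is planted, not evolved: the pipeline under test is
*detection*, and a replication-slippage model would add realism without
adding verification power. Indels are likewise planted post hoc as aligned
gap columns, avoiding the need to implement an aligner. Because
substitution is stochastic, the truth table records each feature's
*realized* statistics (divergence, flanked-SNP count, ambiguity runs,
detectability at each level) measured on the final alignment; tests assert
against realized truth, never against the request.

What a green closed-loop test establishes: the scanner finds exactly the
windows that satisfy the stated criteria, on data whose ground truth is
known by construction. What it does not establish: performance on real
alignments with alignment error, rearrangements, IR duplication,
heterogeneous rates along the genome, or biased base composition — none of
which the generator emulates.

## Degenerate inputs and edge policies

Single-row alignments are rejected for consensus (undefined for the
analysis). All-gap columns yield `-` in the best-base track; all-N columns
do too, with a warning. Non-N IUPAC codes on input demote to `N` with a
warning rather than erroring, because real assembly consensus callers emit
them. `.` normalizes to `-`; `U` to `T`. The final partial window of an
identity profile is emitted and flagged rather than dropped. An SSR
candidate list with no `N` anywhere reports `NA` offsets and
`polymorphic = FALSE`.

## Known limitations

* NJ/K80 replaces ML tree search (above).
* Compound or interrupted microsatellites are not modeled; only simple
  perfect di-/tri-repeats, per the stated marker criteria.
* No in-silico PCR against off-target genomes and no multiplex
  compatibility scoring; the dimer screen is a complementarity-run
  heuristic, not a thermodynamic duplex scan.
* The SSR primer product-size range is assumed equal to the barcode range
  (100–280); the source pipeline hints at a different, unstated range for
  SSRs. It is config-exposed.
* Alignments are consumed, not produced: input must be a single colinear
  aligned-FASTA block, pre-flattened by the user's aligner.
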