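---
title: "Finding W-specific sequence from sexed coverage pools: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding W-specific sequence from sexed coverage pools: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscan)
```

## The coverage model

Consider a ZW system in which females are the heterogametic sex and the
reference assembly was built from a female, so it contains both Z- and
W-derived sequence. If a panel of individuals of known sex is resequenced
and the alignments pooled by sex, the expected pooled depth at a base is
proportional to the number of copies each sex carries:

| sequence class        | copies F / M | expected F : adjusted-M depth | log2 score |
|-----------------------|--------------|-------------------------------|------------|
| autosomal / pseudoautosomal | 2 / 2  | 1 : 1                         | ~0         |
| W-specific            | 1 / 0        | 1/2 : 0                       | large +    |
| Z-hemizygous (lost from W) | 1 / 2   | 1/2 : 1                       | ~−1        |
| collapsed repeat      | 2 / 2, ×k    | k : k, both far above mode    | excluded   |

The scan therefore needs only three ingredients: reliable per-base pooled
depths, a notion of which bases are informative, and a normalisation that
puts male depth on the female scale.

**Depth.** Records that are unmapped, secondary or supplementary (the flag
mask 2308) are excluded, as are reads soft- or hard-clipped at both ends —
a signature of chimeric or partially mapped placements that inflate depth
spuriously. Depth counts aligned reference-consuming positions (CIGAR
M/=/X/D).

**Validity.** With pooled modal nonzero depths `modal_f`, `modal_m`, the
limits are `min = floor(modal/3)` and `max = 3*modal` per sex, and a base
is valid iff `(Cf < max_f AND Cm < max_m) AND (Cf > min_f OR Cm > min_m)`,
all inequalities strict. The OR in the lower condition is essential: a
W-specific base has `Cm = 0` and must stay valid on the strength of its
female depth alone. The mode is taken over *nonzero* depths because
unassembled or unmappable stretches put a large mass at zero that says
nothing about the single-copy peak. Ties between equally common depths
break toward the smaller depth, and the lower limit rounds *down*: with a
lower fraction of 1/3 this maps modal depths 25 and 29 to limits 8 and 9,
whereas nearest-integer rounding would not.

**Normalisation.** Male means are multiplied by `adjustment =
modal_f/modal_m` before ratio formation. Anchoring the adjustment to modal
rather than mean depth makes it robust to repeat content and to the very
signal being sought; a total-throughput (mean-based) alternative is
available via `adjustment_factor(profile, method = "mean")`.

## The interval scan

Each scaffold is partitioned left to right into intervals accumulating
exactly `V = 1000` valid bases, the last interval of a scaffold keeping
whatever remainder is left. `V` fixes the *information content* of every
interval rather than its width: in repeat-dense or poorly covered regions
intervals stretch until they contain enough informative bases, so the
variance of the mean-depth estimates — and hence of the score — is
approximately constant across the genome. Reported boundaries are trimmed
to the first and last valid base actually contained, so interval spans
measure assayable sequence; interval means are computed over valid bases
only, since invalid bases are by definition repeat-inflated or
undersampled. (Both choices are the defaults; the scan exposes them
through its returned per-interval `n_valid`/`span` bookkeeping rather
than config switches, because the alternatives make `span` and the
candidate-bp totals depend on unassayable sequence.)

The score is `log2(mean_f / (adjustment * mean_m))`. A threshold of
score > 2 — female depth more than four-fold the adjusted male depth —
is far beyond what diploid sampling noise produces at `V = 1000`
(the score's standard deviation on diploid sequence is ~0.02 at the
default panel), yet is reached comfortably by hemizygous segments, whose
expected score is unbounded as male coverage approaches zero.

**Zero-male substitution.** When an interval contains no male read at all
the ratio is infinite; the male coverage estimate is replaced by the depth
contribution of half of one aligned read, `(read_length/2)/span` — half a
read is the natural continuity correction for "we might have just missed
one" — and the interval is flagged `zero_male`. The default
`read_length = 125` matches typical short-read data. The substitution
keeps scores finite and ranks fully male-absent intervals above
male-sparse ones of equal female depth without fabricating precision.

**Filters and thresholds.** Intervals with fewer than 500 bp of span or
fewer than 200 valid bases are discarded (scaffold-end remainders and
short scaffolds); both minima are inclusive at the boundary, since the
exclusion is of intervals *below* them. The candidate threshold is strict
(`score > 2`, so exactly 2.0 is not called), matching the semantics of an
excess beyond four-fold.

## The synthetic generator

`build_genome_model()` plants non-overlapping W-specific, Z-hemizygous and
collapsed-repeat segments into an autosomal background, plus segregating
deletion polymorphisms that are *independent of sex* — the main benign
source of presence/absence variation in real panels. `simulate_depth()`
draws per-base depth as an independent Poisson count with mean
`target_depth × copies/2 × repeat_multiplier`, thinned by Hardy-Weinberg
deletion genotypes per individual. The variance structure of real
per-base coverage is not published for data of this kind; Poisson is the
minimal counting-process choice and slightly *understates* real
overdispersion (GC bias, mappability), which is why the generator is a
model of the analysis' assumptions, not of a sequencing instrument —
passing recovery tests demonstrates correctness of the scan, not
field performance on real libraries. Sequencing error, GC bias and
mappability are deliberately out of scope. Repeats are modelled as depth
multipliers (the collapsed-reference signal that causes false positives
in practice) rather than literal sequence copies.

`emit_alignments()` writes placed reads as coordinate-sorted SAM with
configurable fractions of secondary and both-side-clipped records, so the
alignment-filtering path can be tested end-to-end: with no filters, the
total depth equals the total aligned length exactly (a conservation law
used in the tests), and filtered minus unfiltered depth equals exactly the
flagged records' contribution.

One master seed expands to per-individual seeds by the fixed schedule
`(master × 1009 + i) mod (2^31 − 1)`, so partial panel re-runs are
reproducible.

**Default study conditions.** The generator defaults and the recovery
tests use 22 females and 26 males at ~1X each (expected pooled modal
depths 22 and 26), a 10-Mb genome in 10 scaffolds, twenty 2-kb W-specific
segments, ten 2-kb Z-hemizygous segments, five 5-kb repeats at ×50, and
ten 2-kb deletion polymorphisms at frequency 0.3. The 10-Mb scale keeps
the full panel simulation under a minute on one CPU while leaving every
planted segment several intervals wide; the smaller unit-test models
(0.1–1 Mb) are chosen on the same principle.

## Supporting procedures

* **Chromosome assignment** uses *physical* coverage: only properly
  paired, mismatch-free (edit distance 0 on both mates, read from the
  standard `NM` tag; records lacking the tag are conservatively dropped)
  pairs on one scaffold count, each as its outer span, and a scaffold is
  assigned when ≥5% (inclusive) of its bases fall under the span union.
  Fragment spans forgive the sparse, uneven read spacing of
  whole-genome-amplified single-chromosome libraries better than per-base
  read coverage would.
* **Synteny enrichment** keeps alignments of ≥50 aa and ≥60% identity
  (inclusive), one best target per query (identity, then length, then
  input order) to avoid double counting, then scores each chromosome as
  observed homologs over annotated genes.
* **Panel statistics.** A marker present in each animal independently with
  probability 1/2 — a dominant marker segregating at intermediate
  frequency — matches the perfect female-present/male-absent pattern with
  probability `2^-(n_f+n_m)`; for a 6+6 panel, `2^-12 ≈ 2e-4`. The
  classifier distinguishes sex-specific (perfect pattern), near-specific
  (exactly one discordant animal), polymorphic, non-specific (all
  animals) and failed (no animals) markers. Biplex sex calls require the
  internal control band within ±10 bp (gel resolution; configurable)
  before the female-specific band is even consulted.
* **Cross expectations** are exact enumerations of the four equiprobable
  gamete combinations with a viability mask and the rule ZZ male, ZW/WW
  female: ZW×ZW with viable WW gives 3:1 females; ZZ×WW gives all-female
  spawns.
* **Paralog divergence** attributes a substitution to a paralog only when
  it departs from the strict-majority outgroup consensus while the other
  paralog matches it. Columns with focal gaps, without an outgroup
  majority, or with both paralogs off-consensus are reported as excluded
  or unresolvable rather than guessed — parsimony against consensus is
  the minimal attribution model, and counting what it cannot resolve is
  part of the output. Amino-acid impact is counted per codon by
  translating the observed codon against the codon with the attributed
  sites reverted to the ancestral state. Pairwise identity is computed
  over dual-ungapped columns only.

## Numerical choices and degenerate inputs

* All coordinates are 0-based half-open internally and in emitted
  BED/BedGraph; SAM positions are 1-based per the format.
* Scans of all-invalid scaffolds yield no intervals; an all-zero track is
  an error for modal coverage (no mode exists); an interval with zero
  coverage in both sexes cannot arise from valid bases and is asserted
  against.
* Panels require both sexes; ratio formation with zero males is refused at
  pooling time rather than producing an infinite adjustment.
* Degenerate limits (lower ≥ upper, possible only for modal depth < 1/
  fraction) are refused.

## Limitations

* The Poisson depth model ignores overdispersion and correlated coverage
  (GC, mappability); sensitivity estimates from synthetic panels are
  optimistic for real libraries.
* The scan assumes the reference contains the W-derived sequence; a
  male-derived reference cannot reveal W-specific regions at all.
* Modal-ratio normalisation assumes the single-copy peak dominates the
  nonzero depth distribution; heavily repetitive references may need the
  mean-based adjustment.
* Homolog calling trusts the provided alignment table; no alignment is
  performed in-package.
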