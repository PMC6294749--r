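# sexscan

Discovery of female-specific (W-chromosome) sequence in genomes with
homomorphic sex chromosomes, from pooled male/female read-depth ratios.

## The problem

In many amphibians, fish and reptiles the sex chromosomes are
*homomorphic*: a single Mendelian factor determines sex, but the Z and W
(or X and Y) are cytologically indistinguishable and differ over only a
tiny fraction of an often enormous genome. Such sex-limited sequence cannot
be found by karyotyping or ordinary assembly comparison. It can, however,
be found by resequencing a panel of individuals of known sex at low
coverage and scanning the reference for regions where pooled female depth
is far in excess of pooled male depth: W-derived sequence is hemizygous
(one copy) in ZW females and absent (zero copies) in ZZ males.

`sexscan` implements that comparative-coverage scan and its supporting
analyses for laboratories mapping a sex locus: scaffold-to-chromosome
assignment from single-chromosome sequencing libraries, per-chromosome
synteny enrichment of homolog calls, PCR marker-panel statistics,
ZW-system cross expectations, and parsimony counting of derived
substitutions between a gene and its recently acquired sex-linked
duplicate.

## The statistic

Individual alignments are filtered (secondary, supplementary and unmapped
records, and reads clipped at both ends, are dropped), pooled by sex, and
reduced to per-base depths C_f and C_m. From the modal nonzero depths
`modal_f` and `modal_m` the scan derives validity limits

    min = floor(modal / 3),   max = 3 * modal     (per sex)

and a base is **valid** iff

    (C_f < max_f  AND  C_m < max_m)  AND  (C_f > min_f  OR  C_m > min_m).

The upper bounds skip collapsed repeats; the lower bounds drop bases too
thinly sampled in both sexes to be informative. Each scaffold is then
partitioned into intervals containing V = 1000 valid bases, and each
interval receives an enrichment score

    score = log2( mean_f / (adj * mean_m) ),   adj = modal_f / modal_m,

with means taken over valid bases. When an interval contains no male reads
at all, the male mean is replaced by the depth contribution of half of one
read, `(read_length / 2) / span`. Intervals shorter than 500 bp or with
fewer than 200 valid bases are discarded; intervals with score strictly
greater than 2 (female excess beyond four-fold) are candidate W-specific
regions. A hemizygous female-specific segment has expectation
`score ≈ log2(mean_f / small male noise) >> 2`, a Z-hemizygous segment
(one female copy, two male copies) sits near −1, and ordinary diploid
sequence near 0.

A synthetic-data generator (`build_genome_model()`, `simulate_depth()`,
`emit_alignments()`) plants W-specific, Z-hemizygous, collapsed-repeat and
sex-independent indel-polymorphism segments with known coordinates and
draws per-base Poisson depth from the per-sex copy numbers, so the whole
pipeline is testable against ground truth.

## Worked example

Simulate the study-like panel — 22 females and 26 males at ~1X on a 1-Mb
genome carrying five 2-kb W-specific segments — then scan:

```r
library(sexscan)

model <- build_genome_model(n_scaffolds = 4, scaffold_length = 250000,
                            n_w = 5, w_length = 2000,
                            n_z = 3, z_length = 2000,
                            n_repeat = 2, repeat_length = 3000,
                            n_indel = 3, indel_length = 1000, seed = 7)

add <- function(a, b) if (is.null(a)) b else mapply(`+`, a, b, SIMPLIFY = FALSE)
fem <- mal <- NULL
for (i in 1:22) fem <- add(fem, simulate_depth(model, "female", 1, individual_seed(7, i)))
for (i in 1:26) mal <- add(mal, simulate_depth(model, "male", 1, individual_seed(7, 22 + i)))

profile <- sex_coverage_profile(fem, mal, n_females = 22, n_males = 26)
profile
#> sex_coverage_profile: 4 scaffolds, 22 females (modal 22) / 26 males (modal 26), adjustment 0.8462

res <- scan_w_candidates(profile, V = 1000, threshold = 2, read_length = 125)
unlist(res$limits)
#> min_f min_m max_f max_m
#>     7     8    66    78
res$report
#> candidate_report: 5 candidate intervals on 3 scaffolds (1 with >= 2), 5803 bp total, 5 with zero male reads
```

The pooled modal depths (22 and 26) reflect the panel sizes; the limits
are one third and three times the modes; all five candidate intervals have
zero male reads, as expected for truly W-specific sequence, and each of
the five planted segments overlaps a candidate:

```r
head(res$report$intervals[, c("scaffold", "start", "end", "score", "zero_male")], 3)
#>        scaffold  start    end    score zero_male
#> 390 scaffold_02 139052 140198 7.989869      TRUE
#> 575 scaffold_03  77086  78247 8.009491      TRUE
#> 928 scaffold_04 183006 184172 8.014215      TRUE
```

A score near 8 is what the zero-male substitution yields here:
`log2(11.7 / (0.846 * (125/2)/1150)) ≈ 8`, i.e. female depth at half the
diploid mode against half a male read spread over the interval.

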