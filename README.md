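# mirpath

Integrative miRNA–mRNA expression analysis for time-course profiling
studies, with permutation/hypergeometric pathway enrichment combined by
Stouffer's method.

## The problem

In an allergen-challenge mouse model of asthma, lung tissue is profiled
at short- (ST), intermediate- (IT) and long-term (LT) exposure on two
platforms: a two-channel miRNA array (treated vs control RNA pools, in
duplicate) and an mRNA expression array (probe-level log2 ratios of two
treated pools against control). Because miRNAs repress their target
mRNAs, candidate regulatory interactions are found by **inverse
correlation**: a modulated miRNA paired with a predicted target mRNA
changing in the opposite direction. `mirpath` implements that analysis
chain as a tested, reusable package for anyone who needs to reproduce or
adapt it: bioinformaticians working with legacy two-color miRNA arrays
and symbol-keyed target-prediction exports.

## The statistics at its core

For each time point:

- **Fold-induction calling.** Probe signals are background-corrected
  (`max(raw − background, 1)`), log2-transformed, normalized by cyclic
  loess across channel/replicate columns, and summarized per miRNA as
  FI = 2^(mean log2 ratio) with a two-sided one-sample t-test. A miRNA
  is modulated when FI ≥ 1.5 (or ≤ 1/1.5) and p < 0.01. Genes are
  modulated under a ±0.6 log2-ratio rule (= 1.52-fold; feeds pairing) or
  a 1.5-fold-in-both-pools rule (feeds pathway analysis), with a
  multi-probe consistency requirement.
- **Inverse pairing.** (miRNA, gene) pairs with opposing directions and
  prediction p < 0.05.
- **Pathway enrichment.** For pathway *P* and modulated miRNA set *M*,
  the statistic is the number of pairs (m ∈ M, g ∈ P) present in the
  prediction table. Its p-value is the proportion of 1000 random
  redraws of *M* from the chip universe (566 miRNAs at full scale) whose
  count is ≥ the observed one. The mRNA p-value is the upper-tail
  hypergeometric probability of the pathway's overlap with the modulated
  gene set against the 20461-gene chip universe. The two are combined as

  z_i = Φ⁻¹(1 − p_i),  p_combined = 1 − Φ((z₁ + z₂)/√2)

  and pathways with p_combined < 0.05 are selected.
- **Bench assays.** 2^−ΔΔCt qPCR quantification, microarray/qPCR
  direction concordance, and protein-normalized luciferase knockdown
  ratios.

A seeded synthetic-data generator (`simulate_study()`) produces all
inputs with planted effects, and transcriptions of the reference
study's printed summary tables are installed as fixtures.

## Worked example

The `analysis/` directory holds the staged workflow
(`01_simulate_study.R` … `06_bench_assays.R`); each stage writes its
tables under `results/`. Running the differential stage on the packaged
reference fixture:

```r
library(mirpath)
meas <- fixture_mirna_measurements()
sets <- lapply(TIMEPOINTS, function(tp)
  call_modulated_mirnas(meas[meas$timepoint == tp, ]))
sapply(sets, function(s) nrow(s$members))
#> 20 26 69
recurrent_mirnas(sets, k = 3)$mirna_id
#> [1] "mmu-miR-146b"
nrow(recurrent_mirnas(sets, k = 2))
#> [1] 13
```

20, 26 and 69 miRNAs pass the ≥1.5-fold rule at ST, IT and LT; exactly
one (mmu-miR-146b) is modulated at all three time points and 13 at two
or more. On the simulated study (`Rscript analysis/01_simulate_study.R`
through `05_pathway_enrichment.R`) the planted enriched pathway is
selected at every time point under both prediction databases:

```
microcosm: selected 3/2/2 pathways (ST/IT/LT); 4 at one time point, 0 at two, 1 at all three
  selected at every time point: WPSIM0001
planted pathway was WPSIM0001
```

and the bench stage reports

```
platform concordance on 42 fold-change pairs: 95%
discordant: mmu-miR-29c LT; mmu-miR-29c ST
```

i.e. 40 of 42 microarray/qPCR fold-change pairs agree in direction.

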