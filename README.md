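# commvade

Whole-community invasion analysis for methanogenic (anaerobic-digestion)
microbiomes.

When one microbial community is introduced into another — here a
high-methane-producing community (**HP**) invading replicate fermenters of
a low producer (**LP**) at volume fractions of 10, 1, 0.1 and 0.01 % —
three questions arise: did the invader establish, did community
composition shift, and did function (biogas production) change, carried
by which taxa? `commvade` implements the full analysis:

* **ASV origin attribution.** An amplicon sequence variant (ASV) present
  in the endpoint of exactly one pure community is attributable to it;
  ASVs in both or neither are excluded. Per invaded sample the invasion
  statistics are

  *invader read fraction* = Σ reads over invader-only ASVs ÷ Σ reads over
  known-origin ASVs (and likewise for ASV counts), with worst-case bounds
  that assign every unattributed read to the resident.

* **Diversity.** Richness, Pielou evenness (H′/ln S), and first-principles
  weighted and unweighted **UniFrac** over a rooted tree, with one-way
  **PERMANOVA** (pseudo-F on a distance partition, whole-label
  permutation, add-one p) and Bonferroni-adjusted pairwise contrasts.

* **Tipping-point screen.** ASVs present in the high-dose treatments but
  absent from every low-dose replicate, refined to those detected in
  >50 % of each high-dose treatment's replicates.

* **Gas analysis.** Dose trend of cumulative biogas on log10(dose) and
  many-to-one (**Dunnett**) comparisons of each dose against a pure
  community, with family-wise error from seeded Monte-Carlo integration
  of the max-|t| multivariate-t null.

* **A ground-truth synthetic study generator.** Serial-transfer
  Wright-Fisher dynamics with volumetric invasion, multinomial
  bottlenecks, niche-limited invader growth, priority-effect
  (positive-frequency-dependence) establishment thresholds, read
  sampling at 350–500k reads, and a key-taxon-gated biogas model —
  so attribution accuracy, screen recall and the statistics are all
  testable against known truth.

The methods vignette (`vignettes/community-invasion.Rmd`) derives every
model and default.

## Worked example

```r
library(commvade)

study <- simulate_study(sim_config(seed = 11))
study
#> Synthetic invasion study
#> ASV count table: 29 samples x 280 ASVs, 12,528,874 total reads
#> samples: LP_1, LP_2, LP_3, LP_4, LP_5, HP_1 ...
#>   truth: 60 LP-only, 60 HP-only, 160 shared ASVs; 4 key taxa

origins <- attribute_origin(study$table, study$metadata)
score_against_truth(origins, study$truth)
#> Attribution vs. ground truth
#>                true
#> assigned        LP_only HP_only shared
#>   RESIDENT_ONLY      60       0      0
#>   INVADER_ONLY        0      59      0
#>   SHARED              0       0    160
#>   NEITHER             0       1      0
#> label inversions: 0; detection-induced misattributions: 0

invaded <- study$metadata$sample_id[!study$metadata$treatment %in% c("LP", "HP")]
metrics <- invasion_metrics(study$table, origins, samples = invaded)
dose_effect_test(metrics, study$metadata, "read_fraction")
#> Dose effect on invader read_fraction: F(3,16) = 3.043, p = 0.05926

d <- unifrac_matrix(study$table, study$tree, "weighted")
grp <- study$metadata$treatment[match(rownames(study$table),
                                      study$metadata$sample_id)]
permanova(d, grp, n_permutations = 999, seed = 1)
#> PERMANOVA: pseudo-F(5,23) = 116.286, R2 = 0.962, p = 0.001 (999 permutations)

gs <- summarize_gas(study$gas, study$metadata)
many_to_one(gs, "HP", seed = 1)
#> Many-to-one comparisons vs HP (alpha = 0.05):
#>   D10    diff      -3.4  t =   -0.26  p_adj = 0.9964  not distinct
#>   D1     diff      -7.1  t =   -0.54  p_adj = 0.9451  not distinct
#>   D0.1   diff    -484.6  t =  -37.00  p_adj = 1e-05  distinct
#>   D0.01  diff    -476.6  t =  -36.39  p_adj = 1e-05  distinct
```

Read together: the invader's read share does not vary with dose
(p = 0.059) even though its established richness does; composition
separates strongly by treatment; and gas production of the 10 % and 1 %
invasions is indistinguishable from the pure high producer while the two
lowest doses fall far short — the stepped functional response.

`run_study(sim_config(seed = 11), out_dir = "out")` executes every stage
in order (simulate → validate → attribute → diversity → screen → gas) and
writes all tables, a JSON report and a checksummed manifest.
A thin command-line wrapper ships in `inst/cli/commvade`
(`commvade simulate|run-all --config sim.yaml --out DIR`, with a
`--real-data` mode that consumes user-supplied TSV/Newick/CSV files).

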