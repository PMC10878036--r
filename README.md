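# lakevirome

Downstream inference for a year-long, two-depth freshwater lake time series
of prokaryotic (16S ASV) and viral-contig (virome) feature tables. The
package is aimed at microbial ecologists who already have feature tables,
per-contig coverage fractions and host-prediction evidence from an upstream
sequencing workflow, and who want the community-level inference chain:

* **Seasons** — classify each month as de-stratified or
  beginning/middle/end of the stratified period from the two-layer
  temperature profile (de-stratified when |T_surface − T_deep| < 1 °C).
* **Abundance** — relative abundances for ASVs; TPM for viral contigs with a
  coverage gate (TPM set to 0 where mapped reads cover < 80 % of the contig
  length); seeded rarefaction.
* **Community** — Shannon diversity, Bray–Curtis dissimilarity, the monthly
  surface-vs-deep dissimilarity series and the time-lag turnover curve with
  assumption-driven group tests (Student / Welch / Mann–Whitney, gated by
  Kolmogorov–Smirnov normality and an F-test).
* **Habitat preference** — per contig and season,
  `P = sum TPM(surface) / (sum TPM(surface) + sum TPM(deep))`,
  0 = deep-only, 1 = surface-only, undefined when absent from both.
* **Dominance patterns** — existence vs dominance month counts
  (ASVs: relative abundance > 1 %; contigs: TPM rank within 100), classified
  short (< 10 % of the study period, ≥ 1 month), persistent (> 75 %) or
  intermediate.
* **Host assignment** — validate per-contig evidence against the thresholds
  of six methods (genome similarity S_G > 0.15; marker genes; CRISPR spacers
  at 100 % identity; tRNA and direct genome matches at > 97 % identity,
  ≥ 30 bp, e-value < 1e-5; > 80 % single-taxon gene content) and resolve one
  host by the fixed priority i > ii > iii > iv > v > vi.
* **Infection pairs** — for dominant summer ASVs and host-assigned contigs,
  Pearson correlation on aligned monthly series with Benjamini–Hochberg
  correction across the whole family (keep r > 0, p < 0.05, q < 0.05), plus
  a one-sided Mann–Whitney check that each virus rises in its host's
  dominant months.
* **Synthetic lake** — a seeded generator (`simulate_lake()`) producing all
  of the above inputs with planted ground truth (summer bloomers, phages
  tracking their hosts, decoy evidence, temperature-driven production), and
  a `null_lake()` twin without coupling for type-I checks.

## Worked example

```r
library(lakevirome)
sim <- simulate_lake(sim_config(seed = 11))  # synthetic lake + ground truth
pl  <- run_lake_pipeline_sim(sim)            # full inference chain
pl
#> lake pipeline result
#>   months: 16 (2 de-stratified)
#>   features: 300 ASVs, 1500 viral contigs
#>   host-assigned contigs: 321
#>   dominant ASVs: 18; retained infection pairs: 32
summary(pl)
#> surface-vs-deep Bray-Curtis (ASVs):
#>   min 0.053 (month 5), max 0.706 (month 10)
#>   surface lag-6 mean BC 0.461 (n=10)
#>   surface lag-12 mean BC 0.222 (n=4)
#> pairs: 15 ASVs x 27 contigs
#>  month_index paired_asv_relab paired_lbv_tpm_fraction
#>           10        0.4940097               0.4244445
#>           11        0.4272664               0.3053167
#>           12        0.3003495               0.2210022
```

Reading: the two de-stratified months are February–March, where the layer
communities are most similar (Bray–Curtis 0.053); divergence peaks in July
(month 10). Communities sampled 12 months apart are more alike (0.222) than
those 6 months apart (0.461) — annual periodicity. Eighteen ASVs peak above
1 % in the July–September window; 32 (ASV, contig) pairs survive the
correlation + FDR screen, and the paired features carry 30–49 % of the
summer community. Against the generator's ground truth (26 planted pairs)
this run recovers 100 % of the planted links at 0.81 precision.

Real data enter through the readers: `read_metadata()`,
`read_feature_table()`, `read_lengths()`, `read_coverage()`,
`read_evidence()`, `read_taxonomy()`, then `run_lake_pipeline()`.

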