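# metamark

Comparative meta-gene profiling of histone-mark ChIP-seq signal between
two conditions.

## The problem

Overexpression of the H3K36 methyltransferase MMSET (NSD2/WHSC1) in
t(4;14)+ multiple myeloma does not simply add more H3K36me2 where it
already is — it redistributes the mark. In MMSET-low cells H3K36me2
forms focal peaks just upstream of the TSS of expressed genes and stays
low in intergenic space; in MMSET-high cells the mark is globally
elevated (~8-fold in total), dispersed and boundary-less, so that gene
bodies can *lose* relative enrichment while intergenic regions gain it.
Comparing such conditions is statistically awkward: ChIP-seq measures
fractional enrichment, and when most of the genome changes, the
unchanged-majority assumption behind global count normalization fails.

`metamark` implements the analysis toolchain for this situation, for
anyone comparing the genomic distribution of a broad chromatin mark
between two conditions from aligned read positions:

* **Read processing** — duplicate removal (one read per position and
  strand), fragment-length estimation from the strand cross-correlation
  (the lag `d` maximizing the Pearson correlation between the Watson
  5'-frequency vector `f+(x)` and the Crick vector `f−(x+d)` estimates
  `L − 1`), read shifting by `⌊L/2⌋` or extension to full fragments.
* **Density tracks** — per-base centered-count or coverage tracks,
  normalized by the average read frequency per base pair of the
  effective genome size (`N / G_eff`, with `G_eff = 2.7×10⁹` bp for
  human), so the expectation of the read count at any position is 1 and
  a value `v` reads directly as `v`-fold the genome average.
* **Meta-gene and intergenic profiles** — each gene body divided evenly
  into 50 bins (aligning all genes at TSS and TES) plus 50 upstream and
  50 downstream flank bins of 200 bp; upstream intergenic gaps of at
  least 30 kb, trimmed by 10 kb at each end, divided into 100 bins.
* **Expression stratification** — probes filtered on ≥ 4 positive
  values per condition; genes with both condition means < 3 (log scale)
  called `not_expressed`; the rest classified `up` / `down` /
  `no_change` by a two-sample t-test at p < 0.002. Per-class
  condition-ratio curves `(ΣA + pc) / (ΣB + pc)` per bin then show
  where on the meta-gene the conditions diverge — a readout robust to
  the choice of a global normalization factor.
* **Peak-set comparison** — promoter (TSS ± 2 kb) gene assignment, Venn
  counts between conditions, 1:1 matching of shared peaks and Welch
  t-tests on their heights and lengths.
* **Normalization diagnostics** — window-level log2 ratios between
  conditions and Sarle's bimodality coefficient
  `b = (g₁² + 1) / (g₂ + 3(n−1)²/((n−2)(n−3)))` (normal ≈ 1/3;
  > 0.555 flags bimodality, i.e. a mark for which no single
  normalization factor is meaningful).
* **Synthetic data** — generators for genomes, annotations, reads
  (focal and diffuse regimes with known ground truth), replicated
  expression matrices with planted classes, and peak sets with a
  controlled promoter-overlap structure, so every stage is testable
  without external data.

## Worked example

Simulate a two-condition experiment (condition A diffuse/MMSET-high,
condition B focal/MMSET-low) and run the pipeline:

```r
library(metamark)

cfg <- sim_config(seed = 20)           # 60 genes, 2.8 Mb, 2e5 fragments
sim <- simulate_experiment(cfg)
pcfg <- pipeline_config(g_eff = "genome", fragment_length = 150)
res <- run_pipeline(pcfg, sim$reads_a, sim$reads_b, sim$expression,
                    sim$annotation, output_dir = "demo_out")

res$classes
#> <gene_class_table> 60 genes (p < 0.002): up=9, down=6, no_change=36, not_expressed=9
res$diagnostics$report
#> <bimodality_report> b = 0.9165 (threshold 0.555, n = 280): bimodal
res$ratio_curves
#> <class_ratio_profiles> classes: no_change, up, not_expressed, down
#>   no_change      bins 150, ratio range [0.147, 1.640]
#>   up             bins 150, ratio range [0.146, 2.016]
#>   not_expressed  bins 150, ratio range [1.097, 1.798]
#>   down           bins 150, ratio range [0.143, 2.005]
```

The classifier recovers the planted class structure; the diffuse-vs-focal
contrast produces a bimodal window log-ratio distribution (the regime in
which a global normalization factor would mislead); and the ratio curves
dip below 1 around the TSS — the focal condition's TSS peaks are absent
from the diffuse condition — while intergenic-driven bins sit above 1.

Fragment-length estimation on site-structured reads recovers the truth
exactly:

```r
est <- estimate_fragment_length(
  deduplicate(simulate_binding_site_reads(genome(c(chr1 = 1e6)),
                                          1e4, 150, seed = 20)))
est
#> <fragment_length_estimate> length = 150 bp (peak lag 149, search range 50-500)
```

Peak-set comparison with a planted (10, 8, 5) promoter Venn structure
and taller/broader shared peaks in condition A:

```r
pk <- generate_peaks(cfg, sim$annotation, c(10, 8, 5))
venn_counts(assign_promoter_genes(pk$a, sim$annotation),
            assign_promoter_genes(pk$b, sim$annotation))
#> <venn_counts> A-only: 10  common: 8  B-only: 5
compare_peak_dimensions(match_shared_peaks(pk$a, pk$b))
#> <peak_dimension_stats> 8 shared peaks
#>   height  A=19.51 B=9.75  Welch t=11.031, p=4.98e-07
#>   length  A=1480.00 B=986.50  Welch t=7.644, p=5.39e-06
```

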