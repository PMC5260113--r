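# sirtron

Detection and analysis of small interfering RNA (siRNA) clusters in plant
genomes, for researchers studying stress-responsive small-RNA regulation
(e.g. drought time courses) from aligned small-RNA sequencing data.

Plant genomes produce 18–30 nt siRNAs, dominated by 21 and 24 nt classes,
that concentrate in dense genomic clusters — often inside introns
("sirtrons") — and can regulate the genes that host them. `sirtron`
implements the full analysis as composable, data-frame-first R functions:

1. **Preprocessing** — remove reads matching non-coding RNAs (miRNA, rRNA,
   tRNA, snoRNA; exact sequence match, reverse-complement aware), keep
   18–30 nt alignments with 0 mismatches and ≤ 5 mapping sites, and
   normalise counts to reads per million (RPM), with fractional 1/n
   weighting of multi-mapping alignments.
2. **Cluster detection** — one-dimensional DBSCAN over read start
   coordinates: a read is a core point when at least *minpts* reads
   (default 10) lie within *epsilon* (default 100 bp); clusters are
   connected components of core points plus reachable border reads.
   *epsilon* can be chosen from the data via the *k*-dist curve: for each
   read the distance to its *k*-th nearest neighbour (default *k* = 30),
   sorted descending; the curve's valley — the point of maximum
   perpendicular distance to the endpoint chord — is taken as *epsilon*.
   Overlapping clusters are merged across samples into disjoint hulls.
3. **Gene association and correlation** — a cluster targets the gene whose
   body contains it (≥ 50% of its length for boundary-straddling hulls);
   clusters per gene are summed into unique gene–cluster pairs, and log2
   fold changes between consecutive time points, `log2((b+1)/(a+1))`, are
   compared between gene FPKM and cluster RPM with Pearson correlation and
   sign-quadrant counts.
4. **Feature enrichment** — clusters are classed by the host feature
   (5'UTR / CDS / intron / 3'UTR) with maximal overlap, and a
   length-normalised enrichment odds ratio is computed per feature class
   `OR_f = (n_f / L_f) / ((N − n_f) / (L − L_f))`, i.e. cluster density in
   the class relative to density elsewhere; cluster positions are also
   profiled along chromosome arms (centromere → telomere).
5. **Conservation** — UTR and intron regions are tiled with 25-nt bins
   (CDS excluded: coding conservation is uniformly high), each bin is given
   the mean per-base conservation score from a supplied track and labelled
   by cluster overlap, and cluster vs non-cluster bins are compared per
   feature with Welch's t-test repeated over 1000 size-matched random
   selections of non-cluster bins; the fraction of resamples with p ≤ 0.05
   gives the verdict.

A first-class synthetic-data module (`sim_config()`, `simulate_dataset()`)
generates ground-truthed inputs — annotation, nine read libraries (three
plants × 0/1/6 hours after treatment), anti-correlated gene expression, and
a conservation track elevated inside planted intronic clusters — so every
stage is testable without downloads.

## Worked example

```r
library(sirtron)
library(dplyr)

res <- run_all(list(seed = 1, output_dir = tempfile(),
                    simulate = list(seed = 1)))

res$merged_all
#> <merged_clusters> 20 merged clusters
#> # A tibble: 5 × 6
#>   cluster_id   chrom  start    end n_samples n_reads
#>   <chr>        <chr>  <int>  <int>     <int>   <dbl>
#> 1 cluster00001 chr1    6906   7297         9     905
#> 2 cluster00002 chr1   33305  33668         9    4462
#> ...

glance(res$correlation)
#> # A tibble: 1 × 4
#>   estimate  p_value n_pairs anticorrelated_fraction
#>      <dbl>    <dbl>   <int>                   <dbl>
#> 1   -0.831 6.92e-32     120                   0.783

tidy(res$conservation_test)
#> # A tibble: 3 × 8
#>   feature         n_cluster_bins n_noncluster_bins median_p fraction_significant ...
#> 1 five_prime_utr              32               381 6.52e- 1                0.006
#> 2 three_prime_utr             39               395 4.97e- 1                0.02
#> 3 intron                     270              7119 6.01e-68                1
```

The pipeline recovered all 20 planted clusters as merged intervals with
per-sample expression; gene and cluster fold changes are anti-correlated
(pooled Pearson r = −0.83, close to the generator's −0.8, with 78% of pairs
in the anti-correlation quadrants); and the conservation test calls only
introns significant — exactly where the generator placed the score uplift —
while both UTR classes stay at the null level.

Each stage is also usable on its own (`preprocess_reads()`,
`kdist_profile()` + `select_epsilon()`, `detect_clusters()`,
`merge_clusters()`, `assign_targets()`, `gene_cluster_pairs()`,
`feature_odds_ratio()`, `conservation_test()`, ...), reading standard
formats: GFF3 annotation, BED6+3 alignments, bedGraph conservation tracks,
wide FPKM TSVs, and FASTA. `plot_*()` helpers and `autoplot()` methods
produce the standard figures (k-dist curve, length histograms, fold-change
scatter, enrichment bars, arm-position histogram, cumulative conservation).

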