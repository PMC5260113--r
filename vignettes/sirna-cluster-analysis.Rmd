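---
title: "Detecting and characterising siRNA clusters: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising siRNA clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirtron)
```

This vignette explains the science behind `sirtron`: the models and
procedures each stage implements, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the places where the design was genuinely open and the
package had to choose.

## The analysis in one paragraph

Plant small-RNA libraries, after removal of miRNA/rRNA/tRNA/snoRNA reads
and restriction to 18–30 nt perfect alignments with at most five mapping
sites, concentrate into genomic clusters detectable as 1-D density peaks of
read start coordinates. Clusters are found per sample by DBSCAN
(epsilon = 100 bp, minpts = 10), merged across samples into disjoint
hulls, and associated with the genes that contain them. Summed cluster
expression (RPM) is then compared with host-gene expression (FPKM) through
log2 fold changes between consecutive time points; cluster positions are
profiled across gene features (with length-normalised enrichment odds
ratios) and chromosome arms; and evolutionary conservation of cluster
regions is tested per feature class by tiling UTRs and introns with 25-nt
bins and repeatedly comparing cluster-overlapping bins against size-matched
random selections of non-cluster bins with Welch's t-test.

## Coordinates and containers

All intervals are 0-based half-open tibbles (`chrom`, `start`, `end`);
GFF3 (1-based inclusive) and BED (0-based half-open) are converted at the
file boundary so no internal arithmetic ever reasons about inclusivity.
Interval overlap queries are delegated to `IRanges`/`GenomicRanges`.
When a gene has several mRNAs, the representative transcript is the one
with the longest genomic span, ties broken by the lexicographically
smallest transcript id — annotation formats do not say which isoform
defines introns, and a fixed deterministic rule matters more than which
rule. Introns are the gaps between the representative's consecutive exons;
UTRs are derived from the CDS extent in transcript orientation when CDS
records exist, otherwise the gene simply contributes no UTR intervals.

## Preprocessing

* **ncRNA filtering** operates on read sequences, not coordinates: a read
  is removed iff its sequence is an exact substring of a filter-set entry
  on either strand. "Perfect match" is taken literally — one mismatch
  retains the read. Removal is by read id, so all alignments of a matched
  read drop together.
* **Alignment filters** keep reads with length in [18, 30] nt (inclusive
  boundaries), `mismatches <= 0` and `n_sites <= 5` by default.
* **Normalisation** is reads per million: `count * 1e6 / total_processed`.
  Whether the denominator counts reads before or after filtering is
  genuinely ambiguous in practice; `preprocess_reads()` defaults to the
  post-filter count (`denominator = "post_filter"`), which makes per-sample
  siRNA abundances comparable, and offers `"pre_filter"`.
* **Multi-mapping weight**: every alignment of a read with *n* mapping
  sites contributes 1/*n* to any count (`weight_mode = "fractional"`), so
  a read never counts more than once genome-wide; `"full"` counting is
  available. Density clustering itself uses unweighted alignment positions
  — weights affect quantification, not detection.

## Cluster detection

`dbscan_1d()` is a from-scratch 1-D DBSCAN over read start coordinates
(the leftmost aligned base; read length only enters the reported hull).
A point is core iff at least `minpts` points, itself included, lie within
`epsilon`; clusters are the connected components of core points under
epsilon-reachability; non-core points within epsilon of a core point are
border points, attached deterministically to the cluster of the leftmost
core point that reaches them (left-to-right scan order). The
implementation works on the sorted coordinate vector with two-sided binary
search (O(n log n)) and is tested for exact agreement with a textbook
breadth-first DBSCAN on hundreds of random instances.

The neighbourhood radius can be chosen from the data: `kdist()` computes,
for each read, the distance to its *k*-th nearest neighbouring read
(sorted two-sided merge, O(nk)); the values sorted in descending order form
the *k*-dist curve, and `select_epsilon()` returns the curve's valley —
the point of maximum perpendicular distance to the chord joining the
curve's endpoints, ties to the smallest index. A constant curve has no
valley and raises an error; a knee at an endpoint-adjacent index is
flagged low-confidence. *k* = 30 with an independent `minpts = 10` are the
defaults; passing `minpts = k` reproduces the "minpts follows k"
convention some density-clustering tools use.

**Known limitation.** The knee heuristic finds the single most-curved
point. When a large majority of reads are diffuse background, the curve
has two scales — a background elbow at thousands of bp and the
cluster-scale valley below it — and the global knee lands on the
background elbow. The heuristic is therefore only meaningful in the regime
it was described for: libraries whose reads predominantly sit in dense
clusters over sparse noise. The fixed default epsilon = 100 bp does not
suffer from this and is what the pipeline uses unless `cluster$auto` is
set.

**Merging and quantification.** Per-sample clusters are merged by
transitive ≥ 1 bp overlap into disjoint hulls (`merge_clusters()`, checked
against a sweep-line oracle), with member counts and RPM summed. On top of
this the pipeline re-quantifies every merged interval in every library
(`quantify_clusters()`): a cluster that was detected at 0 h but fell below
the density threshold at 6 h would otherwise be assigned zero expression
at 6 h and produce an artefactual log2 fold change of many units; counting
the reads actually present in the region gives the cluster its true
sub-threshold expression. `run_all()` merges per plant for the cluster
catalogues and gene pairing (each plant is an independent biological
system), and builds one additional global merge used for feature
enrichment, chromosomal positioning and conservation labelling, where
cluster *regions* rather than per-plant catalogues are the object of
interest. Whether detection should pool samples first is ambiguous;
per-sample detection plus merging is the closer reading of a per-plant
time-course design and is what the package does.

## Gene association and expression correlation

Genes with FPKM never strictly exceeding 1 at any time point (per plant)
are removed. A merged cluster targets a gene when it lies inside the gene
body; because merging can push hulls past gene edges, containment is
relaxed to ≥ 50% of the cluster's length (`strict_containment = TRUE`
restores full containment), and a cluster straddling two genes goes to the
gene holding the larger share. Clusters targeting a common gene are summed
into one gene–cluster pair. Fold changes use a pseudocount of 1 shared by
numerator and denominator — `log2((b+1)/(a+1))` — which guards zero
expression and keeps the function antisymmetric; no convention for zeros
is universal, and the pseudocount choice only matters for expression
values near or below 1. The correlation report gives Pearson estimates
(t-distribution p-values) per plant × interval and pooled, plus
sign-quadrant counts; `gene_down_cluster_up` and `gene_up_cluster_down`
are the anti-correlation quadrants.

## Feature enrichment and chromosomal positioning

Each genic cluster is labelled with the feature class holding the maximal
bp overlap, ties broken intron > CDS > 5'UTR > 3'UTR (introns and CDS are
the biologically loaded classes; the fixed order only affects exact
50/50 splits). UTRs are far shorter than introns, so raw counts mislead;
the enrichment odds ratio normalises by total feature length:
`OR_f = (n_f / L_f) / ((N − n_f) / (L − L_f))` — the density of clusters
in class *f* relative to the density in all other classes, 1 under uniform
placement (verified by a placement-null simulation), and invariant to
rescaling all lengths. A literal 2×2 counts odds ratio is available via
`or_mode = "counts"`. For chromosomal positioning each cluster midpoint is
mapped to a relative arm position (0 = centromere edge, 1 = chromosome
end; midpoints inside the centromere get 0 and a flag) — at chromosome
scale cluster spans are negligible, so the midpoint suffices.

## Conservation testing

Only 5'UTR, 3'UTR and intron regions are tested; CDS bins are refused
outright because coding conservation is uniformly high and would swamp any
cluster effect. Each feature interval is tiled left-to-right with 25-nt
bins anchored at its left edge (a genome-global grid would split feature
boundaries arbitrarily); remainders under 25 bp are dropped, so the tiling
deficit is bounded by 24 bp per interval. A bin's score is the mean of
track-covered bases; bins with under 50% coverage are flagged and excluded
from testing. A bin is a cluster bin iff it overlaps any merged cluster by
≥ 1 bp. Because cluster bins are far fewer than non-cluster bins, the
two-sided t-test is repeated over 1000 random size-matched selections of
non-cluster bins (without replacement, seeded); Welch's unequal-variance
form is the default since nothing guarantees equal spread, with the pooled
Student form behind `equal_var = TRUE`. The 1000 p-values are summarised
as their median and the fraction ≤ alpha (0.05); a feature is called
significant when that fraction reaches 0.95. How 1000 resampled p-values
should be aggregated is not standardised; the fraction-significant rule is
transparent and calibrated (≈ alpha under the null, checked by
simulation), and all p-values are returned for any other summary.
Degenerate resamples (zero variance in both groups) are counted
non-significant and flagged. The conservation track is consumed as a
per-base reference-coordinate bedGraph; projecting scores from multiple
alignments of orthologs is upstream of this package.

Candidate selection for downstream motif analysis keeps gene–cluster pairs
with opposite-sign fold changes in at least one interval and orthologs in
at least four species including the reference; `export_cluster_fasta()`
writes plus-strand cluster sequences for external motif tools.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_dataset()` is fully
deterministic given the seed (byte-identical files). Defaults: a 2-Mbp
genome (2 chromosomes), 50 non-overlapping genes with 3–5 exons, CDS and
both UTRs; 20 planted clusters (60% intronic, 20% per UTR class) with
spans ≥ 100 bp and ≥ 10 reads per sample — the stated detectability
precondition — and baseline 50–200 reads at 0 h; read lengths drawn from
a 21/24-nt bimodal distribution on 18–30 nt; background alignments Poisson
at 5 reads/kbp per library, uniform genome-wide; per-interval cluster
log2 fold changes N(0, 1.5²); host-gene fold changes drawn conditionally
on the realised cluster fold changes at correlation rho = −0.8; expressed
FPKM baselines lognormal around 100 (clamped ≥ 30, so the analysis
pseudocount is negligible), with two decoy genes pinned at 0.5 FPKM to
exercise the floor filter; conservation scores = feature-specific
baselines (CDS 0.8, 5'UTR 0.45, 3'UTR 0.4, intron 0.25) plus N(0, 0.1²)
noise, +0.3 inside planted *intronic* clusters, clipped to [0, 1].
Reads are emitted as already-aligned single-site, zero-mismatch records
(the pipeline starts after mapping); a configurable contaminant subset
carries sequences copied verbatim from a generated filter FASTA so ncRNA
filtering is exercised end to end.

What the generator does **not** emulate: sequencing error and adapter
artefacts, multi-mapping ambiguity (all reads have one site), strand-
specific phasing registers, realistic chromatin-driven background
structure, isoform diversity, and genuine alignment-projected conservation
tracks. Passing tests therefore demonstrate correctness of the algorithms
and calibration of the statistics under this model — not robustness to
every artefact of real libraries.

## Verification strategy and problem sizes

Every algorithmic core is tested against an independent oracle: k-dist
against all-pairs enumeration, DBSCAN against a breadth-first reference,
merging against a sweep line, knee selection against exhaustive chord
search, bin scoring against direct per-base averaging. End-to-end checks
run at the default conditions: planted-cluster recovery (F1 = 1 at
defaults), anticorrelation recovery with 500 planted gene–cluster pairs
(estimate within 0.1 of −0.8), type-I calibration of the resampled test
over 50 outer seeds × 200 resamples with ~120 cluster bins each (the mean
fraction-significant estimate is dominated by between-seed variance, so
200 resamples per seed suffice), power at the default uplift with 270
cluster bins (fraction ≥ 0.99 at 1000 resamples), and an
enrichment-placement null with 1000 clusters over an annotation with
balanced feature lengths. That last construction also carries a geometric
caveat worth recording: "half of all clusters are intronic" only implies
intron enrichment when introns hold less than half the annotated feature
length, since the odds ratio compares densities; the enrichment checks use
shorter introns (~40% length share) so the premise is coherent.

## Reproducibility

All randomness flows from explicit integer seeds (`sim_config(seed = )`,
`resampled_ttest(seed = )`, the pipeline's `seed`); `run_all()` writes a
manifest with a config hash, the seeds, package version, per-stage record
counts and the complete output list, contains no timestamps, and rerunning
an identical config reproduces every output byte for byte.
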