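# dietshift

Comparative-genomics tooling for a recurring question in insect evolution:
when a lineage shifts diet — here, a predaceous true bug against
plant-feeding relatives — is that shift underwritten by expansion of
diet-related gene families, and are those genes further diversified at the
transcriptome level (expression, isoforms, A-to-I RNA editing)?

`dietshift` is an R package for researchers running this analysis on
ortholog tables, genome annotations and RNA-seq pileups.  It implements the
full inference chain as tidyverse-style functions (tibbles in, tibbles
out), plus a planted-truth simulator that generates every input with known
ground truth so each stage can be validated end to end.

## What it computes

* **Ortho-group classification.** Each ortho-group (OG) carries per-species
  gene counts $(n_{\text{foc}}, n_{r_1}, n_{r_2})$ and is assigned, with
  strict inequalities in fixed precedence, to *focal_unique*
  ($n_{\text{foc}} > j$, relatives 0), *focal_more*
  ($n_{\text{foc}} > k\max(n_{r_1}, n_{r_2})$, at least one relative gene),
  *gradient* ($n_{\text{foc}} > g\,n_{r_1} > g^2 n_{r_2}$) or *other*;
  unique + more form class1 (focal-specific).  A cutoff sweep over $j, k$
  checks robustness, and an intra- vs inter-OG protein-identity contrast
  (global alignment, BLOSUM62) checks that OGs are coherent families.
* **Diet flagging and enrichment.** A built-in Pfam catalog (19
  detoxification / chemosensory / digestion families, 27 accessions —
  cytochrome P450, GSTs, odorant receptors, serine proteases, lipases, ...)
  flags diet genes; OGs are diet-related iff any member gene is.
  Enrichment per category uses Fisher's exact test; quantitative contrasts
  (RPKM, exon counts) use Wilcoxon rank-sum with exact small-sample
  enumeration.
* **Expression.** RPKM from exonic reads over the exon-union gene length,
  and the Spearman correlation of isoform count with exon count.
* **A-to-I editome.** RNA-DNA difference calling from pileups, genomic-SNP
  exclusion, removal of bidirectionally transcribed regions, strand
  resolution (gene strand for genic sites, cluster majority for intergenic
  hyper-editing), category annotation with codon-level recoding
  consequences, per-category repeat enrichment, diet-gene editing
  enrichment, upstream-editing enrichment, and a read-backed linkage
  disequilibrium contrast ($r^2$ of SNP pairs vs editing pairs).
* **Cross-species directional expansion.** Per-OG Welch $t$-test on
  $\log_2(n+1)$ gene counts between predaceous and phytophagous species
  panels, and a one-sided Fisher's exact test on the directional summary.

## Worked example

Everything below runs on simulated data with planted truth, so the numbers
are fully reproducible:

```r
library(dietshift)

sim <- simulate_dataset(sim_config(seed = 42))

classified <- og_classify(sim$og_counts, focal = "focal",
                          rel1 = "rel1", rel2 = "rel2")
flags <- flag_diet_ogs(sim$og_membership, flag_diet_genes(sim$domains))
diet_enrichment(classified, flags)
#> # A tibble: 5 × 5
#>   comparison           fraction_in fraction_out odds_ratio p_value
#> 1 focal_unique_vs_rest      0.125        0.0423      3.23   0.149
#> 2 focal_more_vs_rest        0.125        0.0423      3.23   0.149
#> 3 gradient_vs_rest          0            0.0431      0      1
#> 4 other_vs_rest             0.0418       0.108       0.360  0.0715
#> 5 class1_vs_class2          0.125        0.0417      3.29   0.0457
```

Class1 (focal-specific) OGs carry diet domains three times as often as
shared OGs — the planted enrichment.  The editome pipeline logs every
filter:

```r
sites <- call_editome(sim$pileup, sim$gene_models, sim$genome, sim$snps)
stage_log(sites)
#>   stage               n_in n_out n_removed
#> 1 call_rdd            4060  1882      2178
#> 2 exclude_snps        1882  1832        50
#> 3 mask_bidirectional  1832  1800        32
#> 4 resolve_strand      1800  1800         0
#> 5 annotate_sites      1800  1800         0

summarize_editome(sites)
#> <editome_summary> 1800 sites; A>G fraction 0.977
```

The 50 removals at the SNP stage are exactly the 50 planted contaminant
SNPs-in-RNA; 97.7 % of surviving sites are A>G on the transcript strand,
the planted A-to-I signature.  The cross-species test recovers the planted
predaceous expansion and its direction:

```r
res <- per_og_group_test(sim$panel, sim$panel_labels)
count_directional_significant(res)
#>   n_pred_higher n_phyt_higher n_tested n_total
#> 1            55             0      200     200

direction_fisher(55, 0, 200)
#> 3.71e-19
```

Result objects have `tidy()` / `glance()` methods and `autoplot()` /
`plot_*()` visualisations.

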