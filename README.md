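# adtbgc

Biogeography of specialized-metabolite biosynthetic gene clusters (BGCs)
across human aerodigestive-tract (ADT) microbiomes.

Bacteria colonizing the nasal and oral cavities carry gene clusters for
antibiotics, siderophores, pigments and other specialized metabolites.
`adtbgc` is for microbiome researchers who want to ask, from shotgun
metagenomes and a BGC catalog: *which clusters live where?* It
implements the full analysis chain — BGC catalog bookkeeping, k-mer
pseudoalignment of reads onto biosynthetic ORFs with EM resolution of
multi-mapping, count normalization, alpha/beta diversity, site-enrichment
calling, compositional differential abundance, and BGC/peptide similarity
networks — plus a synthetic-study generator with known ground truth that
validates every stage.

## The statistics at the core

* **Quantification.** Reads pseudoalign to a canonical 31-mer index over
  biosynthetic ORFs: a read's equivalence class is the intersection of
  its k-mers' target sets (absent k-mers ignored, tolerating sequencing
  error). Multi-mapping resolves by multinomial EM with class weights
  αₜ/(Lₜ−k+1); ORF estimates aggregate to BGC counts, get one
  pseudocount, and normalize by median-of-ratios size factors
  sⱼ = medᵢ( cᵢⱼ / (∏ⱼ′ cᵢⱼ′)^(1/n) ).
* **Diversity.** Shannon H′ = −Σ pᵢ ln pᵢ, richness S, equitability
  E_H = H′/ln S; Kruskal–Wallis with Dunn/BH post hoc and ε² = H/(n−1);
  a paired sign test of BGC-level vs species-level H′.
* **Community structure.** Bray–Curtis d(u,v) = Σ|uᵢ−vᵢ|/Σ(uᵢ+vᵢ);
  ANOSIM R = (r̄_between − r̄_within)/(n(n−1)/4) with permutation p;
  NMDS minimizing Kruskal stress-1 via isotonic regression +
  majorization; Ward clustering on squared Euclidean distances with
  per-cluster site purity and pair-counting Jaccard agreement.
* **Enrichment.** One-vs-rest negative-binomial Wald test per site:
  LFC = log₂(μ_F/μ_R), method-of-moments dispersion, delta-method SE
  from Var = μ + αμ²; a BGC is enriched at LFC ≥ 2 (≥4-fold) and
  BH-adjusted p < 1e-08, for sites with ≥200 samples.
* **Compositional testing.** ANCOM-style W: for each taxon, Wilcoxon
  rank-sum tests of every log ratio between sites (BH within taxon);
  flagged when |mean CLR difference| > 0.5 and W reaches the 90th
  percentile.
* **Networks.** BGC distance 1 − (0.2·J + 0.05·AI + 0.75·DSS) over
  domain strings, families = connected components at cutoff 0.3; RiPP
  precursors (ORFs ≤ 450 nt of RiPP/bacteriocin BGCs) classified by a
  rule-based scorer (threshold 0.75), leader-cleaved at the last
  in-frame Gly-Gly motif, and networked by global-alignment identity
  (BLOSUM62, ≥75%).

See the methods vignette (`vignettes/bgc-biogeography-methods.Rmd`) for
assumptions, parameter defaults, and design rationale.

## Worked example

A small synthetic study (12 genomes, 4 sites × 15 samples, 4,000 reads
per sample, one BGC per site planted at 8-fold enrichment):

```r
library(adtbgc)

cfg <- pipeline_config(
  synthetic = synth_config(n_genomes = 12, samples_per_site = 15,
                           reads_per_sample = 4000,
                           bgc_per_genome_range = c(2, 8),
                           planted_per_site = 1, planted_species_fold = 1,
                           seed = 7),
  min_site_samples = 10, anosim_permutations = 999,
  nmds_max_samples = 60, nmds_trymax = 5,
  ancom_min_sample_total = 2000, ancom_min_prevalence = 3,
  ancom_min_taxon_total = 100)

run_pipeline(cfg, "demo_run")

readr::read_tsv("demo_run/community_stats.tsv")
#>             statistic      value
#> 1    anosim_r_species 0.88788713
#> 2    anosim_p_species 0.00100000
#> 3        anosim_r_bgc 0.99423280
#> 4        anosim_p_bgc 0.00100000
#> 5 nmds_stress_species 0.12703216
#> 6     nmds_stress_bgc 0.08144862
#> 7 ward_min_purity_bgc 0.93750000
#> 8  clustering_jaccard 0.36725664

dplyr::filter(readr::read_tsv("demo_run/enrichment.tsv"), enriched)
#>    bgc_id          site      lfc        se            p         padj enriched
#> 1 BGC0051 buccal_mucosa 2.468518 0.1645857 7.524611e-51 4.138536e-49     TRUE
#> 2 BGC0053 tongue_dorsum 2.029782 0.1223994 9.207416e-62 5.064079e-60     TRUE

readr::read_tsv("demo_run/truth_planted_bgcs.tsv")
#>             site  bgc_id fold genome_id
#> 1  buccal_mucosa BGC0051    8      G011
#> 2  tongue_dorsum BGC0053    8      G012
#> 3 external_naris BGC0006    8      G002
#> 4        gingiva BGC0003    8      G001
```

Reading the output: sites separate strongly at both the species level
(ANOSIM R = 0.89, p = 0.001) and the BGC level (R = 0.99); the NMDS
embeddings are faithful (stress ≈ 0.13 and 0.08); the least pure Ward
cluster is 94% one site. The enrichment stage recovers the planted
buccal and tongue BGCs with log₂ fold changes near the realized plant
(≈2.5 and ≈2.0, adjusted p ≪ 1e-08); the two plants hosted by rarer
genomes are below the 4-fold calling rule at this shallow demo depth —
at the default study depth (250 samples/site, 10,000 reads/sample) all
twelve planted BGCs are recovered with zero-to-one false calls in ~1,600
negative tests. Other artifacts in `demo_run/` include the per-category
catalog summary, per-sample diversity, ANCOM results, and the BGC and
peptide networks (`*_edges.tsv`, `*.graphml`).

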