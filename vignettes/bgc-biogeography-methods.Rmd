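---
title: "Methods: BGC biogeography across aerodigestive-tract microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BGC biogeography across aerodigestive-tract microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and overall model

`adtbgc` quantifies specialized-metabolite biosynthetic gene clusters
(BGCs) in shotgun metagenomes from human aerodigestive-tract (ADT) body
sites, and asks where each cluster lives: which sites carry distinct BGC
repertoires, which clusters are enriched at which site, and how the BGC
landscape relates to the underlying bacterial communities. The package
chains eight stages:

1. **synthetic study generation** — a catalog of genomes carrying BGCs,
   site-structured communities, and error-bearing reads with known ground
   truth;
2. **catalog summarization** — category taxonomy (13 categories:
   Bacteriocin, RiPP, NRPS, Terpene, Aryl Polyene, PKS, Siderophore, HSL,
   Ectoine, Phosphonate, Butyrolactone, Hybrid, Other), ADT-vs-environment
   habitat source, nonbiosynthetic-ORF filtering;
3. **quantification** — a canonical 31-mer index over biosynthetic ORFs,
   pseudoalignment of reads to equivalence classes, EM resolution of
   multi-mapping, aggregation to per-BGC counts, median-of-ratios
   size-factor normalization;
4. **alpha diversity** — Shannon H′ (natural log), richness S,
   equitability E_H = H′/ln S, with Kruskal–Wallis + Dunn + BH across
   sites, ε² = H/(n−1) effect sizes, a paired sign test, and per-site
   linear models of BGC diversity on species diversity;
5. **community structure** — Bray–Curtis dissimilarities, ANOSIM with
   permutations, NMDS (Kruskal stress-1), Ward clustering with site
   purity, pair-counting Jaccard agreement between the species- and
   BGC-derived clusterings;
6. **enrichment** — one-vs-rest negative-binomial Wald tests per site at
   the ≥4-fold, adjusted-p < 1e-08 calling rule;
7. **compositional testing** — an ANCOM-style W statistic with the CLR
   decision rule between site pairs;
8. **networks** — a domain-content BGC distance with connected-component
   families at cutoff 0.3, and a RiPP core-peptide identity network after
   rule-based precursor classification and leader cleavage.

Everything is driven end-to-end by `run_pipeline()`; stages communicate
only through files in the run directory, and all randomness derives from
one seed via `derive_seed()`. The package is a library: its functions,
`run_pipeline()`, and `scripts/acceptance.R` are the interface, rather
than a shell tool with subcommands.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is validated.

## What it emulates

Real inputs to this kind of study are (a) an annotated BGC catalog
derived from reference genomes, (b) per-sample species relative-abundance
(RA) tables, and (c) shotgun reads. The generator emulates all three with
known ground truth:

* **Catalog** (`generate_catalog()`): `n_genomes` single-species genomes
  from a pool of common ADT genera; each carries a uniform number of BGCs
  in `bgc_per_genome_range` (default 1–18, the range observed for common
  ADT genera). Each BGC has an antiSMASH-style raw type (two types, for
  hybrids, with probability 0.07), ordered ORFs of random ACGT sequence
  (lengths 300–1500 nt rounded to codons), per-ORF domain strings from a
  type-specific vocabulary (so domain-based distances group clusters by
  type), and biosynthetic flags (10% nonbiosynthetic). BGCs of RiPP or
  bacteriocin character receive a designed precursor ORF — Met + leader +
  Gly-Gly + a Cys/Ser/Thr-rich core — as substrate for the peptide
  modules.
* **Communities** (`generate_communities()`): a single shared
  log-normal(0, 1) species magnitude vector times a bounded per-site
  effect, log-uniform on `[1/f, f]` with `f = site_effect_max_fold = 2`,
  renormalized into per-site mean profiles. Per-sample abundances are
  Dirichlet draws around the site profile with concentration 300.
* **Reads** (`simulate_sample_reads()`): per read, a genome is chosen by
  the sample's species RA; with probability `background_fraction = 0.25`
  the read is a substring of that genome's (once-generated, 20 kb random)
  background sequence, otherwise of one of its BGC ORFs chosen
  proportional to ORF length; strand uniform; per-base substitutions at
  0.5%. Default depth is 10,000 reads of 100 nt per sample, with
  4 sites × 250 samples — the scale at which all recovery statistics in
  this vignette and the acceptance script are computed. ORFs shorter than
  the read length are skipped with a warning.

## Planted ground truth and identifiability

Two signals are planted so that recovery can be scored exactly:

* **Site-enriched BGCs**: three BGCs per site get their ORF-sampling
  weight multiplied 8-fold in that site. A weight multiplier of s on a
  BGC holding a fraction q of its genome's read-eligible ORF weight
  realizes a marginal fold of s / (1 + (s−1)q), so the generator plants
  the smallest-q BGC of multi-BGC genomes drawn from the abundant half of
  the community, and gives host genomes a neutral site effect. This makes
  the realized fold ≈ 6–7 (log2 ≈ 2.5–2.8), attributable to the plant
  alone and comfortably above the 4-fold calling threshold at the default
  depth.
* **A differential species**: one low-BGC-count species is boosted
  10-fold in the first site (site effect otherwise neutral), giving the
  compositional test a known positive whose few BGCs barely perturb the
  enrichment truth set.

## Why the site effects are bounded

Independent heavy-tailed per-site profiles would make most BGC-carrying
genomes — and hence most BGCs — incidentally more than 4-fold different
between sites, so the planted enrichment would be unidentifiable against
a sea of genuine but unplanted differences. Bounding per-species site
effects at 2-fold keeps the incidental focal-vs-rest fold of unplanted
BGCs below the 4-fold calling rule (a single borderline call in ~1,600
negative tests at the defaults), while the site *structure* needed by
ANOSIM/NMDS/Ward comes from the high within-site reproducibility
(concentration 300): body-site communities in repeated human sampling are
highly consistent, and rank-based Bray-Curtis statistics respond to
consistent modest differences just as strongly as to large ones. With
these defaults the species- and BGC-level ANOSIM R (~0.95) and the
clustering agreement (~0.97) sit in the same regime as real multi-site
ADT data.

## What the generator does not emulate

Uniform read starts, a single substitution-only error process, constant
quality strings, single-end reads, no host contamination, one genome per
species, and site effects that are independent across species. Passing
recovery tests therefore demonstrate that the statistical machinery is
correct and well-calibrated under a faithful-but-idealized community
model — not that any particular real dataset would yield the same
numbers.

# Quantification

Sequences are sanitized (`sanitize_sequences()`: IUPAC ambiguity codes
replaced by seeded pseudorandom bases, replacements counted) and indexed
(`build_index()`) with canonical k-mers: each 31-mer is stored under the
lexicographic minimum of itself and its reverse complement, mapping to
its equivalence class (the set of ORFs containing it). Pseudoalignment
intersects the classes of a read's canonical k-mers, *ignoring* k-mers
absent from the index — this tolerates substitution errors; a read is
unassigned only if nothing hits or the intersection is empty.

Multi-mapping is resolved by multinomial EM (`em_quantify()`) with class
weights proportional to abundance over effective length (L − 31 + 1), no
fragment-length model (unnecessary at single-end, fixed-length scale).
Convergence: maximum absolute change in estimated counts < 1e-3 or 200
iterations; the log-likelihood trace is retained and non-decreasing.
ORF estimates are summed per BGC, BGCs undetected in every sample are
dropped with a report, estimates are rounded half-away-from-zero, one
pseudocount is added to every cell, and size factors are the median over
BGCs of count over per-BGC geometric mean. A `<100 total normalized
reads` filter (`abundance_filter()`, strict less-than) mirrors the usual
display filter for heat maps.

The index, pseudoalignment and read simulation are C++ (Rcpp) — a
study-scale run touches ~10^7 reads × ~70 k-mers each — but use R's RNG
stream, so `set.seed()` governs everything.

# Statistical choices

* **Shannon metrics** use natural logarithms; E_H is undefined (NA) at
  richness ≤ 1. BGC-level proportions divide each cluster's estimated
  reads by the sample's total reads (pre-pseudocount estimates).
* **Kruskal–Wallis** H is tie-corrected (via `stats::kruskal.test`);
  Dunn z statistics use joint midranks with tie correction and BH across
  all pairs jointly; ε² = H/(n−1). The compact letter display is built
  greedily over groups sorted by decreasing median: a group joins every
  existing letter whose members it is non-significantly different from,
  else founds a new letter.
* **Sign test**: ties dropped, exact two-sided binomial at every n
  (the exact computation is cheap here, so no normal approximation is
  substituted above n = 1000).
* **ANOSIM** ranks all pairwise dissimilarities jointly with midranks;
  R = (mean between − mean within rank)/(n(n−1)/4); the permutation p
  includes the observed statistic: p = (1 + #{R_perm ≥ R_obs})/(1 +
  n_perm); default 10,000 permutations.
* **NMDS** minimizes Kruskal stress-1 with isotonic regression of
  configuration distances on dissimilarity ranks (primary tie treatment:
  ties ordered by current configuration distance) and Guttman-transform
  majorization; first start from classical scaling, then random restarts
  (relative stress change < 1e-7 or 300 iterations per start; early stop
  after 10 non-improving starts). The best configuration is centered and
  principal-axis rotated. In the pipeline, NMDS runs on a stratified
  subsample (default 160 samples) because its cost is quadratic; ANOSIM,
  clustering and all tests use every sample.
* **Ward clustering** applies `hclust(method = "ward.D")` to squared
  Euclidean distances of log10 normalized counts (BGCs) or log10(RA +
  1e-3) (species; the 0.1% detection floor stops rare-species noise from
  dominating). Flat clusters are cut at K = number of distinct sites;
  purity is the majority-site fraction per cluster. Agreement between the
  two clusterings is pair-counting Jaccard J = n11/(n11 + n10 + n01).
* **Enrichment** is a deliberately simplified negative-binomial Wald
  test: group means of normalized counts, method-of-moments dispersion
  pooled within groups with floor 1e-8, delta-method SE of the log2 fold
  change from the NB variance μ + αμ², two-sided normal p, BH within each
  one-vs-rest contrast. Dispersion shrinkage, outlier replacement and LFC
  moderation are intentionally absent: the validation surface is recovery
  on synthetic data, not bit-agreement with a particular GLM
  implementation. "≥4-fold" is inclusive on the raw LFC; only positive
  LFCs are called enriched; sites qualify at ≥200 samples.
* **ANCOM** replaces zeros with a pseudocount of 1 on estimated counts
  (RA × total reads, rounded), filters samples < 10,000 reads and taxa in
  < 10 samples or < 1,000 total estimated reads (the read-total filter is
  applied per taxon grand total), tests every log ratio with two-sided
  Wilcoxon rank-sum, BH within each taxon's m−1 ratios, W = rejections at
  0.05, and flags taxa with |mean CLR difference| > 0.5 and W at or above
  the empirical 90th percentile (inclusive, quantile type 7).
* **BGC distance** = 1 − (0.2·J + 0.05·AI + 0.75·DSS) over ordered
  domain strings: J = Jaccard of domain sets, AI = Jaccard of adjacent
  ordered domain pairs, DSS = 1 − ΣL1/Σ(sum) over domain copy numbers.
  The copy-number DSS replaces profile-HMM alignment scores — a
  simplification that preserves the metric's structure without an HMM
  dependency. Families are connected components at cutoff 0.3 with
  singletons retained.
* **Peptides**: candidate precursors are ORFs ≤450 nt from RiPP- or
  bacteriocin-containing BGCs (hybrids included), translated in frame 1,
  trailing stop trimmed, internal stops dropped. The classifier is an
  explicit rule-based stand-in (length in [20, 120] aa: 0.4; Gly-Gly
  motif: 0.25; C-terminal-half Cys/Ser/Thr density scaled to 0.35; pass
  at ≥0.75) with a documented import path for externally computed scores.
  Leader cleavage cuts after the last GG whose end lies in the first
  two-thirds of the sequence, else at the midpoint, and always
  reconstructs the precursor. Identity is global Needleman–Wunsch
  (BLOSUM62, gap 11/1), 100 × matches / alignment length; the default
  network threshold is 75% (full-query coverage), with 80% available to
  match stricter renderings — the two conventions are surfaced as a
  configuration choice rather than silently merged.

## Open choices resolved

* Whether the sub-threshold RA filter zeroes entries or drops species:
  entries below 0.1% are zeroed; species are dropped only by the RA-1.0
  and prevalence rules.
* BGC-level ordination uses proportions of normalized counts.
* Hybrids containing a RiPP subtype are categorized Hybrid (composite
  type string wins over subtype membership).
* Per-site diversity regressions pool all samples of a site.
* Domain-level detection of specific enzyme families (e.g. cyclases) is
  out of scope; the catalog's domain strings are opaque tokens.

# Problem sizes and determinism

The default study (4 × 250 samples, 10^7 reads total) runs in about six
minutes on one core: ~40 s simulation, ~2.5 min quantification (index:
~1.7M k-mers), ~1 min community statistics (ANOSIM at 10,000 permutations
in C++), ~1.5 min networks. Unit tests use miniature configurations
(tens of samples, hundreds of reads). Every stage seeds its own RNG
stream via `derive_seed(seed, label)`, and per-sample streams make
samples reproducible independently and in any order; reruns of the same
configuration are byte-identical. FASTQ serialization is optional
(`write_reads`): at full scale the reads are ~2 GB of text, so by default
the quantify stage regenerates each sample's reads from its seed instead
of re-reading files, which is verified to give identical counts.

# Known limitations

* The NB Wald test has no dispersion shrinkage, so it is anticonservative
  for very low counts; the pseudocount and the 4-fold rule dominate in
  practice.
* The rule-based precursor classifier is a stand-in; its scores are
  meaningful only relative to its own rule table. Real classifier scores
  can be supplied via the `scores` argument.
* The BGC distance treats domain strings as exact tokens; truncated or
  mis-annotated domains are not reconciled.
* NMDS on the full sample set is quadratic and therefore subsampled in
  the pipeline; ANOSIM (the inferential statistic) always uses all
  samples.
* ANCOM is implemented for two-group (site-pair) contrasts only.
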