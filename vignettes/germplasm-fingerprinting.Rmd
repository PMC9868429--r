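---
title: "SSR fingerprinting, ploidy and diversity analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSR fingerprinting, ploidy and diversity analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

pearprint implements the standard analysis chain used to characterize a
clonally propagated fruit-tree germplasm collection genotyped with a panel
of codominant microsatellite (SSR) markers: marker informativeness,
genotype-identity resolution (duplicates, synonymies, homonymies), ploidy
determination from SSR profiles and flow cytometry, and partitioning of
diversity within and among geographic origins. A seeded synthetic-germplasm
generator with a ground-truth channel makes every step testable without a
real collection. This vignette documents the statistical methods, the
default parameter values and why they were chosen, and the limitations of
the synthetic validation.

```{r}
library(pearprint)
```

## Data model

A `germplasm_table` holds one row per accession with metadata
(`accession_id`, `name`, `province`) and, per locus, a sorted set of one to
three integer allele sizes in base pairs (`integer(0)` = missing). One
reported size is treated as a homozygote (two copies), two as a
heterozygote, and three as a triallelic profile, the SSR signature of a
triploid. Serialization is plain delimited text with slash-separated sizes
("134/138/142"); `read_genotype_table()` rounds fractional sizes half-up,
records malformed cells with coordinates instead of failing, and drops
accessions missing more than half their loci (a routine quality screen in
collection studies).

## Marker statistics

Allele frequencies are estimated from diploid accessions only (triploids
would otherwise bias counts; an accession is excluded once it reaches the
triploid calling threshold below). For frequencies $p_i$ at a locus scored
in $n$ diploids:

* $N_a$ — observed alleles; $N_e = 1/\sum p_i^2$ — effective alleles;
* $H_o$ — fraction of heterozygous genotypes;
* $H_e = \frac{2n}{2n-1}\left(1-\sum p_i^2\right)$ — unbiased expected
  heterozygosity;
* $I = -\sum p_i \ln p_i$ — Shannon information index;
* $PIC = 1-\sum p_i^2$ — polymorphism information content in the
  gene-diversity form common in germplasm surveys.

Discrimination power of the whole panel is
$DP = 1-\sum_k f_k^2$ over the frequencies $f_k$ of the distinct multilocus
profiles: the probability that two accessions drawn at random (with
replacement) carry different profiles. Accessions with any missing locus
are excluded by default (`missing = "drop"`); `missing = "match_any"`
instead lets an incomplete profile merge with its compatible complete ones.

## Genotype identity

`binarize()` recodes the table as a presence/absence band matrix with one
column per locus–allele combination (missing locus ⇒ `NA` across its
columns). Pairwise similarity is the simple-matching coefficient
$GS = (n_{11}+n_{00})/n$ over mutually scored columns — shared absences are
informative for codominant bands scored on a fixed allele catalogue.
`collapse_genotypes()` joins pairs with $GS \ge 1$ (identity on every
mutually scored locus) and takes connected components as unique genotypes;
components are computed with igraph. Accession names are normalized
(case-folded, province codes FR/LT/RI/RM/VT and bare numerals stripped) so
that:

* a **synonymy** is one genotype carrying two or more distinct normalized
  names;
* a **homonymy** (`find_homonyms()`) is one normalized name spanning more
  than one genotype group; the report includes the closest cross-group
  similarity so near-identical homonyms can be flagged.

The exact-identity threshold (1.0) is deliberate: with highly polymorphic
SSRs, true clones differ only through missing data, which the
mutually-scored restriction already absorbs; any lower threshold creates
similarity clusters, not genotypes (a warning says so if you lower it).

## Ploidy

* **SSR**: `classify_ploidy_ssr()` counts triallelic loci per accession
  and calls `triploid` at `min_loci = 2` or more, `putative_triploid` at
  exactly one. A single triallelic locus can be a scoring artifact or a
  locus duplication, so it is not treated as a final call; two independent
  loci showing three alleles are very unlikely under diploidy.
* **DAPI flow cytometry**: `detect_g1_peaks()` smooths the histogram with a
  centered moving average (window 9 channels) and finds prominent maxima
  with `pracma::findpeaks`. `call_ploidy_dapi()` classifies the
  sample/reference peak ratio into windows $1 \pm 0.1$ (diploid),
  $1.5 \pm 0.1$ (triploid), ~2 (tetraploid candidate), otherwise
  unassigned; $\pm 0.1$ accommodates instrument drift while keeping the
  diploid and triploid windows disjoint.
* **Propidium iodide genome size**: with PI, fluorescence is proportional
  to DNA amount, so
  $2C_{sample} = 2C_{standard}\times(\text{peak}_{sample}/\text{peak}_{standard})$
  per co-chopped internal standard (e.g. *Raphanus sativus* 1.11 pg,
  *Solanum lycopersicum* 1.96 pg), averaged over standards
  (`estimate_genome_size_pi()`); inconsistent implied channels-per-pg
  slopes across standards trigger a warning (likely peak mis-assignment).
* `concordance()` tabulates SSR against cytometric calls, mapping putative
  triploids to diploid by default.

## Population structure

`distance_matrix(kind = "band_mismatch")` counts mismatching bands over
mutually scored columns — the squared Euclidean distance on the binary
encoding, which is the natural input to a distance-based AMOVA. `amova()`
uses the classical sums of squares
$SS_{tot}=\frac{1}{N}\sum_{i<j}d^2_{ij}$,
$SS_{within}=\sum_g \frac{1}{n_g}\sum_{i<j\in g}d^2_{ij}$, variance
components $\sigma^2_w = SS_{within}/(N-G)$ and
$\sigma^2_a = (SS_{among}/(G-1)-\sigma^2_w)/n_0$ with
$n_0 = (N-\sum n_g^2/N)/(G-1)$, and $\Phi_{ST}$ tested by freely permuting
individuals among groups, $p=(\#\{\Phi^*\ge\Phi\}+1)/(B+1)$. Negative
among-group components (common when structure is weak) are reported
untruncated with a warning so percentages stay additive.

`pcoa_ord()` double-centers $-d^2/2$ (Gower) and eigendecomposes; axes with
positive eigenvalues carry coordinates scaled by $\sqrt{\lambda}$, and
percent variance is taken over positive eigenvalues only — the usual
convention when semi-metric distances produce negative eigenvalues.

`evanno_delta_k()` consumes a table of external clustering-run
log-likelihoods (columns `K`, `replicate`, `lnP`) and computes
$\Delta K = \overline{|L''(K)|}/\mathrm{sd}_r\,L(K)$ with the differences
taken per replicate. All local maxima are reported alongside the argmax,
because collections frequently support more than one clustering level.

## The synthetic generator

`synthetic_config()` encodes a realistic regional pear collection as the
default scenario; `simulate_population()` draws it reproducibly from one
seed and returns the table plus a `truth` object (true ploidies, clone
memberships, generating frequencies).

Defaults and their rationale:

| parameter | default | why |
|---|---|---|
| `n_accessions` | 311 | a realistically sized regional collection |
| `n_loci`, `alleles_per_locus` | 9; 12, 18, 11, 23, 19, 17, 9, 20, 15 | a typical well-chosen SSR fingerprinting panel (9–23 alleles per locus) |
| `freq_concentration` | 0.3 | Dirichlet concentration per allele; moment matching $E[\sum p_i^2]=(\alpha+1)/(k\alpha+1)$ puts expected PIC near 0.77, the informativeness of real pear panels |
| `province_weights` | 104, 66, 69, 57, 15 | unequal sampling across five provinces, as field collections have |
| `fst` | 0.017 | Balding–Nichols divergence of province frequencies; weak structure typical of clonally exchanged germplasm |
| `triploid_fraction` | 0.20 | triploidy is common in traditional pear varieties |
| `clone_groups` | 26 groups, sizes 2–10, 61 redundant copies | 311 accessions collapse to 250 genotypes; 14 groups are synonym-style (each copy under its own name), 12 share a name |
| `homonym_groups` | one name spanning 2 genotypes | one classic homonymy case |
| `missing_rate` | 0.011 | per-cell dropout giving per-locus sample sizes in the high-290s to 311 |

Triploids are built mechanistically as an unreduced diploid egg (two draws)
plus a haploid pollen draw, so their triallelic rate per locus emerges from
allele diversity rather than being imposed. Clone copies are exact genotype
copies that can differ only in missingness. Cytometry simulators
(`simulate_cytometry()`, `simulate_pi_run()`) draw Gaussian fluorescence
around ploidy-proportional peaks with a realistic coefficient of variation.

```{r}
sim <- simulate_population(synthetic_config(seed = 1))
panel_summary(sim$table)$mean
```

## What the synthetic validation does and does not show

The generator validates the *statistics*, not the biology: estimators are
checked against generating truth (frequencies, clone membership, ploidy),
closed-form hand computations, and independent oracles. It does not model
null alleles, allelic dropout correlated with DNA quality, mutation within
clone lineages, or linkage between loci; observed allele counts at
`n = 311` run below the configured catalogue because rare alleles go
unsampled, which is itself realistic. Flow-cytometry simulation assumes
clean single-peak G1 distributions; debris is available
(`debris_fraction`) but aggregates and S/G2 phases are not modeled.
Problem sizes throughout the tests (60–1000 accessions, 3–9 loci) are
chosen so that brute-force oracles stay exact and fast.

## Running everything at once

`run_pipeline()` executes the full chain on a genotype file or table and
writes every result as delimited text with a manifest; `render_report()`
formats a plain-text summary including per-accession sheets with synonymy
cross-references.

```{r, eval = FALSE}
cfg <- pipeline_config(output_dir = tempfile("out"))
bundle <- run_pipeline(cfg, table = sim$table)
writeLines(head(render_report(bundle), 30))
```
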