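---
title: "Dissecting maternal and zygotic transcription and early zygotic dosage compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting maternal and zygotic transcription and early zygotic dosage compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement idea

In a cross between two inbred strains, every mRNA deposited into the egg by
the mother carries the maternal strain's alleles, while zygotic transcription
reads off both parental chromosomes. At any site where the two strains are
fixed for different bases, a sequencing read spanning that site is assignable
to one parental chromosome — and any paternal-allele read is unambiguous
evidence of zygotic transcription. `mztcomp` implements the full analysis
built on that observation for a staged single-embryo RNA-seq design: 24
embryos (12 female, 12 male), one embryo per sex at mitotic cycles 10–13 and
two per sex at the cellularization sub-stages 14A–14D. All time profiles in
the package live on this ordered 8-point axis (`stage_levels()`), indexed
internally as t = 0..7; no wall-clock duration is attached to a stage.

The pipeline has five computational stages, each usable on its own:

1. **Fixed-SNP calling** (`call_fixed_snps()`). A position is callable in a
   strain if at least 13 reads cover it and the most common base accounts
   for at least 95% of the A/C/G/T reads; it is a fixed SNP if both strains
   are callable with different consensus bases. Both thresholds follow the
   wording "at least": 13 reads qualify, 19/20 = 95% qualifies. Ambiguous
   (N) reads are excluded from the frequency denominator — the conservative
   reading of "frequency of the most common base". Deeply covered positions
   that fail the 95% rule are tallied per strain as residual within-strain
   polymorphism, a data-quality diagnostic with no downstream role.
2. **Allelic partition** (`normalize_autosomal()`, `partition_rpkm()`).
   Samples are first rescaled by one scalar each so that the summed
   autosomal RPKM is constant across samples; the mean pre-normalization
   total is used as the constant so values keep their scale (any constant
   gives the same downstream ratios). Each gene's RPKM in each sample is
   then split in proportion to its maternal- and paternal-allele
   informative read counts. With zero informative reads the split is
   *undefined* and flagged — never imputed — and such genes are classified
   later by correlation.
3. **Maternal/zygotic classification** (`classify_genes()`), below.
4. **Dosage-compensation scoring** (`score_table()`, `fm_ratio()`,
   `ratio_bins()`, `chrom_aggregate()`), below.
5. **SXL site census** (`count_sxl_sites()`, `scan_sxl()`): occurrences of
   the poly-U octamers AUUUUUUU or UUUUUUUU in 3'UTRs, with a predicted
   target flagged at three or more sites.

## The zygotic-fraction convention

Zygotic transcription is biallelic on the autosomes and the female X, so
paternal-allele reads represent *half* of the zygotic transcript pool. The
per-gene zygotic fraction therefore doubles the paternal share:
`min(1, 2p/(m+p))`. This doubling is what reconciles an allele partition
with a maternal/zygotic partition; it is configurable
(`zygotic_fraction(..., doubling = FALSE)`) because displays in terms of the
raw paternal fraction are also in use. For X-linked genes in males there is
no paternal allele and the fraction is undefined by construction. The
fraction depends only on allele counts, so it is invariant to the per-sample
normalization scalar.

## Classification model

Assignments use **female samples only**: males lack a paternal X, so the
allele dissection is incomplete for X-linked genes in males.

Genes with at least 10 allele-informative reads summed over the 12 female
samples (the threshold is interpreted as a sum, not per sample) are
clustered directly. Each gene contributes a 16-vector: its replicate-averaged
maternal component over the 8 stages followed by its paternal component,
transformed as log2(RPKM + 1) to stabilize a dynamic range that spans four
orders of magnitude. Components at a stage are computed by read-weighted
pooling: counts are summed over the stage's replicates before the allele
fraction is applied to the stage-mean RPKM, so a deep replicate is not
diluted by a shallow one. A stage with zero pooled reads falls back to
maternal = total, paternal = 0 — at negligible coverage the total itself is
near zero, so this choice carries no weight.

Clustering is **k-medians** (k = 20 by default): city-block (L1) distance
with coordinate-wise median centroids, the classical pairing in which the
median is exactly the per-cluster L1 minimizer. The implementation runs
Lloyd-style alternation from 20 random initializations (k distinct data
points), reseeds clusters that empty with the point farthest from its
centroid, and is fully deterministic given a seed. Because the assignment
step minimizes distance to the *old* medians rather than the partition cost
itself, Lloyd iteration can stall one reassignment short of a better
partition; on small instances (n x k up to 5,000) an exhaustive single-point
relocation polish closes that gap. The objective is non-increasing
throughout.

Each cluster is labeled from its back-transformed (linear RPKM) centroid
against a detection floor of eps = 0.5 RPKM:

* **maternal** — paternal centroid never reaches eps, and the maternal level
  at 14D is below its level at C10 ("declining" is judged from the
  endpoints, which is robust to mid-course wiggles);
* **zygotic** — total below eps at C10, with paternal signal appearing;
* **maternal+zygotic** — maternal signal at C10 with paternal signal
  appearing;
* **unclassified** otherwise.

The rules are mutually exclusive, and labels are invariant to a global
rescaling of the data when eps is rescaled with it.

Genes that cannot be clustered (no SNP, or fewer than 10 informative reads)
inherit the label of the cluster whose mean total-expression pattern best
correlates with their own 8-stage female profile, provided the Pearson
correlation strictly exceeds 0.8 (ties break to the lower cluster index;
Spearman is available via `cor_method`). Two deliberate choices here:

* Correlation is computed on the **log2(RPKM + 1) scale** — the same
  transform as the clustering. Linear-scale Pearson centres each profile,
  which erases the early-stage maternal baseline, the single feature that
  separates a maternal+zygotic pattern from a pure zygotic one (and a
  slowly-declining mixed pattern from a pure maternal one). On the log
  scale that baseline survives centring and the assignment is stable.
* A gene whose profile never reaches the detection floor eps is left
  unclassified rather than propagated: the same floor that gates "detected"
  in cluster labeling gates whether a kinetic class can be claimed at all.
  Without this, never-expressed genes are occasionally assigned a class by
  a chance correlation of noise (with 8 stage points, r > 0.8 by chance is
  rare but not negligible when thousands of silent genes are screened).

A known limitation: cluster-level labeling cannot resolve mixed genes whose
minor component is a sliver of the total or sits at the detection floor —
such genes are absorbed by the neighbouring pure-class cluster and inherit
its label. The test suite's perfect-recovery check therefore applies to
genes squarely inside an archetype (both components at twice the floor,
mixture fraction within [0.1, 0.9]); boundary genes are counted in the
overall (non-perfect) recovery rates instead.

## Dosage-compensation statistics

Two statistics quantify early zygotic dosage compensation for X-linked
zygotic genes, both on replicate-averaged stage levels:

* **F:M ratios** (`fm_ratio()`), defined only where both sexes reach 2 RPKM
  (inclusive) — ratios of smaller values are noise-dominated and are
  excluded, not imputed. `ratio_bins()` summarizes their distribution per
  stage for X vs autosomes over bins with edges at
  1/2, 1/1.75, 1/1.5, 1/1.25, 1, 1.25, 1.5, 1.75, 2.
* A per-gene **compensation score** (`compensation_score()`): the
  through-origin least-squares slope of female on male stage levels,
  sum(f·m)/sum(m²), over the 8 stage points. Fitting through the origin
  makes the score a ratio estimator: 1.0 means equal expression, 2.0 means
  female expression double the male — an uncompensated X-linked gene —
  so scores read directly against the biologically meaningful landmarks.
  The score is equivariant under rescaling of the female levels and
  invariant under a common rescaling of both sexes. It is computed for
  zygotic genes whose maximum RPKM strictly exceeds 3.0 ("greater than",
  so a maximum of exactly 3.0 is excluded); slopes are fit on raw RPKM by
  default, with log2 values available via `log2_values`.

`chrom_aggregate()` complements the per-gene view with chromosome-level
sums of the maternal and paternal expression components of zygotic genes
per (arm, sex, stage); entries with undefined partition are excluded from
components and matched totals alike, so the parental components always add
up exactly.

## The synthetic-data generator

`simulate_timecourse()` emulates the study design with full ground truth;
it is first-class, tested code, and every quantitative guarantee of the
package is verified against it. Per gene it draws a class (maternal,
zygotic, maternal+zygotic, or silent), a chromosome arm, amplitude scales,
and kinetics:

* maternal level `M0 * exp(-d_g * t)` with a gene-specific decay rate
  (lognormal around 0.3 per stage unit, spread 0.4 on the log scale);
* zygotic level `Z0 * plogis(s * (t - o_g))` with steepness 1.5 and a
  gene-jittered onset centred at t = 5 (mid cycle 14) — a monotone
  saturating onset matching the observed acceleration of zygotic
  transcription during mid cycle 14. Gene-to-gene kinetic variation is
  essential, not decorative: with one shared decay rate all maternal
  profiles are exactly proportional and any scale-invariant profile
  comparison degenerates;
* for X-linked genes, a true compensation target c drawn uniformly from
  [1.0, 2.0]: the expected male level is the per-X-copy female level times
  2/c (that is, female_total/c), and male paternal reads are zero;
* observed RPKM = expected level x lognormal noise (sd 0.2 on the log
  scale) — expression is positive and replicate scatter is multiplicative —
  then Poisson-quantized at 30 reads per RPKM unit, emulating discrete read
  counting: lowly expressed genes yield exact zeros and tied low values,
  exactly as real single-embryo libraries do. The two noise stages together
  put same-stage replicate Spearman correlations in the mid-0.9s, the
  reproducibility regime of the real assay; without quantization a
  constant-background generator cannot exceed ~0.94 however small the
  noise, because silent genes' ranks are pure noise;
* allele-informative depth per (gene, sample) is Poisson with mean
  2 reads per RPKM unit (zero for the 30% of genes simulated without a
  fixed SNP), split binomially 1:1 between the parental alleles for
  zygotic transcripts on autosomes and the female X; maternal transcripts
  and the silent background (0.01 RPKM) are maternal-allele only.

Class fractions default to 0.38/0.15/0.08 (maternal/zygotic/mixed) with the
remainder silent, and 15% of genes on the X — the proportions of the
annotated fly genome this design targets. The default 2,000 genes is a
desk-scale working size: every distributional property checked by the test
suite is insensitive to gene count beyond a few hundred per class, and the
full suite runs in a few minutes on one CPU. Problem sizes used by the
acceptance checks: 10,000 pileup columns for the caller-vs-oracle identity;
the 2,000-gene default run for classification recovery; 200 genes per
compensation level for score recovery; 1,000 (autosomal) and 500 (X-linked)
zygotic genes for the null-centring and uncompensated-ratio checks.

`simulate_strain_pileups()` generates the genome side: two pileups over
common positions with an exact truth table, engineered so every branch of
the calling rule fires — genuinely fixed differences, identical positions,
low-depth positions (0–12 reads), and residual polymorphism (minor-allele
fractions of 20–40%). Counts are constructed so the intended status always
holds (callable depth is 13 + Poisson; error reads are capped strictly
below 5%).

What the generator does **not** emulate: read-level artefacts (mapping
bias toward the reference allele, positional coverage bias, fragment-length
effects), isoform structure, sample-level library-size factors (observed
RPKM noise is independent across samples, so autosomal normalization is an
identity check rather than a correction on synthetic data), correlated
noise between genes, and genuinely non-logistic onset shapes. Passing tests
therefore certify the *statistics* — the calling rule, the partition
arithmetic, the clustering/labeling/propagation machinery, the score and
ratio estimators — not robustness to alignment-level artefacts, which must
be handled upstream on real data.

## Numerical and degenerate-input conventions

* Partition conservation is exact by construction (the paternal component
  is computed as total minus maternal), and verified to 1e-9.
* Consensus ties go to no-call; with the default 95% rule a tie is
  unreachable at callable depth, so the branch exists for nonstandard
  configurations only.
* Zero-variance profiles have no defined correlation and stay
  unclassified; a sample with zero autosomal total cannot be normalized
  and is an error; negative counts are input errors everywhere.
* F13 imputation (`impute_f13()`) — replacing the suspect female C13
  column by the mean of female C12 and 14A — is optional, flagged in the
  output, idempotent, and intended for single-gene displays; no default
  analysis applies it.
* All randomness (generator, clustering restarts) is seed-controlled;
  `run_pipeline()` derives per-stage seeds deterministically from one
  global seed so stages can be rerun in isolation, and a fixed seed makes
  the whole run byte-identical.

## Reference-scale results

The headline quantities of the originating study — the genome-wide fixed-SNP
count, the number of genes with an informative SNP, the class totals, and
the X-chromosome score tallies — depend on the deposited sequencing data
(GEO accession GSE25180), the two strain genomes and annotation release
5.27. They are not reproducible from this package alone; running the
pipeline on those inputs is the external validation path. Everything the
package asserts about itself is computed from the synthetic generator at
run time by the test suite and `scripts/acceptance.R`.
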