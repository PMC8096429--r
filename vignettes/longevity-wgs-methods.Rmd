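---
title: "Methods: case-control whole-genome analysis of extreme longevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control whole-genome analysis of extreme longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The study design this package serves

`longwgs` implements the computational pipeline of a two-group
whole-genome sequencing comparison between semi-supercentenarians
(individuals aged 105 or more, the *cases*) and younger healthy,
geographically matched *controls*. The scientific questions are: do the
extremely long-lived carry distinctive common variants, haplotypes,
private or rare variants; are they spared the age-related accumulation
of clonal-hematopoiesis somatic mutations in blood; and do their
cardiovascular polygenic risk scores differ from controls?

Raw data of that design are access-restricted, so the package ships a
synthetic cohort generator with planted ground truth. Every analysis
stage is exercised end to end on simulated cohorts whose statistical
structure matches the design: 81 cases (18 male, 63 female) versus 36
controls (13 male, 23 female), 162 versus 72 phased haplotypes, and
deep-coverage read counts over a seven-gene clonal-hematopoiesis panel
(ASXL1, DNMT3A, JAK2, PPM1D, TET2, TP53, SF3B1).

# Quality control

Variant-level: call rate strictly below 98% removes a variant; the
common-variant analyses keep minor allele frequency strictly above 5%.
Both thresholds are read literally (a variant at MAF exactly 5% is
removed), which matters only on the boundary and is documented so the
choice is reproducible.

Sample-level: heterozygosity rate and missingness outliers beyond 3
standard deviations are flagged; reported sex is checked against
X-chromosome heterozygosity (below 0.2 is called male — the check is
standard but has no canonical threshold, so it is configurable).

LD pruning scans position-sorted windows of 50 SNPs, removing the
later-positioned member of any pair with squared dosage correlation
above 0.2, then advances 5 SNPs. The genotypic (composite) r² is used
because it needs no phase; the later-position tie-break makes the
retained set deterministic.

PCA outlier removal standardizes mean-imputed dosages, and excludes
samples beyond 3 SDs on either of the first two components in a single
pass. Outlier statistics can be computed per sampling region or on the
whole cohort; the whole-cohort default was chosen because the
stratified variant requires region labels that are often absent.
Relatedness screening is out of scope: no kinship procedure or cutoff
is specified for this design, and silently inventing one would change
who is excluded.

# Common-variant association

Per-variant association uses additive-dosage logistic regression with
sex as the default covariate (IRLS, 50 iterations, deviance tolerance
1e-8); separation is detected as |beta| > 15 and reported as a flagged,
p-absent row rather than a spurious estimate. Wald intervals are
reported, matching the conventional GWAS toolchain output.

Evidence across independent cohorts is combined by Fisher's method
(`-2 * sum(log p)` against chi-square with 2k df). The genomic inflation
factor is the median back-transformed chi-square over its null median
0.4549364.

Family-wise multiplicity is handled by a seed-controlled max-T
permutation scheme: labels are permuted, the genome-wide minimum
nominal p per permutation forms the reference distribution, and
adjusted p-values are smoothed proportions `(1 + hits) / (n_perm + 1)`.
This is a deliberate, clearly labelled stand-in for sliding-window
adjustment software: it controls FWER but does not model local LD
windows, so adjusted values are comparable in role, not numerically
identical, to windowed methods.

# Haplotype-cluster pseudomarkers

Phased haplotypes (consumed from a phased VCF; unphased input is
rejected rather than phased internally) are grouped within a marker
window by exact allele-sequence identity. Each cluster becomes a
diallelic *pseudomarker* — 2 for members, 1 for non-members — and is
tested with the two-sided Fisher exact test; the odds ratio is the
sample cross-product ratio with a Woolf log-odds interval. Exact
matching replaces the HMM-based localized clustering of phasing
software because the clusters of interest are exactly those whose
members share the same allele at every window marker; the HMM is an
external tool's internal machinery, not part of this method's
contribution.

The two-sided Fisher convention sums hypergeometric probabilities no
larger than the observed table's. On carrier tables reconstructed from
published cluster sizes and group frequencies this reproduces the
printed two-decimal odds ratios (0.19, 0.18, 0.13) and the printed
p-value 1.84e-8 of the 13-marker cluster.

# Private and rare variants

A *private* mutation is carried by exactly one case and no control
(the stricter of the two published phrasings; the looser
absent-from-controls rule is a switch). A variant is *damaging* when
more than 4 of 6 predictor databases vote damaging, i.e. at least 5;
missing votes count as non-damaging. The rare-variant filter keeps MAF
strictly below 1% in both groups.

The per-gene rare-variant test collapses samples to carrier versus
non-carrier and applies the Fisher exact test. This replaces
variance-component testing (SKAT-O-class methods) with a transparent,
exactly calibrated statistic: it keeps the pipeline role while being
reproducible without external machinery, at the cost of power against
genes with mixed protective/deleterious effects. Published
variance-component p-values are therefore not comparison targets.

# The somatic-mutation caller

The caller identifies clonal-hematopoiesis mutations in deep WGS read
counts over the seven-gene panel. The pipeline per observation:

1. **Filters.** SNVs only (indels excluded); alternate allele fraction
   not 0 or 1; normalized coverage >= 10 reads; normalized alternate
   count >= 3 reads; allele fraction strictly above 10%.
2. **Coverage normalization.** Case coverages are transformed so their
   cumulative distribution equals the control one (empirical quantile
   matching with linear interpolation; one global map pooled over all
   panel sites, since the group coverage distribution is a single
   property of the sequencing batches). Alternate/reference counts are
   recomputed as `frequency * normalized coverage` with half-to-even
   rounding (unbiased over many sites).
3. **Recurrence.** A variant with alternate evidence in more than one
   control or more than two cases is excluded everywhere — germline
   polymorphisms recur; clones are private. The published sentence
   conflates this with a population-frequency filter; the two are
   implemented as independent filters, the population ceiling (allele
   frequency below 0.025%) applied only when an annotation is supplied.
4. **Germline exclusion.** Equal-tail exact binomial tests at
   significance 0.05: failing to reject mean 1% or 99% classifies the
   site homozygous germline; failing to reject the group heterozygous
   mean classifies it heterozygous germline. The heterozygous means are
   estimated per group as the median allele fraction in the 0.2–0.8
   band (reference bias pulls them slightly below one half; the
   study-scale values 0.4713/0.4643 are available as an override).
   Equal-tail doubling is used rather than the minimum-likelihood
   two-sided convention because it is reproducible across
   implementations and conservative.
5. **Somatic call.** Whatever survives is SOMATIC. A separate
   *putative* flag records whether the count falls in the equal-tail
   rejection region of Binomial(n, 0.5) built with per-tail mass at
   most 5e-6, so the designed false positive rate of 1e-5 holds by
   construction at every depth; the allele-fraction filter order
   applies all depth/fraction gates before any test, reconciling the
   two published descriptions of the procedure.

Downstream, per-individual mutation counts (zero-filled) are compared
by Mann-Whitney U (exact enumeration up to 8 per group, tie-corrected
normal approximation above), per-gene prevalence by Fisher exact, the
substitution spectrum is collapsed onto the six pyrimidine-referenced
classes, the disruptive subset keeps MODERATE/HIGH impact calls, and
candidate drivers are flagged at >= 7 reports in haematopoietic and
lymphoid malignancies.

**Detection power.** Power to reject the heterozygous null declines
steeply as the clone's allele fraction approaches the heterozygous
band: at ~100x coverage, a clone at VAF 0.40 differs from a het mean of
~0.46 by barely one binomial standard deviation, so a large share of
such clones is indistinguishable from germline heterozygotes at
significance 0.05. Clones at VAF <= 0.30 with coverage >= 60 are
recovered with sensitivity above 0.9 (a property the test suite
verifies); over the full simulated VAF range 0.15–0.40 overall
sensitivity is materially lower, which is an intrinsic property of
binomial testing at this coverage, not an implementation artifact.
Specificity is the design priority: the putative screen's rejection
region is constructed analytically, and simulated germline
heterozygous sites are flagged at a rate at most 1e-5.

# Polygenic risk scores

`GRS = sum(A_i * beta_i)` with `A_i` the effect-allele dosage (0/1/2;
dosage is flipped when the effect allele is the reference allele).
Missing-SNP handling is explicit: below a 10% missingness ratio terms
are simply skipped; above it, proxy substitution searches a local LD
reference panel for the highest-r² candidate present in both panel and
cohort, accepted only above r² = 0.8, inheriting the original weight
(ties break toward the lower genomic position; the proxy's effect
allele is oriented by the sign of its dosage correlation with the
target). The search is local rather than a web-service lookup so the
pipeline has no network dependency.

Score distributions are compared with an assumption-gated location
test: Shapiro-Wilk per group and Levene's (mean-centered) variance test
at significance 0.05 select between Student's t and Wilcoxon. The gates
are named explicitly in the report because the choice of test is part
of the result. A logistic regression of group on score provides the
Wald p alongside.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
study conditions: cohort sizes 81/36 with the study sex composition;
control genotypes in Hardy-Weinberg equilibrium at MAF drawn uniformly
from a configurable range, with planted loci at specified allelic odds
ratios (case allele odds = control odds x OR); 162/72 haplotypes with a
planted carrier sequence at configurable per-group frequencies
(defaults 0.35/0.75, the frequencies of the most significant published
cluster); negative-binomial coverage (means 110x cases / 90x controls,
size 30 — overdispersed, so quantile normalization is non-trivial);
binomial read draws at 0.47 (het), 0.99 (hom-alt), 0.01 (error); and
per-individual per-gene somatic clones at uniform VAF in [0.15, 0.4]
with prevalence 0.15 (cases) versus 0.30 (controls), chosen so the
expected per-individual burden across seven genes reproduces the
published medians (one mutation in cases, two in controls) — the
younger controls carry the heavier clone load, the study's central
somatic finding.

What the generator does **not** emulate: genome-wide LD structure
(haplotype windows are independent), mapping artifacts, batch effects
in allele fraction beyond a single reference-bias constant, and
clone-size distributions beyond a uniform VAF law. Passing tests
therefore demonstrate the correctness and calibration of the
statistical machinery under the modelled structure, not robustness to
alignment-level artifacts of real sequencing.

# Numerical choices and problem sizes

All randomness flows through `set.seed` on user-supplied seeds;
identical seeds reproduce every simulated object exactly. Fisher exact
p-values use a relative tolerance of 1e-7 when comparing hypergeometric
point probabilities (guarding ties lost to floating point). Logistic
fits cap at 50 IRLS iterations with deviance tolerance 1e-8. The test
suite sizes its simulations for a desk-scale machine: null calibration
uses 5,000 variants for logistic association, 600 null genes for the
burden test, and 1,000 replicates for score comparisons; the exhaustive
Fisher-versus-enumeration check covers every 2x2 table with total at
most 60; the designed-FPR simulation uses one million heterozygous
sites.

# Known limitations

- The permutation max-T adjustment and the collapsing burden test are
  stand-ins for windowed-adjustment and variance-component methods; the
  published p-values of those tools are not reproduction targets.
- The somatic caller's sensitivity is bounded by binomial power near
  the heterozygous band (see above).
- Relatedness screening and population-structure correction beyond PCA
  outlier removal are not implemented.
- Published odds ratios that cannot be reconstructed from printed
  marginals (one sex-adjusted logistic OR; one haplotype row whose
  printed OR is inconsistent with its printed frequencies) carry no
  comparison target.
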