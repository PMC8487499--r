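---
title: "Methods: sex-linked marker discovery and hemizygous copy-number detection from GBS data"
author: "zwscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-linked marker discovery from GBS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwscan)
```

# The problem

In dioecious species with young, homomorphic sex chromosomes, the
sex-determining (SD) region is small and barely diverged, so sex cannot be
read off karyotypes or coverage alone. Genotyping-by-sequencing (GBS) of a
panel of sexed, largely unrelated accessions gives thousands of biallelic
markers with per-allele read counts, and three questions become statistical
ones:

1. Which markers are associated with sex?
2. Is the species female-heterogametic (ZW) or male-heterogametic (XY)?
3. Do any sex-associated markers actually reflect *copy-number* differences
   — hemizygous, sex-limited duplications whose paralogous reads collapse
   onto one marker — rather than an ordinary SNP?

`zwscan` implements this inference chain for willow-like panels (a few
hundred accessions, ~60/40 female/male, ~20k markers), plus a simulator
that generates populations with known truth so every stage can be verified
end to end.

# Genotype calling and marker QC

Diploid genotypes are called per cell from the allele depths $(r, a)$ by
maximising the binomial read likelihood with per-read miscall rate $e$
(default 0.01):

$$ P(r, a \mid \text{hom ref}) \propto (1-e)^r e^a,\quad
   P(r, a \mid \text{het}) \propto 2^{-(r+a)},\quad
   P(r, a \mid \text{hom alt}) \propto e^r (1-e)^a. $$

Cells with total depth below 5 reads are no-calls; likelihood ties go to
the heterozygote. The calling rule is deliberately simple — the upstream
pipelines used in practice apply the same two ingredients (an ML decision
and a depth floor) and we claim equivalence only at that level.

Two marker filters mirror standard practice: association markers need a
call rate of at least 75% and minor allele frequency (MAF) strictly above
5%; kinship/structure markers need 95% completeness and MAF of at least
1%. MAF is always computed on called genotypes (two alleles per called
diploid). Both filters are idempotent and report per-criterion removals.

# Association: exact tests and a kinship-aware mixed model

Because sex is dichotomous, the primary scan is a per-marker exact test of
independence between sex and genotype class on the 2×2 or 2×3 contingency
table (Freeman–Halton): the p-value sums, over all tables with the observed
margins, the hypergeometric point probabilities not exceeding the observed
one. `fisher_exact_rc()` enumerates tables in log space with log-gamma
factorials, so p-values of order $10^{-70}$ — routine for a perfect sex
marker in a 265-accession panel — are computed without underflow. A
relative tolerance of $10^{-12}$ guards the "as or more extreme"
comparison so that tied tables are never excluded by floating-point
noise. Significance is controlled family-wise by Bonferroni at
$\alpha = 0.05$ (flag: $p < \alpha/m$, strictly).

The complementary mixed linear model guards against population structure
and relatedness. Sex is coded 0/1 and, following the behaviour of the
standard MLM GWAS tools, modelled as Gaussian:

$$ y = Q\gamma + x\beta + u + \varepsilon,\qquad
   u \sim N(0, \sigma_g^2 K),\quad \varepsilon \sim N(0, \sigma_e^2 I), $$

with $Q$ an intercept plus the top principal components of the dosage
matrix (default 2; the PCA is a stand-in for externally inferred discrete
structure) and $K$ a VanRaden-type realized-relationship matrix — centred
dosage cross-product scaled to unit mean diagonal, bent to positive
semidefiniteness if needed. One spectral decomposition of $K$ is shared
across markers; the variance ratio $\lambda = \sigma_g^2/\sigma_e^2$ is
re-estimated for *every* marker (no population-parameters-previously-
determined shortcut) by profiling the REML criterion on a log-spaced
bracket and refining with `optimize()`. The marker p-value is a Wald
F-test on $\beta$. With $K = I$ and intercept-only covariates the fit
collapses exactly to ordinary least squares, a limiting case the test
suite checks to machine precision. Missing dosages are mean-imputed per
marker; dropping accessions instead would force a fresh eigendecomposition
per marker for little statistical gain at these missingness levels.

**Proximal contamination.** When the kinship set contains only a few
hundred markers, the sex-linked minority contributes a visible "sex
eigenvector" to $K$, and the polygenic term absorbs part of a perfect
marker's effect — MLM p-values for saturated markers then vary erratically
(the motivation for leave-one-chromosome-out estimators in the GWAS
literature). At realistic kinship sizes (thousands of markers, as in the
panels this package targets) the effect is negligible; the rank-
concordance test uses 1200 autosomal markers for this reason.

# Segregation classes and heterogamety

For each significant marker the genotype counts are re-expressed in the
rare-allele (b) orientation and classified:

* **w_strict** — no male carries b and at least half the females do: the
  fingerprint of a fully W-linked allele under female heterogamety;
* **w_loose** — male b-carrier fraction ≤ $\tau_m$ (default 0.05) and the
  female carrier fraction exceeds the male one by ≥ $\tau_\Delta$
  (default 0.3): W-linked with leakage from rare Z–W recombination,
  shared ancestral alleles, or single miscalled reads;
* **z_poly** — males homozygous for b at ≥ $\tau_z$ (default 0.1) while
  females (almost) never are: two alleles segregating on Z over a
  monomorphic W;
* **ambiguous** otherwise.

The thresholds are numeric stand-ins for verbal patterns ("entirely /
almost entirely exclusive to females") and are all configurable; nothing
in the biology pins them to particular values. Note that at 1% read error
and depth 20 across a hundred males, a truly strict W marker has an
appreciable chance of showing one miscalled male carrier and being
classified loose — strict/loose is a statement about the observed table,
not about latent linkage.

Heterogamety is a majority vote: each marker is classified as observed and
with the sexes swapped; W-linked or Z-polymorphic patterns vote for female
heterogamety in the first orientation and male heterogamety in the second.
The verdict reports the winning fraction as its support. No formal model
selection between ZW and XY is attempted — the vote mirrors how such
evidence is actually argued.

# Dosage diagnostics and collapsed paralogs

A well-behaved ("textbook") marker — fully called, common, in
Hardy–Weinberg equilibrium (pooled-sex 1-d.f. chi-square, p > 0.05) —
behaves dose-dependently in read space: an allele's mean depth in
heterozygotes is about half its mean depth in homozygotes, and total depth
is sex-independent. Collapsed paralogs break these rules, and three
deterministic flags capture the breakage:

* **compensation violation** — some het/hom allele-depth ratio outside
  $[0.5 - \delta, 0.5 + \delta]$ (default $\delta = 0.15$). Ratios are
  only computed for classes with at least `n_min = 12` called accessions:
  the ratio's sampling error is roughly $0.5\,\mathrm{cv}\sqrt{2/n}$ and
  GBS depths have coefficient of variation near 0.5, so 12 accessions put
  the noise near $\delta/2$; smaller classes are reported untestable
  rather than misjudged.
* **elevated sex depth ratio** — female:male mean total depth (over *all*
  accessions, called or not) at least 2, guarded by a Welch test at
  p < 0.01 because depths are overdispersed.
* **depth outlier** — marker mean total depth more than 3 s.d. above the
  textbook reference distribution (median/MAD fallback when no textbook
  marker exists).

Under the model that males carry one locus and females $1 + k$ loci of a
tag, the female:male depth ratio estimates $1 + k$, so
`estimate_extra_copies()` reports $\hat k = \text{ratio} - 1$ (floored at
0) with a seeded bootstrap interval over accessions.

Reference copy counting consumes BLAST-style hit tables for the tag
(`count_tag_copies()`, strict e-value comparison). The combined verdict
(`sex_specific_copy_model()`) calls a tag *female-specific multicopy* when
the female-derived reference holds more than one copy, the depth ratio is
elevated, and $\hat k$ agrees (tolerance 1) with the number of copies on
scaffolds that the *linkage map* anchors to the SD chromosome. Copies on
scaffolds placed only by cross-species alignment count as supporting, not
decisive — a deliberately conservative reading, since external-only
placements are the weakest link in draft assemblies. With the bundled
published tables (five reference copies: three on a linkage-anchored
chromosome-15 scaffold, one unanchored, one on chromosome 9) and a depth
ratio of 31.9/9.0, the verdict is female-specific multicopy with
$\hat k \approx 2.5$ against 3 anchored SD-chromosome copies.

# Scaffold anchoring

Scaffolds are assigned to chromosomes by a strict majority (> 50%) of
linkage-map marker hits passing `evalue < 1e-10`; ties or pluralities
yield `NA`, matching how ambiguous scaffolds are reported in practice. The
centre position is the median map position (cM) of supporting hits —
published tables print a single "centre" without defining it, and the
median is robust to stray hits. For conflict detection against a second
reference, W/Z sub-labels collapse to the chromosome number ("Chr15W"
agrees with "15") but are reported verbatim.

# The simulator

`simulate_population()` generates the study conditions the analysis
assumes: by default 265 accessions with expected female fraction 162/265,
2000 autosomal markers, five strictly W-linked, three partially W-linked
(70% of W haplotypes), two Z-polymorphic and two collapsed-paralog
markers with two extra female copies.

* **Depth law**: reads per diploid locus are negative binomial with mean
  `mean_depth` (default 20) and size `depth_dispersion` (default 12,
  chosen so that a mean-60 marker shows s.d. ≈ 19, the overdispersion
  reported for real GBS textbook markers; `Inf` gives Poisson). The field
  offers no canonical GBS depth family; NB is a modelling choice.
* **Allele assignment**: a locus's reads split binomially between its two
  haplotypes; every read's allele is miscalled independently with
  probability `error_rate` (default 0.01).
* **Paralog superposition**: at paralog tags everyone carries one diploid
  locus monomorphic for the common allele; females additionally carry
  `extra_w_copies` hemizygous W-linked loci whose reads carry the rare
  allele. Reads from all copies are summed per allele *before* genotype
  calling, so female total depth is $(1+k)\,\mu$ in expectation versus
  $\mu$ in males and females are called heterozygous — the collapsed-
  paralog phenotype.
* **Z-polymorphic frequencies** are drawn from U(0.4, 0.5): the class is
  only recognisable when males are commonly homozygous rare
  (rate $q^2$), and a near-balanced Z polymorphism keeps that rate well
  clear of the $\tau_z$ threshold even after binomial sampling across
  ~100 males. Lower-frequency Z variants exist in reality but are
  statistically indistinguishable from ambiguous markers at this panel
  size.
* **Structure**: discrete subpopulations with Balding–Nichols-perturbed
  frequencies (`fst_like_divergence`), the simplest structure matching a
  discrete-covariate MLM.
* **Missingness**: cells masked independently at `missing_rate`, default
  0.03 — at that rate roughly the same share of markers passes the 95%
  kinship filter as in the real panels this emulates.
* Sex is Bernoulli(`female_fraction`) then fixed; at least one accession
  of each sex is enforced. Optionally some phenotype records are masked
  `unknown` for filter testing.

What the simulator does **not** emulate: linkage disequilibrium and
recombination maps (markers are independent), pedigree structure,
sequence-level tag artefacts (restriction-site polymorphism, allele
dropout correlated with divergence), depth correlation between markers on
one tag, and variable copy number among carrier females (a fixed $k$ per
marker). Passing recovery tests on simulated data therefore demonstrates
the statistical machinery under the stated generative model, not
robustness to every real-data pathology.

# Numerical and design choices

* Exact-test tie handling: point probabilities compared with relative
  tolerance $10^{-12}$; log-sum-exp for the final sum.
* REML profiling: 21-point log grid on $\lambda \in [10^{-5}, 10^5]$,
  then golden-section/parabolic refinement in the bracketing interval;
  eigenvalues floored at 0; singular per-marker designs are skipped and
  logged.
* Kinship bending: negative eigenvalues floored at zero, matrix rescaled
  to unit mean diagonal.
* Degenerate contingency tables (a zero margin) give p = 1 by convention.
* Monomorphic HWE input gives statistic 0, p 1; the statistic is
  invariant under allele relabelling.
* Bootstrap intervals are seeded and the global RNG state is restored, so
  pipeline runs are bitwise reproducible for a fixed seed.
* Problem sizes in the test suite: the exact-test sweep covers every 2×2
  and 2×3 table with $n \le 25$; calibration and recovery checks use
  265 accessions with 2000 markers (10–20 replicates), the package's
  desk-scale rendition of the study design.

# Known limitations

* The binary trait is modelled with a Gaussian MLM for fidelity to the
  standard tools, not because it is statistically optimal; a logistic
  mixed model would be the principled alternative.
* Heterogamety inference is a vote, not a likelihood comparison; highly
  unbalanced marker ascertainment could bias it.
* The extra-copy estimator assumes all female-specific copies amplify
  like the shared locus; PCR/mapping efficiency differences between
  copies bias $\hat k$ toward the efficient copies.
* Strict/loose W classification reflects observed tables; it cannot
  distinguish rare Z–W recombination from genotyping error (both appear
  as male b-carriers).
* Scaffold anchoring trusts the linkage map over external alignment by
  construction; a systematically wrong map would propagate.
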