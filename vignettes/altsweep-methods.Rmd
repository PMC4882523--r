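---
title: "Detecting high-altitude selective sweeps with altsweep: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting high-altitude selective sweeps with altsweep: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altsweep)
```

## The problem

Populations that colonised high-altitude environments — Tibetan sheep among
them — carry genomic footprints of positive selection around loci involved in
the hypoxia response (the *EPAS1*/HIF axis, erythropoiesis, angiogenesis).
With medium-density SNP-array genotypes from a highland group (G1) and a
lowland group (G2), such sweeps can be localised by combining two
complementary statistics:

* **per-SNP differentiation**, the Weir–Cockerham fixation index
  $F_{ST}$, which responds to allele-frequency divergence between the
  groups regardless of haplotype structure; and
* **cross-population extended haplotype homozygosity (XP-EHH)**, which
  responds to the long, unusually homozygous haplotypes that a recent sweep
  drags to high frequency in one population before recombination erodes
  them.

`altsweep` implements the full desk pipeline around these statistics —
quality control, population-structure diagnostics, both scans, the
upper-quantile intersection rule, gene annotation, and the follow-up
genotype–phenotype association — together with a synthetic-data generator so
that every stage is testable without access to any particular study's
genotypes.

## Quality control and allele orientation

Per-SNP filters follow array practice: minor allele frequency strictly
above `maf_min` (default 0.01, computed over **all** samples jointly),
missing rate strictly below `missing_max` (default 0.05), and the X
chromosome excluded (`exclude_chroms = "X"`). A SNP failing several filters
is attributed to the first failing criterion in the order MAF, missingness,
chromosome, so the QC report's counts sum to the number removed.

Dosages are oriented once at load time (against a supplied allele table, or
the panel-wide minor allele) and that orientation is reused in every group.
Re-orienting per group would silently corrupt between-group frequency
comparisons and the differentiation estimates built from them.

## Population structure

* **LD pruning** follows the PLINK `--indep-pairwise` semantics: sliding
  windows of `window_snps` SNPs (default 25) advanced by `step_snps`
  (default 5), removing SNPs until no retained pair within a window exceeds
  `r2_max` (default 0.05). $r^2$ is the squared Pearson correlation of
  mean-imputed dosage vectors, which keeps the procedure deterministic in
  the presence of missing calls. Inside a window the first offending pair in
  index order loses the member with more missing calls (ties drop the later
  position).
* **IBS distances**: for each sample pair, one minus the mean proportion of
  shared alleles over jointly non-missing SNPs.
* **Classical (Torgerson) MDS** on the IBS distance matrix, as in PLINK's
  `--mds-plot`, with no square-root transform of the distances. Axes are
  sign-fixed (first non-zero loading positive) so results are reproducible.
  Eigenvalues below $10^{-8}$ of the largest are treated as numerical noise:
  their columns are zeroed and a warning recorded, rather than letting
  rounding artefacts masquerade as structure.
* **Nucleotide diversity** per breed uses the unbiased per-site
  heterozygosity $\sum_j 2p_j(1-p_j)\,n_j/(n_j-1)$ divided by
  `total_sites`. The denominator represents the surveyed sequence length;
  with array data it is unknowable, so the default (the SNP count) yields a
  *per-SNP* diversity useful for ranking breeds, not an absolute per-bp
  $\pi$. Matching any particular study's absolute $\pi$ values is therefore
  out of scope by design.
* **Pairwise multi-locus $F_{ST}$** between breeds is the ratio-of-sums
  estimator $\sum_\ell a_\ell / \sum_\ell (a_\ell+b_\ell+c_\ell)$ over loci
  with defined components; negative multi-locus values are clipped to zero
  only when the matrix is used as a distance.
* **Neighbour joining** on that matrix uses the Saitou–Nei algorithm (via
  `ape::nj`); negative branch lengths, which NJ can produce on non-additive
  inputs, are clipped to zero with the residual transferred to the sister
  edge so leaf-to-leaf path lengths are preserved as far as possible. The
  raw pairwise-$F_{ST}$ matrix is used directly (no
  $F_{ST}/(1-F_{ST})$ linearisation), matching how such trees are usually
  drawn from breed panels; linearisation can be applied by the caller
  before `nj_tree()` if desired.

## The Weir–Cockerham estimator

For two populations with per-locus diploid sample sizes $n_i$, alt-allele
frequencies $p_i$ and observed heterozygote proportions $h_i$,
`wc_components()` computes the among-population ($a$), among-individual
($b$) and within-individual ($c$) variance components through the standard
intermediates $\bar n$, $n_c$, $\bar p$, $s^2$ and $\bar h$, and
$\theta = a/(a+b+c)$. Monomorphic loci (zero total variance) and loci with
fewer than two genotyped diploids in either group are flagged undefined
rather than raised as errors, since a genome scan must tolerate them.
Fixed differences give exactly $\theta = 1$; negative $\theta$ values are
kept for ranking (clipping happens only in distance-matrix use).

## EHH, iHH and XP-EHH

EHH at distance $x$ from a core SNP is the probability that two randomly
chosen haplotypes are identical over the whole segment from the core out to
$x$. `altsweep` pools **all** haplotypes of a population at the core (the
cross-population convention) rather than conditioning on core alleles,
because the cross-population comparison asks whether one population is
homozygous where the other is polymorphic. The curve starts at $(0, 1)$ and
each extension partitions haplotypes by identity of the segment including
the core allele; EHH is $\sum_k \binom{m_k}{2} / \binom{n}{2}$ over
partition class sizes.

The decay curve is truncated when it first drops below `ehh_cutoff`
(default 0.05, point retained), when the extension passes
`max_extension_bp` (default 1 Mb), when an inter-SNP gap exceeds
`max_gap_bp` (default 200 kb), or at a chromosome end, with the reason
recorded. These three limits are not properties of the statistic but of
array data: without them, long monomorphic stretches and assembly gaps
produce unbounded, incomparable integrals. The defaults follow common
practice in haplotype-scan software and are configurable in
`scan_config()`.

iHH is the trapezoidal integral of $\max(\mathrm{EHH} - \text{cutoff}, 0)$
over physical distance (the array provides no genetic map), summed over
both sides. If either side is truncated *before* decaying below the cutoff,
the integral is incomparable between populations and the score at that core
is recorded as undefined — these are the "null" XP-EHH scores that the
candidate rule later rescues. The raw score is
$\ln(\mathrm{iHH}_{obs}/\mathrm{iHH}_{ref})$ with G1 (highland) observed
and G2 (lowland) reference, standardized to mean 0 and SD 1 over all
defined scores genome-wide, so positive scores point at selection in the
highland group.

The partition update at each extension is the hot loop of the whole
pipeline and is implemented in C++ (as the established haplotype-scan tools
do); `ehh()`, `ihh()` and `xpehh_scan()` all share that single code path,
and the test suite checks it against an $O(n^2)$ pair-enumeration oracle.

## Candidate selection and annotation

`top_quantile()` selects the $\lceil qM \rceil$ largest defined values
($M$ = number of defined scores), including all boundary ties, and reports
the smallest selected value as the threshold. This ceiling-with-ties rule
reproduces the arithmetic of published "top 1%" counts (e.g. 464 out of
46,355 distinct scores).

Candidates are the intersection of the $F_{ST}$ upper tail (default top 1%)
and the XP-EHH upper tail (default top 5%), **plus** the rescue set: SNPs
in the $F_{ST}$ tail whose XP-EHH is undefined. The rescue rule matters
because strong sweeps approaching fixation are precisely the cases where
EHH may not decay below the cutoff within the allowed span, nulling the
score at the most interesting loci. The two sets are disjoint by
construction.

Genes (from GFF3 via `rtracklayer`, or 6-column BED) are reported when any
candidate SNP falls within `gene_flank_bp` (default 25 kb) of the gene
span. The flank is a reporting choice, not an inference about any study's
procedure: array SNPs tag regulatory neighbourhoods, and 25 kb is a
conservative tagging radius for livestock LD; it is configurable.

## Genotype–phenotype association

The follow-up stage mirrors a candidate-gene workup of six haematological
traits (RBC, HGB, HCT, MCV, MCH, MCHC):

* allele-count chi-squared tests (2×2, no continuity correction — the
  reproducible closed form $N(ad-bc)^2/((a{+}b)(c{+}d)(a{+}c)(b{+}d))$)
  between the groups;
* an ordinary least-squares general linear model of each trait on genotype
  (unordered factor — published comparisons are between genotype classes,
  not dosages; an additive coding can be fitted by recoding the calls) plus
  sex, with the overall genotype effect as the F-test of the full against
  the sex-only model and adjusted means computed at balanced sex weighting;
* Fisher's LSD post hoc: unadjusted pairwise t-tests on the adjusted means
  using the model's residual variance and degrees of freedom;
* Welch two-sample comparisons of each trait between the highland and
  lowland phenotype tables, overall and stratified by sex.

Missing trait values are dropped listwise per trait. A design in which
genotype is confounded with sex is refused with an explicit error rather
than silently dropping terms. No multiple-testing correction is applied
across variants at this stage, matching how such candidate follow-ups are
reported; the scan stage, not the association stage, is the discovery
filter.

## The synthetic-data generator

`sim_config()` defines the package's reference study conditions: two groups
of 40 diploids, 10,000 SNPs on three 50-Mb chromosomes (~15 kb spacing),
background differentiation $F = 0.08$, and a sweep to frequency 0.9 over a
1-Mb span centred on chromosome 1 at 25 Mb.

* **Frequencies** follow the Balding–Nichols model: ancestral frequencies
  uniform on (0.05, 0.95) and group frequencies
  $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ independently per group, so the
  expected Weir–Cockerham differentiation is close to $F$. The chosen
  default $F = 0.08$ sits in the 0.05–0.1 range typical of divergent
  domestic sheep breed groups.
* **Haplotypes** are drawn SNP-wise with a latent first-order Gaussian
  copying process (AR(1) coefficient `rho = 0.3`, restarting at chromosome
  boundaries, marginals exactly Bernoulli($p_j$)), giving geometrically
  decaying baseline LD.
* **The sweep is mechanical**: a fraction of G1 haplotypes equal to the
  sweep frequency is overwritten with one shared donor haplotype across the
  span, with the alternate allele forced at the core for carriers and the
  reference allele for non-carriers (so the core frequency is exact). This
  guarantees the long-shared-haplotype signature that XP-EHH is supposed to
  detect, which is the property under test — it is not a forward simulation
  of selection dynamics.
* **Phenotypes** are baseline + genotype effect + sex effect + Gaussian
  noise. The genotype effect applies to RBC, MCV and MCH (the traits that
  altitude-adaptation follow-ups typically find associated); sex effect and
  noise apply to all six traits; baselines are typical ovine haematology
  values. Sexes alternate for balance.

Every generator is a pure function of the configuration, seed included
(`withr::with_seed`), so fixture bundles are byte-reproducible; the
manifest is written last so a partial bundle is detectable by its absence.

What the generator does **not** emulate: realistic recombination maps and
hotspots, mutation-age structure within haplotypes, breed-level admixture
and relatedness within groups, ascertainment bias of array SNP selection,
and genotyping error. Passing tests on this generator therefore demonstrate
the statistical machinery (estimators, truncation rules, quantile logic,
calibration), not field performance on any particular real panel.

## Numerical choices and degenerate inputs

* Undefined quantities (monomorphic $\theta$, frequencies with zero
  non-missing calls, undecayed iHH) are sentinel-flagged, never silently 0.
* $r^2$ involving a zero-variance dosage vector is treated as 0 (such SNPs
  cannot exceed any pruning threshold).
* `top_quantile` ties at the boundary are all included, so the selected set
  may exceed $\lceil qM \rceil$.
* Two groups with zero variance and equal means compare with $t = 0$,
  $p = 1$ by convention.
* MDS eigenvalues below $10^{-8}$ of the largest are zeroed (see above).
* Chromosome labels sort lexicographically; variants are kept sorted by
  (chromosome, position) in every container.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run entirely on generated
data, scaled to keep a complete run within a few minutes on one core: the
oracle comparisons use 200 random haplotype sets (≤ 20 haplotypes, ≤ 50
SNPs) and 1,000 random loci; calibration and recovery checks use the
reference conditions above (10,000 SNPs, 2 × 40 diploids) with 20 sweep and
20 matched null replicates; the null-calibration of the association model
uses 500 simulated fits at $n = 60$. These sizes are the package's own
choices for a fast, deterministic check of every claim made here.

## Known limitations

* XP-EHH uses physical distance; if a genetic map exists it must be
  baked into the `pos` column by the caller (map-aware integration is not
  implemented).
* The scan assumes pre-phased haplotypes and refuses unphased or missing
  genotypes in the haplotype stage; phasing uncertainty is not propagated.
* Binary PLINK (BED) input, imputation and admixture-model structure
  analysis are out of scope; the STRUCTURE-style analysis a full study
  would add belongs to external tools.
* The NJ tree carries no bootstrap support values.
* Absolute nucleotide diversity depends on an externally supplied
  `total_sites`; per-SNP values are only rank-comparable between breeds
  genotyped on the same panel.
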