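---
title: "Calling archaic introgressed SNPs and testing them for disease association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling archaic introgressed SNPs and testing them for disease association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Non-African genomes carry roughly 1–3% Neandertal-derived DNA from
admixture pulses around 50–60 thousand years ago. An allele shared between
an archaic genome and modern non-Africans can however have two origins:
recent admixture, or incomplete lineage sorting (ILS) — ancestral
polymorphism that survived the archaic–modern split in both lineages. The
two leave very different haplotype footprints, and telling them apart is
the core inference this package implements, followed by the standard
case-control association machinery used to test the resulting archaic
SNPs (aSNPs) against a disease phenotype.

## The aSNP calling model

A panel variant is a *candidate* archaic allele when

a. the allele is shared between the archaic genome and at least one
   non-African population,
b. it is absent from the African outgroup population,
c. the archaic individual is homozygous for it.

Criteria (a)–(c) cannot exclude ILS alleles that have drifted out of the
African outgroup. The fourth criterion is a length test. On each
non-African haplotype, maximal runs of consecutive candidate sites at
which the haplotype carries the archaic allele form *segments*
(`build_segments()`); a run is broken by a candidate site carrying the
non-archaic allele. Recombination breaks ancestral segments down at rate
`r_bp` per bp per generation (1 cM/Mb = 1e-8), so a segment surviving by
ILS has been exposed to recombination over the whole divergence — both
branches — and its expected length is

    E[L] = 1 / (r_bp * G_div),

with `G_div` the total branch generations since divergence (default
`2 * 550000 / 29`, i.e. 550 ky per branch at 29 years per generation;
both knobs sit in `ils_config()` because neither is known precisely).
The local rate `r_bp` is the mean recombination rate over the segment,
interpolated from a HapMap-format genetic map. Tract lengths under
recombination breakdown are modelled as exponential (memoryless), so the
probability that a segment of length `l` is consistent with ILS is the
tail

    p = exp(-l / E[L]),

strictly decreasing in `l` with `p(0) = 1` (`ils_pvalue()`). All segment
p-values in a run form one family and are corrected with the
Benjamini–Hochberg step-up; candidates lying on at least one segment with
adjusted p below 0.05 are called aSNPs (`call_asnps()`).

Numerical conventions worth knowing:

* zero local recombination makes a segment untestable: `E[L]` is an
  infinite sentinel and the p-value is 1, never a division error;
* a segment needs at least `min_markers = 2` markers — a single marker
  spans zero length, has p = 1 by construction, and would only inflate
  the BH family;
* with two genetic maps and `conservative_two_maps = TRUE`, each segment
  uses the larger of the two expected lengths, which makes ILS harder to
  reject;
* all internal coordinates are 0-based half-open; conversion to the
  1-based VCF convention happens only in `read_vcf()`/`write_vcf()`;
* a missing archaic genotype makes a site ineligible (conservative);
* segment construction itself is the one step the underlying literature
  leaves unspecified; the run-based reading used here is deliberately
  isolated behind `build_segments()` so an alternative construction can
  be swapped in.

## The synthetic-data generator

`simulate_panel()` is a tract-level renewal-process simulator, not a
coalescent. That choice is deliberate: it is fast enough to run hundreds
of times in a test suite and it produces exactly the signal the length
test relies on, with per-haplotype ground truth for free.

* *Introgressed tracts* are placed independently per non-African
  haplotype by alternating exponential gaps and exponential tract lengths
  with mean `1/(r_bp * g_adm)` (defaults: `g_adm = 1900` generations,
  about 55 ky; genome fraction `p_adm = 0.02`). Lengths are drawn in
  genetic-map distance and mapped back to base pairs, so rate
  heterogeneity is honoured.
* *ILS tracts* are genome-level entities with mean length
  `1/(r_bp * g_div)` covering fraction `q_ils = 0.01` of the genome; each
  haplotype in every population carries a given entity with probability
  `ils_carrier_p = 0.25` (a package choice — only "random haplotypes" is
  implied by the biology), except that with probability
  `pi_afr_loss = 0.3` an entity is absent from all African haplotypes.
  That last knob creates the two ILS sub-cases a caller must face: tracts
  caught by outgroup sharing, and tracts only the length test can catch.
* *Markers*: archaic-marker site positions are drawn once genome-wide at
  density `mu_arch = 1e-3` per bp, so sites are shared across the panel;
  a site carries the derived allele exactly on haplotypes whose tract
  covers it and is homozygous derived in the archaic pseudo-genome.
  Background SNPs (density `mu_bg = 1e-3`) get uniform random
  frequencies and an ancestral archaic genotype. The African outgroup
  never loses the ancestral allele at a background site — the outgroup is
  the reservoir of ancestral diversity, and without this property pure
  sampling noise in a small simulated outgroup would manufacture
  spurious criterion-(b) candidates that no length test could remove.
  Optional missingness and allele-flip error rates add realism on top.

What the generator does *not* emulate: genealogical noise in tract
lengths (a full ancestral recombination graph would add variance around
the exponential means), mutation loss inside tracts, selection,
demographic size changes, and LD structure in the background SNPs.
Passing tests therefore demonstrate that the caller recovers the length
signal it models, under the stated admixture parameters — not that it is
robust to every feature of real 1000 Genomes data.

Phenotypes (`simulate_phenotypes()`) mirror the fitted model exactly:
Bernoulli status with logit equal to an intercept plus per-allele dosage
effects plus age and sex terms. `simulate_case_control()` draws a
retrospective case-control study at one SNP (controls Hardy–Weinberg,
cases tilted by `OR^g`), which is the cheap way to study estimator
behaviour at realistic cohort sizes (e.g. 2039 cases / 32 592 controls).

## Quality control

`run_qc()` applies the pre-association filters in a fixed order: variant
call rate (< 0.9 removed), sample call rate (< 0.75), heterozygosity
(beyond 3 SD of the panel mean — two-sided, because both contamination
and inbreeding/genotyping failure are artefacts, although excess is the
classical direction), relatedness (PLINK-style method-of-moments PI_HAT
above 0.2; the lower-call-rate member of a pair is removed), principal
component outliers (6 SD on the top 8 components, iterated once so a
gross outlier cannot mask itself by inflating the SD), Hardy–Weinberg
(Pearson chi-square P below 1e-6; when case/control labels are available
the test runs in controls only, so true risk alleles are not discarded),
and imputation quality (INFO r² below 0.7; variants without a score are
kept and logged). PI_HAT moment estimates are clamped at zero and
renormalised; boundary values sit exactly at the thresholds with strict
inequalities, matching the stated rules.

## Association

`fit_logistic()` is a covariate-adjusted logistic regression
(`stats::glm`, IRLS tightened to epsilon 1e-12) reporting the per-allele
log odds ratio, Wald SE, OR with 95% CI (multiplier 1.959964) and
two-sided Wald p — the quantities a GWAS table prints. Complete and
quasi-separation is flagged with a warning, never silent.
`logistic_scan()` is a vectorised Newton solver over all variants at once
that agrees with `glm` to the convergence tolerance and makes
genome-scale null experiments affordable. LD is the squared dosage
correlation (composite r², valid without phase); `ld_dprime()` uses
phased haplotype counts. Pruning is greedy by ascending p-value with
position tie-breaks, so each LD block keeps its lowest-p variant; the
independent-test count uses the same greedy construction in position
order at r² < 0.8, and the Bonferroni threshold is `alpha / m`. The
genomic inflation factor is the median association chi-square over
0.4549. For summary-statistics replication, `concordance_filter()`
requires every study to be nominally significant with the same effect
direction, and refuses to flip mismatched effect alleles silently.

## Validation design and problem sizes

The package validates itself against its own generator:

* tract-length calibration pools eight simulated chromosomes of 10 Mb
  (3 African + 30 non-African diploids, marker densities reduced to
  1e-4/bp since only tracts matter there), giving >500 tracts per origin;
  empirical means sit within 10% of `1/(r_bp G)` for both origins;
* caller accuracy uses the 10 Mb, 50-diploids-per-population panel at
  default parameters; precision and sensitivity are measured at the site
  level against truth tracts. Shrinking `g_div` towards `g_adm` over
  three settings makes ILS tracts approach admixture-tract lengths and
  sensitivity falls monotonically — the expected failure mode of any
  length-based test;
* the null-phenotype control uses a 5 Mb panel with 600 non-African
  diploids (enough minor-allele carriers for Wald statistics to be
  calibrated at aSNP frequencies of a few percent) and 100 phenotype
  seeds. Family-wise control is checked per seed (no aSNP beyond the
  Bonferroni threshold). The inflation factor is computed on the pooled
  null statistics of all seeds: within one 5 Mb chromosome the aSNP
  statistics are strongly correlated within introgressed tracts, so a
  per-seed median fluctuates with the effective number of independent
  tracts (a few hundred), not the nominal aSNP count; pooling across
  seeds restores the precision the +-0.05 band implies.

## Limitations

Single-chromosome processing per call (loop and concatenate for genome
scale); diploid unphased archaic input only (the modern panel must be
phased); no Denisovan three-way attribution; the exponential tail is the
simplest defensible tract-length law — a heavier-tailed alternative would
make calling more conservative; and the published cohort results
themselves (consortium genotypes, 389k-aSNP catalogues) are not
reproducible without the restricted-access data, which is precisely why
the generator exists.
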