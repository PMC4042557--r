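---
title: "Methods: run-based CNV calling and lnRH sweep scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: run-based CNV calling and lnRH sweep scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvsweep)
```

## What the package models

`cnvsweep` implements a desk-scale reconstruction of a CNV-discovery and
selective-sweep workflow for two recently diverged wild populations
screened on a high-density comparative genome hybridization (CGH) array.
The pipeline has five analytic stages plus a synthetic-data generator:

1. **CNV calling** from probe-level log2 ratios by a consecutive-probe
   threshold rule, with a probe-density filter.
2. **Population differentiation** of cross-sample CNV loci by a
   one-tailed hypergeometric test on carrier counts.
3. **Feature overlap** of calls with exon/intron models under a
   fraction-of-CNV rule.
4. **Expression association**: Spearman correlations of CNV size with
   differential-expression statistics, Fisher enrichment of CNVs among
   differentially expressed (DE) versus invariant genes, and a binomial
   direction-concordance test.
5. **Sweep scan**: per-locus expected heterozygosity, the lnRH statistic
   between populations, standardized against a neutral microsatellite
   panel.

## The CNV caller

A probe with log2 ratio $r$ is exceedant when $|r| > \tau$ with
$\tau = 0.5$ by default. A CNV is a *maximal* run of at least $m = 3$
consecutive exceedant probes of uniform sign within one target region.
Choices the rule's prose leaves open, resolved here:

- **Uniform sign per run.** Every call must be classified amplification
  or deletion; a sign change terminates a run. A mixed-sign run has no
  classifiable copy state.
- **Strict inequality** at $\tau$ ($r > 0.5$, not $\ge$).
- **No bridging.** A single sub-threshold probe always breaks a run
  (some commercial segmentation algorithms bridge such probes; this
  implementation never does).
- **Region boundaries.** Probes in different target regions (gene
  $\pm$ 10 kb) are not consecutive on the array, so runs cannot span
  regions even when regions abut.
- **Coordinates.** Call length is first-probe start to last-probe end,
  half-open; probe density is length divided by probe count, and calls
  sparser than one probe per 2 kb (density $> 2000$ bp/probe, boundary
  inclusive) are removed, which suppresses calls built from the sparse
  genome-wide backbone probes.

Population comparisons use the asymptotic two-sample Kolmogorov-Smirnov
test on size/probe/density distributions, a two-sided Mann-Whitney U
with normal approximation and tie correction (no continuity correction)
on per-sample counts, and a two-sided Fisher exact test on the sign-by-
population table. No multiple-testing correction is applied at this
stage; raw p-values are reported. The original deletions-versus-
amplifications comparison (1449 vs 419, Mann-Whitney) does not state its
sampling unit; we compare per-sample deletion counts against per-sample
amplification counts and note the ambiguity.

## Differentiating loci

Per-sample calls are clustered into loci by single-linkage over
same-sign, same-chromosome calls with at least 1 bp of overlap. The
matching rule is not stated in the source analysis; single linkage is
the most permissive rule that still reports one footprint per region,
which is consistent with a reported 0.5 Mb amplification spanning
several genes. Each sample carries at most one flag per locus.

A locus differentiates the populations when one population has at least
4 carriers, the other at most 1, and the one-tailed hypergeometric
probability of an asymmetry at least that extreme (carriers distributed
uniformly over the 10 samples) is below 0.05. The test is one-tailed
because the carrier rule is directional by construction. Note the
tension this creates for 4-vs-1 splits: $P = 26/252 \approx 0.103$, so a
4-vs-1 locus can never pass $\alpha = 0.05$ even though it meets the
count rule; only 4-vs-0, 5-vs-0 and 5-vs-1 splits can. We implement the
rule as stated and document rather than resolve the tension.
Benjamini-Hochberg-adjusted p-values are emitted as an extra labeled
column but never drive the flag.

## Feature overlap

Intervals are 0-based half-open everywhere internally; GFF3 input is
converted at the reader. A (CNV, feature) pair is recorded when the
intersection covers at least 10% of the CNV's length, evaluated
per feature (whether the original analysis merged adjacent features
first is unstated). Element counts deduplicate features; a feature hit
by several CNVs counts once, and the per-class median overlap fraction
is taken over elements using each element's deepest overlap. Strand is
ignored: CGH calls are unstranded.

## Expression association

Genes with no CNV enter the size-versus-expression Spearman correlation
with size 0, so the correlation runs over the whole tested panel (a
`carriers_only` flag restricts it). The two-sided Fisher exact p uses
the minimum-likelihood summation convention. For direction concordance,
a locus overlapping several genes takes the gene with the smallest
expression p-value; a gene with DE calls of opposite sign in different
tissues is classified "opposing_tissues". The concordance test is an
exact binomial on expected-versus-opposite counts at success
probability 1/2, two-sided via the doubled smaller tail, capped at 1.

## Sweep scan

Expected heterozygosity uses the unbiased gene-diversity estimator
$H = \frac{2n}{2n-1}\left(1 - \sum_i \hat p_i^2\right)$ from the $2n$
observed allele copies. A monomorphic locus is assigned the
heterozygosity obtained if exactly one of the $2n$ copies differed
(equal to $2/2n$), preventing a zero $\hat\theta$ in the ratio below.

Under the stepwise mutation model,
$\hat\theta = \frac{1}{2}\left[\left(\frac{1}{1-H}\right)^2 - 1\right]$,
and $\mathrm{lnRH} = \ln(\hat\theta_1 / \hat\theta_2)$; the 1/2 factors
cancel. Which population is the numerator is fixed by configuration and
recorded in the output, since the sign interpretation depends on it.
Candidate lnRH values are standardized against the neutral panel
($z$ with the sample standard deviation, $n - 1$), and loci with
$|z| > 2$ are flagged. The original scan describes $|z| > 2$ as
"p < 0.01"; under a standard normal null $|z| > 2$ corresponds to
$p \approx 0.046$, and the calibration source is unstated, so the
package applies the fixed cutoff as printed and does not recompute the
claimed p.

Region verdicts: "sweep-candidate" when any flanking locus is flagged;
"low-diversity-both" when every locus has both populations' $H$ below
the 5th percentile (configurable) of the neutral panel's pooled $H$ —
the pattern expected for a sweep predating the population split or for
parallel sweeps; otherwise "no-signal". Inconsistent flags within a
region are reported verbatim.

## The synthetic-data generator

The generator emulates the *stated world* of the study design, not its
unpublished raw data:

- **CGH**: 2 populations x 5 samples; probes tiled deterministically,
  left-anchored, one per 170 bp over gene regions extended 10 kb both
  ways; 60-mer probes. Injected CNVs are 200 bp to 600 kb (log-uniform),
  with copy states mapped to shifts by $\log_2(c/2)$; homozygous
  deletions get a finite floor shift of $-3$ because arrays report
  background signal, not $-\infty$. Per-probe noise is Gaussian. The
  empirical noise of the source arrays is unpublished; the default
  `noise_sd = 0.15` is a stand-in chosen so that single noisy probes
  essentially never cross $\tau$ while 3-probe runs from true events
  always do at $|{\rm shift}| \ge 1$. A batch effect is modeled as a
  per-sample noise-sd multiplier (the study attributed its batch
  difference to probe-to-probe noise), not a probe-wise bias.
- **Microsatellites**: 2 populations x 46 diploids, 64 neutral loci
  plus candidates; di- or tri-nucleotide ladders of 5-15 repeats; an
  ancestral allele-frequency spectrum per locus drawn from a flat
  Dirichlet over 8 alleles, shared by both populations. A sweep is
  phenomenological: the target population's spectrum keeps a fraction
  `sweep_factor` of its mass and the rest collapses onto the major
  allele. The lnRH scan only consumes genotype frequencies, so no
  coalescent with linked selection is simulated.
- **Expression**: t statistics from a unit-variance normal, centered at
  0 for non-DE genes (p-values exactly uniform) and shifted by
  `effect_size` for DE genes; `coupling` forces that fraction of
  CNV-carrier genes DE with dosage-concordant sign.

What a green test does **not** establish: the generator has no GC
waves, dye bias, spatial artifacts, linkage between loci, population
structure or drift-mutation balance; recovery and calibration results
certify the algorithms against the generative model stated above, not
performance on real arrays or field genotypes. The headline counts of
the original study (1868 CNVs, 38 differentiating loci, specific KS and
Mann-Whitney p-values) depend on undeposited raw arrays and are not
desk-reproducible; tests therefore check combinatorial exactness,
oracle equivalence, recovery and calibration, plus the in-source
recomputable numbers.

## Numerical choices and degenerate inputs

- Medians use the midpoint-of-two convention (base R).
- Empty call sets yield zero counts with NA statistics, not errors.
- `standardize_lnrh` rejects a zero-variance neutral panel outright.
- Seeds: every generator takes one integer seed; the pipeline forks a
  per-stage seed by a fixed affine map kept below $2^{31}$.
- All randomness flows through R's default RNG; identical seeds give
  byte-identical outputs.

## Known limitations

- Copy number is never quantified beyond amplification/deletion sign;
  dosage differences between populations (e.g. 2x vs 4x everywhere) are
  invisible to the carrier-count rule, as in the original design.
- The clustering rule can chain distant calls through intermediaries
  (single-linkage behavior); with ~170 bp probe spacing and the density
  filter this is rarely material, but it is the permissive choice.
- Interval overlap is exact and unstranded; transcript isoforms,
  promoters and enhancers are out of scope.
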