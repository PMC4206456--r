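---
title: "Long-haplotype selection scans and GWAS catalogue evaluation with haploSweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-haplotype selection scans and GWAS catalogue evaluation with haploSweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploSweep)
```

## The problem

Recombination steadily breaks long haplotypes apart, so a haplotype that is
both uncharacteristically long and common is the classic imprint of a hard
selective sweep: a variant with a strong fitness advantage dragged one
genetic background to high frequency faster than recombination could erode
it. haploSweep implements a scan built on that signature, and around it the
machinery needed to ask a specific comparative-genomics question: do GWAS
risk alleles for a trait (here the motivating case is Type 2 diabetes and
obesity in East Asian populations, under the famine-selection "thrifty
gene" argument) actually sit on positively selected haplotypes, are they
the derived alleles, and are the selection signals specific to one ancestry
group?

The package evaluates that question in four steps per GWAS index SNP:

1. does the SNP fall inside a selection region, and is the selection
   East-Asian specific;
2. does the selected haplotype form carry the reported risk allele;
3. is the risk allele derived relative to an outgroup (chimpanzee) base;
4. how differentiated is the SNP between the ancestry groups
   (locus-specific $F_{ST}$).

A SNP "supports" the hypothesis only if it passes 1-3 with a *derived*
risk allele; step 4 quantifies differentiation for the survivors.

## The scan

A *haplotype form* is an ordered run of (SNP, allele) pairs. For a carrier
frequency bin $f$ (grid: $0.05, 0.10, \dots, 0.95$), the scan enumerates
every maximal form carried (missing genotypes counting as carriers) by at
least a fraction $f$ of chromosomes. Each form is measured two ways: the
genetic distance it spans (cM) and the number of SNPs it contains. Against
the genome-wide universe of $n_f$ candidate forms at its bin, a target form
receives two empirical rank p-values — the fraction of candidates at least
as long in cM, and at least as large in SNP count, ties counting — and the
selection score

$$ \mathrm{score} = p_{cM} \times p_{SNP} \times n_f, $$

with scores strictly below 0.05 flagged as evidence of positive selection.
Because a region long at frequency $f$ is usually long at every lower bin
too, overlapping significant signals of one population are collapsed to the
highest bin (ties: larger genetic length, then leftmost start), and the
collapsed signal's form is the one expected to carry the advantageous
allele.

### Search strategy

The candidate enumeration is exhaustive, not heuristic. Every chromosome
acts as a template: a two-pointer sweep per template finds all windows
$[i, j]$ that cannot be extended in either direction while keeping at least
$\lceil f \cdot 2N \rceil$ matching chromosomes, and the union over
templates is deduplicated and filtered to subset-maximal forms. When no
genotypes are missing this provably equals a brute-force enumeration of
every contiguous allele-specified window (the test suite checks exact set
equality against such an oracle on hundreds of random panels). We chose
this over greedy seed-and-extend growth after establishing that a greedy
carrier-maximizing step can permanently diverge from a maximal window (its
locally best allele choice need not lie on the globally longest form), so
greedy search cannot guarantee the enumeration semantics the score's rank
p-values assume. Greedy bidirectional growth *is* retained behind
`growLongestForm(..., skipAllowance > 0)`, where each side of the seed may
skip up to the allowed number of disrupting SNPs — a tolerance for
genotyping error that an exhaustive contiguous enumeration cannot express.

With missing data the template sweep treats a missing genotype as matching
any template (optimistic carrier counting, biased toward keeping carriers)
and breaks templates at their own missing sites; forms are then only
guaranteed maximal with respect to the observed templates.

### What "significant" means here

The score is a rank statistic, not a calibrated p-value. At every bin the
doubly-maximal candidate scores about $1/n_f$, which is below 0.05 whenever
the bin has more than 20 candidates — so on *any* panel, neutral or not,
the extremes of each bin are flagged. That is the method's design: it is a
genome-wide ranking screen whose hits are the uncharacteristically long
tails, and its discriminating power lies in *how far* a sweep exceeds the
neutral tail, not in the flag itself. Consequently the package's
operating-characteristic tests define detection and false positives as the
same matched event: "a significant signal at the target bin whose form
covers at least 90% of the (implanted, or would-be implanted) region's
SNPs". Implanted sweeps produce that event essentially always; neutral
panels essentially never, because their significant forms are one to two
orders of magnitude shorter than a sweep's span.

## Haplotype similarity index

A sweep seen in several populations can stem from one mutation event in
their common ancestor or from convergent events on different backgrounds.
The HSI between two selected forms is the fraction of identical alleles
over the SNPs present in both forms' site lists (matched by position;
bases compared when available). Values above 0.98 indicate a single shared
event, values below 0.9 convergent evolution; the closed band
$[0.9, 0.98]$ is reported as indeterminate because only the two open
regions are defined by the thresholds. Two identical forms give exactly
1.00.

## Locus-specific $F_{ST}$

For per-population frequencies $p_1, \dots, p_K$ with unweighted mean
$\bar p$,

$$ F_{ST} = \frac{\tfrac1K \sum_i (p_i - \bar p)^2}{\bar p (1 - \bar p)}, $$

the ratio of the observed frequency variance to the maximum variance
possible at the pooled frequency, hence bounded by $[0, 1]$ and exactly 1
for a fixed difference. Sample sizes are deliberately ignored (a `weights`
argument exists for a weighted variant); when $\bar p \in \{0, 1\}$ the
value is defined as 0. One property of this estimator matters for
simulation studies: under a Balding–Nichols model with divergence $F$, the
mean locus value across loci is approximately
$F \tfrac{K-1}{K} \big/ (1 - F/K)$, because the pooled mean absorbs
$1/K$ of the variance. With two demes the mean locus value is therefore
about $F/2$, not $F$; parameter-recovery checks in the test suite use ten
demes, where the bias is inside the tolerance, and the two-deme expectation
is tested against its own closed form. No Bessel-style correction is
applied: the divisor-$K$ variance is what keeps the statistic in $[0,1]$.

## The synthetic-data generator

`simulateStudy()` produces every input the pipeline consumes, with exact
truth records:

* **Neutral structure.** Per SNP an ancestral frequency is drawn uniformly
  from $[\texttt{mafFloor}, 1 - \texttt{mafFloor}]$ (default floor 0.05)
  and perturbed per population by a Balding–Nichols draw at the configured
  divergence. Each population receives `founderHaplotypeCount` (default
  20) founder haplotypes; each sampled chromosome is a Li–Stephens-style
  mosaic of founders with switch probability
  $1 - e^{-\rho\, d_{cM}}$ between adjacent SNPs
  (`mosaicSwitchRate` $\rho$, default 10 per cM), giving LD that decays
  with genetic distance. The genetic map is uniform at
  `recombRateCmPerMb` (default 1 cM/Mb).
* **Sweeps.** A hard sweep is implanted post hoc: one existing chromosome
  is chosen as donor and its region copied onto
  $\mathrm{round}(f \cdot 2N)$ randomly chosen chromosomes — exact control
  over the two quantities the scan estimates (carrier frequency and
  haplotype form), which forward simulation with selection coefficients
  would not give. `sharedOrigin` reuses one donor across populations
  (HSI 1 by construction), otherwise each population draws its own donor.
  An optional linked risk SNP is re-coded so allele 1 is the risk base,
  placed on or off the donor, and guaranteed present off-haplotype when
  off.
* **Catalogue.** `emitCatalog()` turns the truth records into a GWAS-style
  index-SNP table plus an outgroup-allele table, with configurable
  annotation (p-value, odds ratio, population-report flags).

What the generator does *not* emulate: demographic history (bottlenecks,
growth, admixture), soft or polygenic sweeps, genotyping error, strand
ambiguity, and the block-like LD of real recombination maps. Passing the
simulation suite therefore shows the implementation recovers implanted
truth under the stated model, not that the scan's operating
characteristics transfer to arbitrary real cohorts.

### Problem sizes used by the test suite

The recovery experiments run one population of 100 diploids (200
chromosomes), 400 SNPs over 8 Mb (1 cM/Mb), with a 3 Mb sweep at carrier
frequency 0.40 — roughly 20 kb marker spacing, and a sweep more than 20
times the median neutral form length at that bin, the regime the scan is
meant for. Fifty seeded sweep replicates and fifty neutral replicates are
scanned at the target bin; oracle-equivalence checks run on 200 random
panels of at most 16 chromosomes by 12 SNPs, where brute-force window
enumeration is affordable. Balding–Nichols recovery uses 1,000 loci at
divergence 0.01/0.05/0.1.

## The packaged reference tables

Two tables ship with the package (`loadPaperFixtures()`): six T2D index
SNPs with their alleles, ancestral states, association annotations and
population-report flags; and fifteen East-Asian long-haplotype regions
containing them, with haploPS scores, haplotype and allele frequencies and
found-on-haplotype flags. `reproduceFixtureEvaluation()` rebuilds the
four-step verdict table from these fixtures plus fixture-matched synthetic
panels (`fixtureSyntheticPanels()`), whose population sizes (84/85/96/86
diploids), haplotype frequencies, allele frequencies and donor structure
follow the printed values while everything else is random. The panels are
synthetic stand-ins — the underlying reference genotypes are not
redistributable — so only the printed quantities are reproduced.

One transcription quirk is preserved deliberately: the chromosome-15
region (61,999,328–62,941,185) does not contain the printed position of
its index SNP rs7172432 (60,183,681); the two appear to come from
different genome builds. Both are stored verbatim and no lift-over or
reconciliation is attempted, so under the printed coordinates that SNP
does not overlap its region and its risk-on-haplotype call is FALSE — the
same conclusion the printed table reaches ("not found on haplotype"),
via a coordinate route we do not try to repair.

## Numerical and boundary choices

* Internal coordinates are 1-based inclusive; BED export converts to
  0-based half-open. Region containment is boundary-inclusive.
* Carrier thresholds use $\lceil f \cdot 2N - 10^{-9}\rceil$ chromosomes;
  the epsilon guards against floating-point grid values.
* Genetic-map interpolation is linear between anchors and clamps to the
  nearest anchor outside the range (no extrapolated negative or unbounded
  cM at chromosome ends).
* Significance is strict (`score < 0.05`), association filtering is strict
  (`p < 5e-8`): values exactly at a threshold are excluded.
* Scan tie-breaks are fully deterministic: SNP count, then genetic length,
  then leftmost start, then lexicographically smallest allele string.
* When an index SNP lies within a form's span but is not a defining site,
  the allele the form carries is estimated from the form's carrier
  chromosomes; a base must reach a 0.9 majority (configurable) among
  non-missing carriers, otherwise the call is indeterminate. This is
  needed because printed allele frequencies exceed the printed haplotype
  frequencies, so the check cannot demand the SNP be a defining site.
* Outgroup comparison never strand-flips: a base matching neither
  catalogued allele is "unknown" rather than silently complemented.
* The degenerate $F_{ST}$ case $\bar p \in \{0, 1\}$ returns 0.

## Limitations

The scan targets hard sweeps; soft and polygenic sweeps dilute the
long-haplotype imprint below its detection logic, and no attempt is made
to capture them. The score is a ranking screen (see above), so "number of
significant signals" is not a false-positive rate; comparisons should
always be against matched neutral expectations. GWAS association
statistics are consumed as annotations, never recomputed, and no LD-based
tag-SNP expansion is attempted: an index SNP stands for its locus exactly
as printed.
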