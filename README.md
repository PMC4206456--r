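# haploSweep

Hard selective sweeps drag a single haplotype to high frequency faster
than recombination can break it apart, leaving an uncharacteristically
long, common haplotype as their imprint. haploSweep finds that imprint in
phased haplotype panels and uses it to evaluate a population-genetic
question about GWAS findings: do reported risk alleles (the motivating
case is Type 2 diabetes and obesity in East Asian populations, under the
"thrifty gene" famine-selection argument) sit on positively selected
haplotypes, are those alleles derived rather than ancestral, and is the
selection specific to one ancestry group?

It is intended for statistical geneticists who want a tested, scriptable
version of this analysis: a selection scan over phased panels, the
cross-population haplotype similarity index, locus-specific F<sub>ST</sub>,
a four-step GWAS-catalogue evaluation, and a simulator that generates
every input with known ground truth.

## The statistic at its core

For each carrier-frequency bin *f* in {0.05, 0.10, ..., 0.95}, the scan
enumerates every maximal haplotype form (contiguous allele-specified SNP
run) carried by at least a fraction *f* of chromosomes. A form is ranked
against the genome-wide universe of *n<sub>f</sub>* candidates at its bin
by two empirical p-values — the fraction of candidates spanning at least
as much genetic distance (p<sub>cM</sub>) and at least as many SNPs
(p<sub>SNP</sub>), ties counting — and scored as

```
score = p_cM x p_SNP x n_f        (score < 0.05 ==> putative positive selection)
```

Overlapping significant signals are collapsed to the highest frequency
bin, and the surviving form is the haplotype expected to carry the
advantageous allele. Two selected forms from different populations are
compared with the haplotype similarity index (HSI = fraction of identical
alleles over their shared SNPs; > 0.98 indicates a single shared mutation
event, < 0.9 convergent evolution). Population differentiation at an index
SNP uses the locus-specific fixation index, the ratio of the observed
allele-frequency variance across populations to the maximum variance
possible at the pooled frequency.

## Worked example

Simulate two populations (100 diploids each), implant a 3 Mb hard sweep at
carrier frequency 0.40 in CHB with a derived risk allele on the swept
haplotype, scan, and evaluate:

```r
library(haploSweep)

cfg <- simConfig(
  seed = 42, populationLabels = c("CHB", "CEU"), nDiploids = 100,
  nSnps = 400, chromosomeLengthBp = 8e6, divergence = 0.05,
  sweeps = list(sweepSpec(2.5e6, 5.5e6, carrierFrequency = 0.40,
                          populations = "CHB",
                          linkedRiskSnp = list(positionBp = 4e6,
                                               riskBase = "G",
                                               ancestralBase = "A",
                                               onHaplotype = TRUE))))
st  <- simulateStudy(cfg)
res <- scanSelection(st$panels$CHB, maps = st$map, grid = 0.40)
signalForms(res$reported)[[which.max(
  S4Vectors::mcols(signalRegions(res$reported))$snp_count)]]
#> HaplotypeForm chr1:2,441,823-5,523,362 (150 SNPs, 3.082 cM, carrier freq 0.400)
```

The sweep is recovered as a 150-SNP, 3.08 cM form at carrier frequency
0.40 — the doubly-maximal candidate among n<sub>f</sub> = 226 forms at the
bin, so its score is 1/226 ≈ 0.0044, well under 0.05. Evaluating the
emitted GWAS-style catalogue row against the reported signals:

```r
em <- emitCatalog(st$truth$sweeps[[1]], panels = st$panels)
evaluateCatalog(em$catalog, res$reported, panels = st$panels,
                outgroup = em$outgroup, eastAsian = "CHB", other = "CEU")
#>          rsid overlaps_selection risk_on_haplotype risk_is_derived supports_thrifty
#> 1 rs_sim00198               TRUE              true         derived             TRUE
```

The risk allele sits on the selected form, is derived, and the signal is
East-Asian specific, so this constructed case supports the hypothesis —
the configuration real data failed to produce. The risk-allele
frequencies behind step four: CHB 0.490 vs CEU 0.045, locus
F<sub>ST</sub> 0.253.

The packaged reference tables reproduce the published negative headline
instead:

```r
v <- reproduceFixtureEvaluation(seed = 1)$verdicts
sum(v$east_asian_specific_association)  # 3 index SNPs East-Asian-only
sum(v$risk_on_haplotype == "true")      # 3 risk alleles on selected forms
any(v$supports_thrifty)                 # FALSE: all three are ancestral
```

A thin CLI over the same functions lives at
`inst/scripts/haplosweep.R` (subcommands `simulate`, `scan`, `hsi`,
`fst`, `evaluate`, `run-all`).

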