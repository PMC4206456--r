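test_that("catalogue filtering is strict at the genome-wide threshold", {
  fx <- loadPaperFixtures()
  cat <- fx$gwas
  cat$p_value[cat$rsid == "rs1111875"] <- 5e-8  # exactly at the threshold
  kept <- filterCatalog(cat)
  expect_false("rs1111875" %in% kept$rsid)
  expect_true("rs7578597" %in% kept$rsid)      # 1e-9 passes
  expect_equal(nrow(filterCatalog(cat[0, ])), 0L)
  # duplicate rsIDs collapse to the most significant row
  dup <- rbind(fx$gwas, transform(fx$gwas[1, ], p_value = 1e-20))
  kept <- filterCatalog(dup)
  expect_equal(sum(kept$rsid == "rs7578597"), 1L)
  expect_equal(kept$p_value[kept$rsid == "rs7578597"], 1e-20)
  expect_equal(nrow(filterCatalog(fx$gwas, traits = "obesity")), 0L)
})

test_that("index SNPs overlap signals with inclusive boundaries", {
  fx <- loadPaperFixtures()
  sig <- fixtureSignals(fx$regions)
  r <- fx$gwas[fx$gwas$rsid == "rs7578597", ]
  ov <- overlapWithSignals(r, sig)
  expect_setequal(S4Vectors::mcols(signalRegions(ov))$population,
                  c("CHD", "CHS"))
  # a SNP exactly on a region boundary counts as inside
  edge <- r
  edge$position_bp <- 43282562L
  expect_equal(S4Vectors::mcols(signalRegions(
    overlapWithSignals(edge, sig)))$population, "CHD")
  edge$position_bp <- 43282561L  # one bp left of every chr2 region start
  expect_equal(length(overlapWithSignals(edge, sig)), 0L)
})

test_that("risk-allele-on-haplotype reads defining sites off the form", {
  pan <- toyPanel()
  fo <- growLongestForm(pan, 1, 0, f = 0.25)  # sites rs1..rs5, alleles 0
  row <- list(chromosome = "1", position_bp = 3500L,
              risk_allele = snpMeta(pan)$allele0[3])
  expect_equal(riskAlleleOnHaplotype(row, fo, pan), "true")
  row$risk_allele <- snpMeta(pan)$allele1[3]
  expect_equal(riskAlleleOnHaplotype(row, fo, pan), "false")
  outside <- list(chromosome = "1", position_bp = 12000L,
                  risk_allele = "C")
  expect_error(riskAlleleOnHaplotype(outside, fo, pan), "outside the form")
})

test_that("non-defining sites use the carrier majority with an indeterminate band", {
  # panel: 10 chromosomes; form defined on SNPs 1 and 3; SNP 2 inside the
  # span is not a defining site
  snps <- data.frame(rsid = c("a", "b", "c"), chromosome = "1",
                     position_bp = c(100L, 200L, 300L),
                     allele0 = "A", allele1 = "G",
                     cm_position = c(1e-4, 2e-4, 3e-4))
  H <- cbind(rep(0L, 10), c(rep(1L, 6), rep(0L, 4)), rep(0L, 10))
  pan <- HaplotypePanel("P", snps, H)
  fo <- HaplotypeForm("1", data.frame(
    index = c(1L, 3L), rsid = c("a", "c"), position_bp = c(100L, 300L),
    allele = c(0L, 0L), base = c("A", "A")), 2e-4, 1.0)
  row <- list(chromosome = "1", position_bp = 200L, risk_allele = "G")
  # carriers split 6/4: indeterminate under the default 0.9 threshold
  expect_equal(riskAlleleOnHaplotype(row, fo, pan), "indeterminate")
  expect_equal(riskAlleleOnHaplotype(row, fo, pan,
                                     majorityThreshold = 0.6), "true")
  H[, 2] <- c(rep(1L, 10))
  pan <- HaplotypePanel("P", snps, H)
  expect_equal(riskAlleleOnHaplotype(row, fo, pan), "true")
  row$risk_allele <- "A"
  expect_equal(riskAlleleOnHaplotype(row, fo, pan), "false")
})

test_that("ancestral classification compares the outgroup base literally", {
  expect_equal(classifyAncestral("T", "C", "T"), "ancestral")
  expect_equal(classifyAncestral("C", "T", "T"), "derived")
  expect_equal(classifyAncestral("C", "T", NA), "unknown")
  expect_equal(classifyAncestral("C", "T", "G"), "unknown")  # no strand flip
})

test_that("East-Asian specificity follows the report flags and signal populations", {
  fx <- loadPaperFixtures()
  sig <- fixtureSignals(fx$regions)
  ea <- c("CHB", "CHD", "CHS", "JPT")
  row <- fx$gwas[fx$gwas$rsid == "rs10229583", ]
  spec <- eastAsianSpecific(row, overlapWithSignals(row, sig), ea,
                            other = c("CEU", "TSI", "MXL"))
  expect_true(spec$assocSpecific)
  expect_true(spec$selectionSpecific)
  row2 <- fx$gwas[fx$gwas$rsid == "rs7578597", ]
  spec2 <- eastAsianSpecific(row2, overlapWithSignals(row2, sig), ea,
                             other = c("CEU", "TSI", "MXL"))
  expect_false(spec2$assocSpecific)  # reported in Europeans as well
  expect_true(spec2$selectionSpecific)
  # a signal in an unassigned population is a configuration error
  expect_error(eastAsianSpecific(row, overlapWithSignals(row, sig),
                                 c("CHD", "CHS", "JPT"), other = "CEU"),
               "CHB")
  # selection in both ancestry groups is not specific
  mixed <- fx$regions
  mixed$population[mixed$chromosome == "7" & mixed$population == "JPT"] <- "CEU"
  sigM <- fixtureSignals(mixed)
  specM <- eastAsianSpecific(row, overlapWithSignals(row, sigM), ea,
                             other = c("CEU", "TSI", "MXL"))
  expect_false(specM$selectionSpecific)
})

test_that("a derived risk allele on an East-Asian-specific sweep supports the hypothesis", {
  cfg <- simConfig(
    seed = 77, populationLabels = "CHB", nDiploids = 100, nSnps = 400,
    chromosomeLengthBp = 8e6,
    sweeps = list(sweepSpec(
      2.5e6, 5.5e6, 0.40, "CHB",
      linkedRiskSnp = list(positionBp = 4e6, riskBase = "G",
                           ancestralBase = "A", onHaplotype = TRUE))))
  st <- simulateStudy(cfg)
  res <- scanSelection(st$panels$CHB, maps = st$map, grid = 0.40)
  emitted <- emitCatalog(st$truth$sweeps[[1]], panels = st$panels)
  v <- evaluateCatalog(emitted$catalog, res$reported, panels = st$panels,
                       outgroup = emitted$outgroup, eastAsian = "CHB",
                       other = "CEU")
  expect_equal(nrow(v), 1L)
  expect_true(v$overlaps_selection)
  expect_true(v$east_asian_specific_association)
  expect_true(v$east_asian_specific_selection)
  expect_equal(v$risk_on_haplotype, "true")
  expect_equal(v$risk_is_derived, "derived")
  expect_true(v$supports_thrifty)
  # same construction with an ancestral risk allele cannot support it
  cfg2 <- cfg
  cfg2$sweeps[[1]]$linkedRiskSnp$ancestralBase <- "G"
  st2 <- simulateStudy(cfg2)
  res2 <- scanSelection(st2$panels$CHB, maps = st2$map, grid = 0.40)
  em2 <- emitCatalog(st2$truth$sweeps[[1]], panels = st2$panels)
  v2 <- evaluateCatalog(em2$catalog, res2$reported, panels = st2$panels,
                        outgroup = em2$outgroup, eastAsian = "CHB",
                        other = "CEU")
  expect_equal(v2$risk_is_derived, "ancestral")
  expect_false(v2$supports_thrifty)
})

test_that("verdict flags re-derive from their stored evidence", {
  fr <- reproduceFixtureEvaluation(seed = 3)
  v <- fr$verdicts
  rederived <- v$overlaps_selection & v$east_asian_specific_selection &
    v$risk_on_haplotype == "true" & v$risk_is_derived == "derived"
  expect_equal(v$supports_thrifty, rederived)
  expect_equal(v$east_asian_specific_association,
               fr$catalog$reported_east_asian[match(v$rsid, fr$catalog$rsid)] &
                 !fr$catalog$reported_european[match(v$rsid, fr$catalog$rsid)])
})
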