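test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- simConfig(seed = 12, populationLabels = c("A", "B"), nDiploids = 20,
                   nSnps = 100, chromosomeLengthBp = 2e6, divergence = 0.05,
                   sweeps = list(sweepSpec(5e5, 1.5e6, 0.5, "A")))
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(alleleMatrix(s1$panels$A), alleleMatrix(s2$panels$A))
  expect_identical(alleleMatrix(s1$panels$B), alleleMatrix(s2$panels$B))
  expect_identical(snpMeta(s1$panels$A), snpMeta(s2$panels$A))
  expect_equal(s1$truth$sweeps[[1]]$populations$A$carrierRows,
               s2$truth$sweeps[[1]]$populations$A$carrierRows)
  s3 <- simulateStudy(simConfig(seed = 13, populationLabels = c("A", "B"),
                                nDiploids = 20, nSnps = 100,
                                chromosomeLengthBp = 2e6))
  expect_false(identical(alleleMatrix(s1$panels$A), alleleMatrix(s3$panels$A)))
})

test_that("zero divergence gives near-identical population frequencies", {
  cfg <- simConfig(seed = 4, populationLabels = c("A", "B"), nDiploids = 150,
                   nSnps = 300, chromosomeLengthBp = 6e6, divergence = 0)
  sim <- simulateNeutralPanels(cfg)
  fa <- colMeans(alleleMatrix(sim$panels$A))
  fb <- colMeans(alleleMatrix(sim$panels$B))
  expect_identical(sim$truth$popFreq[, "A"], sim$truth$popFreq[, "B"])
  # only founder/mosaic sampling noise separates the realized frequencies
  expect_lt(mean(abs(fa - fb)), 0.12)
  expect_gt(cor(fa, fb), 0.75)
})

test_that("panel divergence tracks the Balding-Nichols parameter", {
  mkMean <- function(div, seed) {
    cfg <- simConfig(seed = seed, populationLabels = c("A", "B"),
                     nDiploids = 150, nSnps = 1000, chromosomeLengthBp = 2e7,
                     divergence = div)
    sim <- simulateNeutralPanels(cfg)
    fa <- colMeans(alleleMatrix(sim$panels$A))
    fb <- colMeans(alleleMatrix(sim$panels$B))
    keep <- (fa + fb) / 2 > 0 & (fa + fb) / 2 < 1
    mean(vapply(which(keep), function(i) locusFst(c(fa[i], fb[i])),
                numeric(1)))
  }
  m0 <- mkMean(0, 31)
  m10 <- mkMean(0.1, 31)
  # a two-deme design measures about half the parameter plus a sampling
  # floor shared by both settings
  expect_gt(m10 - m0, 0.025)
  expect_lt(abs((m10 - m0) - 0.05), 0.02)
})

test_that("sweep implantation hits the requested carrier count exactly", {
  cfg <- simConfig(seed = 8, populationLabels = "A", nDiploids = 100,
                   nSnps = 300, chromosomeLengthBp = 6e6)
  sim <- simulateNeutralPanels(cfg)
  res <- implantSweep(sim$panels, sweepSpec(1e6, 5e6, 0.40, "A"))
  tr <- res$truth$populations$A
  expect_equal(length(tr$carrierRows), 80L)  # round(0.40 * 200)
  expect_equal(tr$implantFrequency, 0.40)
  H <- alleleMatrix(res$panels$A)
  sites <- formSites(tr$form)
  for (r in tr$carrierRows[1:5]) {
    expect_equal(unname(H[r, sites$index]), sites$allele)
  }
  # carrier frequency 1.0 makes the region monomorphic
  res2 <- implantSweep(sim$panels, sweepSpec(1e6, 5e6, 1.0, "A"))
  H2 <- alleleMatrix(res2$panels$A)
  idx <- formSites(res2$truth$populations$A$form)$index
  expect_true(all(apply(H2[, idx], 2, function(col) length(unique(col)) == 1)))
  expect_error(implantSweep(sim$panels, sweepSpec(7e6, 8e6, 0.4, "A")),
               "no panel SNPs")
  expect_error(simConfig(seed = 1, populationLabels = "A", nDiploids = 2,
                         nSnps = 50, chromosomeLengthBp = 1e6,
                         sweeps = list(sweepSpec(1, 1e6, 0.05, "A"))),
               "zero chromosomes")
})

test_that("emitted catalogues carry the designated ancestral state", {
  cfg <- simConfig(
    seed = 9, populationLabels = "A", nDiploids = 50, nSnps = 200,
    chromosomeLengthBp = 4e6,
    sweeps = list(sweepSpec(
      1e6, 3e6, 0.5, "A",
      linkedRiskSnp = list(positionBp = 2e6, riskBase = "T",
                           ancestralBase = "T", onHaplotype = TRUE))))
  st <- simulateStudy(cfg)
  em <- emitCatalog(st$truth$sweeps[[1]], panels = st$panels,
                    reportedEastAsian = TRUE, reportedEuropean = FALSE)
  expect_equal(nrow(em$catalog), 1L)
  r <- em$catalog[1, ]
  expect_equal(classifyAncestral(r$risk_allele, r$no_risk_allele,
                                 em$outgroup$base[1]), "ancestral")
  # risk allele frequency at least the carrier frequency when on-haplotype
  expect_gte(r$risk_allele_frequency, 0.5)
  expect_error(emitCatalog(list(sweeps = list(list(riskSnp = NULL)))),
               "no linked risk SNP")
})

test_that("off-haplotype risk alleles stay off the donor and present elsewhere", {
  cfg <- simConfig(
    seed = 10, populationLabels = "A", nDiploids = 50, nSnps = 200,
    chromosomeLengthBp = 4e6,
    sweeps = list(sweepSpec(
      1e6, 3e6, 0.5, "A",
      linkedRiskSnp = list(positionBp = 2e6, riskBase = "T",
                           ancestralBase = "C", onHaplotype = FALSE))))
  st <- simulateStudy(cfg)
  tr <- st$truth$sweeps[[1]]
  col <- tr$riskSnp$column
  H <- alleleMatrix(st$panels$A)
  expect_true(all(H[tr$populations$A$carrierRows, col] == 0L))
  off <- setdiff(seq_len(nrow(H)), tr$populations$A$carrierRows)
  expect_gt(sum(H[off, col] == 1L), 0L)
})
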