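mkForm <- function(pos, alleles, bases = NULL, chrom = "1") {
  if (is.null(bases)) bases <- ifelse(alleles == 0, "A", "C")
  sites <- data.frame(index = seq_along(pos), rsid = paste0("r", pos),
                      position_bp = pos, allele = alleles, base = bases,
                      stringsAsFactors = FALSE)
  HaplotypeForm(chrom, sites, geneticLengthCm = max(pos) / 1e6,
                carrierFrequency = 0.5)
}

test_that("identical forms have HSI 1.00 and classify as a shared event", {
  a <- mkForm(seq(1000, 10000, by = 1000), rep(c(0L, 1L), 5))
  r <- hsi(a, a)
  expect_equal(r$value, 1.00)
  expect_equal(r$sharedSnpCount, 10L)
  expect_equal(r$classification, "shared_event")
})

test_that("fully discordant and boundary overlaps classify per the thresholds", {
  pos <- seq(1000, 10000, by = 1000)
  al <- rep(c(0L, 1L), 5)
  a <- mkForm(pos, al)
  b <- mkForm(pos, 1L - al)
  r <- hsi(a, b)
  expect_equal(r$value, 0)
  expect_equal(r$classification, "convergent")
  # 9 of 10 alleles equal: exactly 0.9, inside the indeterminate band
  al2 <- al
  al2[10] <- 1L - al2[10]
  r <- hsi(a, mkForm(pos, al2))
  expect_equal(r$value, 0.9)
  expect_equal(r$classification, "indeterminate")
  # just above the shared-event threshold
  pos50 <- seq(1000, 50000, by = 1000)
  al50 <- rep(0L, 50)
  al50b <- al50
  al50b[1] <- 1L
  expect_equal(hsi(mkForm(pos50, al50), mkForm(pos50, al50b))$value, 0.98)
  expect_equal(hsi(mkForm(pos50, al50), mkForm(pos50, al50b))$classification,
               "indeterminate")
})

test_that("disjoint site sets give no_overlap and chromosome mismatch errors", {
  a <- mkForm(c(1000, 2000), c(0L, 1L))
  b <- mkForm(c(5000, 6000), c(0L, 1L))
  r <- hsi(a, b)
  expect_equal(r$value, 0)
  expect_equal(r$sharedSnpCount, 0L)
  expect_equal(r$classification, "no_overlap")
  expect_error(hsi(a, mkForm(c(1000, 2000), c(0L, 1L), chrom = "2")),
               "different chromosomes")
})

test_that("HSI is symmetric, reflexive and invariant to site order", {
  set.seed(3)
  pos <- sort(sample(1e5, 20))
  a <- mkForm(pos, rbinom(20, 1, 0.5))
  b <- mkForm(pos[5:20], rbinom(16, 1, 0.5))
  expect_equal(hsi(a, b)$value, hsi(b, a)$value)
  expect_equal(hsi(a, a)$value, 1)
  perm <- sample(16)
  sitesPerm <- formSites(b)[perm, ]
  sitesPerm <- sitesPerm[order(sitesPerm$position_bp), ]
  b2 <- HaplotypeForm("1", sitesPerm, geneticLengthCm(b), 0.5)
  expect_equal(hsi(a, b2)$value, hsi(a, b)$value)
})

test_that("pairwise HSI matrices are symmetric with unit diagonal", {
  pos <- seq(1000, 20000, by = 1000)
  al <- rbinom(20, 1, 0.5)
  forms <- list(CHB = mkForm(pos, al), CHD = mkForm(pos, al),
                CHS = mkForm(pos, al), JPT = mkForm(pos, al))
  m <- pairwiseHsiMatrix(forms)
  expect_equal(m$value, t(m$value))
  expect_true(all(diag(m$value) == 1))
  expect_true(all(m$value[upper.tri(m$value)] == 1))
  expect_true(all(m$classification[upper.tri(m$classification)] ==
                    "shared_event"))
  one <- pairwiseHsiMatrix(forms[1])
  expect_equal(dim(one$value), c(1L, 1L))
  expect_equal(one$value[1, 1], 1)
})

test_that("shared-origin sweep donors are identical across populations, independent donors are not", {
  shared <- numeric(20)
  indep <- numeric(20)
  for (s in 1:20) {
    cfg <- simConfig(seed = s, populationLabels = c("POPA", "POPB"),
                     nDiploids = 50, nSnps = 200, chromosomeLengthBp = 4e6,
                     divergence = 0.05,
                     sweeps = list(sweepSpec(1e6, 3e6, 0.40,
                                             c("POPA", "POPB"),
                                             sharedOrigin = TRUE)))
    tp <- simulateStudy(cfg)$truth$sweeps[[1]]$populations
    shared[s] <- hsi(tp$POPA$form, tp$POPB$form)$value
    cfg2 <- simConfig(seed = 400 + s, populationLabels = c("POPA", "POPB"),
                      nDiploids = 50, nSnps = 200, chromosomeLengthBp = 4e6,
                      divergence = 0.05,
                      sweeps = list(sweepSpec(1e6, 3e6, 0.40,
                                              c("POPA", "POPB"),
                                              sharedOrigin = FALSE)))
    tp2 <- simulateStudy(cfg2)$truth$sweeps[[1]]$populations
    indep[s] <- hsi(tp2$POPA$form, tp2$POPB$form)$value
  }
  expect_true(all(shared > 0.98))
  expect_gte(mean(indep < 0.9), 0.95)
})
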