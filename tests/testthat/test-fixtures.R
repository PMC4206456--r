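test_that("packaged index-SNP table matches the printed rows", {
  fx <- loadPaperFixtures()
  g <- fx$gwas
  expect_equal(nrow(g), 6L)
  r <- g[g$rsid == "rs7578597", ]
  expect_equal(r$risk_allele, "T")
  expect_equal(r$no_risk_allele, "C")
  expect_equal(r$position_bp, 43586327L)
  expect_false(r$reported_east_asian)
  expect_true(r$reported_european)
  expect_equal(r$ancestral_allele, "T")
  expect_equal(r$p_value, 1e-9)
  expect_true(is.na(g$risk_allele_frequency[g$rsid == "rs5015480"]))
  expect_equal(g$risk_allele_frequency[g$rsid == "rs1111875"], 0.52)
})

test_that("packaged region table matches the printed rows", {
  fx <- loadPaperFixtures()
  reg <- fx$regions
  expect_equal(nrow(reg), 15L)
  chd2 <- reg[reg$population == "CHD" & reg$chromosome == "2", ]
  expect_equal(chd2$start_bp, 43282562L)
  expect_equal(chd2$end_bp, 43910360L)
  expect_equal(chd2$haplops_score, 0.017)
  expect_equal(chd2$hap_freq, 0.45)
  expect_equal(chd2$all_freq, 0.994)
  expect_true(chd2$found_on_hap)
  jpt7 <- reg[reg$population == "JPT" & reg$chromosome == "7", ]
  expect_equal(nrow(jpt7), 2L)
  expect_equal(unique(jpt7$hap_freq), 0.50)
  expect_false(any(reg$found_on_hap[reg$chromosome %in% c("10", "15")]))
})

test_that("fixture signals carry printed scores and are all significant", {
  fx <- loadPaperFixtures()
  sig <- fixtureSignals(fx$regions)
  expect_equal(length(sig), 10L)  # 15 rows collapse to 10 distinct regions
  mc <- S4Vectors::mcols(signalRegions(sig))
  expect_true(all(mc$significant))
  expect_true(all(mc$score < 0.05))
  expect_setequal(unique(mc$population), c("CHB", "CHD", "CHS", "JPT"))
})

test_that("the chr15 region does not contain its index SNP under printed coordinates", {
  fx <- loadPaperFixtures()
  sig <- fixtureSignals(fx$regions)
  row <- fx$gwas[fx$gwas$rsid == "rs7172432", ]
  expect_equal(length(overlapWithSignals(row, sig)), 0L)
})

test_that("fixture-matched synthetic panels honour printed frequencies", {
  fb <- fixtureSyntheticPanels(seed = 11)
  # CHD chr2: haplotype frequency 0.45, risk-allele frequency 0.994
  pan <- fb$panels$CHD
  row <- fb$gwas[fb$gwas$rsid == "rs7578597", ]
  col <- which(snpMeta(pan)$rsid == "rs7578597")
  freq <- alleleFrequencyOnPanel(pan, col, "T")
  expect_equal(freq, round(0.994 * 170) / 170, tolerance = 1e-9)
  form <- fb$forms[["CHD:2:43282562"]]
  expect_equal(carrierFrequency(form), round(0.45 * 170) / 170)
  expect_equal(form@spanStartBp, 43282562L)
  expect_equal(form@spanEndBp, 43910360L)
  # the same donor underlies CHD and CHS at the THADA locus
  r <- hsi(form, fb$forms[["CHS:2:43301270"]])
  expect_equal(r$value, 1)
  expect_equal(r$classification, "shared_event")
})
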