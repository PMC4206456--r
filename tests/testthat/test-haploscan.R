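test_that("a panel of identical chromosomes yields one all-SNP form at any bin", {
  pan <- toyPanel()
  H <- matrix(rep(alleleMatrix(pan)[1, ], each = 8), nrow = 8)
  pan <- HaplotypePanel("TOY", snpMeta(pan), H)
  fo <- growLongestForm(pan, 3, H[1, 3], f = 0.95)
  expect_equal(snpCount(fo), 6L)
  expect_equal(carrierFrequency(fo), 1.0)
  sc <- scanPopulation(pan, grid = 0.95)[[1]]
  expect_length(sc, 1L)
  expect_equal(snpCount(sc[[1]]), 6L)
})

test_that("the packaged toy panel matches the enumeration oracle at f = 0.25", {
  pan <- toyPanel()
  H <- alleleMatrix(pan)
  want <- sort(vapply(oracleMaximalWindows(H, 0.25), windowKey, character(1)))
  got <- sort(vapply(scanPopulation(pan, grid = 0.25)[[1]], formKey,
                     character(1)))
  expect_identical(got, want)
  # the longest grown form through any seed equals the oracle's longest
  lens <- vapply(oracleAllWindows(H, 0.25), function(w) w$end - w$start + 1L,
                 integer(1))
  best <- growLongestForm(pan, 1, 0, f = 0.25)
  expect_equal(snpCount(best), max(lens))
})

test_that("a seed below the frequency bin returns no form", {
  pan <- toyPanel()  # rs6 allele G (code 1) appears on 4/8 = 0.5
  expect_null(growLongestForm(pan, 6, 1, f = 0.75))
  expect_null(growLongestForm(pan, 4, 1, f = 0.30))  # rs4 T on 2/8 = 0.25
  expect_error(growLongestForm(pan, 99, 0, f = 0.25), "out of range")
})

test_that("greedy growth with a skip allowance bridges a disrupted site", {
  pan <- toyPanel()
  H <- matrix(rep(alleleMatrix(pan)[1, ], each = 8), nrow = 8)
  H[, 4] <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)  # SNP 4 splits the carriers
  pan <- HaplotypePanel("TOY", snpMeta(pan), H)
  noSkip <- growLongestForm(pan, 2, H[1, 2], f = 0.95, skipAllowance = 0)
  skip1 <- growLongestForm(pan, 2, H[1, 2], f = 0.95, skipAllowance = 1)
  expect_lt(snpCount(noSkip), snpCount(skip1))
  expect_false(4L %in% formSites(skip1)$index)  # skipped, not a site
  expect_equal(snpCount(skip1), 5L)
})

test_that("carrier sets shrink as the frequency bin rises (monotone growth)", {
  for (seedVal in c(3, 9)) {
    pan <- randomTestPanel(16, 12, seed = seedVal)
    for (col in seq_len(12)) {
      for (al in 0:1) {
        prev <- NULL
        for (f in c(0.125, 0.25, 0.5)) {
          fo <- growLongestForm(pan, col, al, f)
          if (is.null(fo)) break
          if (!is.null(prev)) {
            expect_lte(snpCount(fo), snpCount(prev))
            expect_lte(geneticLengthCm(fo), geneticLengthCm(prev))
          }
          prev <- fo
        }
      }
    }
  }
})

test_that("scans are deterministic", {
  pan <- randomTestPanel(20, 15, seed = 5)
  a <- scanSelection(pan, grid = c(0.25, 0.5))
  b <- scanSelection(pan, grid = c(0.25, 0.5))
  expect_equal(as.data.frame(a$candidates), as.data.frame(b$candidates))
})

test_that("empirical p-values count ties toward the numerator", {
  # lengths 0.5, 1, 2, 2, 3: a 2.0 cM target is matched-or-beaten by 3 of 5
  forms <- list(rankForm(5, 0.5), rankForm(6, 1), rankForm(7, 2),
                rankForm(8, 2), rankForm(9, 3))
  p <- empiricalPValues(forms[[3]], forms)
  expect_equal(p$p_cm, 3 / 5)
  expect_equal(p$p_snp, 3 / 5)  # counts 7, 8, 9
  # a unique double maximum among 100 forms ranks 1/100 in both metrics
  many <- c(lapply(1:99, function(i) rankForm(5 + (i %% 3), 0.2 + i / 1000)),
            list(rankForm(20, 5)))
  p <- empiricalPValues(many[[100]], many)
  expect_equal(p$p_cm, 0.01)
  expect_equal(p$p_snp, 0.01)
  # the genome-wide minimum in both metrics gets p = 1
  p <- empiricalPValues(forms[[1]], forms)
  expect_equal(p$p_cm, 1)
  expect_equal(p$p_snp, 1)
  expect_error(empiricalPValues(forms[[1]], list()), "empty")
})

test_that("the selection score is the p-value product times the universe size", {
  s <- haploPSScore(1, 1, 100)
  expect_equal(s$score, 100)
  expect_false(s$significant)
  s <- haploPSScore(0.01, 0.02, 100)
  expect_equal(s$score, 0.02)
  expect_true(s$significant)
  # unique double maximum among N: score 1/N, significant iff N > 20
  for (N in c(10, 20, 21, 100)) {
    s <- haploPSScore(1 / N, 1 / N, N)
    expect_equal(s$score, 1 / N)
    expect_equal(s$significant, N > 20)
  }
  expect_error(haploPSScore(0, 0.5, 10), "p-values")
  expect_error(haploPSScore(0.5, 0.5, 0), "nF")
})

test_that("scores are invariant under permutation of the candidate list", {
  pan <- randomTestPanel(16, 12, seed = 8)
  forms <- scanPopulation(pan, grid = 0.25)[[1]]
  target <- forms[[2]]
  p1 <- empiricalPValues(target, forms)
  set.seed(1)
  p2 <- empiricalPValues(target, sample(forms))
  expect_equal(p1, p2)
})

test_that("collapse keeps only the highest frequency bin among overlapping signals", {
  mkSig <- function(start, end, bin, score, pop = "POP1", cm = 1) {
    gr <- GenomicRanges::GRanges("1", IRanges::IRanges(start, end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      population = pop, frequency_bin = bin, p_cm = 0.01, p_snp = 0.01,
      n_f = 100L, score = score, significant = score < 0.05,
      carrier_frequency = bin, snp_count = 10L, genetic_length_cm = cm)
    SelectionSignalSet(gr, list(NULL))
  }
  sigs <- combineSignals(mkSig(100, 2000, 0.20, 0.01),
                         mkSig(150, 1900, 0.30, 0.01),
                         mkSig(200, 1800, 0.40, 0.01))
  out <- collapseToHighestFrequency(sigs)
  expect_equal(length(out), 1L)
  expect_equal(S4Vectors::mcols(signalRegions(out))$frequency_bin, 0.40)

  disjoint <- combineSignals(mkSig(100, 500, 0.20, 0.01),
                             mkSig(5000, 6000, 0.40, 0.01))
  expect_equal(length(collapseToHighestFrequency(disjoint)), 2L)

  single <- mkSig(1, 10, 0.4, 0.01)
  expect_equal(as.data.frame(collapseToHighestFrequency(single)),
               as.data.frame(single))
  # non-significant signals are dropped before collapsing
  expect_equal(length(collapseToHighestFrequency(mkSig(1, 10, 0.4, 0.5))), 0L)
  # ties on bin resolve by genetic length
  tied <- combineSignals(mkSig(100, 2000, 0.40, 0.01, cm = 1),
                         mkSig(100, 2000, 0.40, 0.01, cm = 2))
  out <- collapseToHighestFrequency(tied)
  expect_equal(S4Vectors::mcols(signalRegions(out))$genetic_length_cm, 2)
})

test_that("allele frequencies on a panel ignore missing chromosomes", {
  pan <- toyPanel()
  H <- alleleMatrix(pan)
  expect_equal(alleleFrequencyOnPanel(pan, 6, "G"), mean(H[, 6] == 1))
  H[, 1] <- 0L
  mono <- HaplotypePanel("TOY", snpMeta(pan), H)
  expect_equal(alleleFrequencyOnPanel(mono, 1, "A"), 1.0)
  H[1:2, 2] <- NA
  H[3, 2] <- 1L
  pan2 <- HaplotypePanel("TOY", snpMeta(pan), H)
  expect_equal(alleleFrequencyOnPanel(pan2, 2, "T"),
               mean(H[-(1:2), 2] == 1))
  expect_error(alleleFrequencyOnPanel(pan, 1, "T"), "not an allele")
})

test_that("missing genotypes count as carriers during growth", {
  pan <- toyPanel()
  H <- matrix(rep(alleleMatrix(pan)[1, ], each = 8), nrow = 8)
  H[5:8, 3] <- 1L   # split at SNP 3 ...
  H[5:6, 3] <- NA   # ... but two of the non-carriers are missing
  pan <- HaplotypePanel("TOY", snpMeta(pan), H)
  fo <- growLongestForm(pan, 1, H[1, 1], f = 0.75)
  # 4 definite carriers + 2 missing = 6/8 = 0.75 keeps SNP 3 in the form
  expect_true(3L %in% formSites(fo)$index)
  expect_equal(snpCount(fo), 6L)
})
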