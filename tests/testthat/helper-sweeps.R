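# Shared machinery for the sweep-recovery experiments: the detection event
# is "a significant signal at the target bin whose form covers at least
# `minRecovery` of the (implanted, or would-be implanted) region's SNPs" --
# the same event for sweep and neutral replicates.

sweepExperimentConfig <- function(seed, withSweep) {
  sweeps <- if (withSweep) {
    list(sweepSpec(2.5e6, 5.5e6, carrierFrequency = 0.40,
                   populations = "POP1"))
  } else list()
  simConfig(seed = seed, populationLabels = "POP1", nDiploids = 100,
            nSnps = 400, chromosomeLengthBp = 8e6, sweeps = sweeps)
}

# best fraction of the target site set covered by any significant signal at
# the bin; target sites given as "index allele" keys
bestRecoveryAtBin <- function(signalSet, targetKeys, bin) {
  mc <- S4Vectors::mcols(signalRegions(signalSet))
  hits <- which(mc$significant & abs(mc$frequency_bin - bin) < 1e-9)
  best <- 0
  for (k in hits) {
    fs <- formSites(signalForms(signalSet)[[k]])
    best <- max(best, mean(targetKeys %in% paste(fs$index, fs$allele)))
  }
  best
}

sweepReplicate <- function(seed, bins = 0.40) {
  st <- simulateStudy(sweepExperimentConfig(seed, withSweep = TRUE))
  res <- scanSelection(st$panels$POP1, maps = st$map, grid = bins)
  ds <- formSites(st$truth$sweeps[[1]]$populations$POP1$form)
  list(scan = res, truthKeys = paste(ds$index, ds$allele),
       panel = st$panels$POP1)
}

neutralReplicate <- function(seed, bins = 0.40) {
  st <- simulateStudy(sweepExperimentConfig(seed, withSweep = FALSE))
  res <- scanSelection(st$panels$POP1, maps = st$map, grid = bins)
  snps <- snpMeta(st$panels$POP1)
  idx <- which(snps$position_bp >= 2.5e6 & snps$position_bp <= 5.5e6)
  # the would-be implant covers every region SNP on either allele: count a
  # signal as a matched event if it covers >= 90% of the region's SNPs
  list(scan = res, regionIdx = idx)
}

neutralMatchedEvent <- function(rep, bin = 0.40, minRecovery = 0.9) {
  mc <- S4Vectors::mcols(signalRegions(rep$scan$candidates))
  hits <- which(mc$significant & abs(mc$frequency_bin - bin) < 1e-9)
  for (k in hits) {
    fs <- formSites(signalForms(rep$scan$candidates)[[k]])
    if (mean(rep$regionIdx %in% fs$index) >= minRecovery) return(TRUE)
  }
  FALSE
}
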