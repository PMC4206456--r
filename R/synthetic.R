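# Synthetic multi-population phased panels with realistic LD decay
# (Li-Stephens-style founder mosaics), Balding-Nichols divergence between
# populations, and implantable hard sweeps with exact truth records. Sweeps
# are implanted post hoc -- one donor haplotype copied to a chosen carrier
# count -- rather than forward-simulated, which gives exact control of the
# two quantities the scan estimates: carrier frequency and haplotype form.

#' Simulation configuration
#'
#' @param seed RNG seed; every downstream draw is reproducible from it.
#' @param populationLabels one label per population.
#' @param nDiploids diploid sample size per population (scalar recycled, or
#'   one value per population); a panel has `2 * nDiploids` chromosomes.
#' @param nSnps number of SNPs on the simulated chromosome.
#' @param chromosome chromosome label.
#' @param chromosomeLengthBp chromosome length in bp.
#' @param recombRateCmPerMb uniform recombination rate (cM/Mb).
#' @param founderHaplotypeCount founder haplotypes per population; sampled
#'   chromosomes are switch-point mosaics of these.
#' @param mosaicSwitchRate founder switch intensity (switches per cM);
#'   larger values give faster LD decay.
#' @param mafFloor lower bound of the ancestral allele-frequency spectrum,
#'   in (0, 0.5).
#' @param divergence Balding-Nichols divergence parameter in `[0, 1)`
#'   applied between populations.
#' @param sweeps list of [sweepSpec()] entries.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(seed = 1L, populationLabels = "POP1", nDiploids = 100L,
                      nSnps = 400L, chromosome = "1",
                      chromosomeLengthBp = 8e6L, recombRateCmPerMb = 1,
                      founderHaplotypeCount = 20L, mosaicSwitchRate = 10,
                      mafFloor = 0.05, divergence = 0, sweeps = list()) {
  nPops <- length(populationLabels)
  nDiploids <- rep(as.integer(nDiploids), length.out = nPops)
  stopifnot(nPops >= 1, all(nDiploids > 0), nSnps > 0,
            chromosomeLengthBp > nSnps, recombRateCmPerMb > 0,
            founderHaplotypeCount > 1, mosaicSwitchRate > 0)
  if (mafFloor <= 0 || mafFloor >= 0.5) stop("mafFloor must lie in (0, 0.5)")
  if (divergence < 0 || divergence >= 1) stop("divergence must lie in [0, 1)")
  for (sw in sweeps) {
    if (!inherits(sw, "SweepSpec")) stop("sweeps must be sweepSpec() objects")
    if (sw$endBp > chromosomeLengthBp) stop("sweep region outside chromosome")
    n2 <- 2 * nDiploids[match(sw$populations, populationLabels)]
    if (anyNA(n2)) stop("sweep population not in populationLabels")
    if (any(round(sw$carrierFrequency * n2) < 1)) {
      stop("sweep carrier frequency rounds to zero chromosomes")
    }
  }
  structure(list(seed = as.integer(seed), populationLabels = populationLabels,
                 nDiploids = nDiploids, nSnps = as.integer(nSnps),
                 chromosome = as.character(chromosome),
                 chromosomeLengthBp = as.integer(chromosomeLengthBp),
                 recombRateCmPerMb = recombRateCmPerMb,
                 founderHaplotypeCount = as.integer(founderHaplotypeCount),
                 mosaicSwitchRate = mosaicSwitchRate, mafFloor = mafFloor,
                 divergence = divergence, sweeps = sweeps),
            class = "SimConfig")
}

#' Sweep specification
#'
#' @param startBp,endBp sweep region (1-based inclusive).
#' @param carrierFrequency target carrier fraction in (0, 1]; the donor
#'   haplotype is copied onto `round(carrierFrequency * 2N)` chromosomes.
#' @param populations populations receiving the sweep.
#' @param sharedOrigin if `TRUE` one donor is used for all listed
#'   populations (a single ancestral mutation event); otherwise each
#'   population gets an independent donor drawn from its own panel
#'   (convergent evolution).
#' @param linkedRiskSnp optional list
#'   `list(positionBp=, riskBase=, ancestralBase=, onHaplotype=)`
#'   describing a GWAS-style risk SNP tied to the sweep; the SNP snaps to
#'   the nearest simulated site inside the region. With
#'   `onHaplotype = TRUE` the donor carries the risk base, otherwise the
#'   risk base occurs only off the donor haplotype.
#' @return a `SweepSpec` list.
#' @export
sweepSpec <- function(startBp, endBp, carrierFrequency, populations,
                      sharedOrigin = TRUE, linkedRiskSnp = NULL) {
  stopifnot(startBp >= 1, endBp >= startBp, length(populations) >= 1)
  if (carrierFrequency <= 0 || carrierFrequency > 1) {
    stop("carrierFrequency must lie in (0, 1]")
  }
  if (!is.null(linkedRiskSnp)) {
    need <- c("positionBp", "riskBase", "ancestralBase", "onHaplotype")
    if (!all(need %in% names(linkedRiskSnp))) {
      stop("linkedRiskSnp needs fields: ", paste(need, collapse = ", "))
    }
    if (linkedRiskSnp$positionBp < startBp || linkedRiskSnp$positionBp > endBp) {
      stop("linkedRiskSnp must lie inside the sweep region")
    }
  }
  structure(list(startBp = as.integer(startBp), endBp = as.integer(endBp),
                 carrierFrequency = carrierFrequency,
                 populations = populations, sharedOrigin = sharedOrigin,
                 linkedRiskSnp = linkedRiskSnp),
            class = "SweepSpec")
}

#' Simulate neutral multi-population panels
#'
#' Per SNP, an ancestral frequency is drawn uniformly from
#' `[mafFloor, 1 - mafFloor]` and perturbed per population by a
#' Balding-Nichols draw at the divergence parameter. Each population gets
#' `founderHaplotypeCount` founder haplotypes sampled from its frequencies,
#' and each sampled chromosome is a founder mosaic whose switch points
#' occur with probability `1 - exp(-mosaicSwitchRate * d_cM)` between
#' adjacent SNPs, so LD decays with genetic distance. The genetic map is
#' uniform at `recombRateCmPerMb`. Sweep specs in the config are ignored
#' here; see [implantSweep()] / [simulateStudy()].
#'
#' @param config a [simConfig()].
#' @return list with `panels` (named list of [HaplotypePanel-class]), `map`
#'   (a [geneticMap()]) and `truth` (ancestral and per-population
#'   frequencies plus the config).
#' @export
simulateNeutralPanels <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  M <- config$nSnps
  pos <- sort(sample.int(config$chromosomeLengthBp, M))
  cm <- pos * config$recombRateCmPerMb / 1e6
  basePairs <- t(vapply(seq_len(M), function(i) sample(BASES, 2),
                        character(2)))
  p <- runif(M, config$mafFloor, 1 - config$mafFloor)
  K <- length(config$populationLabels)
  popFreq <- simulateBaldingNichols(p, config$divergence, K)
  colnames(popFreq) <- config$populationLabels
  switchP <- 1 - exp(-config$mosaicSwitchRate * diff(cm))
  snps <- data.frame(rsid = sprintf("rs_sim%05d", seq_len(M)),
                     chromosome = config$chromosome, position_bp = pos,
                     allele0 = basePairs[, 1], allele1 = basePairs[, 2],
                     cm_position = cm, stringsAsFactors = FALSE)
  panels <- list()
  for (k in seq_len(K)) {
    nF <- config$founderHaplotypeCount
    founders <- matrix(rbinom(nF * M, 1L, rep(popFreq[, k], each = nF)),
                       nrow = nF, ncol = M)
    n2 <- 2L * config$nDiploids[k]
    H <- matrix(0L, nrow = n2, ncol = M)
    for (h in seq_len(n2)) {
      sw <- runif(M - 1) < switchP
      runId <- cumsum(c(1L, sw))
      ids <- sample.int(nF, max(runId), replace = TRUE)
      H[h, ] <- founders[cbind(ids[runId], seq_len(M))]
    }
    # guard against columns fixed for missingness-free monomorphism is fine;
    # monomorphic columns are legal panel content
    panels[[config$populationLabels[k]]] <-
      HaplotypePanel(config$populationLabels[k], snps, H)
  }
  map <- geneticMap(config$chromosome, c(1, config$chromosomeLengthBp),
                    c(1, config$chromosomeLengthBp) *
                      config$recombRateCmPerMb / 1e6)
  list(panels = panels, map = map,
       truth = list(ancestralFreq = p, popFreq = popFreq, config = config))
}

#' Implant a hard sweep into simulated panels
#'
#' Copies a single donor haplotype over the sweep region onto
#' `round(carrierFrequency * 2N)` randomly chosen chromosomes of each
#' listed population, emulating the long-haplotype imprint of a hard sweep.
#' The donor is an existing chromosome sampled from the (first listed, when
#' `sharedOrigin`) population's panel. An optional linked risk SNP is
#' re-labelled so that allele code 1 is the risk base, the donor carries
#' (or avoids) it per `onHaplotype`, and its presence off the haplotype is
#' guaranteed.
#'
#' @param panels named list of [HaplotypePanel-class] (as from
#'   [simulateNeutralPanels()]).
#' @param spec a [sweepSpec()].
#' @return list with modified `panels` and a `truth` record (per
#'   population: donor [HaplotypeForm-class], carrier rows, realized
#'   implant frequency; plus the risk-SNP bookkeeping).
#' @export
implantSweep <- function(panels, spec) {
  stopifnot(inherits(spec, "SweepSpec"))
  missingPop <- setdiff(spec$populations, names(panels))
  if (length(missingPop)) stop("panel(s) missing: ", paste(missingPop, collapse = ", "))
  ref <- panels[[spec$populations[1]]]
  snps <- snpMeta(ref)
  cols <- which(snps$position_bp >= spec$startBp &
                  snps$position_bp <= spec$endBp)
  if (!length(cols)) stop("sweep region [", spec$startBp, ", ", spec$endBp,
                          "] contains no panel SNPs")
  riskInfo <- NULL
  if (!is.null(spec$linkedRiskSnp)) {
    lr <- spec$linkedRiskSnp
    riskCol <- cols[which.min(abs(snps$position_bp[cols] - lr$positionBp))]
    nonRisk <- if (lr$ancestralBase != lr$riskBase) lr$ancestralBase
               else if (snps$allele0[riskCol] != lr$riskBase) snps$allele0[riskCol]
               else snps$allele1[riskCol]
    if (nonRisk == lr$riskBase) stop("cannot choose a non-risk base")
    # relabel so code 1 = risk base, in every panel (shared SNP metadata)
    for (nm in names(panels)) {
      s2 <- snpMeta(panels[[nm]])
      s2$allele0[riskCol] <- nonRisk
      s2$allele1[riskCol] <- lr$riskBase
      panels[[nm]] <- HaplotypePanel(population(panels[[nm]]), s2,
                                     alleleMatrix(panels[[nm]]))
    }
    riskInfo <- list(column = riskCol,
                     positionBp = snps$position_bp[riskCol],
                     rsid = snps$rsid[riskCol], riskBase = lr$riskBase,
                     nonRiskBase = nonRisk,
                     ancestralBase = lr$ancestralBase,
                     onHaplotype = isTRUE(lr$onHaplotype))
  }
  sharedDonor <- NULL
  truthPops <- list()
  for (popName in spec$populations) {
    pan <- panels[[popName]]
    H <- alleleMatrix(pan)
    n2 <- nrow(H)
    if (is.null(sharedDonor) || !spec$sharedOrigin) {
      donorRow <- sample.int(n2, 1)
      donor <- H[donorRow, cols]
      donor[is.na(donor)] <- 0L
      if (!is.null(riskInfo)) {
        donor[match(riskInfo$column, cols)] <-
          if (riskInfo$onHaplotype) 1L else 0L
      }
      if (spec$sharedOrigin) sharedDonor <- donor
    }
    if (spec$sharedOrigin) donor <- sharedDonor
    nc <- round(spec$carrierFrequency * n2)
    carrierIdx <- sample.int(n2, nc)
    H[carrierIdx, cols] <- matrix(donor, nrow = nc, ncol = length(cols),
                                  byrow = TRUE)
    if (!is.null(riskInfo) && !riskInfo$onHaplotype) {
      off <- setdiff(seq_len(n2), carrierIdx)
      if (length(off) && !any(H[off, riskInfo$column] == 1L, na.rm = TRUE)) {
        flip <- off[seq_len(max(1L, round(0.2 * length(off))))]
        H[flip, riskInfo$column] <- 1L
      }
    }
    pan <- HaplotypePanel(popName, snpMeta(pan), H)
    panels[[popName]] <- pan
    truthPops[[popName]] <- list(
      form = makeForm(pan, cols, donor, nc),
      carrierRows = sort(carrierIdx),
      implantFrequency = nc / n2
    )
  }
  list(panels = panels,
       truth = list(populations = truthPops, riskSnp = riskInfo, spec = spec))
}

#' Simulate a full study: neutral panels plus configured sweeps
#'
#' Convenience wrapper: [simulateNeutralPanels()] followed by
#' [implantSweep()] for every sweep in the config, all reproducible from
#' `config$seed`.
#'
#' @param config a [simConfig()].
#' @return list with `panels`, `map` and `truth` (`neutral` plus a `sweeps`
#'   list of implant truth records).
#' @export
simulateStudy <- function(config) {
  sim <- simulateNeutralPanels(config)
  panels <- sim$panels
  sweeps <- list()
  for (sw in config$sweeps) {
    res <- implantSweep(panels, sw)
    panels <- res$panels
    sweeps[[length(sweeps) + 1L]] <- res$truth
  }
  list(panels = panels, map = sim$map,
       truth = list(neutral = sim$truth, sweeps = sweeps))
}

#' Emit a GWAS-style catalogue and outgroup table from sweep truth
#'
#' One catalogue row per linked risk SNP found in the truth records, with
#' configurable annotation fields; the outgroup table carries each SNP's
#' designated ancestral base. Risk-allele frequencies are computed from the
#' supplied panels when given.
#'
#' @param truth the `truth` element of [simulateStudy()] (or a list with a
#'   `sweeps` list of [implantSweep()] truth records).
#' @param panels optional named panel list for frequency annotation.
#' @param trait,pValue,oddsRatio,reportedEastAsian,reportedEuropean
#'   annotation fields applied to every emitted row.
#' @return list with `catalog` and `outgroup` data frames.
#' @export
emitCatalog <- function(truth, panels = NULL, trait = "T2D", pValue = 1e-9,
                        oddsRatio = 1.2, reportedEastAsian = TRUE,
                        reportedEuropean = FALSE) {
  sweeps <- truth$sweeps
  if (is.null(sweeps)) sweeps <- list(truth)
  withRisk <- Filter(function(s) !is.null(s$riskSnp), sweeps)
  if (!length(withRisk)) stop("no linked risk SNP in the truth records")
  rows <- lapply(withRisk, function(s) {
    r <- s$riskSnp
    pop1 <- names(s$populations)[1]
    freq <- if (!is.null(panels) && !is.null(panels[[pop1]])) {
      alleleFrequencyOnPanel(panels[[pop1]], r$column, r$riskBase)
    } else NA_real_
    chrom <- s$populations[[1]]$form@chromosome
    data.frame(rsid = r$rsid, chromosome = chrom, position_bp = r$positionBp,
               no_risk_allele = r$nonRiskBase, risk_allele = r$riskBase,
               risk_allele_frequency = freq, nearest_genes = "SIMGENE",
               p_value = pValue, odds_ratio = oddsRatio, trait = trait,
               reported_east_asian = reportedEastAsian,
               reported_european = reportedEuropean,
               ancestral_allele = r$ancestralBase, stringsAsFactors = FALSE)
  })
  catalog <- do.call(rbind, rows)
  catalog <- validateCatalog(catalog[!duplicated(catalog$rsid), , drop = FALSE])
  rownames(catalog) <- NULL
  outgroup <- data.frame(rsid = catalog$rsid, base = catalog$ancestral_allele,
                         stringsAsFactors = FALSE)
  list(catalog = catalog, outgroup = outgroup)
}
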