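# Core long-haplotype selection scan: locate the maximal allele-specified
# haplotype forms at each carrier-frequency bin, rank a target form against
# the genome-wide candidate universe at its bin (two empirical p-values),
# and score = p_cm * p_snp * n_f, significant when < 0.05.

#' Carrier-frequency grid
#'
#' The scan's frequency grid: 0.05 to 0.95 in steps of 0.05 (19 bins) by
#' default. A haplotype "at frequency f" is one whose carrier fraction is at
#' least f; reported frequencies are grid values.
#'
#' @param min,max,step grid limits and spacing.
#' @return numeric vector of bins.
#' @export
frequencyGrid <- function(min = 0.05, max = 0.95, step = 0.05) {
  if (min <= 0 || max > 1 || step <= 0 || min > max) stop("invalid frequency grid")
  bins <- seq(min, max, by = step)
  round(bins, 10)
}

needCount <- function(f, n) as.integer(ceiling(f * n - 1e-9))

chromosomeBlocks <- function(snps) {
  chr <- snps$chromosome
  blocks <- split(seq_along(chr), factor(chr, levels = unique(chr)))
  lapply(blocks, function(i) c(lo = min(i), hi = max(i)))
}

makeForm <- function(panel, cols, alleles, carriers) {
  snps <- snpMeta(panel)
  n <- nChromosomes(panel)
  alleles <- as.integer(alleles)
  base <- snps$allele0[cols]
  one <- alleles == 1L
  base[one] <- snps$allele1[cols][one]
  sites <- structure(
    list(index = as.integer(cols), rsid = snps$rsid[cols],
         position_bp = snps$position_bp[cols], allele = alleles, base = base),
    class = "data.frame", row.names = c(NA_integer_, -length(cols))
  )
  cm <- snps$cm_position[cols]
  glen <- if (anyNA(cm)) NA_real_ else cm[length(cm)] - cm[1]
  # internal fast path: inputs come pre-validated from the scan core, so
  # skip the validity pass (it dominates run time when a scan emits
  # thousands of candidate forms)
  S4Vectors::new2("HaplotypeForm", chromosome = snps$chromosome[cols[1]],
                  sites = sites, check = FALSE,
                  spanStartBp = sites$position_bp[1],
                  spanEndBp = sites$position_bp[nrow(sites)],
                  geneticLengthCm = as.numeric(glen),
                  snpCount = nrow(sites),
                  carrierFrequency = carriers / n)
}

#' Allele frequency of a base at a panel SNP
#'
#' Fraction of non-missing chromosomes carrying `alleleBase` at the SNP.
#'
#' @param panel a [HaplotypePanel-class].
#' @param snpIndex 1-based SNP column index.
#' @param alleleBase base letter; must be one of the SNP's two alleles.
#' @return frequency in `[0, 1]`.
#' @export
alleleFrequencyOnPanel <- function(panel, snpIndex, alleleBase) {
  snps <- snpMeta(panel)
  if (snpIndex < 1 || snpIndex > nrow(snps)) stop("snpIndex out of range")
  code <- if (alleleBase == snps$allele0[snpIndex]) 0L
          else if (alleleBase == snps$allele1[snpIndex]) 1L
          else stop("base ", alleleBase, " is not an allele of ",
                    snps$rsid[snpIndex], " (", snps$allele0[snpIndex], "/",
                    snps$allele1[snpIndex], ")")
  col <- alleleMatrix(panel)[, snpIndex]
  mean(col[!is.na(col)] == code)
}

#' Grow the longest haplotype form through a seed site
#'
#' Finds the longest haplotype form (allele-specified SNP run) that contains
#' the site (`seedSnpIndex`, `seedAllele`) and is carried by at least a
#' fraction `f` of chromosomes; missing genotypes count as carrying. With
#' `skipAllowance = 0` the search is exact: every chromosome carrying the
#' seed allele serves as a template and all maximal windows through the seed
#' are enumerated, so the result provably matches a brute-force enumeration
#' of contiguous allele-specified windows. With `skipAllowance > 0` the
#' search is greedy bidirectional: adjacent SNPs are appended with the
#' allele keeping the most carriers, and a SNP whose best allele would drop
#' the carrier fraction below `f` may be skipped, up to `skipAllowance`
#' times per side (a tolerance for genotyping error).
#'
#' @param panel a [HaplotypePanel-class].
#' @param seedSnpIndex 1-based SNP column of the seed.
#' @param seedAllele 0 or 1.
#' @param f carrier-frequency threshold (a grid bin).
#' @param skipAllowance per-side skip budget (default 0).
#' @return a [HaplotypeForm-class], or `NULL` when the seed allele frequency
#'   (among non-missing chromosomes) is below `f`.
#' @export
growLongestForm <- function(panel, seedSnpIndex, seedAllele, f,
                            skipAllowance = 0) {
  H <- alleleMatrix(panel)
  if (seedSnpIndex < 1 || seedSnpIndex > ncol(H)) stop("seed index out of range")
  if (!seedAllele %in% c(0L, 1L)) stop("seedAllele must be 0 or 1")
  col <- H[, seedSnpIndex]
  if (mean(col[!is.na(col)] == seedAllele) < f) return(NULL)
  n <- nrow(H)
  need <- needCount(f, n)
  blocks <- chromosomeBlocks(snpMeta(panel))
  chr <- snpMeta(panel)$chromosome[seedSnpIndex]
  b <- blocks[[chr]]
  cm <- snpMeta(panel)$cm_position
  cmSafe <- if (anyNA(cm)) rep(0, length(cm)) else cm
  if (skipAllowance == 0) {
    res <- cpp_grow_exact(H, b["lo"] - 1L, b["hi"] - 1L, seedSnpIndex - 1L,
                          as.integer(seedAllele), need, cmSafe)
    if (!length(res)) return(NULL)
    cols <- seq.int(res$start + 1L, res$end + 1L)
    makeForm(panel, cols, res$alleles, res$carriers)
  } else {
    res <- cpp_grow_greedy(H, b["lo"] - 1L, b["hi"] - 1L, seedSnpIndex - 1L,
                           as.integer(seedAllele), need,
                           as.integer(skipAllowance))
    makeForm(panel, res$sites + 1L, res$alleles, res$carriers)
  }
}

subsetFilterForms <- function(forms) {
  if (length(forms) <= 1) return(forms)
  keys <- vapply(forms, function(fo) {
    s <- formSites(fo)
    paste(fo@chromosome, paste(s$index, s$allele, sep = ":", collapse = ","))
  }, character(1))
  forms <- forms[!duplicated(keys)]
  sizes <- vapply(forms, snpCount, integer(1))
  ord <- order(-sizes)
  kept <- list()
  for (k in ord) {
    s <- formSites(forms[[k]])
    key <- paste(s$index, s$allele, sep = ":")
    contained <- FALSE
    for (q in kept) {
      if (forms[[q]]@chromosome != forms[[k]]@chromosome) next
      sq <- formSites(forms[[q]])
      if (sq$position_bp[1] <= s$position_bp[1] &&
          sq$position_bp[nrow(sq)] >= s$position_bp[nrow(s)] &&
          all(key %in% paste(sq$index, sq$allele, sep = ":"))) {
        contained <- TRUE
        break
      }
    }
    if (!contained) kept <- c(kept, k)
  }
  forms[sort(unlist(kept))]
}

#' Scan a panel for candidate haplotype forms at each frequency bin
#'
#' For every bin f of the grid, enumerates the deduplicated maximal
#' haplotype forms carried by at least a fraction f of chromosomes -- the
#' genome-wide candidate universe against which a target form is ranked.
#' With `skipAllowance = 0` this is an exhaustive search (equivalent to
#' enumerating every contiguous allele-specified window and keeping the
#' subset-maximal ones); with a positive allowance it falls back to greedy
#' growth from every qualifying (seed SNP, allele) pair.
#'
#' @inheritParams growLongestForm
#' @param grid frequency bins (default [frequencyGrid()]).
#' @return named list (one element per bin, names = bin values) of lists of
#'   [HaplotypeForm-class] objects.
#' @export
scanPopulation <- function(panel, grid = frequencyGrid(), skipAllowance = 0) {
  if (nSnps(panel) == 0) stop("empty panel")
  H <- alleleMatrix(panel)
  n <- nrow(H)
  blocks <- chromosomeBlocks(snpMeta(panel))
  out <- vector("list", length(grid))
  names(out) <- format(grid)
  for (gi in seq_along(grid)) {
    f <- grid[gi]
    need <- needCount(f, n)
    forms <- list()
    for (b in blocks) {
      lo <- b[["lo"]]; hi <- b[["hi"]]
      if (skipAllowance == 0) {
        seg <- cpp_scan_segment(H, lo - 1L, hi - 1L, need)
        if (length(seg$start)) {
          forms <- c(forms, lapply(seq_along(seg$start), function(k) {
            cols <- seq.int(seg$start[k] + 1L, seg$end[k] + 1L)
            makeForm(panel, cols, seg$alleles[[k]], seg$carriers[k])
          }))
        }
      } else {
        for (col in lo:hi) {
          x <- H[, col]
          freq0 <- mean(x[!is.na(x)] == 0L)
          for (al in c(0L, 1L)) {
            fr <- if (al == 0L) freq0 else 1 - freq0
            if (fr < f) next
            res <- cpp_grow_greedy(H, lo - 1L, hi - 1L, col - 1L, al, need,
                                   as.integer(skipAllowance))
            forms[[length(forms) + 1L]] <- makeForm(panel, res$sites + 1L,
                                                    res$alleles, res$carriers)
          }
        }
      }
    }
    out[[gi]] <- if (skipAllowance == 0) forms else subsetFilterForms(forms)
  }
  out
}

#' Empirical rank p-values for a target form
#'
#' Against the candidate universe at the target's frequency bin: `p_cm` is
#' the fraction of candidate forms spanning a genetic distance at least as
#' large as the target's, `p_snp` the fraction spanning at least as many
#' SNPs. Ties count toward the numerator, so the target always counts
#' itself and both values lie in (0, 1].
#'
#' @param targetForm a [HaplotypeForm-class], member of `allForms`.
#' @param allForms list of candidate forms at the same bin (non-empty).
#' @return named list with `p_cm` and `p_snp`.
#' @export
empiricalPValues <- function(targetForm, allForms) {
  if (!length(allForms)) stop("empty candidate list")
  cms <- vapply(allForms, geneticLengthCm, numeric(1))
  cnts <- vapply(allForms, snpCount, integer(1))
  if (anyNA(cms)) stop("candidate forms lack genetic lengths; attach a map first")
  list(p_cm = mean(cms >= geneticLengthCm(targetForm)),
       p_snp = mean(cnts >= snpCount(targetForm)))
}

#' haploPS-style selection score
#'
#' `score = p_cm * p_snp * n_f`, where `n_f` is the genome-wide number of
#' candidate haplotypes at the bin; scores strictly below 0.05 are
#' interpreted as evidence of positive selection.
#'
#' @param pCm,pSnp empirical p-values in (0, 1].
#' @param nF candidate universe size (>= 1).
#' @return list with `score` and logical `significant`.
#' @export
haploPSScore <- function(pCm, pSnp, nF) {
  if (any(pCm <= 0 | pCm > 1) || any(pSnp <= 0 | pSnp > 1)) {
    stop("empirical p-values must lie in (0, 1]")
  }
  if (any(nF < 1)) stop("nF must be >= 1")
  score <- pCm * pSnp * nF
  list(score = score, significant = score < 0.05)
}

binSignals <- function(panel, forms, f) {
  nF <- length(forms)
  cms <- vapply(forms, geneticLengthCm, numeric(1))
  cnts <- vapply(forms, snpCount, integer(1))
  pCm <- (nF - (rank(cms, ties.method = "min") - 1)) / nF
  pSnp <- (nF - (rank(cnts, ties.method = "min") - 1)) / nF
  score <- pCm * pSnp * nF
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(forms, function(fo) fo@chromosome, character(1)),
    ranges = IRanges::IRanges(
      start = vapply(forms, function(fo) fo@spanStartBp, integer(1)),
      end = vapply(forms, function(fo) fo@spanEndBp, integer(1))
    )
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    population = population(panel), frequency_bin = f, p_cm = pCm,
    p_snp = pSnp, n_f = nF, score = score,
    significant = score < 0.05,
    carrier_frequency = vapply(forms, carrierFrequency, numeric(1)),
    snp_count = cnts, genetic_length_cm = cms
  )
  SelectionSignalSet(gr, forms)
}

#' Combine several SelectionSignalSet objects
#' @param ... [SelectionSignalSet-class] objects (or a single list of them).
#' @return one combined [SelectionSignalSet-class].
#' @export
combineSignals <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !is(sets[[1]], "SelectionSignalSet")) sets <- sets[[1]]
  sets <- Filter(function(s) length(s) > 0, unname(sets))
  if (!length(sets)) {
    return(SelectionSignalSet(emptySignalRanges(), list()))
  }
  regions <- suppressWarnings(do.call(c, lapply(sets, signalRegions)))
  forms <- do.call(c, lapply(sets, signalForms))
  SelectionSignalSet(regions, forms)
}

emptySignalRanges <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    population = character(), frequency_bin = numeric(), p_cm = numeric(),
    p_snp = numeric(), n_f = integer(), score = numeric(),
    significant = logical(), carrier_frequency = numeric(),
    snp_count = integer(), genetic_length_cm = numeric()
  )
  gr
}

#' Collapse significant signals to the highest frequency bin
#'
#' A site with an uncharacteristically long haplotype at frequency f also
#' tends to show one at every lower bin, so only the evidence at the highest
#' frequency is reported: among significant signals of one population whose
#' regions overlap by at least 1 bp on the same chromosome, the signal with
#' the highest bin is kept (ties: larger genetic length, then smaller start
#' position). Non-overlapping signals pass through.
#'
#' @param signals a [SelectionSignalSet-class] (non-significant entries are
#'   dropped).
#' @return the collapsed [SelectionSignalSet-class].
#' @export
collapseToHighestFrequency <- function(signals) {
  sig <- signals[S4Vectors::mcols(signalRegions(signals))$significant]
  if (length(sig) <= 1) return(sig)
  mc <- S4Vectors::mcols(signalRegions(sig))
  ord <- order(-mc$frequency_bin, -mc$genetic_length_cm,
               GenomicRanges::start(signalRegions(sig)))
  keptIdx <- integer()
  gr <- signalRegions(sig)
  for (k in ord) {
    overlapped <- FALSE
    if (length(keptIdx)) {
      samePop <- mc$population[keptIdx] == mc$population[k]
      if (any(samePop)) {
        hits <- GenomicRanges::countOverlaps(gr[k], gr[keptIdx[samePop]])
        overlapped <- hits > 0
      }
    }
    if (!overlapped) keptIdx <- c(keptIdx, k)
  }
  sig[sort(keptIdx)]
}

#' Run the full selection scan on one population panel
#'
#' Scans every frequency bin, scores every candidate form against its bin's
#' genome-wide universe, and collapses the significant signals to the
#' highest frequency per region.
#'
#' @inheritParams scanPopulation
#' @param maps optional [geneticMap()] or named list of maps; required when
#'   the panel's `cm_position` has not been filled yet.
#' @return list with elements `candidates` (all scored forms, every bin) and
#'   `reported` (collapsed significant signals), both
#'   [SelectionSignalSet-class]. Significance is strict: `score < 0.05`.
#' @export
scanSelection <- function(panel, maps = NULL, grid = frequencyGrid(),
                          skipAllowance = 0) {
  if (!is.null(maps)) panel <- addGeneticMap(panel, maps)
  if (anyNA(snpMeta(panel)$cm_position)) {
    stop("panel lacks genetic map positions; supply `maps`")
  }
  byBin <- scanPopulation(panel, grid = grid, skipAllowance = skipAllowance)
  sets <- list()
  for (gi in seq_along(grid)) {
    forms <- byBin[[gi]]
    if (!length(forms)) next
    sets[[length(sets) + 1L]] <- binSignals(panel, forms, grid[gi])
  }
  candidates <- combineSignals(sets)
  list(candidates = candidates,
       reported = collapseToHighestFrequency(candidates))
}
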