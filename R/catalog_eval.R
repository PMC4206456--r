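# Four-step evaluation of GWAS index SNPs against selection evidence:
# (i) genome-wide-significant trait associations vs East-Asian-specific
# selection regions; (ii) is the risk allele on the selected haplotype
# form; (iii) is the risk allele derived relative to an outgroup;
# (iv) between-ancestry FST at the SNP.

#' Filter a GWAS catalogue to indisputable associations
#'
#' Keeps rows whose trait is in `traits` and whose association p-value is
#' strictly below `pThreshold` (a row at exactly the threshold is
#' excluded). Duplicate rsIDs collapse to the most significant row.
#'
#' @param catalog catalogue `data.frame` (see [readGwasCatalog()]).
#' @param traits traits to keep.
#' @param pThreshold genome-wide significance threshold (strict `<`).
#' @return the filtered `data.frame`.
#' @export
filterCatalog <- function(catalog, traits = c("T2D", "obesity"),
                          pThreshold = 5e-8) {
  keep <- catalog$trait %in% traits & catalog$p_value < pThreshold
  out <- catalog[keep, , drop = FALSE]
  if (nrow(out) > 1) {
    out <- out[order(out$p_value), , drop = FALSE]
    out <- out[!duplicated(out$rsid), , drop = FALSE]
    out <- out[order(match(out$rsid, catalog$rsid)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Selection signals containing an index SNP
#'
#' A SNP overlaps a selection signal when it lies within the signal region,
#' boundaries inclusive, on the same chromosome.
#'
#' @param row one catalogue row (`data.frame` or list with `chromosome`,
#'   `position_bp`).
#' @param signals a [SelectionSignalSet-class].
#' @return the overlapping subset of `signals`.
#' @export
overlapWithSignals <- function(row, signals) {
  gr <- signalRegions(signals)
  hit <- as.character(GenomicRanges::seqnames(gr)) == as.character(row$chromosome) &
    GenomicRanges::start(gr) <= row$position_bp &
    GenomicRanges::end(gr) >= row$position_bp
  signals[hit]
}

#' Is the risk allele carried by a selected haplotype form?
#'
#' If the index SNP is one of the form's defining sites the answer is read
#' off the form directly. If the SNP lies within the form's span but is not
#' a defining site, the allele carried by the form is estimated from the
#' form's carrier chromosomes at that SNP: `"true"`/`"false"` when one base
#' reaches the majority threshold among non-missing carriers, otherwise
#' `"indeterminate"` (also when the SNP is absent from the panel).
#'
#' @param row catalogue row with `chromosome`, `position_bp`, `risk_allele`.
#' @param form the signal's [HaplotypeForm-class].
#' @param panel the population's [HaplotypePanel-class] (used for
#'   non-defining sites).
#' @param majorityThreshold carrier-majority threshold (default 0.9).
#' @return `"true"`, `"false"` or `"indeterminate"`.
#' @export
riskAlleleOnHaplotype <- function(row, form, panel = NULL,
                                  majorityThreshold = 0.9) {
  if (as.character(row$chromosome) != form@chromosome) {
    stop("SNP and form lie on different chromosomes")
  }
  pos <- row$position_bp
  if (pos < form@spanStartBp || pos > form@spanEndBp) {
    stop("SNP at ", pos, " lies outside the form span [", form@spanStartBp,
         ", ", form@spanEndBp, "]")
  }
  s <- formSites(form)
  hit <- which(s$position_bp == pos)
  if (length(hit)) {
    return(if (identical(s$base[hit], row$risk_allele)) "true" else "false")
  }
  if (is.null(panel)) return("indeterminate")
  snps <- snpMeta(panel)
  col <- which(snps$chromosome == form@chromosome & snps$position_bp == pos)
  if (!length(col)) return("indeterminate")
  H <- alleleMatrix(panel)
  idx <- s$index
  if (anyNA(idx)) return("indeterminate")
  carriers <- rep(TRUE, nrow(H))
  for (k in seq_len(nrow(s))) {
    v <- H[, idx[k]]
    carriers <- carriers & (is.na(v) | v == s$allele[k])
  }
  x <- H[carriers, col]
  x <- x[!is.na(x)]
  if (!length(x)) return("indeterminate")
  riskCode <- if (row$risk_allele == snps$allele0[col]) 0L
              else if (row$risk_allele == snps$allele1[col]) 1L
              else return("indeterminate")
  fracRisk <- mean(x == riskCode)
  if (fracRisk >= majorityThreshold) "true"
  else if (1 - fracRisk >= majorityThreshold) "false"
  else "indeterminate"
}

#' Ancestral/derived classification of a risk allele
#'
#' Compares the catalogued alleles to the outgroup base (e.g. the
#' chimpanzee allele). No strand flipping is attempted: an outgroup base
#' matching neither catalogued allele yields `"unknown"` rather than a
#' silent A/T-C/G flip.
#'
#' @param riskAllele,noRiskAllele the catalogued bases.
#' @param outgroupBase outgroup base, or `NA` when unknown.
#' @return `"ancestral"` (risk allele equals the outgroup base),
#'   `"derived"` (the non-risk allele does) or `"unknown"`.
#' @export
classifyAncestral <- function(riskAllele, noRiskAllele, outgroupBase) {
  if (is.na(outgroupBase)) return("unknown")
  if (outgroupBase == riskAllele) return("ancestral")
  if (outgroupBase == noRiskAllele) return("derived")
  "unknown"
}

#' East-Asian specificity of association and selection
#'
#' @param row catalogue row (for the reported-population flags).
#' @param overlappingSignals [SelectionSignalSet-class] of signals
#'   containing the SNP.
#' @param eastAsian labels counting as East Asian.
#' @param other all remaining population labels that were scanned; a signal
#'   population outside both sets is a configuration error.
#' @return list with logicals `assocSpecific` (reported in East Asians and
#'   not in Europeans) and `selectionSpecific` (at least one overlapping
#'   significant East Asian signal and none in any other population).
#' @export
eastAsianSpecific <- function(row, overlappingSignals, eastAsian,
                              other = character()) {
  mc <- S4Vectors::mcols(signalRegions(overlappingSignals))
  pops <- unique(mc$population[mc$significant])
  unknown <- setdiff(pops, c(eastAsian, other))
  if (length(unknown)) {
    stop("population label(s) not assigned to a group: ",
         paste(unknown, collapse = ", "))
  }
  list(assocSpecific = isTRUE(row$reported_east_asian) &&
         !isTRUE(row$reported_european),
       selectionSpecific = any(pops %in% eastAsian) &&
         !any(pops %in% other))
}

#' Four-step evaluation of GWAS index SNPs against selection signals
#'
#' Applies, per filtered catalogue row: region overlap (step i), risk
#' allele on the selected haplotype form (step ii), ancestral/derived
#' classification against the outgroup (step iii), and between-population
#' FST at the SNP (step iv, attached once steps i-ii converge and panel
#' frequencies are available). A row supports the thrifty-gene expectation
#' only when it overlaps an East-Asian-specific selection signal, its risk
#' allele sits on the selected haplotype, and that allele is derived.
#'
#' @param catalog catalogue `data.frame` (unfiltered; filtering applied
#'   internally via [filterCatalog()]).
#' @param signals reported selection signals across populations
#'   ([SelectionSignalSet-class]).
#' @param panels named list of [HaplotypePanel-class] keyed by population
#'   (used for haplotype-carrier checks and FST frequencies; may omit
#'   populations).
#' @param outgroup `data.frame` with `rsid`, `base` (see
#'   [readOutgroupAlleles()]); defaults to the catalogue's
#'   `ancestral_allele` column.
#' @param eastAsian,other population label groups (see
#'   [eastAsianSpecific()]).
#' @param fstPairs optional list of `c(popA, popB)` pairs for step iv.
#' @param majorityThreshold see [riskAlleleOnHaplotype()].
#' @param traits,pThreshold see [filterCatalog()].
#' @return verdict `data.frame`, one row per filtered index SNP, with an
#'   `fst` list-column of named per-pair values.
#' @export
evaluateCatalog <- function(catalog, signals, panels = list(),
                            outgroup = NULL,
                            eastAsian = c("CHB", "CHD", "CHS", "JPT"),
                            other = character(), fstPairs = NULL,
                            majorityThreshold = 0.9,
                            traits = c("T2D", "obesity"), pThreshold = 5e-8) {
  rows <- filterCatalog(catalog, traits = traits, pThreshold = pThreshold)
  if (nrow(rows) == 0) {
    out <- data.frame(rsid = character(), trait = character(),
                      populations_with_signal = character(),
                      overlaps_selection = logical(),
                      east_asian_specific_association = logical(),
                      east_asian_specific_selection = logical(),
                      risk_on_haplotype = character(),
                      risk_is_derived = character(),
                      supports_thrifty = logical(), stringsAsFactors = FALSE)
    out$fst <- list()
    return(out)
  }
  if (is.null(outgroup)) {
    outgroup <- data.frame(rsid = rows$rsid, base = rows$ancestral_allele,
                           stringsAsFactors = FALSE)
  }
  verdicts <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    ov <- overlapWithSignals(row, signals)
    mc <- S4Vectors::mcols(signalRegions(ov))
    sigPops <- unique(mc$population[mc$significant])
    spec <- eastAsianSpecific(row, ov, eastAsian, other)

    onHap <- "false"
    if (length(ov)) {
      calls <- character()
      for (k in seq_len(length(ov))) {
        if (!mc$significant[k]) next
        form <- signalForms(ov)[[k]]
        if (is.null(form)) {
          calls <- c(calls, "indeterminate")
          next
        }
        pan <- panels[[mc$population[k]]]
        calls <- c(calls, tryCatch(
          riskAlleleOnHaplotype(row, form, pan, majorityThreshold),
          error = function(e) NA_character_))
      }
      calls <- calls[!is.na(calls)]
      onHap <- if (any(calls == "true")) "true"
               else if (any(calls == "indeterminate")) "indeterminate"
               else "false"
    }

    og <- outgroup$base[match(row$rsid, outgroup$rsid)]
    derived <- classifyAncestral(row$risk_allele, row$no_risk_allele,
                                 if (length(og)) og else NA_character_)

    fst <- NULL
    if (!is.null(fstPairs) && length(ov) && onHap == "true") {
      vals <- c()
      for (pair in fstPairs) {
        fa <- panelFrequency(panels[[pair[1]]], row)
        fb <- panelFrequency(panels[[pair[2]]], row)
        v <- if (is.na(fa) || is.na(fb)) NA_real_ else locusFst(c(fa, fb))
        vals[paste(pair, collapse = "-")] <- v
      }
      fst <- vals
    }

    verdicts[[i]] <- data.frame(
      rsid = row$rsid,
      trait = row$trait,
      populations_with_signal = paste(sigPops, collapse = ","),
      overlaps_selection = length(ov) > 0 && any(mc$significant),
      east_asian_specific_association = spec$assocSpecific,
      east_asian_specific_selection = spec$selectionSpecific,
      risk_on_haplotype = onHap,
      risk_is_derived = derived,
      supports_thrifty = length(ov) > 0 && any(mc$significant) &&
        spec$selectionSpecific && onHap == "true" && derived == "derived",
      stringsAsFactors = FALSE
    )
    verdicts[[i]]$fst <- list(fst)
  }
  out <- do.call(rbind, verdicts)
  rownames(out) <- NULL
  out
}

# risk-allele frequency of a catalogue SNP in one panel; NA when the SNP
# (or the panel) is absent
panelFrequency <- function(panel, row) {
  if (is.null(panel)) return(NA_real_)
  snps <- snpMeta(panel)
  col <- which(snps$chromosome == as.character(row$chromosome) &
                 snps$position_bp == row$position_bp)
  if (!length(col)) return(NA_real_)
  tryCatch(alleleFrequencyOnPanel(panel, col[1], row$risk_allele),
           error = function(e) NA_real_)
}
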