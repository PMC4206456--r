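#' @useDynLib haploSweep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats approx rbeta rbinom runif setNames
#' @importFrom utils head packageVersion
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols DataFrame
NULL

BASES <- c("A", "C", "G", "T")

#' HaplotypePanel: phased haplotypes for one population
#'
#' Holds a phased 0/1 allele matrix (rows = chromosomes, so 2N for N
#' diploids; columns = SNPs) together with per-SNP metadata. Missing
#' genotypes are `NA` and are treated optimistically (as matching) during
#' carrier counting. Internal coordinates are 1-based inclusive.
#'
#' @slot population single population label, e.g. `"CHB"`.
#' @slot snps `data.frame` with columns `rsid`, `chromosome`,
#'   `position_bp` (1-based), `allele0`, `allele1` (distinct bases in
#'   A/C/G/T; code 0 maps to `allele0`), and `cm_position` (genetic map
#'   position in cM; may be `NA` until a map is attached with
#'   [addGeneticMap()]).
#' @slot alleles integer matrix of 0/1/`NA`, one column per SNP.
#'
#' @seealso [readPhasedPanel()], [simulateNeutralPanels()]
#' @export
setClass("HaplotypePanel",
  slots = c(population = "character", snps = "data.frame", alleles = "matrix")
)

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  if (length(object@population) != 1L) msg <- c(msg, "population must be a single label")
  need <- c("rsid", "chromosome", "position_bp", "allele0", "allele1", "cm_position")
  if (!all(need %in% names(object@snps))) {
    msg <- c(msg, paste("snps must have columns:", paste(need, collapse = ", ")))
  } else {
    s <- object@snps
    if (ncol(object@alleles) != nrow(s)) {
      msg <- c(msg, "ncol(alleles) must equal nrow(snps)")
    }
    if (nrow(object@alleles) %% 2L != 0L) {
      msg <- c(msg, "chromosome count (rows of alleles) must be even")
    }
    if (nrow(s) > 0) {
      byChr <- split(s$position_bp, factor(s$chromosome, levels = unique(s$chromosome)))
      if (!all(vapply(byChr, function(p) all(diff(p) > 0), logical(1)))) {
        msg <- c(msg, "positions must be strictly increasing within each chromosome")
      }
      cmByChr <- split(seq_len(nrow(s)), factor(s$chromosome, levels = unique(s$chromosome)))
      okCm <- vapply(cmByChr, function(i) {
        cm <- s$cm_position[i]
        cm <- cm[!is.na(cm)]
        length(cm) < 2 || all(diff(cm) >= 0)
      }, logical(1))
      if (!all(okCm)) msg <- c(msg, "cm_position must be non-decreasing with position")
      badAll <- !(s$allele0 %in% BASES) | !(s$allele1 %in% BASES) | s$allele0 == s$allele1
      if (any(badAll)) msg <- c(msg, "allele0/allele1 must be distinct bases in A,C,G,T")
    }
    vals <- object@alleles
    if (!all(vals %in% c(0L, 1L, NA_integer_))) msg <- c(msg, "alleles must be 0, 1 or NA")
    if (ncol(vals) > 0 && any(colMeans(is.na(vals)) >= 1)) {
      msg <- c(msg, "every SNP must have at least one non-missing chromosome")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param population population label.
#' @param snps SNP metadata `data.frame` (see [HaplotypePanel-class]);
#'   `cm_position` defaults to `NA` if absent.
#' @param alleles matrix of 0/1/`NA`, rows = chromosomes, columns = SNPs.
#' @return a validated [HaplotypePanel-class] object.
#' @export
HaplotypePanel <- function(population, snps, alleles) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (is.null(snps$cm_position)) snps$cm_position <- NA_real_
  snps$position_bp <- as.integer(snps$position_bp)
  snps$chromosome <- as.character(snps$chromosome)
  snps$rsid <- as.character(snps$rsid)
  storage.mode(alleles) <- "integer"
  dimnames(alleles) <- NULL
  rownames(snps) <- NULL
  new("HaplotypePanel", population = as.character(population), snps = snps,
      alleles = alleles)
}

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel '", object@population, "': ",
      nrow(object@alleles), " chromosomes x ", ncol(object@alleles),
      " SNPs (", length(unique(object@snps$chromosome)),
      " chromosome(s); ", sum(is.na(object@alleles)), " missing calls)\n",
      sep = "")
})

#' HaplotypeForm: an allele-specified haplotype
#'
#' An ordered run of (SNP, allele) sites on one chromosome, the unit the
#' selection scan reports: the haplotype form expected to carry the
#' advantageous allele. Span endpoints are the first and last site
#' positions; genetic length is the cM distance between them.
#'
#' @slot chromosome chromosome label.
#' @slot sites `data.frame` with columns `index` (column in the source
#'   panel, may be `NA` for forms read back from disk), `rsid`,
#'   `position_bp`, `allele` (0/1) and `base`.
#' @slot spanStartBp,spanEndBp first and last site positions (1-based).
#' @slot geneticLengthCm genetic length spanned, in cM.
#' @slot snpCount number of sites.
#' @slot carrierFrequency fraction of chromosomes carrying the form.
#' @export
setClass("HaplotypeForm",
  slots = c(chromosome = "character", sites = "data.frame",
            spanStartBp = "integer", spanEndBp = "integer",
            geneticLengthCm = "numeric", snpCount = "integer",
            carrierFrequency = "numeric")
)

setValidity("HaplotypeForm", function(object) {
  msg <- character()
  s <- object@sites
  if (!all(c("index", "rsid", "position_bp", "allele", "base") %in% names(s))) {
    msg <- c(msg, "sites needs columns index, rsid, position_bp, allele, base")
  } else {
    if (nrow(s) < 1L) msg <- c(msg, "a form needs at least one site")
    if (nrow(s) > 1 && !all(diff(s$position_bp) > 0)) {
      msg <- c(msg, "sites must be strictly increasing in position")
    }
    if (!all(s$allele %in% c(0L, 1L))) msg <- c(msg, "site alleles must be 0 or 1")
    if (nrow(s) >= 1 && (object@spanStartBp != s$position_bp[1] ||
                         object@spanEndBp != s$position_bp[nrow(s)])) {
      msg <- c(msg, "span endpoints must equal first/last site positions")
    }
    if (object@snpCount != nrow(s)) msg <- c(msg, "snpCount must equal number of sites")
  }
  if (!is.na(object@geneticLengthCm) && object@geneticLengthCm < 0) {
    msg <- c(msg, "geneticLengthCm must be >= 0")
  }
  if (!is.na(object@carrierFrequency) &&
      (object@carrierFrequency <= 0 || object@carrierFrequency > 1)) {
    msg <- c(msg, "carrierFrequency must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeForm
#'
#' @param chromosome chromosome label.
#' @param sites data.frame with columns `index`, `rsid`, `position_bp`,
#'   `allele`, `base` (see [HaplotypeForm-class]).
#' @param geneticLengthCm genetic length in cM (`NA` if no map attached).
#' @param carrierFrequency carrier fraction in (0, 1].
#' @return a validated [HaplotypeForm-class] object.
#' @export
HaplotypeForm <- function(chromosome, sites, geneticLengthCm = NA_real_,
                          carrierFrequency = NA_real_) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$index <- as.integer(sites$index)
  sites$position_bp <- as.integer(sites$position_bp)
  sites$allele <- as.integer(sites$allele)
  rownames(sites) <- NULL
  new("HaplotypeForm", chromosome = as.character(chromosome), sites = sites,
      spanStartBp = sites$position_bp[1],
      spanEndBp = sites$position_bp[nrow(sites)],
      geneticLengthCm = as.numeric(geneticLengthCm),
      snpCount = nrow(sites),
      carrierFrequency = as.numeric(carrierFrequency))
}

setMethod("show", "HaplotypeForm", function(object) {
  cat("HaplotypeForm chr", object@chromosome, ":",
      format(object@spanStartBp, big.mark = ","), "-",
      format(object@spanEndBp, big.mark = ","), " (",
      object@snpCount, " SNPs, ",
      if (is.na(object@geneticLengthCm)) "cM NA" else
        sprintf("%.3f cM", object@geneticLengthCm),
      ", carrier freq ",
      if (is.na(object@carrierFrequency)) "NA" else
        sprintf("%.3f", object@carrierFrequency),
      ")\n", sep = "")
})

#' SelectionSignalSet: scored selection signals
#'
#' Couples a `GRanges` of candidate/reported selection regions with the
#' haplotype form behind each signal. Metadata columns: `population`,
#' `frequency_bin`, `p_cm`, `p_snp`, `n_f`, `score`, `significant`,
#' `carrier_frequency`, `snp_count`, `genetic_length_cm`.
#'
#' @slot regions `GRanges`, one range per signal (1-based inclusive).
#' @slot forms list of [HaplotypeForm-class] (or `NULL` where the form is
#'   unknown, e.g. signals transcribed from a printed table).
#' @export
setClass("SelectionSignalSet",
  slots = c(regions = "GRanges", forms = "list")
)

setValidity("SelectionSignalSet", function(object) {
  msg <- character()
  mc <- S4Vectors::mcols(object@regions)
  need <- c("population", "frequency_bin", "p_cm", "p_snp", "n_f", "score",
            "significant", "carrier_frequency", "snp_count", "genetic_length_cm")
  if (!all(need %in% names(mc))) {
    msg <- c(msg, paste("regions mcols must include:", paste(need, collapse = ", ")))
  } else {
    ok <- is.na(mc$score) | (mc$significant == (mc$score < 0.05))
    if (!all(ok)) msg <- c(msg, "significant flag must equal score < 0.05")
  }
  if (length(object@forms) != length(object@regions)) {
    msg <- c(msg, "forms must parallel regions")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SelectionSignalSet
#'
#' @param regions `GRanges` with the metadata columns listed in
#'   [SelectionSignalSet-class].
#' @param forms list of [HaplotypeForm-class] or `NULL`, parallel to
#'   `regions`.
#' @return a validated [SelectionSignalSet-class].
#' @export
SelectionSignalSet <- function(regions, forms = vector("list", length(regions))) {
  new("SelectionSignalSet", regions = regions, forms = forms)
}

setMethod("show", "SelectionSignalSet", function(object) {
  mc <- S4Vectors::mcols(object@regions)
  cat("SelectionSignalSet: ", length(object@regions), " signal(s), ",
      sum(mc$significant), " significant, populations: ",
      paste(unique(mc$population), collapse = ", "), "\n", sep = "")
  if (length(object@regions)) show(head(object@regions, 5))
})

#' @describeIn SelectionSignalSet-class number of signals.
#' @param x a `SelectionSignalSet`.
#' @export
setMethod("length", "SelectionSignalSet", function(x) length(x@regions))

#' @describeIn SelectionSignalSet-class subset signals.
#' @param i index (integer or logical).
#' @param j,...,drop unused.
#' @export
setMethod("[", "SelectionSignalSet", function(x, i, j, ..., drop = TRUE) {
  if (is.logical(i)) i <- which(i)
  SelectionSignalSet(x@regions[i], x@forms[i])
})
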