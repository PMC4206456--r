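#' @name accessors
#' @title Accessors for haploSweep objects
#' @description Slot accessors for [HaplotypePanel-class],
#'   [HaplotypeForm-class] and [SelectionSignalSet-class]; user code should
#'   use these instead of `@`.
#' @param x an object.
#' @return the corresponding slot content.
NULL

#' @rdname accessors
#' @export
setGeneric("population", function(x) standardGeneric("population"))
#' @rdname accessors
#' @export
setGeneric("snpMeta", function(x) standardGeneric("snpMeta"))
#' @rdname accessors
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))
#' @rdname accessors
#' @export
setGeneric("nChromosomes", function(x) standardGeneric("nChromosomes"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("formSites", function(x) standardGeneric("formSites"))
#' @rdname accessors
#' @export
setGeneric("snpCount", function(x) standardGeneric("snpCount"))
#' @rdname accessors
#' @export
setGeneric("geneticLengthCm", function(x) standardGeneric("geneticLengthCm"))
#' @rdname accessors
#' @export
setGeneric("carrierFrequency", function(x) standardGeneric("carrierFrequency"))
#' @rdname accessors
#' @export
setGeneric("signalRegions", function(x) standardGeneric("signalRegions"))
#' @rdname accessors
#' @export
setGeneric("signalForms", function(x) standardGeneric("signalForms"))

#' @rdname accessors
#' @export
setMethod("population", "HaplotypePanel", function(x) x@population)
#' @rdname accessors
#' @export
setMethod("snpMeta", "HaplotypePanel", function(x) x@snps)
#' @rdname accessors
#' @export
setMethod("alleleMatrix", "HaplotypePanel", function(x) x@alleles)
#' @rdname accessors
#' @export
setMethod("nChromosomes", "HaplotypePanel", function(x) nrow(x@alleles))
#' @rdname accessors
#' @export
setMethod("nSnps", "HaplotypePanel", function(x) ncol(x@alleles))
#' @rdname accessors
#' @export
setMethod("formSites", "HaplotypeForm", function(x) x@sites)
#' @rdname accessors
#' @export
setMethod("snpCount", "HaplotypeForm", function(x) x@snpCount)
#' @rdname accessors
#' @export
setMethod("geneticLengthCm", "HaplotypeForm", function(x) x@geneticLengthCm)
#' @rdname accessors
#' @export
setMethod("carrierFrequency", "HaplotypeForm", function(x) x@carrierFrequency)
#' @rdname accessors
#' @export
setMethod("signalRegions", "SelectionSignalSet", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("signalForms", "SelectionSignalSet", function(x) x@forms)

#' Convert a SelectionSignalSet to a data.frame
#'
#' One row per signal, mirroring the columns of the signals TSV written by
#' [writeSignalsTsv()] (minus the encoded form sites).
#'
#' @param x a [SelectionSignalSet-class].
#' @param row.names,optional,... passed for generic compatibility; unused.
#' @return a `data.frame`.
#' @export
#' @exportS3Method base::as.data.frame
as.data.frame.SelectionSignalSet <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  gr <- x@regions
  mc <- as.data.frame(S4Vectors::mcols(gr))
  data.frame(
    population = mc$population,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr),
    frequency_bin = mc$frequency_bin,
    p_cm = mc$p_cm,
    p_snp = mc$p_snp,
    n_f = mc$n_f,
    score = mc$score,
    significant = mc$significant,
    carrier_frequency = mc$carrier_frequency,
    snp_count = mc$snp_count,
    genetic_length_cm = mc$genetic_length_cm,
    stringsAsFactors = FALSE
  )
}
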