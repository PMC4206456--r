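# Haplotype similarity index (HSI): fraction of identical alleles over the
# SNPs shared by two selected haplotype forms. A sweep present in several
# populations can stem from one mutation event in their common ancestor
# (near-identical forms) or from convergent evolution on different
# backgrounds (discordant forms); the HSI separates the two.

classifyHsi <- function(value, sharedSnpCount) {
  if (sharedSnpCount == 0) return("no_overlap")
  if (value > 0.98) return("shared_event")
  if (value < 0.9) return("convergent")
  "indeterminate"
}

#' Haplotype similarity index between two forms
#'
#' Over the SNPs present in both forms' site lists (matched by position),
#' the fraction carrying identical alleles. Values above 0.98 indicate a
#' single mutation event in the populations' common ancestor
#' (`shared_event`); values below 0.9 indicate likely convergent evolution
#' (`convergent`); the closed interval `[0.9, 0.98]` is `indeterminate`.
#' Forms with no shared SNPs give `no_overlap` with value 0.
#'
#' @param formA,formB [HaplotypeForm-class] objects on the same chromosome.
#' @return an object of class `HsiResult`: list with `value`,
#'   `sharedSnpCount` and `classification`.
#' @export
hsi <- function(formA, formB) {
  if (formA@chromosome != formB@chromosome) {
    stop("forms lie on different chromosomes (", formA@chromosome, " vs ",
         formB@chromosome, ")")
  }
  sa <- formSites(formA)
  sb <- formSites(formB)
  m <- match(sa$position_bp, sb$position_bp)
  shared <- which(!is.na(m))
  if (!length(shared)) {
    res <- list(value = 0, sharedSnpCount = 0L, classification = "no_overlap")
    class(res) <- "HsiResult"
    return(res)
  }
  # compare bases when both sides carry them, else the 0/1 codes
  ba <- sa$base[shared]
  bb <- sb$base[m[shared]]
  same <- if (!anyNA(ba) && !anyNA(bb)) ba == bb
          else sa$allele[shared] == sb$allele[m[shared]]
  value <- mean(same)
  res <- list(value = value, sharedSnpCount = length(shared),
              classification = classifyHsi(value, length(shared)))
  class(res) <- "HsiResult"
  res
}

#' @exportS3Method base::print
print.HsiResult <- function(x, ...) {
  cat(sprintf("HSI = %.4f over %d shared SNP(s): %s\n", x$value,
              x$sharedSnpCount, x$classification))
  invisible(x)
}

#' Pairwise HSI matrix for co-localised signals
#'
#' @param forms list of [HaplotypeForm-class] objects (e.g. the selected
#'   forms of one region across populations); names are used as labels.
#' @return list of three labelled square matrices: `value` (diagonal 1),
#'   `sharedSnpCount` and `classification`.
#' @export
pairwiseHsiMatrix <- function(forms) {
  k <- length(forms)
  if (k < 1) stop("need at least one form")
  labs <- names(forms)
  if (is.null(labs)) labs <- paste0("form", seq_len(k))
  value <- matrix(1, k, k, dimnames = list(labs, labs))
  shared <- matrix(NA_integer_, k, k, dimnames = list(labs, labs))
  cls <- matrix("shared_event", k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    shared[i, i] <- snpCount(forms[[i]])
    for (j in seq_len(k)) {
      if (j <= i) next
      r <- hsi(forms[[i]], forms[[j]])
      value[i, j] <- value[j, i] <- r$value
      shared[i, j] <- shared[j, i] <- r$sharedSnpCount
      cls[i, j] <- cls[j, i] <- r$classification
    }
  }
  list(value = value, sharedSnpCount = shared, classification = cls)
}
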