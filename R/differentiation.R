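# Locus-specific fixation index: the divergence of population-specific
# allele frequencies from their pooled average, as the ratio of the
# observed frequency variance to the maximum variance possible under the
# pooled frequency.

#' Locus-specific FST from per-population allele frequencies
#'
#' With frequencies p_1..p_K and pooled mean p-bar (unweighted; sample
#' sizes are ignored unless `weights` are supplied), the value is
#' `mean((p_i - p-bar)^2) / (p-bar * (1 - p-bar))`. The denominator is the
#' largest variance attainable at that pooled frequency (all populations
#' fixed for one or the other allele), so the value lies in `[0, 1]`. When
#' the pooled frequency is 0 or 1 no variance is possible and the value is
#' 0 by convention.
#'
#' @param freqs numeric vector of per-population frequencies (length >= 2,
#'   each in `[0, 1]`).
#' @param weights optional non-negative weights (e.g. sample sizes) for a
#'   weighted mean and weighted variance; default unweighted.
#' @return FST value in `[0, 1]`.
#' @examples
#' locusFst(c(0.8, 0.3)) # 0.0625 / 0.2475
#' @export
locusFst <- function(freqs, weights = NULL) {
  if (length(freqs) < 2) stop("need frequencies for at least two populations")
  if (any(is.na(freqs)) || any(freqs < 0 | freqs > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  if (is.null(weights)) {
    weights <- rep(1, length(freqs))
  } else {
    if (length(weights) != length(freqs) || any(weights < 0) || sum(weights) == 0) {
      stop("invalid weights")
    }
  }
  w <- weights / sum(weights)
  pbar <- sum(w * freqs)
  den <- pbar * (1 - pbar)
  if (den == 0) return(0)
  sum(w * (freqs - pbar)^2) / den
}

#' Pairwise locus FST table across population groups
#'
#' One value per (SNP, population from group A, population from group B),
#' mirroring the layout of printed between-ancestry FST tables.
#'
#' @param freqTable numeric matrix (rows = SNPs, named; columns =
#'   populations, named) of allele frequencies; `NA` where a SNP is absent
#'   from a population's panel.
#' @param groupA,groupB population label vectors (columns of `freqTable`).
#' @return long `data.frame` with columns `rsid`, `pop_a`, `pop_b`, `fst`
#'   (`NA`, never fabricated, where either frequency is missing).
#' @export
fstMatrix <- function(freqTable, groupA, groupB) {
  freqTable <- as.matrix(freqTable)
  missingPop <- setdiff(c(groupA, groupB), colnames(freqTable))
  if (length(missingPop)) {
    stop("no frequencies for population(s): ", paste(missingPop, collapse = ", "))
  }
  grid <- expand.grid(pop_a = groupA, pop_b = groupB,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(rownames(freqTable), function(snp) {
    vals <- vapply(seq_len(nrow(grid)), function(k) {
      fa <- freqTable[snp, grid$pop_a[k]]
      fb <- freqTable[snp, grid$pop_b[k]]
      if (is.na(fa) || is.na(fb)) NA_real_ else locusFst(c(fa, fb))
    }, numeric(1))
    data.frame(rsid = snp, pop_a = grid$pop_a, pop_b = grid$pop_b, fst = vals,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate per-population allele frequencies under Balding-Nichols
#'
#' Each population's frequency is drawn from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` around the ancestral frequency
#' `p`, giving `E[p_k] = p` and `Var[p_k] = F p (1 - p)`; `F = 0` returns
#' `p` unchanged. Note that the unweighted locus FST computed from K such
#' frequencies has expectation close to `F (K - 1) / K`, not `F` itself:
#' with few populations the pooled mean absorbs part of the variance.
#'
#' @param p ancestral frequencies (vector, one per locus).
#' @param fst divergence parameter in `[0, 1)`.
#' @param nPops number of populations.
#' @return matrix (loci x populations) of frequencies.
#' @export
simulateBaldingNichols <- function(p, fst, nPops) {
  if (fst < 0 || fst >= 1) stop("divergence must lie in [0, 1)")
  if (fst == 0) return(matrix(rep(p, nPops), ncol = nPops))
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  m <- vapply(seq_len(nPops), function(k) rbeta(length(p), a, b),
              numeric(length(p)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(p))
  m
}
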