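# Brute-force window-enumeration oracle, kept independent of the scan
# implementation: enumerate every contiguous allele-specified window, count
# carriers directly, and filter to subset-maximal windows.

oracleAllWindows <- function(H, f) {
  n <- nrow(H)
  M <- ncol(H)
  need <- as.integer(ceiling(f * n - 1e-9))
  out <- list()
  for (i in 1:M) {
    for (j in i:M) {
      keys <- apply(H[, i:j, drop = FALSE], 1, paste, collapse = "")
      tab <- table(keys)
      for (s in names(tab)[tab >= need]) {
        out[[length(out) + 1]] <- list(start = i, end = j, str = s,
                                       carriers = unname(tab[[s]]))
      }
    }
  }
  out
}

oracleMaximalWindows <- function(H, f) {
  cands <- oracleAllWindows(H, f)
  if (!length(cands)) return(cands)
  keep <- rep(TRUE, length(cands))
  for (a in seq_along(cands)) {
    A <- cands[[a]]
    for (b in seq_along(cands)) {
      if (a == b) next
      B <- cands[[b]]
      if (B$start <= A$start && B$end >= A$end &&
          !(B$start == A$start && B$end == A$end) &&
          substr(B$str, A$start - B$start + 1,
                 A$end - B$start + 1) == A$str) {
        keep[a] <- FALSE
        break
      }
    }
  }
  cands[keep]
}

windowKey <- function(w) paste(w$start, w$end, w$str)

formKey <- function(form) {
  s <- formSites(form)
  paste(s$index[1], s$index[nrow(s)], paste(s$allele, collapse = ""))
}

# random phased panel with per-SNP frequencies; positions random so SNP
# count and genetic length decorrelate
randomTestPanel <- function(n, M, seed) {
  set.seed(seed)
  H <- matrix(rbinom(n * M, 1, rep(runif(M, 0.2, 0.8), each = n)), n, M)
  pos <- sort(sample.int(1e6, M))
  snps <- data.frame(rsid = paste0("s", 1:M), chromosome = "1",
                     position_bp = pos, allele0 = "A", allele1 = "C",
                     cm_position = pos / 1e6, stringsAsFactors = FALSE)
  HaplotypePanel("TEST", snps, H)
}

# minimal form with a given SNP count and genetic length, for ranking tests
rankForm <- function(snpCount, cm) {
  pos <- seq(1000L, by = 1000L, length.out = snpCount)
  sites <- data.frame(index = seq_len(snpCount), rsid = paste0("r", pos),
                      position_bp = pos, allele = 0L, base = "A",
                      stringsAsFactors = FALSE)
  HaplotypeForm("1", sites, geneticLengthCm = cm, carrierFrequency = 0.5)
}

toyPanel <- function() {
  readPhasedPanel(system.file("extdata", "toy.hap", package = "haploSweep"),
                  population = "TOY")
}
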