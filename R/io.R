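#' @importFrom data.table fread fwrite as.data.table
NULL

# ---- genetic maps -----------------------------------------------------------

#' Genetic map for one chromosome
#'
#' A set of (position, cM) anchors. Between anchors the cM position is
#' linearly interpolated; outside the anchored range it clamps to the
#' nearest anchor (constant extrapolation), which keeps cM bounded and
#' non-negative at chromosome ends.
#'
#' @param chromosome chromosome label.
#' @param positionBp integer positions (bp, 1-based), strictly increasing.
#' @param cm genetic map positions (cM), non-decreasing.
#' @return an object of class `GeneticMap`.
#' @export
geneticMap <- function(chromosome, positionBp, cm) {
  positionBp <- as.numeric(positionBp)
  cm <- as.numeric(cm)
  if (length(positionBp) != length(cm)) stop("positionBp and cm lengths differ")
  if (is.unsorted(positionBp, strictly = TRUE)) stop("anchor positions must be strictly increasing")
  if (is.unsorted(cm)) stop("anchor cM values must be non-decreasing")
  structure(list(chromosome = as.character(chromosome),
                 anchors = data.frame(position_bp = positionBp, cm = cm)),
            class = "GeneticMap")
}

#' @exportS3Method base::print
print.GeneticMap <- function(x, ...) {
  cat("GeneticMap chr", x$chromosome, ": ", nrow(x$anchors), " anchors, ",
      sprintf("%.3f", max(x$anchors$cm) - min(x$anchors$cm)), " cM\n", sep = "")
  invisible(x)
}

#' Read a genetic map file
#'
#' Accepts the usual whitespace-separated map layout with columns
#' (position, rate in cM/Mb, cumulative cM) -- the rate column is ignored --
#' or a two-column (position, cM) file. A header line is detected
#' automatically.
#'
#' @param path file path.
#' @param chromosome chromosome label to attach to the map.
#' @return a [geneticMap()] object.
#' @export
readGeneticMap <- function(path, chromosome = "1") {
  tab <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(tab) < 2) stop("genetic map needs at least (position, cM) columns: ", path)
  cmCol <- if (ncol(tab) >= 3) 3L else 2L
  geneticMap(chromosome, tab[[1]], tab[[cmCol]])
}

#' Interpolate a genetic map position
#'
#' Linear interpolation between the bracketing anchors; queries outside the
#' anchored range return the nearest anchor's cM.
#'
#' @param map a [geneticMap()] object.
#' @param positionBp query position(s) in bp.
#' @return cM position(s).
#' @examples
#' m <- geneticMap("1", c(0, 1e6), c(0, 1))
#' interpolateCm(m, 5e5) # 0.5
#' @export
interpolateCm <- function(map, positionBp) {
  if (!inherits(map, "GeneticMap")) stop("map must be a GeneticMap")
  if (nrow(map$anchors) < 2) {
    stop("genetic map for chromosome ", map$chromosome, " needs >= 2 anchors")
  }
  stats::approx(map$anchors$position_bp, map$anchors$cm, xout = positionBp,
                rule = 2, ties = "ordered")$y
}

#' Attach genetic map positions to a panel
#'
#' Fills the `cm_position` column of the panel's SNP metadata by
#' interpolating the supplied map(s).
#'
#' @param panel a [HaplotypePanel-class].
#' @param maps a single [geneticMap()] (single-chromosome panels) or a named
#'   list of maps keyed by chromosome label.
#' @return the panel with `cm_position` filled.
#' @export
addGeneticMap <- function(panel, maps) {
  if (inherits(maps, "GeneticMap")) maps <- setNames(list(maps), maps$chromosome)
  snps <- snpMeta(panel)
  for (chr in unique(snps$chromosome)) {
    if (is.null(maps[[chr]])) {
      stop("no genetic map supplied for chromosome ", chr)
    }
    i <- snps$chromosome == chr
    snps$cm_position[i] <- interpolateCm(maps[[chr]], snps$position_bp[i])
  }
  HaplotypePanel(population(panel), snps, alleleMatrix(panel))
}

# ---- phased panels ----------------------------------------------------------

parseVcfPanel <- function(path, population) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic <- ref %in% BASES & alt %in% BASES
  phased <- !apply(gt, 1, function(g) any(grepl("/", g, fixed = TRUE)))
  keep <- biallelic & phased
  nDropped <- sum(!keep)
  if (nDropped > 0) {
    message("readPhasedPanel: dropped ", nDropped,
            " site(s) (multi-allelic, non-SNP or unphased) from ", path)
  }
  if (!any(keep)) stop("no phased biallelic SNPs in ", path)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  # one pair of haplotype columns per sample
  hapList <- lapply(seq_len(ncol(gt)), function(j) {
    parts <- strsplit(gt[, j], "|", fixed = TRUE)
    a1 <- suppressWarnings(as.integer(vapply(parts, function(p) p[1], character(1))))
    a2 <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1))))
    rbind(a1, a2)
  })
  alleles <- do.call(rbind, hapList)
  ord <- order(as.character(fix[, "CHROM"]), as.numeric(fix[, "POS"]))
  fix <- fix[ord, , drop = FALSE]
  alleles <- alleles[, ord, drop = FALSE]
  snps <- data.frame(
    rsid = ifelse(fix[, "ID"] == ".", paste0("snp", seq_len(nrow(fix))), fix[, "ID"]),
    chromosome = as.character(fix[, "CHROM"]),
    position_bp = as.integer(as.numeric(fix[, "POS"])),
    allele0 = ref[keep][ord],
    allele1 = alt[keep][ord],
    cm_position = NA_real_,
    stringsAsFactors = FALSE
  )
  HaplotypePanel(population, snps, alleles)
}

parseHapLegendPanel <- function(hapPath, legendPath, population, chromosome) {
  if (!file.exists(legendPath)) stop("legend file not found: ", legendPath)
  leg <- data.table::fread(legendPath, header = TRUE, data.table = FALSE)
  need <- c("rsid", "position_bp", "allele0", "allele1")
  if (!all(need %in% names(leg))) {
    # IMPUTE-style header: id position a0 a1
    alt <- c("id", "position", "a0", "a1")
    if (all(alt %in% names(leg))) {
      names(leg)[match(alt, names(leg))] <- need
    } else {
      stop("legend ", legendPath, " must have columns ",
           paste(need, collapse = ", "), " (or id/position/a0/a1)")
    }
  }
  if (is.null(leg$chromosome)) leg$chromosome <- chromosome
  if (is.null(leg$cm_position)) leg$cm_position <- NA_real_
  hap <- data.table::fread(hapPath, header = FALSE, na.strings = c("?", "NA"),
                           data.table = FALSE)
  if (nrow(hap) != nrow(leg)) {
    stop("hap/legend row mismatch: ", nrow(hap), " vs ", nrow(leg),
         " (", hapPath, ")")
  }
  bad <- which(!vapply(hap, function(col) all(col %in% c(0L, 1L, NA)), logical(1)))
  if (length(bad)) stop("non 0/1 haplotype value in column ", bad[1], " of ", hapPath)
  alleles <- t(as.matrix(hap))
  if (ncol(alleles) == 0) stop("no phased sites in ", hapPath)
  HaplotypePanel(population, leg[, c("rsid", "chromosome", "position_bp",
                                     "allele0", "allele1", "cm_position")],
                 alleles)
}

#' Read a phased haplotype panel
#'
#' Reads phased haplotypes from a VCF with phased diploid genotypes or from
#' an IMPUTE-style `.hap`/`.legend` pair (one row per SNP, one `.hap` column
#' per chromosome; missing coded `?`). Multi-allelic, non-SNP and unphased
#' VCF sites are dropped with a message.
#'
#' @param path path to the `.vcf` or `.hap` file.
#' @param format `"auto"` (by extension), `"vcf"` or `"hap-legend"`.
#' @param population population label attached to the panel.
#' @param legendPath legend path (defaults to `path` with `.hap` replaced by
#'   `.legend`).
#' @param chromosome fallback chromosome label when the legend lacks one.
#' @return a [HaplotypePanel-class] with `2N` chromosome rows.
#' @export
readPhasedPanel <- function(path, format = c("auto", "vcf", "hap-legend"),
                            population = "POP",
                            legendPath = sub("\\.hap$", ".legend", path),
                            chromosome = "1") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "hap-legend"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") parseVcfPanel(path, population)
  else parseHapLegendPanel(path, legendPath, population, chromosome)
}

#' Write a panel as a `.hap`/`.legend` pair
#'
#' @param panel a [HaplotypePanel-class].
#' @param prefix output prefix; writes `prefix.hap` and `prefix.legend`.
#' @return invisibly, the two paths written.
#' @export
writePanel <- function(panel, prefix) {
  hapPath <- paste0(prefix, ".hap")
  legPath <- paste0(prefix, ".legend")
  leg <- snpMeta(panel)
  data.table::fwrite(leg, legPath, sep = "\t", na = "NA", quote = FALSE)
  hap <- as.data.frame(t(alleleMatrix(panel)))
  data.table::fwrite(hap, hapPath, sep = " ", na = "?", quote = FALSE,
                     col.names = FALSE)
  invisible(c(hap = hapPath, legend = legPath))
}

# ---- GWAS catalogue and outgroup tables ------------------------------------

GWAS_COLS <- c("rsid", "chromosome", "position_bp", "no_risk_allele",
               "risk_allele", "risk_allele_frequency", "nearest_genes",
               "p_value", "odds_ratio", "trait", "reported_east_asian",
               "reported_european", "ancestral_allele")

asFlag <- function(x) {
  if (is.logical(x)) return(x)
  toupper(as.character(x)) %in% c("Y", "YES", "TRUE", "1")
}

validateCatalog <- function(cat) {
  miss <- setdiff(GWAS_COLS, names(cat))
  if (length(miss)) stop("GWAS catalogue missing column(s): ", paste(miss, collapse = ", "))
  if (any(cat$risk_allele == cat$no_risk_allele)) {
    stop("risk and no-risk alleles must differ (",
         paste(cat$rsid[cat$risk_allele == cat$no_risk_allele], collapse = ", "), ")")
  }
  anc <- cat$ancestral_allele
  bad <- !is.na(anc) & anc != cat$risk_allele & anc != cat$no_risk_allele
  if (any(bad)) {
    stop("ancestral allele matches neither catalogued allele for ",
         paste(cat$rsid[bad], collapse = ", "))
  }
  cat
}

#' Read a GWAS index-SNP table
#'
#' Tab-separated with columns `rsid`, `chromosome`, `position_bp`,
#' `no_risk_allele`, `risk_allele`, `risk_allele_frequency` (`NR` or empty
#' for not reported), `nearest_genes` (comma-separated symbols), `p_value`,
#' `odds_ratio`, `trait`, `reported_east_asian`, `reported_european` (Y/N),
#' `ancestral_allele` (outgroup base, or empty).
#'
#' @param path file path.
#' @return a validated `data.frame`, one row per index SNP.
#' @export
readGwasCatalog <- function(path) {
  cat <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                           na.strings = c("NR", "NA", "", "."),
                           colClasses = list(character = "chromosome"))
  cat$chromosome <- as.character(cat$chromosome)
  cat$position_bp <- as.integer(cat$position_bp)
  cat$risk_allele_frequency <- suppressWarnings(as.numeric(cat$risk_allele_frequency))
  cat$reported_east_asian <- asFlag(cat$reported_east_asian)
  cat$reported_european <- asFlag(cat$reported_european)
  cat$ancestral_allele <- as.character(cat$ancestral_allele)
  validateCatalog(cat)
}

#' Write a GWAS index-SNP table
#' @param catalog a catalogue `data.frame` (see [readGwasCatalog()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGwasCatalog <- function(catalog, path) {
  out <- catalog[, GWAS_COLS]
  out$reported_east_asian <- ifelse(out$reported_east_asian, "Y", "N")
  out$reported_european <- ifelse(out$reported_european, "Y", "N")
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read / write an outgroup (ancestral) allele table
#'
#' Two tab-separated columns: `rsid` and `base` (A/C/G/T, or `.`/empty when
#' the outgroup state is unknown).
#'
#' @param path file path.
#' @return `data.frame` with columns `rsid`, `base`.
#' @export
readOutgroupAlleles <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                           na.strings = c("", ".", "NA"))
  if (!all(c("rsid", "base") %in% names(tab))) {
    stop("outgroup table needs columns rsid, base: ", path)
  }
  tab$base <- toupper(as.character(tab$base))
  bad <- !is.na(tab$base) & !(tab$base %in% BASES)
  if (any(bad)) stop("invalid outgroup base for ", paste(tab$rsid[bad], collapse = ", "))
  tab[, c("rsid", "base")]
}

#' @rdname readOutgroupAlleles
#' @param outgroup `data.frame` with columns `rsid`, `base`.
#' @export
writeOutgroupAlleles <- function(outgroup, path) {
  data.table::fwrite(outgroup[, c("rsid", "base")], path, sep = "\t",
                     na = ".", quote = FALSE)
  invisible(path)
}

# ---- signals: TSV and BED ---------------------------------------------------

encodeFormSites <- function(form) {
  if (is.null(form)) return(NA_character_)
  s <- formSites(form)
  paste(sprintf("%d:%d:%s", s$position_bp, s$allele, s$base), collapse = ";")
}

decodeFormSites <- function(txt, chromosome, geneticLengthCm, carrierFrequency) {
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  sites <- data.frame(
    index = NA_integer_,
    rsid = NA_character_,
    position_bp = as.integer(vapply(parts, `[`, character(1), 1)),
    allele = as.integer(vapply(parts, `[`, character(1), 2)),
    base = vapply(parts, `[`, character(1), 3),
    stringsAsFactors = FALSE
  )
  HaplotypeForm(chromosome, sites, geneticLengthCm, carrierFrequency)
}

#' Write / read selection signals as TSV
#'
#' One row per signal; columns mirror the printed selection-region tables
#' (population, region, haploPS score, frequency bin, carrier frequency)
#' plus the encoded haplotype-form sites so a signal file round-trips.
#'
#' @param signals a [SelectionSignalSet-class].
#' @param path file path.
#' @return `writeSignalsTsv()`: invisibly, `path`; `readSignalsTsv()`: a
#'   [SelectionSignalSet-class].
#' @export
writeSignalsTsv <- function(signals, path) {
  df <- as.data.frame(signals)
  df$form_sites <- vapply(signalForms(signals), encodeFormSites, character(1))
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname writeSignalsTsv
#' @export
readSignalsTsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = list(character = c("chromosome")))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chromosome),
    ranges = IRanges::IRanges(start = df$start_bp, end = df$end_bp)
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    population = df$population, frequency_bin = df$frequency_bin,
    p_cm = df$p_cm, p_snp = df$p_snp, n_f = df$n_f, score = df$score,
    significant = as.logical(df$significant),
    carrier_frequency = df$carrier_frequency, snp_count = df$snp_count,
    genetic_length_cm = df$genetic_length_cm
  )
  forms <- lapply(seq_len(nrow(df)), function(i) {
    decodeFormSites(df$form_sites[i], df$chromosome[i],
                    df$genetic_length_cm[i], df$carrier_frequency[i])
  })
  SelectionSignalSet(gr, forms)
}

#' Write selection regions as BED
#'
#' Converts the internal 1-based inclusive regions to BED's 0-based
#' half-open convention; chromosome labels get a `chr` prefix if absent.
#'
#' @param signals a [SelectionSignalSet-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSignalsBed <- function(signals, path) {
  df <- as.data.frame(signals)
  chrom <- ifelse(grepl("^chr", df$chromosome), df$chromosome,
                  paste0("chr", df$chromosome))
  bed <- data.frame(chrom = chrom, start = df$start_bp - 1L, end = df$end_bp,
                    name = paste0(df$population, "_f", df$frequency_bin),
                    score = df$score)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Read a BED file of regions back to 1-based inclusive coordinates
#'
#' @param path BED path (at least 3 columns).
#' @return a `data.frame` with `chromosome` (without `chr` prefix),
#'   `start_bp`, `end_bp`.
#' @export
readRegionsBed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (nrow(bed) == 0) {
    return(data.frame(chromosome = character(), start_bp = integer(),
                      end_bp = integer()))
  }
  data.frame(chromosome = sub("^chr", "", as.character(bed[[1]])),
             start_bp = as.integer(bed[[2]]) + 1L,
             end_bp = as.integer(bed[[3]]),
             stringsAsFactors = FALSE)
}

#' Write / read the per-SNP evaluation report
#'
#' One row per index SNP: the four-step verdict columns produced by
#' [evaluateCatalog()], with the per-pair FST values flattened to a
#' `pair=value` list.
#'
#' @param verdicts verdict `data.frame` from [evaluateCatalog()].
#' @param path file path.
#' @return `writeReportTsv()`: invisibly `path`; `readReportTsv()`: a
#'   `data.frame`.
#' @export
writeReportTsv <- function(verdicts, path) {
  out <- verdicts
  if (!is.null(out$fst) && is.list(out$fst)) {
    out$fst <- vapply(out$fst, function(v) {
      if (is.null(v) || !length(v)) return(NA_character_)
      paste(sprintf("%s=%.6g", names(v), v), collapse = ";")
    }, character(1))
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname writeReportTsv
#' @export
readReportTsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    na.strings = c("NA", ""))
}
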