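#' Genotype matrix constructor
#'
#' Alternate-allele dosage genotypes (0/1/2, `NA` for missing) for a
#' set of samples at biallelic loci with genomic coordinates.
#' Positions are 1-based base pairs (VCF convention) and must be
#' strictly increasing within each chromosome.
#'
#' @param genotypes integer matrix, samples in rows, loci in columns.
#' @param loci data frame with columns `chrom` and `pos`.
#' @param samples character vector of sample ids (defaults to rownames).
#' @return object of class `genotype_data`.
#' @export
genotype_data <- function(genotypes, loci, samples = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(genotypes)))
  if (!all(genotypes %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be alternate-allele dosages 0/1/2 or NA")
  if (nrow(loci) != ncol(genotypes))
    stop("loci table and genotype columns disagree")
  loci <- data.frame(chrom = as.character(loci$chrom),
                     pos = as.integer(loci$pos),
                     stringsAsFactors = FALSE)
  for (ch in unique(loci$chrom)) {
    p <- loci$pos[loci$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  rownames(genotypes) <- samples
  structure(list(samples = samples, loci = loci, genotypes = genotypes),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("Genotype data:", length(x$samples), "samples x",
      nrow(x$loci), "loci on", length(unique(x$loci$chrom)),
      "chromosome(s);", sum(is.na(x$genotypes)), "missing calls\n")
  invisible(x)
}

#' Read genotypes from CSV or minimal VCF
#'
#' CSV layout: header `CHROM,POS` followed by one column per sample,
#' entries 0/1/2/NA.  The VCF reader (via the vcfR package) parses only
#' the GT field of biallelic records (`0/0`, `0/1`, `1/1`, `./.`;
#' phased separators accepted); non-biallelic records are skipped with
#' a message reporting the count.
#'
#' @param path input file.
#' @param format `"csv"` or `"vcf"`.
#' @return a [genotype_data()] object.
#' @export
read_genotypes <- function(path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (!all(c("CHROM", "POS") %in% names(tab)))
      stop("CSV must have CHROM and POS columns")
    samples <- setdiff(names(tab), c("CHROM", "POS"))
    g <- t(as.matrix(tab[, samples, drop = FALSE]))
    return(genotype_data(g,
                         loci = data.frame(chrom = tab$CHROM, pos = tab$POS),
                         samples = samples))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  biallelic <- !is.na(alt) & !grepl(",", alt)
  n_skip <- sum(!biallelic)
  if (n_skip > 0)
    message("skipped ", n_skip, " non-biallelic record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- vcfR::getFIX(v)[biallelic, , drop = FALSE]
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  g <- t(apply(gt, 2L, code))
  rownames(g) <- colnames(gt)
  genotype_data(g,
                loci = data.frame(chrom = fix[, "CHROM"],
                                  pos = as.integer(fix[, "POS"])),
                samples = colnames(gt))
}

#' Write genotypes to CSV
#'
#' Inverse of the CSV layout of [read_genotypes()].
#'
#' @param g a [genotype_data()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_data"))
  tab <- data.frame(CHROM = g$loci$chrom, POS = g$loci$pos,
                    t(g$genotypes), check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
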