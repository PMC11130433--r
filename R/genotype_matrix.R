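#' Genotype matrix container
#'
#' Bundles an accessions x markers dosage matrix with its marker map
#' (chromosome, position, alleles). Dosages are biallelic alt-allele counts
#' in `{0, 1, 2}` (inbred accessions carry only 0 and 2) or `NA` when
#' missing. Minor-allele frequencies are always recomputed from the
#' dosages, never trusted from input metadata.
#'
#' @param dosages numeric matrix, accessions in rows (rownames are
#'   accession ids), markers in columns.
#' @param map data.frame with one row per marker and columns `marker`,
#'   `chrom`, `pos` (1-based bp), `ref`, `alt`. Positions must be strictly
#'   increasing within each chromosome.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` and `map`; `map` gains recomputed `maf` and `low_maf`
#'   (MAF <= 0.05) columns.
#' @export
genotype_matrix <- function(dosages, map) {
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)))
  req <- c("marker", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(map))) {
    stop("map must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(map) != ncol(dosages)) {
    stop("map rows must match dosage columns")
  }
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  ord_ok <- tapply(map$pos, map$chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(ord_ok))) {
    stop("marker positions must be strictly increasing within chromosome")
  }
  colnames(dosages) <- map$marker
  map$maf <- marker_maf(dosages)
  map$low_maf <- map$maf <= 0.05
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

marker_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d accessions x %d markers on %d chromosome(s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom))
  ))
  cat(sprintf(
    "  MAF range %.3f-%.3f; %d marker(s) with MAF <= 0.05; %d missing call(s)\n",
    min(x$map$maf), max(x$map$maf), sum(x$map$low_maf), sum(is.na(x$dosages))
  ))
  invisible(x)
}

#' Write genotypes as a plain dosage TSV
#'
#' Column layout: marker, chrom, pos, ref, alt, then one column per
#' accession holding the dosage.
#'
#' @param geno a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, path) {
  tab <- cbind(
    geno$map[, c("marker", "chrom", "pos", "ref", "alt")],
    as.data.frame(t(geno$dosages))
  )
  utils::write.table(tab, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a dosage TSV written by [write_dosage_tsv()]
#'
#' @param path file path.
#' @return A [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.table(path,
    header = TRUE, sep = "\t",
    check.names = FALSE, colClasses = list(chrom = "character")
  )
  meta <- c("marker", "chrom", "pos", "ref", "alt")
  dos <- t(as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE]))
  storage.mode(dos) <- "double"
  colnames(dos) <- tab$marker
  genotype_matrix(dos, tab[, meta])
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' Homozygous dosages are written as `0/0` and `1/1`, heterozygotes as
#' `0/1`, missing as `./.`.
#'
#' @param geno a [genotype_matrix()].
#' @param path output file path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  acc <- rownames(geno$dosages)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=tempoqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
      "INFO", "FORMAT", acc
    ), collapse = "\t")
  ), con)
  gt <- matrix(gt_code[as.character(t(geno$dosages))],
    nrow = ncol(geno$dosages)
  )
  gt[is.na(gt)] <- "./."
  lines <- paste(geno$map$chrom, geno$map$pos, geno$map$marker,
    geno$map$ref, geno$map$alt, ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Biallelic SNPs only; the GT field is converted to alt-allele dosage.
#'
#' @param path path to a VCF file.
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
    dimnames = dimnames(gt)
  )
  clean <- gsub("\\|", "/", gt)
  dose[clean %in% c("0/0", "0")] <- 0
  dose[clean %in% c("0/1", "1/0")] <- 1
  dose[clean %in% c("1/1", "1")] <- 2
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  map <- data.frame(
    marker = ifelse(is.na(fix$ID) | fix$ID == ".",
      paste0(fix$CHROM, ":", fix$POS), fix$ID
    ),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    stringsAsFactors = FALSE
  )
  keep <- nchar(map$ref) == 1L & nchar(map$alt) == 1L
  genotype_matrix(t(dose[keep, , drop = FALSE]), map[keep, , drop = FALSE])
}
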