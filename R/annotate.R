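#' Write a gene annotation as GFF3
#'
#' @param genes a `gene_annotation` data.frame (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  stopifnot(all(genes$start >= 1), all(genes$start <= genes$end))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(paste(genes$chrom, "tempoqtl", "gene", genes$start,
      genes$end, ".", genes$strand, ".",
      paste0("ID=", genes$gene_id, ";Name=", genes$gene_id),
      sep = "\t"
    ), con)
  }
  invisible(path)
}

#' Read gene-level features from a GFF3 file
#'
#' @param path GFF3 path.
#' @param feature feature type to keep (default `"gene"`).
#' @return A `gene_annotation` data.frame.
#' @export
read_gff3 <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  genes <- data.frame(
    gene_id = if (length(gr)) as.character(gr$ID) else character(),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- c("gene_annotation", "data.frame")
  genes
}

#' Candidate genes within a window of significant markers
#'
#' Reports every gene whose body intersects the closed interval
#' `[pos - window, pos + window]` around each marker, on the same
#' chromosome (so a gene touching the boundary at exactly `window` bp is
#' included). Distance is 0 when the marker lies inside the gene,
#' otherwise the gap to the nearest gene edge; the relation records
#' whether the gene contains the marker or lies upstream (before) or
#' downstream (after) of it in genome coordinates. Strand is reported
#' for context but ignored for inclusion.
#'
#' @param markers data.frame with columns `marker`, `chrom`, `pos` (a
#'   hits table from [longitudinal_gwas()] also works; duplicate markers
#'   are collapsed).
#' @param annotation a `gene_annotation` data.frame or a GFF3 path.
#' @param window scan half-width in bp (default 15000).
#' @return data.frame of class `candidate_report`: `marker`, `gene_id`,
#'   `distance`, `relation`, `strand`. Markers on chromosomes absent
#'   from the annotation yield no rows and a warning.
#' @export
scan_window <- function(markers, annotation, window = 15000) {
  if (is.character(annotation)) annotation <- read_gff3(annotation)
  mk <- unique(markers[, c("marker", "chrom", "pos")])
  mk$chrom <- as.character(mk$chrom)
  missing_chr <- setdiff(mk$chrom, unique(annotation$chrom))
  if (length(missing_chr) && nrow(annotation)) {
    warning(
      "marker chromosome(s) absent from annotation: ",
      paste(missing_chr, collapse = ", ")
    )
  }
  if (!nrow(annotation) || !nrow(mk)) {
    out <- data.frame(
      marker = character(), gene_id = character(),
      distance = integer(), relation = character(), strand = character(),
      stringsAsFactors = FALSE
    )
    class(out) <- c("candidate_report", "data.frame")
    return(out)
  }
  q <- GenomicRanges::GRanges(
    mk$chrom,
    IRanges::IRanges(pmax(1L, mk$pos - window), mk$pos + window)
  )
  s <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start, annotation$end)
  )
  # our own warning above covers disjoint chromosome sets
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  )
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  pos <- mk$pos[qi]
  gstart <- annotation$start[si]
  gend <- annotation$end[si]
  inside <- pos >= gstart & pos <= gend
  distance <- ifelse(inside, 0L,
    ifelse(pos < gstart, gstart - pos, pos - gend)
  )
  relation <- ifelse(inside, "contains",
    ifelse(pos < gstart, "downstream", "upstream")
  )
  out <- data.frame(
    marker = mk$marker[qi], gene_id = annotation$gene_id[si],
    distance = as.integer(distance), relation = relation,
    strand = annotation$strand[si], stringsAsFactors = FALSE
  )
  out <- out[order(out$marker, out$distance, out$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("candidate_report", "data.frame")
  out
}
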