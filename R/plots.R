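#' Temporal Manhattan plot of longitudinal GWAS hits
#'
#' Day after planting against genome position, one point per
#' high-confidence hit; stringent-tier hits are drawn solid, lower-tier
#' hits open.
#'
#' @param hits hits table from [longitudinal_gwas()] (or the result).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the plotted data.frame.
#' @export
plot_temporal_manhattan <- function(hits, ...) {
  if (inherits(hits, "longitudinal_gwas")) hits <- hits$hits
  if (!nrow(hits)) {
    plot(0, 0, type = "n", xlab = "genome position", ylab = "DAP", ...)
    return(invisible(hits))
  }
  chroms <- sort(unique(hits$chrom))
  offs <- stats::setNames(
    cumsum(c(0, rep(7.5e7, length(chroms) - 1))),
    chroms
  )
  x <- hits$pos + offs[hits$chrom]
  plot(x, hits$DAP,
    pch = ifelse(hits$tier == "stringent", 19, 1),
    col = (match(hits$chrom, chroms) - 1) %% 2 + 1,
    xlab = "genome position (chromosomes concatenated)",
    ylab = "DAP", ...
  )
  invisible(hits)
}

#' Temporal allele-effect plot for one marker
#'
#' Mean trait value per allele class over days, with significance stars
#' at days where the marker was a high-confidence GWAS hit (two stars for
#' the stringent tier, one for the lower tier).
#'
#' @param aes an [allele_effect_series()].
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `aes`.
#' @export
plot_allele_series <- function(aes, ...) {
  al <- attr(aes, "alleles")
  graphics::matplot(aes$DAP, cbind(aes$mean_ref, aes$mean_alt),
    type = "l", lty = 1, col = c("steelblue", "firebrick"),
    xlab = "DAP", ylab = "trait value", ...
  )
  graphics::legend("topleft",
    legend = c(al["ref"], al["alt"]),
    col = c("steelblue", "firebrick"), lty = 1, bty = "n"
  )
  star <- ifelse(is.na(aes$tier), "",
    ifelse(aes$tier == "stringent", "**", "*")
  )
  ymax <- pmax(aes$mean_ref, aes$mean_alt)
  graphics::text(aes$DAP, ymax, star, pos = 3, cex = 0.8)
  invisible(aes)
}
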