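#' Percentile ranks of a cross-section of values
#'
#' Converts values to percentiles between 0 and 100 using
#' `100 * (rank - 1) / (n - 1)` with average ranks for ties; with all
#' values tied every percentile is 50. Missing values stay missing.
#'
#' @param x numeric vector (one trait at one day, across accessions).
#' @return Percentiles in `[0, 100]`.
#' @export
percentile_rank <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  out <- rep(NA_real_, length(x))
  if (n < 2L) stop("need >= 2 non-missing values")
  out[obs] <- 100 * (rank(x[obs], ties.method = "average") - 1) / (n - 1)
  out
}

#' Accession x day matrix for one trait
#'
#' @param traits an accession-level long trait table (or `trait_data`).
#' @param trait trait name to extract.
#' @return Numeric matrix, accessions in rows (sorted by id), days in
#'   columns.
#' @export
trait_matrix <- function(traits, trait) {
  tab <- if (inherits(traits, "trait_data")) traits$accession else traits
  tab <- tab[tab$trait == trait, ]
  if (!nrow(tab)) stop("trait not found: ", trait)
  m <- tapply(tab$value, list(tab$accession, tab$DAP), function(v) v[1])
  m[order(rownames(m)), order(as.integer(colnames(m))), drop = FALSE]
}

#' Per-day percentile table for a trait or trait ratio
#'
#' @param traits accession-level long trait table or `trait_data`.
#' @param trait trait name; for a ratio give `c("height", "biomass")`
#'   (numerator, denominator).
#' @return Accession x day matrix of percentiles.
#' @export
percentile_table <- function(traits, trait) {
  m <- if (length(trait) == 2L) {
    num <- trait_matrix(traits, trait[1])
    den <- trait_matrix(traits, trait[2])
    r <- num / den
    r[!is.finite(r)] <- NA
    r
  } else {
    trait_matrix(traits, trait)
  }
  apply(m, 2L, function(col) {
    if (sum(!is.na(col)) < 2L) rep(NA_real_, length(col))
    else percentile_rank(col)
  })
}

#' Classify ideotype-positive and ideotype-negative accessions
#'
#' Averages each accession's WUE percentile and height-to-biomass-ratio
#' percentile over the window. Ideotype-positive accessions combine a
#' ratio in the bottom `ratio_frac` of the population with a WUE in the
#' top `wue_frac`; ideotype-negative accessions are the mirror image
#' (bottom `wue_frac` of WUE, top `ratio_frac` of the ratio).
#'
#' @param wue_pct accession x day percentile matrix for WUE.
#' @param ratio_pct accession x day percentile matrix for
#'   height:biomass.
#' @param window inclusive DAP range, e.g. `c(15, 31)` (early) or
#'   `c(39, 56)` (late).
#' @param wue_frac top/bottom WUE fraction (default 0.10).
#' @param ratio_frac bottom/top ratio fraction (default 0.05).
#' @return A list of class `ideotype_report`: `positives`, `negatives`,
#'   `means` (per-accession window-mean percentiles), `window`.
#' @export
select_ideotypes <- function(wue_pct, ratio_pct, window = c(15, 31),
                             wue_frac = 0.10, ratio_frac = 0.05) {
  days <- as.integer(colnames(wue_pct))
  sel <- days >= window[1] & days <= window[2]
  if (!any(sel)) stop("window contains no days")
  acc <- intersect(rownames(wue_pct), rownames(ratio_pct))
  wue_m <- rowMeans(wue_pct[acc, sel, drop = FALSE], na.rm = TRUE)
  rat_m <- rowMeans(ratio_pct[acc, sel, drop = FALSE], na.rm = TRUE)
  pos <- acc[wue_m >= 100 * (1 - wue_frac) & rat_m <= 100 * ratio_frac]
  neg <- acc[wue_m <= 100 * wue_frac & rat_m >= 100 * (1 - ratio_frac)]
  structure(
    list(
      positives = sort(pos), negatives = sort(neg),
      means = data.frame(
        accession = acc, wue_pct = unname(wue_m),
        ratio_pct = unname(rat_m), stringsAsFactors = FALSE
      ),
      window = window
    ),
    class = "ideotype_report"
  )
}

#' Cluster temporal trait profiles
#'
#' Hierarchical clustering of accession profiles (days as coordinates)
#' with Euclidean distances and Ward's agglomeration, cut at `k`
#' clusters. Accessions with incomplete profiles over the day range are
#' dropped with a warning. Besides the per-cluster mean profile, a
#' PCA-weighted mean is computed for clustergram-style displays: members
#' are weighted by the rank of their score on the first principal
#' component of the profile matrix.
#'
#' @param traits accession-level long trait table or `trait_data`.
#' @param trait trait to cluster.
#' @param k number of clusters (default 7).
#' @param dap_range inclusive day range (default `c(12, 56)`).
#' @return A list of class `cluster_result`: `k`, `assignments` (named
#'   integer vector), `mean_profiles` (k x days), `pca_weighted_means`,
#'   `hclust` (the linkage record), `days`.
#' @export
cluster_profiles <- function(traits, trait, k = 7, dap_range = c(12, 56)) {
  m <- trait_matrix(traits, trait)
  days <- as.integer(colnames(m))
  m <- m[, days >= dap_range[1] & days <= dap_range[2], drop = FALSE]
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    warning(sum(!complete), " accession(s) with incomplete profiles dropped")
    m <- m[complete, , drop = FALSE]
  }
  if (k > nrow(m)) stop("k exceeds the number of complete profiles")
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  assign <- stats::cutree(hc, k = k)
  mean_profiles <- do.call(rbind, lapply(seq_len(k), function(cl) {
    colMeans(m[assign == cl, , drop = FALSE])
  }))
  pc1 <- stats::prcomp(m, center = TRUE, scale. = FALSE)$x[, 1]
  pca_weighted <- do.call(rbind, lapply(seq_len(k), function(cl) {
    rows <- which(assign == cl)
    w <- rank(pc1[rows])
    colSums(m[rows, , drop = FALSE] * w) / sum(w)
  }))
  rownames(mean_profiles) <- rownames(pca_weighted) <-
    paste0("cluster", seq_len(k))
  structure(
    list(
      k = k, assignments = assign, mean_profiles = mean_profiles,
      pca_weighted_means = pca_weighted, hclust = hc,
      days = as.integer(colnames(m))
    ),
    class = "cluster_result"
  )
}

#' Mean silhouette width across candidate cluster counts
#'
#' Aid for choosing `k`: Ward clustering is cut at each candidate count
#' and the mean silhouette width reported.
#'
#' @inheritParams cluster_profiles
#' @param k_range candidate cluster counts (default 2:10).
#' @return data.frame with columns `k`, `mean_silhouette`.
#' @export
silhouette_curve <- function(traits, trait, k_range = 2:10,
                             dap_range = c(12, 56)) {
  if (!requireNamespace("cluster", quietly = TRUE)) {
    stop("the 'cluster' package is required for silhouette_curve")
  }
  m <- trait_matrix(traits, trait)
  days <- as.integer(colnames(m))
  m <- m[, days >= dap_range[1] & days <= dap_range[2], drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  d <- stats::dist(m)
  hc <- stats::hclust(d, method = "ward.D2")
  data.frame(
    k = k_range,
    mean_silhouette = vapply(k_range, function(k) {
      mean(cluster::silhouette(stats::cutree(hc, k), d)[, 3])
    }, numeric(1))
  )
}

#' Top and bottom accessions for a trait at one day
#'
#' @param traits accession-level long trait table or `trait_data`.
#' @param trait trait name.
#' @param dap day at which to rank.
#' @param fraction fraction per tail (default 0.05); each set holds
#'   `ceiling(fraction * n)` accessions.
#' @return A list with `top` and `bottom` accession id vectors (ties
#'   broken by accession id).
#' @export
rank_top_bottom <- function(traits, trait, dap, fraction = 0.05) {
  m <- trait_matrix(traits, trait)
  col <- which(as.integer(colnames(m)) == dap)
  if (!length(col)) stop("no values at DAP ", dap)
  v <- m[, col]
  v <- v[!is.na(v)]
  n_take <- ceiling(fraction * length(v))
  o_desc <- order(-v, names(v))
  o_asc <- order(v, names(v))
  list(
    top = names(v)[o_desc[seq_len(n_take)]],
    bottom = names(v)[o_asc[seq_len(n_take)]]
  )
}
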