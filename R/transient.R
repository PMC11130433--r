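#' Per-day multi-locus GWAS across traits
#'
#' Runs the MLMM engine once per (trait, day): genotypes are MAF-filtered
#' and mean-imputed, the Astle-Balding kinship and its eigendecomposition
#' are computed once for the accession panel shared with the trait table,
#' and the first `n_pcs` genotype principal components enter every model
#' as structure covariates. Phenotypes are Box-Cox transformed when a
#' Shapiro-Wilk test rejects normality at `normality_alpha` (set
#' `boxcox = "never"` or `"always"` to override). A failed single fit is
#' logged and skipped, never fatal.
#'
#' @param geno a [genotype_matrix()].
#' @param traits accession-level long trait table or `trait_data`.
#' @param trait_names traits to analyze (default: all in the table).
#' @param dap_range inclusive day range to analyze (default: all days
#'   present).
#' @param n_pcs number of structure covariates (default 3).
#' @param maf_min MAF filter threshold.
#' @param alpha familywise level for model selection.
#' @param max_steps forward-search cap.
#' @param gamma extended-BIC weight.
#' @param boxcox `"auto"` (default), `"never"` or `"always"`.
#' @param normality_alpha Shapiro-Wilk level driving the `"auto"` rule.
#' @return A list of class `longitudinal_gwas`: `fits` (named
#'   `trait@DAP`), `hits` (long data.frame marker/chrom/pos/trait/DAP/
#'   tier/p), `panel` (accessions used), `m_markers`, `skipped`,
#'   `transform_log`.
#' @export
longitudinal_gwas <- function(geno, traits, trait_names = NULL,
                              dap_range = NULL, n_pcs = 3,
                              maf_min = 0.05, alpha = 0.05,
                              max_steps = 20, gamma = 1.0,
                              boxcox = c("auto", "never", "always"),
                              normality_alpha = 0.01) {
  boxcox <- match.arg(boxcox)
  tab <- if (inherits(traits, "trait_data")) traits$accession else traits
  if (is.null(trait_names)) trait_names <- unique(tab$trait)
  daps <- sort(unique(tab$DAP))
  if (!is.null(dap_range)) {
    daps <- daps[daps >= dap_range[1] & daps <= dap_range[2]]
  }
  panel <- intersect(rownames(geno$dosages), unique(tab$accession))
  if (length(panel) < 10L) stop("fewer than 10 accessions shared")
  sub <- geno
  sub$dosages <- geno$dosages[panel, , drop = FALSE]
  fg <- maf_filter_impute(sub, maf_min = maf_min)
  K <- astle_balding_kinship(fg)
  eigen_K <- eigen(K$matrix, symmetric = TRUE)
  pcs <- genotype_pca(fg, n_pcs = n_pcs)$scores
  X0 <- cbind(intercept = 1, pcs)
  map <- fg$map

  fits <- list()
  hits <- list()
  skipped <- character(0)
  transform_log <- list()
  for (tr in trait_names) {
    sub_tr <- tab[tab$trait == tr, ]
    for (dd in daps) {
      key <- paste0(tr, "@", dd)
      res <- tryCatch({
        v <- sub_tr$value[sub_tr$DAP == dd][
          match(panel, sub_tr$accession[sub_tr$DAP == dd])
        ]
        ok <- !is.na(v)
        if (sum(ok) < 10L) stop("too few phenotyped accessions")
        y <- v[ok]
        transform <- boxcox == "always" ||
          (boxcox == "auto" && length(y) >= 10 &&
            stats::shapiro.test(y)$p.value < normality_alpha)
        if (transform) {
          offset <- if (min(y) <= 0) -min(y) + 1e-6 * (diff(range(y)) + 1)
          else 0
          y <- boxcox_transform(y, offset = offset)$transformed
        }
        transform_log[[key]] <- transform
        if (all(ok)) {
          fit <- mlmm(y, X0, markers = fg$dosages, map = map,
            alpha = alpha, max_steps = max_steps, gamma = gamma,
            eigen_K = eigen_K
          )
        } else {
          Ksub <- K$matrix[ok, ok]
          fit <- mlmm(y, X0[ok, , drop = FALSE],
            K = Ksub,
            markers = fg$dosages[ok, , drop = FALSE], map = map,
            alpha = alpha, max_steps = max_steps, gamma = gamma
          )
        }
        fit
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- c(skipped, key)
        next
      }
      fits[[key]] <- res
      hc <- res$selection$high_confidence
      if (nrow(hc)) {
        idx <- match(hc$marker, map$marker)
        hits[[key]] <- data.frame(
          marker = hc$marker, chrom = map$chrom[idx], pos = map$pos[idx],
          trait = tr, DAP = dd, tier = hc$tier,
          p = res$scan0$p[match(hc$marker, res$scan0$marker)],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else data.frame(
    marker = character(), chrom = character(), pos = integer(),
    trait = character(), DAP = integer(), tier = character(),
    p = numeric(), stringsAsFactors = FALSE
  )
  rownames(hits) <- NULL
  structure(
    list(
      fits = fits, hits = hits, panel = panel,
      m_markers = ncol(fg$dosages), daps = daps, skipped = skipped,
      transform_log = transform_log, map = map
    ),
    class = "longitudinal_gwas"
  )
}

# group sorted integer days into maximal runs with a gap tolerance
group_runs <- function(daps, gap = 0) {
  daps <- sort(unique(daps))
  if (!length(daps)) {
    return(data.frame(start = integer(), end = integer()))
  }
  brk <- c(0L, which(diff(daps) > gap + 1L), length(daps))
  data.frame(
    start = daps[brk[-length(brk)] + 1L],
    end = daps[brk[-1L]]
  )
}

#' Assemble transient-QTL tracks from longitudinal hits
#'
#' Groups each marker-trait pair's significant days into maximal
#' consecutive runs (an optional gap tolerance can bridge isolated
#' non-significant days). A track is transient when at least one
#' non-significant day separates its runs, or when it switches off
#' before the final analyzed day.
#'
#' @param hits the `hits` table of a [longitudinal_gwas()] result (or
#'   the result itself).
#' @param final_dap last analyzed day (inferred from the result when one
#'   is passed).
#' @param gap tolerated gap between consecutive significant days
#'   (default 0 = strict consecutiveness).
#' @return data.frame of class `transient_tracks`: one row per run with
#'   `marker`, `trait`, `start`, `end`, `n_daps` (total significant days
#'   of the pair), `n_runs`, `transient`.
#' @export
detect_transient <- function(hits, final_dap = NULL, gap = 0) {
  if (inherits(hits, "longitudinal_gwas")) {
    if (is.null(final_dap)) final_dap <- max(hits$daps)
    hits <- hits$hits
  }
  if (!nrow(hits)) {
    out <- data.frame(
      marker = character(), trait = character(), start = integer(),
      end = integer(), n_daps = integer(), n_runs = integer(),
      transient = logical()
    )
    class(out) <- c("transient_tracks", "data.frame")
    return(out)
  }
  if (is.null(final_dap)) final_dap <- max(hits$DAP)
  keys <- split(hits, paste(hits$marker, hits$trait, sep = "\r"))
  out <- do.call(rbind, lapply(keys, function(h) {
    runs <- group_runs(h$DAP, gap = gap)
    transient <- nrow(runs) > 1L || max(h$DAP) < final_dap
    data.frame(
      marker = h$marker[1], trait = h$trait[1],
      start = runs$start, end = runs$end,
      n_daps = length(unique(h$DAP)), n_runs = nrow(runs),
      transient = transient, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out <- out[order(out$marker, out$trait, out$start), ]
  class(out) <- c("transient_tracks", "data.frame")
  out
}

#' Markers significant for two or more traits
#'
#' @param hits the `hits` table of a [longitudinal_gwas()] result (or
#'   the result itself).
#' @return A named list: for each pleiotropic marker, a list mapping
#'   trait name to the sorted vector of significant days.
#' @export
detect_pleiotropy <- function(hits) {
  if (inherits(hits, "longitudinal_gwas")) hits <- hits$hits
  if (!nrow(hits)) return(list())
  by_marker <- split(hits, hits$marker)
  multi <- Filter(function(h) length(unique(h$trait)) >= 2L, by_marker)
  lapply(multi, function(h) {
    lapply(split(h$DAP, h$trait), function(d) sort(unique(d)))
  })
}

#' Per-allele phenotype trajectory at one marker
#'
#' For every day, accession trait values are grouped by homozygous allele
#' class at the marker and compared with a Welch two-sample t-test. Days
#' where the marker was a high-confidence GWAS hit can be tagged with
#' their confidence tier by passing the hits table.
#'
#' @param geno a [genotype_matrix()].
#' @param traits accession-level long trait table or `trait_data`.
#' @param marker marker id.
#' @param trait trait name.
#' @param hits optional hits table for tier tagging.
#' @param min_class minimum accessions per allele class for testing
#'   (default 3); below it the means are still reported but the test is
#'   suppressed.
#' @return data.frame of class `allele_effect_series`: per day the means
#'   and counts per allele class, their difference (alt minus ref
#'   homozygote), Welch p-value, and GWAS tier (`NA` when not a hit).
#' @export
allele_effect_series <- function(geno, traits, marker, trait,
                                 hits = NULL, min_class = 3) {
  tab <- if (inherits(traits, "trait_data")) traits$accession else traits
  tab <- tab[tab$trait == trait, ]
  j <- match(marker, geno$map$marker)
  if (is.na(j)) stop("unknown marker: ", marker)
  dos <- geno$dosages[, j]
  classes <- sort(unique(dos[dos %in% c(0, 2)]))
  if (length(classes) < 2L) stop("marker has fewer than 2 homozygous classes")
  ref_allele <- geno$map$ref[j]
  alt_allele <- geno$map$alt[j]
  daps <- sort(unique(tab$DAP))
  rows <- lapply(daps, function(dd) {
    sub <- tab[tab$DAP == dd, ]
    v <- sub$value[match(names(dos), sub$accession)]
    g0 <- v[dos == 0 & !is.na(v)]
    g2 <- v[dos == 2 & !is.na(v)]
    testable <- length(g0) >= min_class && length(g2) >= min_class &&
      (stats::sd(g0) > 0 || stats::sd(g2) > 0)
    pv <- if (testable) {
      stats::t.test(g2, g0)$p.value
    } else {
      NA_real_
    }
    data.frame(
      DAP = dd, mean_ref = mean(g0), n_ref = length(g0),
      mean_alt = mean(g2), n_alt = length(g2),
      diff = mean(g2) - mean(g0), p = pv,
      tested = testable, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$tier <- NA_character_
  if (!is.null(hits)) {
    if (inherits(hits, "longitudinal_gwas")) hits <- hits$hits
    h <- hits[hits$marker == marker & hits$trait == trait, ]
    out$tier[match(h$DAP, out$DAP)] <- h$tier
  }
  attr(out, "marker") <- marker
  attr(out, "alleles") <- c(ref = ref_allele, alt = alt_allele)
  class(out) <- c("allele_effect_series", "data.frame")
  out
}
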