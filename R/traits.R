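#' Composite plant area from three camera views
#'
#' Plant area is the sum of the pixel counts from the top view and the two
#' side views, multiplied by the zoom-level scale factor so that areas
#' remain comparable when the optical zoom changes during the run.
#'
#' @param tv_px,sv1_px,sv2_px pixel counts (vectors recycle together).
#' @param scale_factor positive scale factor for the active zoom level.
#' @return Composite area in scaled pixel units.
#' @export
composite_area <- function(tv_px, sv1_px, sv2_px, scale_factor = 1) {
  if (any(c(tv_px, sv1_px, sv2_px) < 0, na.rm = TRUE)) {
    stop("pixel counts must be >= 0")
  }
  if (any(scale_factor <= 0)) stop("scale_factor must be > 0")
  (tv_px + sv1_px + sv2_px) * scale_factor
}

#' Germination day from a top-view area series
#'
#' The earliest day with a positive top-view area is the germination day;
#' a plant with no positive value never germinated.
#'
#' @param values top-view areas.
#' @param daps day indices aligned with `values`.
#' @return The germination DAP, or `NA` if the plant never germinated.
#' @export
call_germination <- function(values, daps = seq_along(values)) {
  stopifnot(length(values) == length(daps))
  o <- order(daps)
  hit <- which(values[o] > 0)
  if (!length(hit)) return(NA_real_)
  daps[o][hit[1]]
}

#' Death day from a top-view area series
#'
#' A plant is called dead when, after germinating, its top-view area is
#' zero for `run` consecutive days; the death day is the first day of that
#' run. This operational rule exists to support the exclusion of plants
#' that died early in the experiment.
#'
#' @param values top-view areas ordered by `daps`.
#' @param daps day indices.
#' @param run number of consecutive zero days that defines death.
#' @return The death DAP, or `NA` if the plant never died (or never
#'   germinated).
#' @export
call_death <- function(values, daps = seq_along(values), run = 5) {
  o <- order(daps)
  v <- values[o]
  dd <- daps[o]
  g <- call_germination(v, dd)
  if (is.na(g)) return(NA_real_)
  post <- which(dd > g)
  if (length(post) < run) return(NA_real_)
  zero <- v[post] == 0
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= run)
  if (!length(hit)) return(NA_real_)
  dd[post][starts[hit[1]]]
}

#' Exclude accessions whose plants failed to establish
#'
#' An accession is retained when at least `min_plants` of its plants
#' germinated and neither died by the cutoff day. Mirrors the exclusion of
#' accessions that never germinated or died by 46 DAP.
#'
#' @param plants data.frame with columns `plant_id`, `accession`,
#'   `germ_dap` (NA if never germinated) and `death_dap` (NA if alive).
#' @param cutoff death cutoff day (default 46).
#' @param min_plants minimum surviving plants per accession (default 2).
#' @return Character vector of retained accession ids.
#' @export
exclude_failed <- function(plants, cutoff = 46, min_plants = 2) {
  ok <- !is.na(plants$germ_dap) &
    (is.na(plants$death_dap) | plants$death_dap > cutoff)
  counts <- tapply(ok, plants$accession, sum)
  names(counts)[counts >= min_plants]
}

#' Flag gross outliers by the k-MAD rule
#'
#' A value is an outlier when its absolute deviation from the median
#' exceeds `k` raw median absolute deviations (MAD without the normal
#' consistency constant). The default fence of 40 MAD is deliberately
#' conservative: it targets gross image-segmentation artifacts, not
#' distributional outliers. When the MAD is zero the rule is undefined and
#' nothing is flagged.
#'
#' @param x numeric vector (NAs pass through unflagged).
#' @param k MAD multiplier (default 40).
#' @return Logical vector, `TRUE` where `x` is an outlier.
#' @export
mad_outliers <- function(x, k = 40) {
  out <- rep(FALSE, length(x))
  obs <- !is.na(x)
  if (sum(obs) < 3L) return(out)
  med <- stats::median(x[obs])
  mad_raw <- stats::median(abs(x[obs] - med))
  if (mad_raw == 0) return(out)
  out[obs] <- abs(x[obs] - med) > k * mad_raw
  out
}

#' Remove k-MAD outliers from a series
#'
#' Flagged values are replaced by `NA` (removed, never imputed).
#'
#' @inheritParams mad_outliers
#' @return `x` with outliers set to `NA`; the logical flag vector is
#'   attached as attribute `"removed"`.
#' @export
remove_outliers <- function(x, k = 40) {
  bad <- mad_outliers(x, k)
  x[bad] <- NA
  attr(x, "removed") <- bad
  x
}

#' Smooth a daily series with loess
#'
#' Fits a locally-weighted polynomial regression of value on day and
#' returns the fitted values at the observed days; downstream analyses use
#' these fitted values as the phenotype. Series with fewer than five
#' observed points are returned unchanged, flagged via the `"smoothed"`
#' attribute.
#'
#' @param values numeric series (NAs allowed; they stay NA).
#' @param daps day indices.
#' @param span loess span (default 0.5).
#' @param degree local polynomial degree (default 2).
#' @return Fitted values aligned with `daps`, with attribute `"smoothed"`.
#' @export
smooth_series <- function(values, daps = seq_along(values), span = 0.5,
                          degree = 2) {
  obs <- !is.na(values)
  if (sum(obs) < 5L) {
    attr(values, "smoothed") <- FALSE
    return(values)
  }
  fit <- stats::loess(values[obs] ~ daps[obs],
    span = span, degree = degree,
    control = stats::loess.control(surface = "direct")
  )
  out <- values
  out[obs] <- stats::fitted(fit)
  attr(out, "smoothed") <- TRUE
  out
}

#' Calibrate biomass from endpoint fresh weight
#'
#' Ordinary least squares of harvest fresh weight on image-derived area at
#' the calibration day; the fitted line converts area to biomass on every
#' day, floored at zero.
#'
#' @param areas areas at the calibration day, one per plant.
#' @param fresh_weights endpoint fresh weights, aligned with `areas`.
#' @return List of class `biomass_calibration`: `slope`, `intercept`,
#'   `r2`, `n`.
#' @export
calibrate_biomass <- function(areas, fresh_weights) {
  keep <- !is.na(areas) & !is.na(fresh_weights)
  if (sum(keep) < 3L) stop("need >= 3 paired observations")
  if (stats::var(areas[keep]) == 0) stop("zero variance in areas")
  fit <- stats::lm(fresh_weights[keep] ~ areas[keep])
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = suppressWarnings(summary(fit)$r.squared), n = sum(keep)
    ),
    class = "biomass_calibration"
  )
}

#' Apply a biomass calibration to areas
#'
#' @param calibration a [calibrate_biomass()] result.
#' @param areas areas to convert.
#' @return Biomass values, floored at 0.
#' @export
apply_biomass <- function(calibration, areas) {
  pmax(calibration$slope * areas + calibration$intercept, 0)
}

#' Water use efficiency series
#'
#' WUE at day t is the plant area divided by the cumulative water added
#' through day t. Days with zero cumulative water give a missing value,
#' never an infinity.
#'
#' @param areas area series ordered by `daps`.
#' @param water_g daily water additions aligned with `daps`.
#' @param daps day indices.
#' @return WUE series (area units per gram).
#' @export
compute_wue <- function(areas, water_g, daps = seq_along(areas)) {
  if (any(water_g < 0, na.rm = TRUE)) stop("water added must be >= 0")
  o <- order(daps)
  cum <- cumsum(ifelse(is.na(water_g[o]), 0, water_g[o]))
  wue <- rep(NA_real_, length(areas))
  ok <- cum > 0
  wue[o][ok] <- areas[o][ok] / cum[ok]
  wue
}

#' Relative growth rate between two time points
#'
#' RGR is the difference of the mean log areas at the two time points
#' divided by the elapsed days: the replicate areas are log-transformed
#' first, then averaged. Nonpositive areas are dropped from the log-mean.
#'
#' @param areas_t1,areas_t2 replicate areas at the two time points.
#' @param t1,t2 day indices, `t2 > t1`.
#' @return RGR in per-day units (NA when either log-mean is empty).
#' @export
compute_rgr <- function(areas_t1, areas_t2, t1, t2) {
  if (t2 <= t1) stop("t2 must exceed t1")
  lm1 <- log(areas_t1[!is.na(areas_t1) & areas_t1 > 0])
  lm2 <- log(areas_t2[!is.na(areas_t2) & areas_t2 > 0])
  if (!length(lm1) || !length(lm2)) return(NA_real_)
  (mean(lm2) - mean(lm1)) / (t2 - t1)
}

#' Daily RGR series from replicate area series
#'
#' Applies [compute_rgr()] to consecutive-day pairs; the value for the
#' pair (t, t+1) is reported at day t+1.
#'
#' @param area_mat plants x days matrix of areas (replicates of one
#'   accession).
#' @param daps day indices for the columns.
#' @return Named numeric vector of RGR per day (first day NA).
#' @export
rgr_series <- function(area_mat, daps = seq_len(ncol(area_mat))) {
  o <- order(daps)
  area_mat <- area_mat[, o, drop = FALSE]
  daps <- daps[o]
  out <- rep(NA_real_, length(daps))
  for (i in seq_along(daps)[-1]) {
    out[i] <- compute_rgr(
      area_mat[, i - 1L], area_mat[, i],
      daps[i - 1L], daps[i]
    )
  }
  stats::setNames(out, daps)
}

#' Derive analysis traits from raw measurement tables
#'
#' Runs the full trait pipeline: composite area from the three views,
#' germination and death calling, exclusion of failed accessions, gross
#' outlier removal by the 40-MAD rule applied per trait per day across
#' plants, per-plant loess smoothing over days, biomass calibration from
#' endpoint fresh weight, WUE from cumulative water, RGR from replicate
#' log areas, and finally the replicate median per accession.
#'
#' @param pheno long-format measurement table with columns `plant_id`,
#'   `accession`, `replicate`, `DAP`, `trait`, `value`; traits `tv_area`,
#'   `sv_area1`, `sv_area2`, `height_px`, `hull_px` daily and
#'   `fresh_weight` at the final day.
#' @param water watering table with columns `plant_id`, `DAP`, `water_g`.
#' @param zoom_breaks days at which the optical zoom changed.
#' @param scale_factors one scale factor per zoom period
#'   (`length(zoom_breaks) + 1`).
#' @param mad_k MAD fence multiplier.
#' @param span,degree loess parameters.
#' @param calibration_dap day whose areas calibrate biomass.
#' @param death_cutoff exclusion cutoff day.
#' @param min_plants minimum established plants per retained accession.
#' @param traits which derived traits to compute (default all six);
#'   restricting the set skips the smoothing work of unused measurements.
#' @return A list of class `trait_data`: `plant` (plant-level smoothed
#'   long table), `accession` (replicate-median long table with traits
#'   area, height, hull_area, biomass, wue, rgr), `calibration`,
#'   `germination` (per plant), `retained` accession ids.
#' @export
derive_traits <- function(pheno, water, zoom_breaks = c(19, 40),
                          scale_factors = c(1, 1, 1), mad_k = 40,
                          span = 0.5, degree = 2, calibration_dap = 51,
                          death_cutoff = 46, min_plants = 2,
                          traits = c(
                            "area", "height", "hull_area", "biomass",
                            "wue", "rgr"
                          )) {
  stopifnot(length(scale_factors) == length(zoom_breaks) + 1L)
  traits <- match.arg(traits, several.ok = TRUE)
  daps <- sort(unique(pheno$DAP))
  n_days <- max(daps)

  wide <- function(df) {
    m <- tapply(df$value, list(df$plant_id, df$DAP), function(v) v[1])
    m[, order(as.integer(colnames(m))), drop = FALSE]
  }
  tv <- wide(pheno[pheno$trait == "tv_area", ])
  sv1 <- wide(pheno[pheno$trait == "sv_area1", ])
  sv2 <- wide(pheno[pheno$trait == "sv_area2", ])
  ids <- rownames(tv)
  day_idx <- as.integer(colnames(tv))
  period <- findInterval(day_idx, zoom_breaks) + 1L
  sf <- scale_factors[period]
  area <- composite_area(tv, sv1[ids, , drop = FALSE],
    sv2[ids, , drop = FALSE],
    scale_factor = rep(sf, each = nrow(tv))
  )
  height <- wide(pheno[pheno$trait == "height_px", ])[ids, , drop = FALSE]
  hull <- wide(pheno[pheno$trait == "hull_px", ])[ids, , drop = FALSE]

  meta <- unique(pheno[, c("plant_id", "accession", "replicate")])
  meta <- meta[match(ids, meta$plant_id), ]

  germ <- apply(tv, 1L, call_germination, daps = day_idx)
  death <- vapply(
    seq_along(ids),
    function(i) call_death(tv[i, ], day_idx), numeric(1)
  )
  plants <- data.frame(
    plant_id = ids, accession = meta$accession,
    replicate = meta$replicate, germ_dap = germ, death_dap = death,
    stringsAsFactors = FALSE
  )
  retained <- exclude_failed(plants,
    cutoff = death_cutoff,
    min_plants = min_plants
  )
  live <- meta$accession %in% retained & !is.na(germ) &
    (is.na(death) | death > death_cutoff)

  qc_one <- function(mat) {
    m <- mat[live, , drop = FALSE]
    # gross artifacts: fence across measured (germinated) plants per day
    for (j in seq_len(ncol(m))) {
      pos <- which(!is.na(m[, j]) & m[, j] > 0)
      m[pos, j] <- remove_outliers(m[pos, j], k = mad_k)
    }
    # per-plant temporal smoothing over the germinated span
    for (i in seq_len(nrow(m))) {
      g <- germ[live][i]
      span_cols <- which(day_idx >= g)
      m[i, span_cols] <- smooth_series(m[i, span_cols],
        daps = day_idx[span_cols], span = span, degree = degree
      )
      m[i, ] <- pmax(m[i, ], 0)
    }
    m
  }
  need_area <- any(c("area", "biomass", "wue", "rgr") %in% traits)
  area_s <- if (need_area) qc_one(area) else NULL
  live_ids <- ids[live]
  live_meta <- meta[live, ]

  plant_traits <- list()
  if ("area" %in% traits) plant_traits$area <- area_s
  if ("height" %in% traits) plant_traits$height <- qc_one(height)
  if ("hull_area" %in% traits) plant_traits$hull_area <- qc_one(hull)

  calibration <- NULL
  if ("biomass" %in% traits) {
    fwt <- pheno[pheno$trait == "fresh_weight", ]
    fw <- fwt$value[match(live_ids, fwt$plant_id)]
    cal_col <- which.min(abs(day_idx - calibration_dap))
    calibration <- calibrate_biomass(area_s[, cal_col], fw)
    plant_traits$biomass <- apply_biomass(calibration, area_s)
  }
  if ("wue" %in% traits) {
    wmat <- tapply(water$water_g, list(water$plant_id, water$DAP),
      function(v) v[1]
    )
    wmat <- wmat[live_ids, order(as.integer(colnames(wmat))), drop = FALSE]
    wue_s <- t(vapply(
      seq_along(live_ids),
      function(i) compute_wue(area_s[i, ], wmat[i, ], day_idx),
      numeric(length(day_idx))
    ))
    dimnames(wue_s) <- dimnames(area_s)
    plant_traits$wue <- wue_s
  }
  plant_long <- do.call(rbind, lapply(names(plant_traits), function(tr) {
    m <- plant_traits[[tr]]
    data.frame(
      plant_id = rep(live_ids, times = ncol(m)),
      accession = rep(live_meta$accession, times = ncol(m)),
      replicate = rep(live_meta$replicate, times = ncol(m)),
      DAP = rep(day_idx, each = nrow(m)),
      trait = tr, value = as.vector(m), stringsAsFactors = FALSE
    )
  }))

  acc_of <- live_meta$accession
  acc_median <- function(m) {
    do.call(rbind, lapply(split(seq_len(nrow(m)), acc_of), function(rows) {
      apply(m[rows, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    }))
  }
  acc_long <- do.call(rbind, lapply(names(plant_traits), function(tr) {
    m <- acc_median(plant_traits[[tr]])
    data.frame(
      accession = rep(rownames(m), times = ncol(m)),
      DAP = rep(day_idx, each = nrow(m)),
      trait = tr, value = as.vector(m), stringsAsFactors = FALSE
    )
  }))
  if ("rgr" %in% traits) {
    rgr_long <- do.call(
      rbind,
      lapply(split(seq_len(nrow(area_s)), acc_of), function(rows) {
        r <- rgr_series(area_s[rows, , drop = FALSE], day_idx)
        data.frame(
          accession = acc_of[rows[1]], DAP = day_idx, trait = "rgr",
          value = unname(r), stringsAsFactors = FALSE
        )
      })
    )
    acc_long <- rbind(acc_long, rgr_long)
  }
  rownames(acc_long) <- NULL

  structure(
    list(
      plant = plant_long, accession = acc_long,
      calibration = calibration, germination = plants,
      retained = retained
    ),
    class = "trait_data"
  )
}

#' @export
print.trait_data <- function(x, ...) {
  cat(sprintf(
    "trait_data: %d accessions retained, traits: %s\n",
    length(x$retained), paste(unique(x$accession$trait), collapse = ", ")
  ))
  if (!is.null(x$calibration)) {
    cat(sprintf(
      "  biomass calibration: slope %.4g, intercept %.4g, r2 %.3f (n=%d)\n",
      x$calibration$slope, x$calibration$intercept, x$calibration$r2,
      x$calibration$n
    ))
  }
  invisible(x)
}

#' Write an accession-level trait table as TSV
#'
#' @param traits a `trait_data` object or its `accession` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traits_tsv <- function(traits, path) {
  tab <- if (inherits(traits, "trait_data")) traits$accession else traits
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
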