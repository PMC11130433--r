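#' Simulate structured inbred genotypes
#'
#' Draws homozygous biallelic genotypes (dosages 0/2) for a panel of
#' inbred accessions split into subpopulations under the Balding-Nichols
#' model: each marker has an ancestral allele frequency drawn
#' Uniform(0.1, 0.9) and per-subpopulation frequencies drawn
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F the configured fst. Markers are
#' assigned strictly increasing positions along `n_chromosomes`
#' chromosomes. Markers are independent within subpopulations: no local
#' linkage-disequilibrium blocks are simulated, so population structure is
#' the only source of marker correlation.
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix()] with an added `subpop` attribute giving
#'   the subpopulation assignment per accession.
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, "genotypes"))
  n <- cfg$n_accessions
  m <- cfg$n_markers
  acc <- sprintf("ACC%04d", seq_len(n))
  subpop <- rep(seq_len(cfg$n_subpops), length.out = n)

  p_anc <- stats::runif(m, 0.1, 0.9)
  f <- cfg$fst
  p_sub <- matrix(0, nrow = cfg$n_subpops, ncol = m)
  for (s in seq_len(cfg$n_subpops)) {
    p_sub[s, ] <- stats::rbeta(m, p_anc * (1 - f) / f,
      (1 - p_anc) * (1 - f) / f
    )
  }
  # inbred lines: one ancestral draw fixed to homozygosity
  dos <- matrix(0, nrow = n, ncol = m, dimnames = list(acc, NULL))
  for (j in seq_len(n)) {
    dos[j, ] <- 2 * stats::rbinom(m, 1L, p_sub[subpop[j], ])
  }

  per_chrom <- diff(floor(seq(0, m, length.out = cfg$n_chromosomes + 1)))
  chrom <- rep(seq_len(cfg$n_chromosomes), times = per_chrom)
  chrom_len <- 7e7
  pos <- unlist(lapply(per_chrom, function(k) {
    sort(sample.int(chrom_len, k))
  }))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  map <- data.frame(
    marker = paste0(chrom, ":", pos), chrom = as.character(chrom),
    pos = pos, ref = ref, alt = unname(alt), stringsAsFactors = FALSE
  )
  g <- genotype_matrix(dos, map)
  attr(g, "subpop") <- stats::setNames(subpop, acc)
  g
}

#' Simulate temporal phenotypes, watering records and ground truth
#'
#' Plant area follows a discrete logistic recursion
#' `A[t+1] = A[t] + r_t A[t] (1 - A[t]/Amax)` from 1% of the asymptote at
#' the accession's germination day, with the daily rate `r_t` scaled by
#' the temperature-phase multiplier. Planted QTL perturb the growth rate,
#' the asymptote, or the emitted value, only while their DAP window is
#' open. A kinship-structured polygenic deviation (drawn once per
#' accession and scaled by the population mean curve, so heritability
#' varies over the run) plus independent per-plant measurement noise are
#' added on top; together they realize the configured broad-sense
#' heritability at the plant level. Raw "image" traits are emitted at
#' pixel level: one top view and two side views of area, height pixels
#' and hull-area pixels (monotone transforms of area with independent
#' noise), endpoint fresh weight, and a daily watering record under the
#' fixed-target-mass protocol. A configured fraction of plants never
#' germinates; a configured fraction of measured cells is multiplied by
#' `outlier_factor` to mimic segmentation artifacts, with every injection
#' recorded in the truth object.
#'
#' @param geno a [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg the same [sim_config()] used for the genotypes.
#' @return A list with elements `pheno` (long data.frame: plant_id,
#'   accession, replicate, DAP, trait, value), `water` (plant_id, DAP,
#'   water_g) and `truth` (class `sim_truth`: planted QTL, true polygenic
#'   heritability, subpopulation assignments, non-germinated plant ids,
#'   injected outlier coordinates, per-accession germination days).
#' @export
simulate_phenotypes <- function(geno, cfg) {
  validate_sim_config(cfg)
  acc <- rownames(geno$dosages)
  n <- length(acc)
  if (n != cfg$n_accessions) stop("genotypes and cfg disagree on panel size")
  for (q in cfg$qtl_specs) {
    if (q$marker_index > ncol(geno$dosages)) {
      stop("QTL marker_index out of range for this genotype matrix")
    }
  }
  d <- cfg$n_days
  r_reps <- cfg$n_replicates
  mult <- phase_multiplier_by_day(cfg)

  set.seed(child_seed(cfg$seed, "germination"))
  germ_vals <- seq(cfg$germ_dap_range[1], cfg$germ_dap_range[2])
  germ <- germ_vals[sample.int(length(germ_vals), n, replace = TRUE)]

  # accession-level expected area curves, including QTL action
  half_dose <- geno$dosages / 2 # 0/1 for inbred lines
  area_acc <- matrix(0, nrow = n, ncol = d)
  add_acc <- matrix(0, nrow = n, ncol = d)
  a <- numeric(n)
  for (t in seq_len(d)) {
    r_t <- rep(cfg$growth_rate * mult[t], n)
    amax_t <- rep(cfg$amax, n)
    for (q in cfg$qtl_specs) {
      if (t >= q$window[1] && t <= q$window[2]) {
        dose <- half_dose[, q$marker_index]
        if (q$mode == "growth_rate") r_t <- r_t + q$effect_size * dose
        if (q$mode == "asymptote") amax_t <- amax_t + q$effect_size * dose
        if (q$mode == "additive_on_trait") {
          add_acc[, t] <- add_acc[, t] + q$effect_size * dose
        }
      }
    }
    newly <- germ == t
    a[newly] <- 0.01 * cfg$amax
    grown <- a > 0
    a[grown] <- a[grown] + r_t[grown] * a[grown] * (1 - a[grown] / amax_t[grown])
    area_acc[, t] <- a
  }
  mean_curve <- colMeans(area_acc)

  # polygenic deviation: one standardized draw per accession with
  # covariance proportional to the realized kinship
  set.seed(child_seed(cfg$seed, "polygenic"))
  h2 <- min(cfg$polygenic_h2, 0.99)
  if (h2 > 0) {
    K <- astle_balding_kinship(maf_filter_impute(geno))
    eg <- eigen(K$matrix, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    g_raw <- drop(eg$vectors %*% (sqrt(lam) * stats::rnorm(n)))
    g_std <- (g_raw - mean(g_raw)) / stats::sd(g_raw)
    cv_noise <- cfg$measurement_noise_sd
    cv_g <- if (cv_noise > 0) cv_noise * sqrt(h2 / (1 - h2)) else 0.1
  } else {
    g_std <- numeric(n)
    cv_g <- 0
  }

  set.seed(child_seed(cfg$seed, "nongerm"))
  n_plants <- n * r_reps
  plant_acc <- rep(acc, each = r_reps)
  plant_rep <- rep(seq_len(r_reps), times = n)
  plant_id <- paste0(plant_acc, "_r", plant_rep)
  nongerm <- stats::runif(n_plants) < cfg$nongerm_rate

  set.seed(child_seed(cfg$seed, "noise"))
  acc_idx <- rep(seq_len(n), each = r_reps)
  area_pl <- matrix(0, nrow = n_plants, ncol = d)
  for (t in seq_len(d)) {
    base <- area_acc[acc_idx, t] + add_acc[acc_idx, t]
    live <- base > 0 & !nongerm
    cv_t <- cfg$measurement_noise_sd *
      if (t >= cfg$late_noise_start) cfg$late_noise_mult else 1
    sd_t <- sqrt((cv_t * mean_curve[t])^2 + cfg$noise_floor_px^2)
    val <- base + mean_curve[t] * cv_g * g_std[acc_idx] +
      stats::rnorm(n_plants, 0, sd_t)
    area_pl[live, t] <- pmax(val[live], 0)
  }
  rel_noise <- function() matrix(
    stats::rnorm(n_plants * d, 0, cfg$measurement_noise_sd),
    n_plants, d
  )
  height_pl <- 3 * sqrt(area_pl) * (1 + rel_noise())
  hull_pl <- 1.5 * area_pl^1.1 * (1 + rel_noise())
  height_pl[area_pl == 0] <- 0
  hull_pl[area_pl == 0] <- 0
  height_pl <- pmax(height_pl, 0)
  hull_pl <- pmax(hull_pl, 0)

  fw <- cfg$fresh_weight_per_area * area_pl[, d] *
    (1 + stats::rnorm(n_plants, 0, 0.05))
  fw <- pmax(fw, 0)
  fw[nongerm] <- 0

  # injected gross artifacts on the pixel-level traits
  set.seed(child_seed(cfg$seed, "outliers"))
  traits3 <- list(area = area_pl, height = height_pl, hull = hull_pl)
  out_rec <- list()
  for (tr in names(traits3)) {
    mat <- traits3[[tr]]
    eligible <- which(mat > 0)
    hit <- eligible[stats::runif(length(eligible)) < cfg$outlier_rate]
    mat[hit] <- mat[hit] * cfg$outlier_factor
    traits3[[tr]] <- mat
    if (length(hit)) {
      out_rec[[tr]] <- data.frame(
        plant_id = plant_id[(hit - 1L) %% n_plants + 1L],
        DAP = (hit - 1L) %/% n_plants + 1L,
        trait = tr, stringsAsFactors = FALSE
      )
    }
  }
  area_pl <- traits3$area
  height_pl <- traits3$height
  hull_pl <- traits3$hull
  outliers <- if (length(out_rec)) do.call(rbind, out_rec) else
    data.frame(plant_id = character(), DAP = integer(), trait = character())

  # fixed-target-mass watering: daily water replaces evaporation plus
  # area-proportional transpiration, capped at the saturation deficit
  evap_g <- 15
  water_per_area <- 0.004
  water_g <- pmin(cfg$saturation_g, evap_g + water_per_area * area_pl)

  long <- function(mat, trait) {
    data.frame(
      plant_id = rep(plant_id, times = d),
      accession = rep(plant_acc, times = d),
      replicate = rep(plant_rep, times = d),
      DAP = rep(seq_len(d), each = n_plants),
      trait = trait, value = as.vector(mat), stringsAsFactors = FALSE
    )
  }
  pheno <- rbind(
    long(0.2 * area_pl, "tv_area"),
    long(0.4 * area_pl, "sv_area1"),
    long(0.4 * area_pl, "sv_area2"),
    long(height_pl, "height_px"),
    long(hull_pl, "hull_px"),
    data.frame(
      plant_id = plant_id, accession = plant_acc, replicate = plant_rep,
      DAP = d, trait = "fresh_weight", value = fw, stringsAsFactors = FALSE
    )
  )
  water <- data.frame(
    plant_id = rep(plant_id, times = d),
    DAP = rep(seq_len(d), each = n_plants),
    water_g = as.vector(water_g), stringsAsFactors = FALSE
  )

  truth <- structure(
    list(
      qtl_specs = cfg$qtl_specs,
      true_polygenic_h2 = cfg$polygenic_h2,
      subpop_assignments = attr(geno, "subpop"),
      nongerminated = plant_id[nongerm],
      outliers = outliers,
      germination_dap = stats::setNames(germ, acc)
    ),
    class = "sim_truth"
  )
  list(pheno = pheno, water = water, truth = truth)
}

#' Simulate a toy gene annotation
#'
#' Places non-overlapping gene intervals on each chromosome of a genotype
#' map. Roughly half of the genes are anchored on randomly chosen markers
#' (so the candidate-gene window scan always has genuine overlaps to
#' find); the rest are placed uniformly.
#'
#' @param geno a [genotype_matrix()] supplying chromosomes and positions.
#' @param genes_per_chrom number of genes per chromosome.
#' @param seed integer seed.
#' @param anchor_markers marker indices that must each receive a spanning
#'   gene (e.g. planted QTL, so the candidate scan has a guaranteed hit).
#' @return A `gene_annotation` data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (1-based inclusive coordinates).
#' @export
simulate_annotation <- function(geno, genes_per_chrom = 20, seed = 1,
                                anchor_markers = integer(0)) {
  stopifnot(genes_per_chrom >= 0)
  set.seed(child_seed(seed, "annotation"))
  chroms <- unique(geno$map$chrom)
  out <- list()
  for (ch in chroms) {
    if (genes_per_chrom == 0) next
    on_ch <- geno$map$chrom == ch
    pos <- geno$map$pos[on_ch]
    forced <- geno$map$pos[intersect(anchor_markers, which(on_ch))]
    n_anchor <- min(length(pos), max(
      ceiling(genes_per_chrom / 2) - length(forced), 0
    ))
    anchors <- c(forced, sample(pos, n_anchor))
    n_anchor <- length(anchors)
    n_free <- max(genes_per_chrom - n_anchor, 0)
    n_tot <- n_anchor + n_free
    starts <- c(
      pmax(1, anchors - sample(200:2000, n_anchor, replace = TRUE)),
      sample.int(7e7, n_free)
    )
    widths <- sample(500:8000, n_tot, replace = TRUE)
    ends <- starts + widths - 1L
    # anchored genes (listed first) win any overlap against free genes
    priority <- order(seq_len(n_tot) > n_anchor, starts)
    keep <- logical(n_tot)
    acc_start <- integer(0)
    acc_end <- integer(0)
    for (i in priority) {
      if (!any(starts[i] <= acc_end & ends[i] >= acc_start)) {
        keep[i] <- TRUE
        acc_start <- c(acc_start, starts[i])
        acc_end <- c(acc_end, ends[i])
      }
    }
    o <- order(starts[keep])
    out[[ch]] <- data.frame(
      chrom = ch, start = as.integer(starts[keep][o]),
      end = as.integer(ends[keep][o]),
      strand = sample(c("+", "-"), sum(keep), replace = TRUE)[o],
      stringsAsFactors = FALSE
    )
  }
  genes <- if (length(out)) do.call(rbind, out) else
    data.frame(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), stringsAsFactors = FALSE
    )
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes <- cbind(
    gene_id = sprintf("GENE%04d", seq_len(nrow(genes))),
    genes
  )
  rownames(genes) <- NULL
  class(genes) <- c("gene_annotation", "data.frame")
  genes
}

#' Write a full synthetic dataset to disk
#'
#' Emits the genotype matrix as VCF and dosage TSV, phenotypes and
#' watering records as CSV, the annotation as GFF3, and the simulation
#' ground truth as JSON. All outputs are plain text.
#'
#' @param geno a [genotype_matrix()].
#' @param sim result of [simulate_phenotypes()].
#' @param annotation result of [simulate_annotation()], or NULL to skip.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_dataset <- function(geno, sim, annotation = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(geno, file.path(dir, "genotypes.vcf"))
  write_dosage_tsv(geno, file.path(dir, "genotypes.tsv"))
  utils::write.csv(sim$pheno, file.path(dir, "phenotypes.csv"),
    row.names = FALSE
  )
  utils::write.csv(sim$water, file.path(dir, "water.csv"),
    row.names = FALSE
  )
  if (!is.null(annotation)) {
    write_gff3(annotation, file.path(dir, "genes.gff3"))
  }
  truth <- sim$truth
  truth$qtl_specs <- lapply(truth$qtl_specs, unclass)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
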