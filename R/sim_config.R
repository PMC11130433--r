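#' Specify a planted QTL for the phenotype simulator
#'
#' @param marker_index column index of the causal marker in the genotype
#'   matrix.
#' @param trait name of the simulated trait the QTL acts on (currently the
#'   growth model drives everything through `"area"`).
#' @param effect_size per-alt-allele effect on the parameter selected by
#'   `mode`: a growth-rate increment (per day), an asymptote increment
#'   (area units), or an additive shift on the trait value itself.
#' @param window integer pair `(start DAP, end DAP)`; the effect is active
#'   only for days inside the window (a transient QTL). Rate and asymptote
#'   effects act on growth while the window is open, so their consequences
#'   on attained size persist after the window closes.
#' @param mode one of `"growth_rate"`, `"asymptote"`,
#'   `"additive_on_trait"`.
#' @return An object of class `qtl_spec`.
#' @export
qtl_spec <- function(marker_index, trait = "area", effect_size,
                     window, mode = c(
                       "growth_rate", "asymptote",
                       "additive_on_trait"
                     )) {
  mode <- match.arg(mode)
  stopifnot(
    length(window) == 2L, window[1] <= window[2], window[1] >= 1,
    marker_index >= 1, is.finite(effect_size)
  )
  structure(
    list(
      marker_index = as.integer(marker_index), trait = trait,
      effect_size = effect_size, window = as.integer(window), mode = mode
    ),
    class = "qtl_spec"
  )
}

#' Simulation configuration
#'
#' Defines the study conditions the synthetic dataset emulates: a panel of
#' inbred accessions with subpopulation structure, grown with replication
#' under a three-phase temperature schedule (15/15, 24/19 and 32/22 degree
#' day/night phases covering 56 days), imaged daily, and watered to a fixed
#' target mass. Growth follows a discrete logistic recursion whose rate is
#' scaled per temperature phase; planted QTL perturb growth only inside
#' their DAP windows; a polygenic background with kinship-structured
#' covariance contributes the configured broad-sense heritability.
#'
#' @param n_accessions number of accessions.
#' @param n_subpops number of subpopulations (Balding-Nichols model).
#' @param fst differentiation among subpopulations, in (0, 1).
#' @param n_markers number of biallelic markers.
#' @param n_chromosomes number of chromosomes markers are spread over.
#' @param n_replicates plants per accession (default 3).
#' @param n_days experiment length in days after planting (default 56).
#' @param temperature_phases data.frame with columns `start`, `end`,
#'   `day_c`, `night_c`; phases must tile `1..n_days` without overlap.
#' @param temp_multipliers growth-rate multiplier per phase (coldest phase
#'   slows growth most).
#' @param qtl_specs list of [qtl_spec()] objects.
#' @param polygenic_h2 target broad-sense heritability contributed by the
#'   kinship-structured polygenic background, in `[0, 1]`.
#' @param measurement_noise_sd per-plant measurement noise as a coefficient
#'   of variation relative to the population mean trait value that day.
#' @param noise_floor_px absolute measurement-noise floor in pixels,
#'   dominating while plants are small (segmentation noise does not shrink
#'   with the plant).
#' @param late_noise_start,late_noise_mult from `late_noise_start` DAP the
#'   relative measurement noise is multiplied by `late_noise_mult`,
#'   emulating the loss of measurement fidelity once leaves overlap; the
#'   default multiplier 1 leaves it off.
#' @param outlier_rate fraction of (plant, day, trait) cells inflated to
#'   mimic segmentation artifacts.
#' @param outlier_factor multiplicative inflation applied to outlier cells.
#' @param nongerm_rate fraction of plants that never germinate (all-zero
#'   top-view area).
#' @param amax logistic asymptote of plant area (pixel units).
#' @param growth_rate base logistic rate per day at the warmest phase.
#' @param germ_dap_range inclusive DAP range from which each accession's
#'   germination day is drawn.
#' @param carrier_g,saturation_g,pot_g masses (grams) of the plant carrier,
#'   soil water at saturation, and substrate-filled pot; their sum is the
#'   watering target mass.
#' @param fresh_weight_per_area grams of shoot fresh weight per unit area
#'   used for the endpoint harvest.
#' @param seed root random seed.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 200, n_subpops = 3, fst = 0.2,
                       n_markers = 500, n_chromosomes = 5,
                       n_replicates = 3, n_days = 56,
                       temperature_phases = default_temperature_phases(),
                       temp_multipliers = c(0.35, 0.7, 1.0),
                       qtl_specs = list(),
                       polygenic_h2 = 0.3,
                       measurement_noise_sd = 0.1,
                       noise_floor_px = 25,
                       late_noise_start = 43, late_noise_mult = 1,
                       outlier_rate = 0.001, outlier_factor = 50,
                       nongerm_rate = 0.05,
                       amax = 50000, growth_rate = 0.18,
                       germ_dap_range = c(5, 9),
                       carrier_g = 342, saturation_g = 250, pot_g = 600,
                       fresh_weight_per_area = 0.002,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_temperature_phases <- function() {
  data.frame(
    start = c(1L, 32L, 39L), end = c(31L, 38L, 56L),
    day_c = c(15, 24, 32), night_c = c(15, 19, 22)
  )
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!(fst > 0 && fst < 1)) stop("fst must be in (0, 1)")
    if (n_subpops > n_accessions) stop("n_subpops exceeds n_accessions")
    for (f in c("polygenic_h2", "outlier_rate", "nongerm_rate")) {
      v <- cfg[[f]]
      if (v < 0 || v > 1) stop(f, " must be in [0, 1]")
    }
    if (measurement_noise_sd < 0) stop("measurement_noise_sd must be >= 0")
    ph <- temperature_phases[order(temperature_phases$start), ]
    covered <- unlist(Map(seq, ph$start, ph$end))
    if (!identical(as.integer(covered), seq_len(n_days))) {
      stop("temperature phases must tile 1..n_days without overlap")
    }
    if (length(temp_multipliers) != nrow(temperature_phases)) {
      stop("one temp_multiplier per temperature phase required")
    }
    if (length(qtl_specs) > n_markers) stop("more QTL than markers")
    for (q in qtl_specs) {
      stopifnot(inherits(q, "qtl_spec"))
      if (q$window[2] > n_days) stop("QTL window outside 1..n_days")
      if (q$marker_index > n_markers) stop("QTL marker_index out of range")
    }
    if (germ_dap_range[1] < 1 || germ_dap_range[2] > n_days) {
      stop("germ_dap_range outside experiment span")
    }
  })
  invisible(cfg)
}

# per-day growth-rate multiplier implied by the temperature schedule
phase_multiplier_by_day <- function(cfg) {
  ph <- cfg$temperature_phases
  mult <- numeric(cfg$n_days)
  for (i in seq_len(nrow(ph))) {
    mult[ph$start[i]:ph$end[i]] <- cfg$temp_multipliers[i]
  }
  mult
}

#' Watering target mass from its components
#'
#' The watering protocol maintains each potted plant at a fixed target
#' mass: the plant carrier plus the water mass at saturation plus the
#' substrate-filled pot (the growing plant's own mass is deliberately not
#' part of the target). The defaults reproduce the 1192 g target used by
#' the growth-chamber protocol this package models.
#'
#' @param carrier_g mass of the plant carrier (g).
#' @param saturation_g water mass at field saturation (g).
#' @param pot_g mass of the substrate-filled pot (g).
#' @return Target mass in grams.
#' @export
water_budget_check <- function(carrier_g = 342, saturation_g = 250,
                               pot_g = 600) {
  masses <- c(carrier_g, saturation_g, pot_g)
  if (any(!is.finite(masses)) || any(masses < 0)) {
    stop("masses must be finite and >= 0")
  }
  sum(masses)
}
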