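#' Default end-to-end run configuration
#'
#' A flat list of every pipeline parameter with its default. The analysis
#' defaults follow the protocol the package models: three genotype PCs as
#' structure covariates, familywise alpha 0.05, MAF filter > 0.05, 40-MAD
#' outlier fence, 15 kb candidate window, clustering over DAP 12-56,
#' ideotype windows 15-31 (early) and 39-56 (late) with 5%/10% thresholds,
#' biomass calibration at 51 DAP and establishment cutoff at 46 DAP.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed root seed.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(out_dir = "tempoqtl_run", seed = 1) {
  structure(list(
    out_dir = out_dir,
    seed = seed,
    stages = c(
      "simulate", "traits", "heritability", "cluster",
      "ideotype", "gwas", "transient", "annotate"
    ),
    # simulation
    n_accessions = 120, n_subpops = 3, fst = 0.2, n_markers = 400,
    n_chromosomes = 5, n_replicates = 3, n_days = 56,
    polygenic_h2 = 0.3, measurement_noise_sd = 0.1,
    outlier_rate = 0.001, nongerm_rate = 0.05, genes_per_chrom = 20,
    qtl_marker_index = 0, qtl_effect_size = 0.06,
    qtl_window_start = 20, qtl_window_end = 30,
    # traits
    mad_k = 40, loess_span = 0.5, loess_degree = 2,
    calibration_dap = 51, death_cutoff = 46, min_plants = 2,
    # clustering / ideotypes
    cluster_trait = "wue", k_clusters = 7,
    cluster_dap_min = 12, cluster_dap_max = 56,
    ideotype_early = c(15, 31), ideotype_late = c(39, 56),
    wue_frac = 0.10, ratio_frac = 0.05,
    # gwas
    gwas_traits = "area", gwas_dap_min = 12, gwas_dap_max = 56,
    n_pcs = 3, maf_min = 0.05, alpha = 0.05, max_steps = 20,
    extbic_gamma = 1.0,
    # annotation
    window_bp = 15000
  ), class = "run_config")
}

#' Validate a run configuration against the schema
#'
#' Unknown keys are errors (not warnings), so a mistyped parameter can
#' never silently fall back to its default.
#'
#' @param config a named list.
#' @return The config, classed `run_config`, invisibly.
#' @export
validate_run_config <- function(config) {
  schema <- default_run_config()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(names(schema), names(config))
  if (length(missing)) {
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  }
  bad_stage <- setdiff(config$stages, schema$stages)
  if (length(bad_stage)) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  }
  invisible(structure(config, class = "run_config"))
}

#' Read / write a run configuration as YAML
#'
#' The file round-trips losslessly: every parameter is written, and
#' unknown keys fail validation on read.
#'
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @return `read_run_config` returns the validated config;
#'   `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("ideotype_early", "ideotype_late")) {
    cfg[[k]] <- as.numeric(unlist(cfg[[k]]))
  }
  cfg$stages <- as.character(unlist(cfg$stages))
  cfg$gwas_traits <- as.character(unlist(cfg$gwas_traits))
  validate_run_config(cfg)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(utils::capture.output(utils::str(
    config[order(names(config))],
    digits.d = 12
  )), tf)
  unname(tools::md5sum(tf))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the stages in dependency order — simulate, derive traits,
#' heritability, cluster, ideotype, GWAS, transient tracks, candidate
#' annotation — communicating through plain-text files under
#' `config$out_dir`, and writes a run manifest with the configuration
#' hash and per-file checksums. A stage whose outputs already exist under
#' the same configuration hash is skipped (resumable runs); deselecting a
#' stage in `config$stages` reuses whatever its outputs on disk are.
#'
#' @param config a `run_config` list (see [default_run_config()]).
#' @return The manifest (list of class `run_manifest`), invisibly
#'   written to `run_manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- validate_run_config(config)
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  manifest_path <- file.path(dir, "run_manifest.json")
  prev <- if (file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  } else {
    NULL
  }
  manifest <- list(
    tool = "tempoqtl",
    version = as.character(utils::packageVersion("tempoqtl")),
    config_hash = hash, stages = list(), warnings = character(0)
  )
  fp <- function(...) file.path(dir, ...)

  stage_outputs <- list(
    simulate = c(
      "genotypes.vcf", "genotypes.tsv", "phenotypes.csv",
      "water.csv", "genes.gff3", "truth.json"
    ),
    traits = c("traits_accession.tsv", "traits_plant.tsv"),
    heritability = "heritability.tsv",
    cluster = c("cluster_assignments.tsv", "cluster_profiles.tsv"),
    ideotype = c("ideotype_early.json", "ideotype_late.json"),
    gwas = c("gwas_hits.tsv", "gwas_summary.tsv"),
    transient = c("transient_tracks.tsv", "pleiotropy.json"),
    annotate = "candidates.tsv"
  )
  cached <- function(stage) {
    !is.null(prev) && identical(prev$config_hash, hash) &&
      all(file.exists(fp(stage_outputs[[stage]])))
  }
  record <- function(stage, status) {
    files <- fp(stage_outputs[[stage]])
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- list(
      status = status,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      checksums = as.list(tools::md5sum(files))
    )
  }
  enabled <- function(stage) stage %in% config$stages

  if (enabled("simulate")) {
    if (cached("simulate")) {
      record("simulate", "cached")
    } else {
      scfg <- sim_config(
        n_accessions = config$n_accessions, n_subpops = config$n_subpops,
        fst = config$fst, n_markers = config$n_markers,
        n_chromosomes = config$n_chromosomes,
        n_replicates = config$n_replicates, n_days = config$n_days,
        polygenic_h2 = config$polygenic_h2,
        measurement_noise_sd = config$measurement_noise_sd,
        outlier_rate = config$outlier_rate,
        nongerm_rate = config$nongerm_rate, seed = config$seed
      )
      geno <- simulate_genotypes(scfg)
      # qtl_marker_index 0 = auto: the marker with realized MAF nearest 0.4,
      # so the planted signal is always common enough to map
      qtl_idx <- if (config$qtl_marker_index > 0) {
        config$qtl_marker_index
      } else {
        which.min(abs(geno$map$maf - 0.4))
      }
      scfg$qtl_specs <- list(qtl_spec(
        marker_index = qtl_idx,
        effect_size = config$qtl_effect_size,
        window = c(config$qtl_window_start, config$qtl_window_end),
        mode = "growth_rate"
      ))
      sim <- simulate_phenotypes(geno, scfg)
      ann <- simulate_annotation(geno,
        genes_per_chrom = config$genes_per_chrom, seed = config$seed,
        anchor_markers = qtl_idx
      )
      write_sim_dataset(geno, sim, ann, dir)
      record("simulate", "run")
      message(sprintf(
        "simulate: %d accessions x %d markers, %d plants",
        config$n_accessions, config$n_markers,
        config$n_accessions * config$n_replicates
      ))
    }
  }

  need_traits <- any(vapply(
    c("traits", "heritability", "cluster", "ideotype", "gwas"),
    enabled, logical(1)
  ))
  if (enabled("traits")) {
    if (cached("traits")) {
      record("traits", "cached")
    } else {
      pheno <- utils::read.csv(fp("phenotypes.csv"),
        stringsAsFactors = FALSE
      )
      water <- utils::read.csv(fp("water.csv"), stringsAsFactors = FALSE)
      td <- derive_traits(pheno, water,
        mad_k = config$mad_k,
        span = config$loess_span, degree = config$loess_degree,
        calibration_dap = config$calibration_dap,
        death_cutoff = config$death_cutoff,
        min_plants = config$min_plants
      )
      write_traits_tsv(td$accession, fp("traits_accession.tsv"))
      utils::write.table(td$plant, fp("traits_plant.tsv"),
        sep = "\t",
        quote = FALSE, row.names = FALSE
      )
      record("traits", "run")
      message(sprintf(
        "traits: %d accessions retained of %d",
        length(td$retained), length(unique(pheno$accession))
      ))
    }
  }
  read_acc_traits <- function() {
    utils::read.table(fp("traits_accession.tsv"),
      header = TRUE, sep = "\t",
      stringsAsFactors = FALSE
    )
  }

  if (enabled("heritability")) {
    if (cached("heritability")) {
      record("heritability", "cached")
    } else {
      plant <- utils::read.table(fp("traits_plant.tsv"),
        header = TRUE,
        sep = "\t", stringsAsFactors = FALSE
      )
      h2 <- heritability_curves(list(plant = plant),
        n_replicates = config$n_replicates
      )
      utils::write.table(h2, fp("heritability.tsv"),
        sep = "\t",
        quote = FALSE, row.names = FALSE
      )
      record("heritability", "run")
      message(sprintf("heritability: %d trait-day fits", nrow(h2)))
    }
  }

  if (enabled("cluster")) {
    if (cached("cluster")) {
      record("cluster", "cached")
    } else {
      acc <- read_acc_traits()
      cl <- cluster_profiles(acc, config$cluster_trait,
        k = config$k_clusters,
        dap_range = c(config$cluster_dap_min, config$cluster_dap_max)
      )
      utils::write.table(
        data.frame(
          accession = names(cl$assignments),
          cluster = unname(cl$assignments)
        ),
        fp("cluster_assignments.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      profs <- data.frame(
        cluster = rownames(cl$mean_profiles),
        cl$mean_profiles,
        check.names = FALSE
      )
      utils::write.table(profs, fp("cluster_profiles.tsv"),
        sep = "\t",
        quote = FALSE, row.names = FALSE
      )
      record("cluster", "run")
      message(sprintf(
        "cluster: %d accessions in %d clusters",
        length(cl$assignments), cl$k
      ))
    }
  }

  if (enabled("ideotype")) {
    if (cached("ideotype")) {
      record("ideotype", "cached")
    } else {
      acc <- read_acc_traits()
      wue_pct <- percentile_table(acc, "wue")
      ratio_pct <- percentile_table(acc, c("height", "biomass"))
      for (w in c("early", "late")) {
        win <- config[[paste0("ideotype_", w)]]
        rep_ <- select_ideotypes(wue_pct, ratio_pct,
          window = win,
          wue_frac = config$wue_frac, ratio_frac = config$ratio_frac
        )
        jsonlite::write_json(
          list(
            window = win, positives = rep_$positives,
            negatives = rep_$negatives
          ),
          fp(paste0("ideotype_", w, ".json")),
          auto_unbox = FALSE, digits = NA
        )
      }
      record("ideotype", "run")
      message("ideotype: early and late reports written")
    }
  }

  if (enabled("gwas")) {
    if (cached("gwas")) {
      record("gwas", "cached")
    } else {
      geno <- read_dosage_tsv(fp("genotypes.tsv"))
      acc <- read_acc_traits()
      lg <- longitudinal_gwas(geno, acc,
        trait_names = config$gwas_traits,
        dap_range = c(config$gwas_dap_min, config$gwas_dap_max),
        n_pcs = config$n_pcs, maf_min = config$maf_min,
        alpha = config$alpha, max_steps = config$max_steps,
        gamma = config$extbic_gamma
      )
      utils::write.table(lg$hits, fp("gwas_hits.tsv"),
        sep = "\t",
        quote = FALSE, row.names = FALSE
      )
      summ <- data.frame(
        fit = names(lg$fits),
        pseudo_h2_null = vapply(
          lg$fits,
          function(f) f$pseudo_h2_path[1], numeric(1)
        ),
        n_cofactors = vapply(
          lg$fits,
          function(f) length(f$cofactors), numeric(1)
        )
      )
      utils::write.table(summ, fp("gwas_summary.tsv"),
        sep = "\t",
        quote = FALSE, row.names = FALSE
      )
      record("gwas", "run")
      message(sprintf(
        "gwas: %d fits, %d high-confidence hit rows, %d skipped",
        length(lg$fits), nrow(lg$hits), length(lg$skipped)
      ))
    }
  }
  read_hits <- function() {
    utils::read.table(fp("gwas_hits.tsv"),
      header = TRUE, sep = "\t",
      colClasses = list(chrom = "character"), stringsAsFactors = FALSE
    )
  }

  if (enabled("transient")) {
    if (cached("transient")) {
      record("transient", "cached")
    } else {
      hits <- read_hits()
      tracks <- detect_transient(hits, final_dap = config$gwas_dap_max)
      utils::write.table(tracks, fp("transient_tracks.tsv"),
        sep = "\t",
        quote = FALSE, row.names = FALSE
      )
      pleio <- detect_pleiotropy(hits)
      jsonlite::write_json(pleio, fp("pleiotropy.json"), digits = NA)
      record("transient", "run")
      message(sprintf(
        "transient: %d run(s) across %d marker-trait pair(s)",
        nrow(tracks), length(unique(paste(tracks$marker, tracks$trait)))
      ))
    }
  }

  if (enabled("annotate")) {
    if (cached("annotate")) {
      record("annotate", "cached")
    } else {
      hits <- read_hits()
      cand <- scan_window(hits, fp("genes.gff3"),
        window = config$window_bp
      )
      utils::write.table(cand, fp("candidates.tsv"),
        sep = "\t",
        quote = FALSE, row.names = FALSE
      )
      record("annotate", "run")
      message(sprintf("annotate: %d candidate gene row(s)", nrow(cand)))
    }
  }

  manifest <- structure(manifest, class = "run_manifest")
  jsonlite::write_json(unclass(manifest), manifest_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
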