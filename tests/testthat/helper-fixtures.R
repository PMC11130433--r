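# shared fixtures and independent oracles, built once per test run

# small default panel (outliers and non-germination on, no QTL)
tiny_panel <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$val)) {
      cfg <- sim_config(n_accessions = 80, n_markers = 200, seed = 42)
      geno <- simulate_genotypes(cfg)
      sim <- simulate_phenotypes(geno, cfg)
      cache$val <- list(cfg = cfg, geno = geno, sim = sim)
    }
    cache$val
  }
})

# clean panel with one transient growth-rate QTL (DAP 20-30) planted on a
# common marker; no polygenic background, artifacts or failed plants
qtl_panel <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$val)) {
      cfg <- sim_config(
        n_accessions = 80, n_markers = 200, seed = 42,
        polygenic_h2 = 0, outlier_rate = 0, nongerm_rate = 0
      )
      geno <- simulate_genotypes(cfg)
      qtl_idx <- which.min(abs(geno$map$maf - 0.4))
      cfg$qtl_specs <- list(qtl_spec(
        marker_index = qtl_idx, effect_size = 0.06,
        window = c(20, 30), mode = "growth_rate"
      ))
      sim <- simulate_phenotypes(geno, cfg)
      cache$val <- list(
        cfg = cfg, geno = geno, sim = sim,
        qtl_idx = qtl_idx, qtl_marker = geno$map$marker[qtl_idx]
      )
    }
    cache$val
  }
})

# composite plant x day area matrix straight from a raw pheno table
raw_area_matrix <- function(pheno) {
  views <- c("tv_area", "sv_area1", "sv_area2")
  parts <- lapply(views, function(tr) {
    sub <- pheno[pheno$trait == tr, ]
    m <- tapply(sub$value, list(sub$plant_id, sub$DAP), function(v) v[1])
    m[order(rownames(m)), order(as.integer(colnames(m))), drop = FALSE]
  })
  parts[[1]] + parts[[2]] + parts[[3]]
}

# explicit-inverse GLS oracle for the marker scan: builds Sigma per marker
# and inverts it directly, no spectral shortcut
gls_scan_oracle <- function(y, X, K, varcomp, markers) {
  n <- length(y)
  Sigma <- varcomp$sigma2_g * K + varcomp$sigma2_e * diag(n)
  Si <- solve(Sigma)
  p <- ncol(X)
  vapply(seq_len(ncol(markers)), function(j) {
    Xj <- cbind(X, markers[, j])
    XtSiX <- t(Xj) %*% Si %*% Xj
    b <- solve(XtSiX, t(Xj) %*% Si %*% y)
    r <- y - Xj %*% b
    rss <- drop(t(r) %*% Si %*% r)
    s2 <- rss / (n - p - 1)
    se2 <- s2 * solve(XtSiX)[p + 1, p + 1]
    stats::pf(b[p + 1]^2 / se2, 1, n - p - 1, lower.tail = FALSE)
  }, numeric(1))
}

# brute-force all-pairs candidate-window oracle
window_scan_oracle <- function(markers, genes, window) {
  rows <- list()
  for (i in seq_len(nrow(markers))) {
    for (j in seq_len(nrow(genes))) {
      if (markers$chrom[i] != genes$chrom[j]) next
      lo <- markers$pos[i] - window
      hi <- markers$pos[i] + window
      if (genes$end[j] >= lo && genes$start[j] <= hi) {
        rows[[length(rows) + 1]] <- data.frame(
          marker = markers$marker[i], gene_id = genes$gene_id[j],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(marker = character(), gene_id = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$marker, out$gene_id), , drop = FALSE]
}

# long trait table from an accession x day value matrix
long_trait_table <- function(mat, trait) {
  data.frame(
    accession = rep(rownames(mat), times = ncol(mat)),
    DAP = rep(as.integer(colnames(mat)), each = nrow(mat)),
    trait = trait, value = as.vector(mat), stringsAsFactors = FALSE
  )
}

# logistic growth curve used to plant clustering archetypes
logistic_curve <- function(days, amax, r, t0) {
  amax / (1 + exp(-r * (days - t0)))
}
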