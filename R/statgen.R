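#' Filter markers by minor allele frequency and impute missing dosages
#'
#' Markers whose MAF does not exceed `maf_min`, or with zero dosage
#' variance, are dropped; remaining missing dosages are replaced by the
#' marker's observed mean dosage (so imputed values need not lie in
#' {0, 1, 2}).
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min MAF threshold; markers must satisfy MAF > `maf_min`
#'   (default 0.05).
#' @return A list of class `filtered_genotypes` with elements `dosages`
#'   (numeric matrix, imputed), `map` (retained markers, MAF recomputed)
#'   and `n_dropped`.
#' @export
maf_filter_impute <- function(geno, maf_min = 0.05) {
  dos <- geno$dosages
  maf <- marker_maf(dos)
  v <- apply(dos, 2L, stats::var, na.rm = TRUE)
  keep <- !is.na(maf) & maf > maf_min & !is.na(v) & v > 0
  if (!any(keep)) stop("no markers pass the MAF filter")
  dos <- dos[, keep, drop = FALSE]
  mu <- colMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(idx)) dos[idx] <- mu[idx[, 2L]]
  map <- geno$map[keep, , drop = FALSE]
  map$maf <- pmin(mu / 2, 1 - mu / 2)
  structure(
    list(dosages = dos, map = map, n_dropped = sum(!keep)),
    class = "filtered_genotypes"
  )
}

#' Astle-Balding kinship matrix
#'
#' Realized relationship matrix with allele-frequency standardization:
#' `K[j,k] = (1/m) * sum_i (x[i,j] - 2 p_i)(x[i,k] - 2 p_i) /
#' (2 p_i (1 - p_i))` with `p_i` the observed (post-imputation) allele
#' frequency of marker i. For fully inbred panels the diagonal approaches
#' 2 (1 + f with inbreeding coefficient f = 1).
#'
#' @param geno a `filtered_genotypes` object from [maf_filter_impute()]
#'   (monomorphic markers must be removed first).
#' @return A list of class `kinship_matrix` with elements `matrix`
#'   (symmetric, accessions x accessions) and `n_markers`.
#' @export
astle_balding_kinship <- function(geno) {
  dos <- if (inherits(geno, "filtered_genotypes")) geno$dosages
  else geno$dosages
  p <- colMeans(dos) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic marker present; apply maf_filter_impute first")
  }
  z <- sweep(dos, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(z) / ncol(dos)
  K <- (K + t(K)) / 2
  structure(
    list(matrix = K, n_markers = ncol(dos)),
    class = "kinship_matrix"
  )
}

#' Principal components of the genotype matrix
#'
#' Column-centered dosages are decomposed by SVD; the top score vectors
#' are returned as population-structure covariates. Signs are fixed by
#' making each component's largest-magnitude loading positive, so results
#' do not depend on LAPACK sign conventions.
#'
#' @param geno a `filtered_genotypes` object.
#' @param n_pcs number of components (default 3).
#' @return A list of class `genotype_pca`: `scores` (accessions x n_pcs),
#'   `loadings`, `var_explained` (fractions).
#' @export
genotype_pca <- function(geno, n_pcs = 3) {
  dos <- geno$dosages
  if (n_pcs >= nrow(dos)) stop("n_pcs must be < number of accessions")
  x <- scale(dos, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(k) {
    l <- sv$v[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs), 2L, flip, "*")
  loadings <- sweep(sv$v, 2L, flip, "*")
  rownames(scores) <- rownames(dos)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  structure(
    list(
      scores = scores, loadings = loadings,
      var_explained = sv$d^2 / sum(sv$d^2)
    ),
    class = "genotype_pca"
  )
}

#' Box-Cox power transformation with profile-likelihood lambda
#'
#' Chooses lambda maximizing the Box-Cox profile log-likelihood over a
#' grid on [-2, 2] (step 0.01) and returns the transformed values
#' `(y^lambda - 1)/lambda`, or `log(y)` at lambda = 0.
#'
#' @param values positive values; if any are zero, set `offset` to shift
#'   them first.
#' @param offset added to `values` before transforming (default 0).
#' @return A list of class `boxcox_fit`: `lambda`, `transformed`.
#' @export
boxcox_transform <- function(values, offset = 0) {
  y <- values + offset
  obs <- !is.na(y)
  if (any(y[obs] <= 0)) stop("values must be positive after offset")
  bc <- MASS::boxcox(y[obs] ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  tr <- rep(NA_real_, length(y))
  tr[obs] <- if (abs(lambda) < 1e-12) log(y[obs]) else
    (y[obs]^lambda - 1) / lambda
  structure(list(lambda = lambda, transformed = tr), class = "boxcox_fit")
}

#' Broad-sense heritability from replicated accessions
#'
#' Fits the one-way random-effects model `Y = mu + genotype + error` to
#' the replicate values of one trait at one day and returns
#' `H2 = sigma2_genotype / (sigma2_genotype + sigma2_error)`. Only
#' accessions with the full replicate count enter the fit. Two estimation
#' paths are provided: REML via `lme4::lmer`, and the balanced-design
#' ANOVA method of moments `sigma2_g = (MSB - MSW) / r` (negative
#' estimates clipped at zero); for balanced data they agree.
#'
#' @param values trait values.
#' @param accession accession id per value.
#' @param n_replicates required replicate count per accession (default 3).
#' @param method `"reml"` (default) or `"anova"`.
#' @return A list of class `heritability_result`: `H2`, `sigma2_g`,
#'   `sigma2_e`, `n_accessions`, `method`.
#' @export
heritability <- function(values, accession, n_replicates = 3,
                         method = c("reml", "anova")) {
  method <- match.arg(method)
  keep <- !is.na(values)
  values <- values[keep]
  accession <- as.character(accession[keep])
  counts <- table(accession)
  full <- names(counts)[counts == n_replicates]
  if (length(full) < 2L) stop("need >= 2 accessions with full replication")
  sel <- accession %in% full
  y <- values[sel]
  g <- factor(accession[sel])

  if (method == "reml") {
    fit <- suppressWarnings(suppressMessages(lme4::lmer(y ~ (1 | g),
      control = lme4::lmerControl(
        check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4)
      )
    )))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2g <- vc$vcov[vc$grp == "g"]
    s2e <- vc$vcov[vc$grp == "Residual"]
  } else {
    fit <- stats::aov(y ~ g)
    tab <- summary(fit)[[1]]
    msb <- tab["g", "Mean Sq"]
    msw <- tab["Residuals", "Mean Sq"]
    s2g <- max((msb - msw) / n_replicates, 0)
    s2e <- msw
  }
  h2 <- if (s2g + s2e > 0) s2g / (s2g + s2e) else 0
  structure(
    list(
      H2 = h2, sigma2_g = s2g, sigma2_e = s2e,
      n_accessions = length(full), method = method
    ),
    class = "heritability_result"
  )
}

#' Per-day heritability curves for every trait
#'
#' Applies [heritability()] to the plant-level trait table at each
#' (trait, day) combination.
#'
#' @param trait_data a `trait_data` object from [derive_traits()] (its
#'   `plant` table is used).
#' @param n_replicates required replicate count.
#' @param method estimation path, see [heritability()].
#' @return data.frame with columns `trait`, `DAP`, `H2`, `sigma2_g`,
#'   `sigma2_e`, `n_accessions`.
#' @export
heritability_curves <- function(trait_data, n_replicates = 3,
                                method = "reml") {
  tab <- trait_data$plant
  combos <- unique(tab[, c("trait", "DAP")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- tab[tab$trait == combos$trait[i] & tab$DAP == combos$DAP[i], ]
    res <- tryCatch(
      heritability(sub$value, sub$accession, n_replicates, method),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    data.frame(
      trait = combos$trait[i], DAP = combos$DAP[i], H2 = res$H2,
      sigma2_g = res$sigma2_g, sigma2_e = res$sigma2_e,
      n_accessions = res$n_accessions, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$trait, out$DAP), ]
}
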