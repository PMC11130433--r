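# small structured test bed shared across blocks
mlmm_bed <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$val)) {
      cfg <- sim_config(n_accessions = 60, n_markers = 120, seed = 77)
      g <- simulate_genotypes(cfg)
      fg <- maf_filter_impute(g)
      K <- astle_balding_kinship(fg)$matrix
      cache$val <- list(
        fg = fg, K = K,
        eigen_K = eigen(K, symmetric = TRUE),
        X0 = cbind(intercept = 1, genotype_pca(fg)$scores)
      )
    }
    cache$val
  }
})

test_that("REML recovers a planted pseudo-heritability of one half", {
  b <- mlmm_bed()
  n <- nrow(b$K)
  eg <- b$eigen_K
  chol_half <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  X <- matrix(1, n, 1)
  set.seed(1)
  # sigma2_g = sigma2_e = 1: u ~ N(0, K), e ~ N(0, I)
  est <- replicate(100, {
    y <- drop(chol_half %*% rnorm(n)) + rnorm(n)
    reml_variance_components(y, X, eigen_K = eg)$pseudo_h2
  })
  expect_lt(abs(mean(est) - 0.5), 0.07)
})

test_that("pure-noise phenotypes yield near-zero pseudo-heritability", {
  cfg <- sim_config(n_accessions = 200, n_markers = 300, seed = 78)
  fg <- maf_filter_impute(simulate_genotypes(cfg))
  eg <- eigen(astle_balding_kinship(fg)$matrix, symmetric = TRUE)
  X <- matrix(1, 200, 1)
  set.seed(2)
  h2 <- replicate(200, {
    reml_variance_components(rnorm(200), X, eigen_K = eg)$pseudo_h2
  })
  expect_gte(mean(h2 < 0.1), 0.95)
})

test_that("with identity kinship only the total variance is identified", {
  set.seed(3)
  n <- 200
  y <- rnorm(n, 0, sqrt(2))
  vc <- reml_variance_components(y, matrix(1, n, 1), K = diag(n))
  expect_lt(abs((vc$sigma2_g + vc$sigma2_e) / 2 - 1), 0.1)
})

test_that("rank-deficient designs are rejected with the offending column", {
  b <- mlmm_bed()
  n <- nrow(b$K)
  X <- cbind(intercept = 1, dup = rep(1, n))
  expect_error(
    reml_variance_components(rnorm(n), X, eigen_K = b$eigen_K),
    "dup"
  )
})

test_that("the spectral scan equals the explicit-inverse GLS oracle", {
  b <- mlmm_bed()
  set.seed(4)
  n <- nrow(b$K)
  y <- drop(b$fg$dosages[, 5]) * 0.3 + rnorm(n)
  vc <- reml_variance_components(y, b$X0, eigen_K = b$eigen_K)
  sc <- scan_markers(y, b$X0,
    varcomp = vc, markers = b$fg$dosages,
    eigen_K = b$eigen_K
  )
  oracle <- gls_scan_oracle(y, b$X0, b$K, vc, b$fg$dosages)
  expect_lt(max(abs(sc$p - oracle)), 1e-8)
})

test_that("the scan collapses to plain OLS when the kinship effect vanishes", {
  set.seed(5)
  n <- 80
  m <- 40
  M <- matrix(rbinom(n * m, 1, 0.4) * 2, n, m)
  colnames(M) <- paste0("m", 1:m)
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  vc <- list(delta = 1e10, sigma2_g = 1e-10, sigma2_e = 1)
  sc <- scan_markers(y, X,
    K = diag(n), varcomp = vc,
    markers = M
  )
  ols <- vapply(seq_len(m), function(j) {
    f <- summary(stats::lm(y ~ M[, j]))
    f$coefficients[2, 4]
  }, numeric(1))
  expect_equal(sc$p, ols, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("collinear markers are flagged with p = 1", {
  set.seed(6)
  n <- 50
  M <- cbind(const = rep(2, n), ok = rbinom(n, 1, 0.5) * 2)
  sc <- scan_markers(rnorm(n), matrix(1, n, 1),
    K = diag(n),
    varcomp = list(delta = 1), markers = M
  )
  expect_true(sc$collinear[1])
  expect_identical(sc$p[1], 1)
  expect_false(sc$collinear[2])
})

test_that("scan p-values are invariant to location and scale of y", {
  b <- mlmm_bed()
  set.seed(7)
  y <- rnorm(nrow(b$K))
  vc <- reml_variance_components(y, b$X0, eigen_K = b$eigen_K)
  sc1 <- scan_markers(y, b$X0,
    varcomp = vc, markers = b$fg$dosages,
    eigen_K = b$eigen_K
  )
  y2 <- 3.7 * y + 11
  vc2 <- reml_variance_components(y2, b$X0, eigen_K = b$eigen_K)
  sc2 <- scan_markers(y2, b$X0,
    varcomp = vc2, markers = b$fg$dosages,
    eigen_K = b$eigen_K
  )
  expect_equal(sc1$p, sc2$p, tolerance = 1e-6)
})

test_that("a strong planted marker is the first cofactor and survives mBonf", {
  b <- mlmm_bed()
  set.seed(8)
  n <- nrow(b$K)
  target <- b$fg$map$marker[10]
  y <- b$fg$dosages[, 10] * 2 + rnorm(n, 0, 1)
  fit <- mlmm(y, b$X0,
    markers = b$fg$dosages, map = b$fg$map,
    eigen_K = b$eigen_K
  )
  expect_identical(fit$cofactors[1], target)
  expect_true(target %in% fit$selection$mbonf)
  expect_true(target %in% fit$selection$high_confidence$marker)
  expect_identical(
    fit$selection$high_confidence$tier[
      fit$selection$high_confidence$marker == target
    ],
    "stringent"
  )
  # selected models are subsets of the forward path
  expect_true(all(fit$selection$mbonf %in% fit$cofactors))
  expect_true(all(fit$selection$extbic %in% fit$cofactors))
  expect_setequal(
    fit$selection$high_confidence$marker,
    union(fit$selection$mbonf, fit$selection$extbic)
  )
})

test_that("the pseudo-heritability path is nonincreasing and stops on noise", {
  b <- mlmm_bed()
  set.seed(9)
  y <- rnorm(nrow(b$K))
  fit <- mlmm_forward(y, b$X0,
    markers = b$fg$dosages, map = b$fg$map,
    eigen_K = b$eigen_K
  )
  expect_lte(length(fit$cofactors), 20)
  path <- fit$pseudo_h2_path
  expect_true(all(diff(path) <= 0.02))
  final <- fit$steps[[length(fit$steps)]]$varcomp$pseudo_h2
  stopped <- final <= 0.01 || length(fit$cofactors) == 20
  expect_true(stopped)
})

test_that("multiple-Bonferroni selection applies the corrected threshold", {
  b <- mlmm_bed()
  set.seed(10)
  n <- nrow(b$K)
  # strong signal: cofactor p far below 0.05 / 1000
  y_strong <- b$fg$dosages[, 20] * 3 + rnorm(n, 0, 0.5)
  fit_s <- mlmm_forward(y_strong, b$X0,
    markers = b$fg$dosages,
    map = b$fg$map, eigen_K = b$eigen_K
  )
  sel_s <- select_models(fit_s, m_effective = 1000)
  expect_equal(sel_s$threshold, 0.05 / 1000)
  expect_true(b$fg$map$marker[20] %in% sel_s$mbonf)
  # weak signal: best cofactor p around 1e-3 fails the same threshold
  y_weak <- b$fg$dosages[, 20] * 0.45 + rnorm(n, 0, 1)
  fit_w <- mlmm_forward(y_weak, b$X0,
    markers = b$fg$dosages,
    map = b$fg$map, eigen_K = b$eigen_K, max_steps = 3
  )
  if (length(fit_w$steps) >= 2 && fit_w$steps[[2]]$cofactor_p[1] > 5e-5) {
    # the constructed case: moderate signal fails the corrected threshold
    expect_identical(
      select_models(fit_w, m_effective = 1000)$mbonf,
      character(0)
    )
  }
})

test_that("marker order only permutes the scan, never the selection", {
  b <- mlmm_bed()
  set.seed(11)
  y <- b$fg$dosages[, 30] * 1.5 + rnorm(nrow(b$K))
  fit1 <- mlmm(y, b$X0,
    markers = b$fg$dosages, map = b$fg$map,
    eigen_K = b$eigen_K
  )
  o <- rev(seq_len(ncol(b$fg$dosages)))
  fit2 <- mlmm(y, b$X0,
    markers = b$fg$dosages[, o], map = b$fg$map[o, ],
    eigen_K = b$eigen_K
  )
  expect_identical(fit1$cofactors, fit2$cofactors)
  expect_setequal(fit1$selection$mbonf, fit2$selection$mbonf)
})
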