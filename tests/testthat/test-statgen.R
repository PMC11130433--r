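make_geno <- function(dos, chrom = NULL, pos = NULL) {
  m <- ncol(dos)
  if (is.null(rownames(dos))) rownames(dos) <- paste0("A", seq_len(nrow(dos)))
  genotype_matrix(dos, data.frame(
    marker = paste0("m", seq_len(m)),
    chrom = if (is.null(chrom)) rep("1", m) else chrom,
    pos = if (is.null(pos)) seq_len(m) * 100L else pos,
    ref = rep("A", m), alt = rep("T", m), stringsAsFactors = FALSE
  ))
}

test_that("MAF filtering uses strict > and imputes the marker mean", {
  dos <- cbind(
    rep(2, 10), # monomorphic: dropped
    c(1, rep(0, 9)), # MAF exactly 0.05 (1 of 20 alleles): dropped at > 0.05
    c(0, 0, rep(2, 8)), # MAF 0.10: kept
    c(0, 2, 2, 2, NA, rep(2, 5)) # missing call
  )
  g <- make_geno(dos)
  fg <- maf_filter_impute(g, maf_min = 0.05)
  expect_identical(fg$map$marker, c("m3", "m4"))
  expect_equal(unname(fg$dosages[5, "m4"]), mean(c(0, 2, 2, 2, 2, 2, 2, 2, 2)))
  expect_identical(fg$n_dropped, 2L)
  expect_error(maf_filter_impute(make_geno(cbind(rep(2, 10)))), "no markers")
})

test_that("Astle-Balding kinship matches direct formula evaluation", {
  g <- make_geno(cbind(c(2, 0)))
  K <- astle_balding_kinship(maf_filter_impute(g, maf_min = 0.2))
  expect_equal(unname(K$matrix), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
})

test_that("kinship agrees with a per-entry loop oracle and is equivariant", {
  fg <- maf_filter_impute(tiny_panel()$geno)
  K <- astle_balding_kinship(fg)$matrix
  expect_equal(K, t(K), tolerance = 1e-10)
  expect_true(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  > -1e-8)
  # brute-force loop over a corner of the matrix
  dos <- fg$dosages
  p <- colMeans(dos) / 2
  for (j in 1:4) {
    for (k in 1:4) {
      kij <- mean((dos[j, ] - 2 * p) * (dos[k, ] - 2 * p) / (2 * p * (1 - p)))
      expect_equal(K[j, k], kij, tolerance = 1e-10)
    }
  }
  # fully homozygous panel: diagonal near 2 (1 + f with f = 1)
  expect_equal(mean(diag(K)), 2, tolerance = 0.1)
  # permuting accessions permutes rows and columns identically
  o <- rev(seq_len(nrow(dos)))
  K2 <- astle_balding_kinship(list(dosages = dos[o, ]))$matrix
  expect_equal(unname(K2), unname(K[o, o]), tolerance = 1e-12)
  # flipping ref/alt at every marker leaves kinship unchanged
  K3 <- astle_balding_kinship(list(dosages = 2 - dos))$matrix
  expect_equal(unname(K3), unname(K), tolerance = 1e-10)
})

test_that("genotype PCA is orthogonal, reconstructive, and sign-stable", {
  fg <- maf_filter_impute(tiny_panel()$geno)
  pca <- genotype_pca(fg, n_pcs = 3)
  gram <- crossprod(pca$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # full-rank reconstruction reproduces the centered matrix
  n <- nrow(fg$dosages)
  x <- scale(fg$dosages, center = TRUE, scale = FALSE)
  sv <- svd(x)
  expect_equal(sv$u %*% diag(sv$d) %*% t(sv$v), unclass(x),
    ignore_attr = TRUE, tolerance = 1e-8
  )
  expect_error(genotype_pca(fg, n_pcs = n), "n_pcs")
  # two runs give identical (not sign-flipped) scores
  expect_identical(pca$scores, genotype_pca(fg, n_pcs = 3)$scores)
})

test_that("PC1 separates two simulated subpopulations", {
  cfg <- sim_config(
    n_accessions = 80, n_subpops = 2, fst = 0.3,
    n_markers = 2000, seed = 31
  )
  g <- simulate_genotypes(cfg)
  pcs <- genotype_pca(maf_filter_impute(g))$scores
  r <- cor(pcs[, 1], as.numeric(attr(g, "subpop")))
  expect_gt(abs(r), 0.9)
})

test_that("Box-Cox lambda recovery and the log branch", {
  y <- c(1, 2, 5, 10)
  bc0 <- boxcox_transform(y)
  set.seed(7)
  lam_ln <- replicate(20, boxcox_transform(exp(rnorm(500, 0, 0.4)))$lambda)
  expect_lt(abs(mean(lam_ln)), 0.1)
  lam_nm <- replicate(20, boxcox_transform(rnorm(500, 10, 2))$lambda)
  expect_lt(abs(mean(lam_nm) - 1), 0.25)
  # transformed values at the log branch equal natural log exactly
  z <- exp(rnorm(200, 1, 1))
  bc <- boxcox_transform(z)
  if (abs(bc$lambda) < 1e-12) {
    expect_identical(bc$transformed, log(z))
  } else {
    expect_equal(bc$transformed, (z^bc$lambda - 1) / bc$lambda)
  }
  expect_error(boxcox_transform(c(1, -2, 3)), "positive")
})

test_that("heritability is 1 without replicate noise and ~0 for pure noise", {
  acc <- rep(paste0("A", 1:20), each = 3)
  vals <- rep(rnorm(20), each = 3)
  h <- heritability(vals, acc)
  expect_equal(h$H2, 1, tolerance = 1e-6)
  set.seed(8)
  h2s <- replicate(200, {
    heritability(rnorm(600), rep(paste0("A", 1:200), each = 3),
      method = "anova"
    )$H2
  })
  expect_lt(mean(h2s), 0.05)
})

test_that("balanced-design REML equals the ANOVA method of moments", {
  set.seed(9)
  for (i in 1:5) {
    g <- rnorm(40)
    y <- rep(g, each = 3) + rnorm(120, 0, sqrt(runif(1, 0.3, 3)))
    acc <- rep(paste0("A", 1:40), each = 3)
    hr <- heritability(y, acc, method = "reml")
    ha <- heritability(y, acc, method = "anova")
    expect_equal(hr$H2, ha$H2, tolerance = 1e-6)
    expect_equal(hr$sigma2_g, ha$sigma2_g, tolerance = 1e-4)
  }
  # accessions missing a replicate are excluded from the fit
  y <- c(rep(1:10, each = 3), 99)
  acc <- c(rep(paste0("A", 1:10), each = 3), "A11")
  expect_identical(heritability(y, acc)$n_accessions, 10L)
  expect_error(heritability(1:4, c("a", "a", "a", "b")), ">= 2")
})

test_that("true heritability of one half is recovered on average", {
  set.seed(10)
  est <- replicate(100, {
    g <- rnorm(300)
    y <- rep(g, each = 3) + rnorm(900)
    heritability(y, rep(paste0("A", 1:300), each = 3),
      method = "anova"
    )$H2
  })
  expect_gt(mean(est), 0.45)
  expect_lt(mean(est), 0.55)
})

test_that("generator heritability rises early and falls under late noise", {
  cfg <- sim_config(
    n_accessions = 100, n_markers = 200, seed = 12,
    polygenic_h2 = 0.5, nongerm_rate = 0, outlier_rate = 0,
    noise_floor_px = 60, late_noise_mult = 4
  )
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  area <- raw_area_matrix(sim$pheno)
  acc <- sub("_r[0-9]+$", "", rownames(area))
  h2_at <- function(day) {
    heritability(area[, as.character(day)], acc, method = "anova")$H2
  }
  early <- h2_at(10)
  mid <- h2_at(35)
  late <- h2_at(50)
  expect_lt(early, mid)
  expect_gt(mid, late)
})
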