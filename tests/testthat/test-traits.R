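test_that("composite area sums views and respects zoom scaling", {
  expect_identical(composite_area(100, 200, 300, 1.0), 600)
  expect_identical(composite_area(0, 0, 0, 3.7), 0)
  # halved raw counts at doubled scale give the same area
  pre <- composite_area(100, 200, 300, 1.0)
  post <- composite_area(50, 100, 150, 2.0)
  expect_identical(pre, post)
  expect_error(composite_area(-1, 0, 0), ">= 0")
  expect_error(composite_area(1, 1, 1, 0), "> 0")
})

test_that("germination and death calling follow the top-view series", {
  expect_equal(call_germination(c(0, 0, 0, 5, 9)), 4)
  expect_true(is.na(call_germination(rep(0, 6))))
  # germinated at 3, zero from day 6 for 5 days: dead at 6
  v <- c(0, 0, 4, 6, 7, 0, 0, 0, 0, 0, 2)
  expect_equal(call_death(v), 6)
  expect_true(is.na(call_death(c(0, 0, 4, 6, 7, 0, 0, 2, 3, 4, 5))))
})

test_that("accessions without established plants are excluded", {
  plants <- data.frame(
    plant_id = paste0("p", 1:9),
    accession = rep(c("A", "B", "C"), each = 3),
    germ_dap = c(NA, NA, NA, 5, 6, NA, 5, 5, 5),
    death_dap = c(NA, NA, NA, NA, 40, NA, NA, NA, NA)
  )
  kept <- exclude_failed(plants, cutoff = 46)
  expect_identical(sort(kept), "C") # A never germinated, B has 1 survivor
  expect_identical(sort(exclude_failed(plants, cutoff = 30)), c("B", "C"))
})

test_that("retained accessions equal a brute-force recount on synthetic data", {
  p <- tiny_panel()
  td <- derive_traits(p$sim$pheno, p$sim$water, traits = "area")
  plants <- td$germination
  ok <- !is.na(plants$germ_dap) &
    (is.na(plants$death_dap) | plants$death_dap > 46)
  brute <- sort(names(which(tapply(ok, plants$accession, sum) >= 2)))
  expect_identical(sort(td$retained), brute)
  # every non-germinated plant id from the truth is called NA
  ng <- p$sim$truth$nongerminated
  expect_true(all(is.na(plants$germ_dap[plants$plant_id %in% ng])))
})

test_that("the 40-MAD fence removes gross artifacts and nothing else", {
  x <- c(10, 11, 12, 13, 500)
  out <- remove_outliers(x, k = 40)
  expect_identical(attr(out, "removed"), c(rep(FALSE, 4), TRUE))
  expect_identical(out[1:4], x[1:4])
  expect_true(is.na(out[5]))
  # zero MAD: the rule is undefined, nothing is flagged
  expect_false(any(attr(remove_outliers(c(5, 5, 5, 5)), "removed")))
  expect_false(any(mad_outliers(c(1, 2))))
})

test_that("injected artifacts are flagged, clean measurements retained", {
  cfg <- sim_config(
    n_accessions = 40, n_markers = 60, seed = 17,
    outlier_rate = 0.01, nongerm_rate = 0
  )
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  area <- raw_area_matrix(sim$pheno)
  inj <- sim$truth$outliers
  inj <- inj[inj$trait == "area", ]
  flagged <- matrix(FALSE, nrow(area), ncol(area), dimnames = dimnames(area))
  for (j in seq_len(ncol(area))) {
    pos <- which(area[, j] > 0)
    flagged[pos, j] <- mad_outliers(area[pos, j], k = 40)
  }
  inj_idx <- cbind(
    match(inj$plant_id, rownames(area)),
    match(as.character(inj$DAP), colnames(area))
  )
  expect_gt(mean(flagged[inj_idx]), 0.99)
  clean <- flagged
  clean[inj_idx] <- FALSE
  expect_lt(sum(clean) / (sum(area > 0) - nrow(inj)), 0.001)
})

test_that("loess smoothing reproduces exact trends and attenuates noise", {
  daps <- 1:45
  line <- 2 * daps
  sm <- smooth_series(line, daps)
  expect_equal(as.numeric(sm), line, tolerance = 1e-6)
  const <- smooth_series(rep(7, 20), 1:20)
  expect_equal(as.numeric(const), rep(7, 20), tolerance = 1e-6)
  short <- smooth_series(c(1, 2, 9), 1:3)
  expect_false(attr(short, "smoothed"))
  set.seed(1)
  wins <- replicate(500, {
    y <- line + rnorm(45, 0, 3)
    fit <- smooth_series(y, daps)
    sqrt(mean((fit - line)^2)) < sqrt(mean((y - line)^2))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("biomass calibration recovers exact slopes and floors predictions", {
  areas <- seq(100, 4000, length.out = 50)
  cal <- calibrate_biomass(areas, 0.002 * areas)
  expect_equal(cal$slope, 0.002, tolerance = 1e-10)
  expect_equal(cal$intercept, 0, tolerance = 1e-8)
  expect_equal(cal$r2, 1)
  set.seed(2)
  a <- rnorm(300, 1000, 200)
  w <- sample(0.002 * a) # permuted: weights independent of area
  expect_lt(calibrate_biomass(a, w)$r2, 0.05)
  cal2 <- calibrate_biomass(c(1, 2, 3, 4), c(10, 1, 1, 1))
  expect_true(all(apply_biomass(cal2, c(0, 1, 100)) >= 0))
  expect_error(calibrate_biomass(rep(5, 10), 1:10), "variance")
})

test_that("biomass calibration is unit consistent", {
  set.seed(3)
  a <- rnorm(100, 2000, 300)
  w <- 0.002 * a + rnorm(100, 0, 0.3)
  c1 <- calibrate_biomass(a, w)
  c10 <- calibrate_biomass(10 * a, w)
  expect_equal(c10$slope, c1$slope / 10, tolerance = 1e-10)
  expect_equal(c10$r2, c1$r2, tolerance = 1e-12)
})

test_that("WUE divides area by cumulative water and never explodes", {
  wue <- compute_wue(
    areas = c(100, 300, 500), water_g = c(50, 100, 100),
    daps = 1:3
  )
  expect_equal(wue[3], 2.0) # 500 / 250
  z <- compute_wue(c(5, 10), c(0, 0), 1:2)
  expect_true(all(is.na(z)))
  a <- c(120, 250, 480)
  w <- c(30, 40, 50)
  expect_equal(compute_wue(a, 2 * w), compute_wue(a, w) / 2)
  expect_error(compute_wue(a, c(-1, 2, 3)), ">= 0")
})

test_that("RGR recovers exponential growth rates exactly", {
  for (r in c(0.05, 0.1, 0.3)) {
    for (pair in list(c(1, 2), c(3, 10), c(20, 45))) {
      w1 <- exp(r * pair[1]) * c(1, 1, 1)
      w2 <- exp(r * pair[2]) * c(1, 1, 1)
      expect_equal(compute_rgr(w1, w2, pair[1], pair[2]), r,
        tolerance = 1e-12
      )
    }
  }
  expect_equal(compute_rgr(c(exp(1), exp(3)), c(exp(2), exp(4)), 5, 6), 1.0)
  expect_equal(compute_rgr(c(7, 7), c(7, 7), 1, 2), 0)
  expect_error(compute_rgr(1, 2, 3, 3), "exceed")
})

test_that("derived traits are invariant to record order", {
  p <- qtl_panel()
  pheno <- p$sim$pheno
  water <- p$sim$water
  td1 <- derive_traits(pheno, water, traits = c("area", "wue"))
  set.seed(4)
  td2 <- derive_traits(
    pheno[sample(nrow(pheno)), ],
    water[sample(nrow(water)), ],
    traits = c("area", "wue")
  )
  expect_equal(td1$accession, td2$accession)
  expect_identical(td1$retained, td2$retained)
})

test_that("the trait pipeline emits complete accession series", {
  p <- tiny_panel()
  td <- derive_traits(p$sim$pheno, p$sim$water)
  expect_setequal(
    unique(td$accession$trait),
    c("area", "height", "hull_area", "biomass", "wue", "rgr")
  )
  area <- td$accession[td$accession$trait == "area", ]
  # smoothed series have no gaps over the germinated span
  late <- area[area$DAP >= 12, ]
  expect_false(any(is.na(late$value)))
  expect_true(all(td$accession$value[td$accession$trait == "biomass"] >= 0,
    na.rm = TRUE
  ))
})
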