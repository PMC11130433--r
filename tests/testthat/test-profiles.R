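test_that("percentile ranks follow the (rank-1)/(n-1) convention", {
  expect_equal(percentile_rank(c(1, 2, 3, 4)),
    c(0, 100 / 3, 200 / 3, 100),
    tolerance = 1e-10
  )
  expect_equal(percentile_rank(c(5, 5)), c(50, 50))
  expect_equal(percentile_rank(c(7, 7, 7)), c(50, 50, 50))
  x <- c(3, NA, 1, 9)
  p <- percentile_rank(x)
  expect_true(is.na(p[2]))
  expect_equal(p[c(1, 3, 4)], c(50, 0, 100))
  expect_error(percentile_rank(c(1, NA)), ">= 2")
})

test_that("percentiles are invariant to strictly monotone transforms", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(30)
    expect_equal(percentile_rank(x), percentile_rank(exp(x)))
    expect_equal(percentile_rank(x), percentile_rank(2 * x + 5))
    # and agree with a brute-force pairwise count under distinct values
    brute <- vapply(
      x,
      function(v) 100 * sum(x < v) / (length(x) - 1), numeric(1)
    )
    expect_equal(percentile_rank(x), brute)
  }
})

test_that("ideotype selection matches a brute-force filter", {
  set.seed(2)
  n <- 300
  days <- 15:31
  acc <- sprintf("S%03d", 1:n)
  wue <- matrix(rnorm(n * length(days)),
    n,
    dimnames = list(acc, days)
  )
  ratio <- 0.3 * wue + rnorm(n * length(days)) # correlated traits
  wue_pct <- apply(wue, 2, percentile_rank)
  ratio_pct <- apply(ratio, 2, percentile_rank)
  rownames(wue_pct) <- rownames(ratio_pct) <- acc
  rep_ <- select_ideotypes(wue_pct, ratio_pct, window = c(15, 31))
  wm <- rowMeans(wue_pct)
  rm_ <- rowMeans(ratio_pct)
  brute_pos <- sort(acc[wm >= 90 & rm_ <= 5])
  brute_neg <- sort(acc[wm <= 10 & rm_ >= 95])
  expect_identical(rep_$positives, brute_pos)
  expect_identical(rep_$negatives, brute_neg)
  expect_length(intersect(rep_$positives, rep_$negatives), 0)
})

test_that("single-day ideotype archetypes classify as expected", {
  acc <- c("hero", "mid", "anti")
  mk <- function(w, r) {
    list(
      wue = matrix(w, 3, 2, dimnames = list(acc, c(20, 21))),
      ratio = matrix(r, 3, 2, dimnames = list(acc, c(20, 21)))
    )
  }
  tabs <- mk(c(95, 50, 5), c(2, 50, 98))
  rep_ <- select_ideotypes(tabs$wue, tabs$ratio, window = c(20, 21))
  expect_identical(rep_$positives, "hero")
  expect_identical(rep_$negatives, "anti")
  # high WUE alone is not enough
  tabs2 <- mk(c(95, 50, 5), c(50, 50, 50))
  rep2 <- select_ideotypes(tabs2$wue, tabs2$ratio, window = c(20, 21))
  expect_length(rep2$positives, 0)
  expect_error(
    select_ideotypes(tabs$wue, tabs$ratio, window = c(40, 50)),
    "window"
  )
})

test_that("ideotype sets shrink as thresholds tighten", {
  set.seed(3)
  n <- 200
  acc <- sprintf("S%03d", 1:n)
  wue_pct <- matrix(percentile_rank(rnorm(n)), n,
    dimnames = list(acc, "20")
  )
  ratio_pct <- matrix(percentile_rank(rnorm(n)), n,
    dimnames = list(acc, "20")
  )
  loose <- select_ideotypes(wue_pct, ratio_pct,
    window = c(20, 20),
    wue_frac = 0.5, ratio_frac = 0.5
  )
  tight <- select_ideotypes(wue_pct, ratio_pct,
    window = c(20, 20),
    wue_frac = 0.25, ratio_frac = 0.25
  )
  expect_true(all(tight$positives %in% loose$positives))
  expect_true(all(tight$negatives %in% loose$negatives))
})

test_that("planted growth archetypes are recovered by Ward clustering", {
  set.seed(4)
  days <- 12:56
  arch <- list(
    c(amax = 20000, r = 0.12, t0 = 38),
    c(amax = 45000, r = 0.18, t0 = 30),
    c(amax = 70000, r = 0.25, t0 = 24)
  )
  n_per <- 30
  profiles <- do.call(rbind, lapply(seq_along(arch), function(a) {
    base <- logistic_curve(days, arch[[a]]["amax"], arch[[a]]["r"],
      arch[[a]]["t0"])
    t(replicate(n_per, base * (1 + rnorm(length(days), 0, 0.02))))
  }))
  rownames(profiles) <- sprintf("S%03d", seq_len(nrow(profiles)))
  colnames(profiles) <- days
  truth <- rep(1:3, each = n_per)
  names(truth) <- rownames(profiles)
  tab <- long_trait_table(profiles, "area")
  cl <- cluster_profiles(tab, "area", k = 3, dap_range = c(12, 56))
  ari <- mclust::adjustedRandIndex(cl$assignments[names(truth)], truth)
  expect_gte(ari, 0.9)
  # merge heights never decrease along the agglomeration
  expect_true(all(diff(cl$hclust$height) >= -1e-8))
  # each mean profile is the average of its members
  for (k in 1:3) {
    members <- names(cl$assignments)[cl$assignments == k]
    expect_equal(unname(cl$mean_profiles[k, ]),
      unname(colMeans(profiles[members, , drop = FALSE])),
      tolerance = 1e-12
    )
  }
})

test_that("k = 1 returns the grand mean profile and input order is irrelevant", {
  set.seed(5)
  days <- 12:20
  m <- matrix(rnorm(20 * length(days), 100, 10), 20,
    dimnames = list(sprintf("S%02d", 1:20), days)
  )
  tab <- long_trait_table(m, "area")
  cl1 <- cluster_profiles(tab, "area", k = 1, dap_range = c(12, 20))
  expect_equal(unname(cl1$mean_profiles[1, ]), unname(colMeans(m)))
  shuffled <- tab[sample(nrow(tab)), ]
  cl_a <- cluster_profiles(tab, "area", k = 4, dap_range = c(12, 20))
  cl_b <- cluster_profiles(shuffled, "area", k = 4, dap_range = c(12, 20))
  expect_identical(cl_a$assignments, cl_b$assignments)
  expect_error(cluster_profiles(tab, "area", k = 21), "k exceeds")
})

test_that("duplicating every accession leaves cluster mean profiles unchanged", {
  set.seed(6)
  days <- 12:20
  m <- matrix(rnorm(12 * length(days), 100, 20), 12,
    dimnames = list(sprintf("S%02d", 1:12), days)
  )
  m2 <- rbind(m, m)
  rownames(m2) <- c(rownames(m), paste0(rownames(m), "dup"))
  cl1 <- cluster_profiles(long_trait_table(m, "area"), "area",
    k = 3,
    dap_range = c(12, 20)
  )
  cl2 <- cluster_profiles(long_trait_table(m2, "area"), "area",
    k = 3,
    dap_range = c(12, 20)
  )
  match_rows <- function(a, b) {
    # clusters may be renumbered; compare as unordered sets of profiles
    a_sorted <- a[order(a[, 1]), , drop = FALSE]
    b_sorted <- b[order(b[, 1]), , drop = FALSE]
    expect_equal(unname(a_sorted), unname(b_sorted), tolerance = 1e-8)
  }
  match_rows(cl1$mean_profiles, cl2$mean_profiles)
})

test_that("top and bottom sets match a brute-force sort", {
  set.seed(7)
  n <- 100
  m <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("S%03d", 1:n), "51"))
  tab <- long_trait_table(m, "biomass")
  tb <- rank_top_bottom(tab, "biomass", dap = 51, fraction = 0.05)
  expect_length(tb$top, 5)
  expect_length(tb$bottom, 5)
  v <- m[, 1]
  expect_setequal(tb$top, names(sort(v, decreasing = TRUE))[1:5])
  expect_setequal(tb$bottom, names(sort(v))[1:5])
  expect_length(intersect(tb$top, tb$bottom), 0)
})
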