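test_that("distance matrices are symmetric with zero diagonal", {
  sites <- site_table()
  pm <- data.frame(sample = sites$population, population = sites$population,
                   elevation_m = sites$elevation_m, lat = sites$lat,
                   lon = sites$lon)
  for (kind in c("geography", "elevation")) {
    dm <- build_distances(pm, kind, env = sites)
    expect_equal(unname(diag(dm)), rep(0, 5))
    expect_equal(unclass(dm), t(unclass(dm)), ignore_attr = TRUE)
  }
  dm <- build_distances(pm, "elevation")
  expect_equal(dm["A1", "B1"], 2591 - 2195)
})

test_that("site-table environmental extremes give the largest distance", {
  sites <- site_table()
  pm <- data.frame(sample = sites$population, population = sites$population,
                   elevation_m = sites$elevation_m, lat = sites$lat,
                   lon = sites$lon)
  dm <- build_distances(pm, "environment", env = sites)
  off <- dm[upper.tri(dm)]
  expect_equal(dm["RF_CM", "D1"], max(off))
})

test_that("Mantel r matches hand-computed Pearson and perfect correlation", {
  set.seed(40)
  # 10 populations: the identity permutation is essentially never redrawn,
  # so perfect correlation attains the minimal p
  d1 <- matrix(0, 10, 10, dimnames = list(LETTERS[1:10], LETTERS[1:10]))
  d1[upper.tri(d1)] <- seq_len(45)
  d1 <- d1 + t(d1)
  d2 <- 2 * d1
  mt <- mantel_test(d1, d2, n_perm = 999)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_equal(mt$p, 0.001)
  # hand-built second matrix on 4 populations: r equals cor() on the 6 pairs
  d1 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d1[upper.tri(d1)] <- c(1, 2, 3, 4, 5, 6)
  d1 <- d1 + t(d1)
  d3 <- matrix(0, 4, 4, dimnames = dimnames(d1))
  d3[upper.tri(d3)] <- c(2, 1, 5, 3, 6, 4)
  d3 <- d3 + t(d3)
  mt3 <- mantel_test(d1, d3, n_perm = 99)
  expect_equal(mt3$r, cor(d1[upper.tri(d1)], d3[upper.tri(d3)]),
               tolerance = 1e-12)
  # affine rescaling leaves r unchanged
  mt4 <- mantel_test(d1, 10 + 3 * d3, n_perm = 99)
  expect_equal(mt4$r, mt3$r, tolerance = 1e-12)
  expect_error(mantel_test(d1, matrix(1, 4, 4) - diag(1, 4), n_perm = 99),
               "constant")
})

test_that("Mantel statistic agrees with vegan's implementation", {
  set.seed(44)
  a <- as.matrix(dist(matrix(rnorm(14), 7)))
  b <- as.matrix(dist(matrix(rnorm(14), 7)))
  dimnames(a) <- dimnames(b) <- list(letters[1:7], letters[1:7])
  mine <- mantel_test(a, b, n_perm = 99)
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 99)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("self-correlation is 1 and p never reaches zero", {
  set.seed(41)
  d <- as.matrix(dist(rnorm(6)))
  dimnames(d) <- list(letters[1:6], letters[1:6])
  mt <- mantel_test(d, d, n_perm = 99)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_gt(mt$p, 0)
})

test_that("trait suite flags untestable categories and nails zero-noise clines", {
  sites <- site_table()
  pm <- data.frame(sample = sites$population, population = sites$population,
                   elevation_m = sites$elevation_m, lat = sites$lat,
                   lon = sites$lon)
  set.seed(42)
  traits <- gen_trait_clines(pm, slopes = c(mass = -2, femur = -1),
                             noise_sd = 0)
  traits$clutch <- c(5, NA, NA, NA, 4)      # only 2 complete populations
  preds <- list(elevation = build_distances(pm, "elevation"),
                geography = build_distances(pm, "geography"))
  grid <- trait_association_suite(
    traits, categories = list(growth = c("mass", "femur"),
                              reproductive = "clutch"),
    predictors = preds, pm = pm, n_perm = 99)
  growth_elev <- grid[grid$category == "growth" & grid$predictor == "elevation", ]
  expect_equal(growth_elev$r, 1, tolerance = 1e-9)
  repro <- grid[grid$category == "reproductive", ]
  expect_true(all(is.na(repro$r)))
  # a trait equal to elevation itself correlates perfectly with elevation
  t2 <- data.frame(population = pm$population, elev_trait = pm$elevation_m)
  g2 <- trait_association_suite(t2, list(x = "elev_trait"), preds["elevation"],
                                pm, n_perm = 99)
  expect_equal(g2$r, 1, tolerance = 1e-9)
})

test_that("genetic distances pass through linearized Fst intact", {
  set.seed(43)
  g <- random_geno(12, 60)
  pm <- make_popmap(rownames(g$calls), rep(c("A", "B", "C"), each = 4))
  pf <- pairwise_fst(g, pm)
  dm <- build_distances(pm, "genetic", fst = pf$linearized)
  expect_equal(unclass(dm)[rownames(pf$linearized), colnames(pf$linearized)],
               pf$linearized, ignore_attr = TRUE)
})
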