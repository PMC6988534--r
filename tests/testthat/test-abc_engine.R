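test_that("reference tables are balanced, labelled and seed-reproducible", {
  set.seed(4)
  tab <- build_reference_table(c("ss", "am"), 10, c(3, 3), 30)
  expect_equal(nrow(tab), 20)
  expect_equal(as.vector(base::table(tab$model)[c("ss", "am")]), c(10L, 10L))
  expect_true(all(c("m", "ne_1", "ne_2") %in% names(tab)))
  set.seed(4)
  tab2 <- build_reference_table(c("ss", "am"), 10, c(3, 3), 30)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
})

test_that("rejection posterior follows the accepted-set shares", {
  set.seed(5)
  tab <- gaussian_table(60, model = "A")
  tab$model <- rep(c("A", "B", "C"), each = 20)
  # tol = 1 accepts everything: probabilities equal table shares
  obs <- setNames(rnorm(6), paste0("g", 1:6))
  post <- abc_reject(obs, tab, tol = 1)
  expect_equal(unname(post$prob), rep(1 / 3, 3))
  expect_equal(sum(post$prob), 1, tolerance = 1e-9)
  # observation equal to one row, single acceptance: that row's model wins
  row7 <- unlist(tab[7, grep("^ss_", names(tab))])
  post1 <- abc_reject(row7, tab, tol = 1 / 60)
  expect_equal(unname(post1$prob[tab$model[7]]), 1)
})

test_that("rejection acceptance reproduces hand-sorted distances", {
  tab <- gaussian_table(6, n_stats = 2)
  tab$model <- c("A", "A", "A", "B", "B", "B")
  obs <- c(g1 = 0.3, g2 = -0.1)
  st_c <- attr(tab, "ss_center"); st_s <- attr(tab, "ss_scale")
  z <- sweep(sweep(as.matrix(tab[c("ss_g1", "ss_g2")]), 2, st_c), 2, st_s, "/")
  zo <- (c(0.3, -0.1) - st_c) / st_s
  d <- sqrt(colSums((t(z) - zo)^2))
  set.seed(1)
  post <- abc_reject(obs, tab, tol = 0.5)
  expect_setequal(post$accepted, order(d)[1:3])
  expect_equal(sort(post$distance), sort(d[order(d)[1:3]]), tolerance = 1e-12)
})

test_that("rejection probabilities are invariant to monotone stat rescaling", {
  set.seed(6)
  tab <- gaussian_table(200, n_stats = 4)
  tab$model <- rep(c("A", "B"), 100)
  obs <- setNames(rnorm(4), paste0("g", 1:4))
  p1 <- abc_reject(obs, tab, tol = 0.1)$prob
  # affine rescaling of one statistic is absorbed by median/MAD
  tab2 <- tab
  tab2$ss_g2 <- 100 + 7 * tab2$ss_g2
  sm <- as.matrix(tab2[grep("^ss_", names(tab2))])
  attr(tab2, "ss_center") <- apply(sm, 2, median)
  attr(tab2, "ss_scale") <- apply(sm, 2, mad)
  obs2 <- obs; obs2["g2"] <- 100 + 7 * obs2["g2"]
  p2 <- abc_reject(obs2, tab2, tol = 0.1)$prob
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("soft-max posterior is symmetric for identical simulators and sums to 1", {
  set.seed(8)
  n <- 400
  stats <- matrix(rnorm(2 * n * 5), 2 * n)
  colnames(stats) <- paste0("ss_g", 1:5)
  tab <- data.frame(model = rep(c("A", "B"), each = n),
                    m = runif(2 * n, 0.001, 0.05), ne_1 = 1000, stats)
  class(tab) <- c("abc_reftable", "data.frame")
  attr(tab, "prior") <- prior_spec()
  obs <- setNames(rep(0, 5), paste0("g", 1:5))
  post <- regression_model_probs(obs, tab, tol = 0.5)
  expect_equal(sum(post$prob), 1, tolerance = 1e-9)
  expect_equal(unname(post$prob["A"]), 0.5, tolerance = 0.1)
})

test_that("soft-max posterior identifies linearly separable models", {
  set.seed(9)
  n <- 300
  stats <- rbind(matrix(rnorm(n * 3, mean = 3), n),
                 matrix(rnorm(n * 3, mean = -3), n))
  colnames(stats) <- paste0("ss_g", 1:3)
  tab <- data.frame(model = rep(c("A", "B"), each = n),
                    m = runif(2 * n, 0.001, 0.05), ne_1 = 1000, stats)
  class(tab) <- c("abc_reftable", "data.frame")
  obs <- setNames(rep(3, 3), paste0("g", 1:3))
  post <- regression_model_probs(obs, tab, tol = 1)
  expect_gt(post$prob["A"], 0.95)
  # duplicating every row leaves the posterior unchanged
  tab2 <- rbind(tab, tab)
  class(tab2) <- c("abc_reftable", "data.frame")
  post2 <- regression_model_probs(obs, tab2, tol = 1)
  expect_equal(post$prob, post2$prob, tolerance = 0.02)
})

test_that("models absent from the accepted set get probability zero, flagged", {
  set.seed(10)
  n <- 100
  stats <- rbind(matrix(rnorm(n, mean = 0), n),
                 matrix(rnorm(n, mean = 50), n))
  colnames(stats) <- "ss_g1"
  tab <- data.frame(model = rep(c("A", "B"), each = n), m = 0.01,
                    ne_1 = 1000, stats)
  class(tab) <- c("abc_reftable", "data.frame")
  post <- regression_model_probs(c(g1 = 0), tab, tol = 0.2)
  expect_equal(unname(post$prob["B"]), 0)
  expect_equal(post$untestable, "B")
})

test_that("cross-validation is at chance for identical models, perfect for separable ones", {
  set.seed(11)
  n <- 150
  stats <- matrix(rnorm(2 * n * 4), 2 * n)
  colnames(stats) <- paste0("ss_g", 1:4)
  tab <- data.frame(model = rep(c("A", "B"), each = n), m = 0.01,
                    ne_1 = 1000, stats)
  class(tab) <- c("abc_reftable", "data.frame")
  cv <- cross_validate(tab, n_cv = 40, tol = 0.05, method = "rejection")
  expect_true(all(rowSums(cv$confusion) == 40))
  expect_lt(abs(cv$mean_correct - 0.5), 0.2)     # binomial noise around chance

  stats2 <- rbind(matrix(rnorm(n * 4, 4), n), matrix(rnorm(n * 4, -4), n))
  colnames(stats2) <- paste0("ss_g", 1:4)
  tab2 <- data.frame(model = rep(c("A", "B"), each = n), m = 0.01,
                     ne_1 = 1000, stats2)
  class(tab2) <- c("abc_reftable", "data.frame")
  for (method in c("rejection", "mnlogistic")) {
    cv2 <- cross_validate(tab2, n_cv = 25, tol = 0.1, method = method)
    expect_gte(cv2$mean_correct, 0.95)
  }
  expect_error(cross_validate(tab2, n_cv = 10, tol = 0.1, method = "bogus"))
})

test_that("goodness-of-fit p-values behave at the extremes and stay in (0, 1]", {
  set.seed(12)
  tab <- gaussian_table(500)
  # an observation far outside the table: minimal possible p
  far <- setNames(rep(60, 6), paste0("g", 1:6))
  gof_far <- goodness_of_fit(far, tab, tol = 0.01, n_rep = 99)
  expect_equal(gof_far$p, 1 / 100)
  # typical observations give unremarkable p
  obs <- setNames(rnorm(6), paste0("g", 1:6))
  gof <- goodness_of_fit(obs, tab, tol = 0.01, n_rep = 99)
  expect_true(gof$p > 0 && gof$p <= 1)
  expect_error(goodness_of_fit(obs, tab, tol = 0.01, n_rep = 0), "n_rep")
})

test_that("parameter posterior with tol = 1 and no adjustment recovers the prior", {
  set.seed(13)
  tab <- gaussian_table(4000)
  obs <- setNames(rnorm(6), paste0("g", 1:6))
  post <- estimate_parameters(obs, tab, tol = 1, adjust = FALSE)
  med_ne <- post$summary$median[post$summary$parameter == "ne_1"]
  expect_equal(med_ne, sqrt(200 * 10000), tolerance = 0.1)
  med_m <- post$summary$median[post$summary$parameter == "m"]
  expect_equal(med_m, 0.0255, tolerance = 0.1)
})

test_that("parameter intervals always lie inside the prior support", {
  set.seed(14)
  tab <- gaussian_table(800)
  # adjustment may push estimates far; clamping keeps them in bounds
  obs <- setNames(rep(4, 6), paste0("g", 1:6))
  post <- estimate_parameters(obs, tab, tol = 0.2)
  expect_true(all(post$summary$lower <= post$summary$median + 1e-12))
  expect_true(all(post$summary$median <= post$summary$upper + 1e-12))
  m_row <- post$summary[post$summary$parameter == "m", ]
  expect_true(m_row$lower >= 0.001 && m_row$upper <= 0.05)
  ne_row <- post$summary[post$summary$parameter == "ne_1", ]
  expect_true(ne_row$lower >= 200 && ne_row$upper <= 10000)
})

test_that("reference tables round-trip through CSV plus sidecar", {
  set.seed(15)
  tab <- build_reference_table("ss", 5, c(3, 3), 20)
  path <- tempfile(fileext = ".csv")
  write_reference_table(tab, path)
  back <- read_reference_table(path)
  expect_equal(as.data.frame(tab), as.data.frame(back), tolerance = 1e-12)
  expect_equal(attr(tab, "ss_center"), attr(back, "ss_center"),
               tolerance = 1e-12)
  o <- dataset_sumstats(simulate_dataset(demographic_model("ss", c(500, 500),
                                                           0.01),
                                         c(3, 3), 20)$genotypes,
                        make_popmap(paste0(rep(c("P1_", "P2_"), each = 3),
                                           1:3),
                                    rep(c("P1", "P2"), each = 3)))
  expect_s3_class(suppressWarnings(abc_reject(o, back, tol = 0.5)),
                  "abc_posterior")
})
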