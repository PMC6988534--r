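test_that("folded spectra match a hand tally and conserve locus counts", {
  # 2 diploids per pop, 6 loci
  calls <- rbind(a1 = c(0L, 1L, 2L, 2L, 1L, 0L),
                 a2 = c(0L, 0L, 2L, 1L, 1L, 0L),
                 b1 = c(1L, 0L, 2L, 0L, 2L, 0L),
                 b2 = c(1L, 0L, 2L, 0L, 2L, 0L))
  g <- geno(calls)
  pm <- make_popmap(rownames(calls), c("A", "A", "B", "B"))
  afs <- minor_afs(g, pm)
  # pop A alt counts: 0,1,4,3,2,0 -> minor: 0,1,0,1,2,0 -> classes 0:2 = (3,2,1)
  expect_equal(unname(afs$sfs$A), c(3, 2, 1))
  # pop B alt counts: 2,0,4,0,4,0 -> minor: 2,0,0,0,0,0 -> (5,0,1)
  expect_equal(unname(afs$sfs$B), c(5, 0, 1))
  expect_equal(unname(afs$n_polymorphic), c(3, 1))
  expect_equal(sum(afs$sfs$A), afs$n_loci)
})

test_that("folding makes spectra invariant to allele relabelling", {
  set.seed(20)
  g <- random_geno(8, 50)
  pm <- make_popmap(rownames(g$calls), rep(c("A", "B"), each = 4))
  a1 <- minor_afs(g, pm)
  flipped <- geno(2L - g$calls)
  a2 <- minor_afs(flipped, pm)
  expect_equal(a1$sfs, a2$sfs)
})

test_that("every-locus-singleton matrices put all mass in class 1", {
  calls <- matrix(0L, 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  calls[1, ] <- 1L
  pm <- make_popmap(paste0("s", 1:4), rep("A", 4))
  afs <- minor_afs(geno(calls), pm)
  expect_equal(unname(afs$sfs$A), c(0, 10, 0, 0, 0))
})

test_that("expected spectra are proper distributions and reproducible", {
  mod <- demographic_model("ss", c(800, 800), 0.02)
  set.seed(21)
  e1 <- expected_afs(mod, c(4, 4), n_sim_loci = 300, seed = 55)
  e2 <- expected_afs(mod, c(4, 4), n_sim_loci = 300, seed = 55)
  expect_identical(e1, e2)
  for (p in e1) {
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("single-deme folded spectrum follows the neutral 1/i + 1/(2n-i) form", {
  one <- demographic_model("ss", 1000, 0.01)
  n_dip <- 5; n_loci <- 8000
  set.seed(22)
  sim <- simulate_dataset(one, n_dip, n_loci)
  counts <- minor_afs(sim$genotypes, sim$popmap)$sfs[[1]][-1]
  i <- 1:n_dip
  theo <- 1 / i + 1 / (2 * n_dip - i)
  theo[n_dip] <- 1 / n_dip
  theo <- theo / sum(theo)
  se <- sqrt(theo * (1 - theo) / n_loci)
  expect_true(all(abs(counts / n_loci - theo) < 3.5 * se))
})

test_that("composite log-likelihood does hand arithmetic and obeys Gibbs", {
  expect_equal(composite_ll(c(10, 5), c(2 / 3, 1 / 3)),
               10 * log(2 / 3) + 5 * log(1 / 3))
  expect_equal(composite_ll(c(10, 5), c(2 / 3, 1 / 3)), -9.5477, tolerance = 1e-4)
  # maximal when expected equals observed proportions
  obs <- c(7, 2, 1)
  at_truth <- composite_ll(obs, obs / sum(obs))
  for (k in 1:10) {
    alt <- prop.table(runif(3))
    expect_gte(at_truth, composite_ll(obs, alt))
  }
  # linear in the observed counts
  expect_equal(composite_ll(3 * obs, obs / sum(obs)), 3 * at_truth)
  expect_error(composite_ll(c(1, 1), c(1, 0)), "zero expected")
})

test_that("likelihood discriminates the generating parameters from distant ones", {
  set.seed(23)
  truth <- demographic_model("ss", c(1000, 1000), 0.002)
  far <- demographic_model("ss", c(1000, 1000), 0.05)
  e_true <- expected_afs(truth, c(6, 6), n_sim_loci = 4000, seed = 77)
  e_far <- expected_afs(far, c(6, 6), n_sim_loci = 4000, seed = 77)
  diffs <- replicate(10, {
    sim <- simulate_dataset(truth, c(6, 6), 300)
    afs <- minor_afs(sim$genotypes, sim$popmap)
    composite_ll(afs, e_true) - composite_ll(afs, e_far)
  })
  expect_gt(mean(diffs), 0)
})

test_that("fit_afs respects bounds, restarts monotonicity and fixed parameters", {
  set.seed(24)
  truth <- demographic_model("ss", c(1500, 1500), 0.01)
  sim <- simulate_dataset(truth, c(5, 5), 150)
  afs <- minor_afs(sim$genotypes, sim$popmap)
  f1 <- fit_afs(afs, "ss", c(5, 5), restarts = 1, n_sim_loci = 300,
                max_cycles = 2)
  expect_true(f1$par[["m"]] >= 0.001 && f1$par[["m"]] <= 0.05)
  expect_true(f1$par[["ne"]] >= 200 && f1$par[["ne"]] <= 10000)
  f2 <- fit_afs(afs, "ss", c(5, 5), fixed = list(m = 0.01), restarts = 2,
                n_sim_loci = 300, max_cycles = 2)
  expect_equal(unname(f2$par[["m"]]), 0.01)
})

test_that("parametric bootstrap gives ordered, reproducible intervals", {
  set.seed(25)
  truth <- demographic_model("ss", c(1500, 1500), 0.01)
  sim <- simulate_dataset(truth, c(4, 4), 120)
  afs <- minor_afs(sim$genotypes, sim$popmap)
  fit <- fit_afs(afs, "ss", c(4, 4), fixed = list(m = 0.01), restarts = 1,
                 n_sim_loci = 250, max_cycles = 2)
  set.seed(26)
  bt <- parametric_bootstrap(fit, n_boot = 4, n_snps = 120)
  expect_true(all(bt$lower <= bt$upper))
  set.seed(26)
  bt2 <- parametric_bootstrap(fit, n_boot = 4, n_snps = 120)
  expect_equal(bt, bt2)
  expect_error(parametric_bootstrap(fit, n_boot = 1), "n_boot")
})

test_that("bootstrap intervals tighten with more observed loci", {
  set.seed(27)
  truth <- demographic_model("ss", c(1500, 1500), 0.01)
  width_at <- function(n_snps) {
    mean(replicate(3, {
      sim <- simulate_dataset(truth, c(4, 4), n_snps)
      afs <- minor_afs(sim$genotypes, sim$popmap)
      fit <- fit_afs(afs, "ss", c(4, 4), fixed = list(m = 0.01),
                     restarts = 1, n_sim_loci = 250, max_cycles = 2)
      bt <- parametric_bootstrap(fit, n_boot = 8, n_snps = n_snps)
      log(bt$upper[bt$parameter == "ne"]) - log(bt$lower[bt$parameter == "ne"])
    }))
  }
  expect_lt(width_at(2000), width_at(200))
})
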