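# Folded (minor-allele) site-frequency spectra and composite-likelihood
# parameter estimation with a Monte-Carlo expected spectrum.
#
# Each population's folded spectrum counts loci by minor-allele copy number
# 0..n_k (n_k diploids = 2 n_k copies, folded at n_k); class 0 holds loci
# monomorphic within that population. The composite log-likelihood treats
# loci and populations as independent: sum over classes of obs * log(exp).
#
# Because each locus carries exactly one mutation conditioned on segregating
# in the pooled sample, the spectrum shape depends on the migration-scaled
# genealogy only (products like 4*Ne*m); absolute rates are identified only
# when some parameters are fixed. fit_afs() therefore accepts a `fixed` list.

#' Folded minor-allele site-frequency spectra per population
#'
#' @param g A complete (no missing calls) [geno()] object.
#' @param pm Population map.
#' @return An object of class `joint_afs`: per-population counts over minor
#'   allele copy classes `0..n_k`, the per-population polymorphic totals and
#'   the total locus count.
#' @export
minor_afs <- function(g, pm) {
  calls <- g$calls
  if (anyNA(calls)) stop("minor_afs requires a complete genotype matrix")
  idx <- pop_indices(calls, pm)
  sfs <- lapply(idx, function(rows) {
    sub <- calls[rows, , drop = FALSE]
    nk <- nrow(sub)
    alt <- colSums(sub)
    minor <- pmin(alt, 2 * nk - alt)
    tabulate(minor + 1L, nbins = nk + 1L) |>
      setNames(0:nk)
  })
  structure(list(sfs = sfs,
                 n_polymorphic = vapply(sfs, function(s) sum(s[-1]), numeric(1)),
                 n_loci = ncol(calls)),
            class = "joint_afs")
}

#' @export
print.joint_afs <- function(x, ...) {
  cat("Folded site-frequency spectra over", x$n_loci, "loci\n")
  for (p in names(x$sfs))
    cat(" ", p, ": ", sum(x$sfs[[p]][-1]), " polymorphic\n", sep = "")
  invisible(x)
}

#' Monte-Carlo expected folded spectrum under a demographic model
#'
#' Simulates `n_sim_loci` conditioned SNPs under the model and converts the
#' per-population folded spectra to proportions with add-one smoothing (so no
#' class has probability zero).
#'
#' @param model A [demographic_model()].
#' @param samples Per-deme diploid sample sizes.
#' @param n_sim_loci Simulated loci (default 2000).
#' @param seed Optional seed for the simulation stream.
#' @return A list of per-population probability vectors over classes
#'   `0..n_k`, each summing to 1.
#' @export
expected_afs <- function(model, samples, n_sim_loci = 2000, seed = NULL) {
  sim <- simulate_dataset(model, samples, n_sim_loci, seed = seed)
  afs <- minor_afs(sim$genotypes, sim$popmap)
  lapply(afs$sfs, function(s) {
    sm <- s + 1
    sm / sum(sm)
  })
}

#' Composite log-likelihood of observed spectra
#'
#' @param obs Observed counts: a `joint_afs` or a list/vector of counts.
#' @param expected Expected proportions with matching class support (a list
#'   of per-population vectors, or one vector).
#' @return `sum(obs * log(expected))` over all classes and populations.
#' @export
composite_ll <- function(obs, expected) {
  oc <- if (inherits(obs, "joint_afs")) obs$sfs else obs
  if (!is.list(oc)) oc <- list(oc)
  if (!is.list(expected)) expected <- list(expected)
  if (length(oc) != length(expected))
    stop("observed and expected population lists differ in length")
  ll <- 0
  for (i in seq_along(oc)) {
    o <- as.numeric(oc[[i]]); e <- as.numeric(expected[[i]])
    if (length(o) != length(e))
      stop("class supports do not align for population ", i)
    if (any(e <= 0 & o > 0))
      stop("zero expected proportion with positive observed count")
    use <- o > 0
    ll <- ll + sum(o[use] * log(e[use]))
  }
  ll
}

#' Maximize the composite likelihood over (m, Ne)
#'
#' Cyclic coordinate search on (m, log Ne) with common random numbers: each
#' candidate parameter vector is scored with [expected_afs()] run on a fixed
#' sub-seed, making the Monte-Carlo likelihood surface deterministic for the
#' optimizer. Cycles stop when the relative parameter change falls below
#' `reltol`; the best of `restarts` seeded random starts is returned.
#'
#' @param obs Observed `joint_afs`.
#' @param label Gene-flow model label.
#' @param samples Per-deme diploid sample sizes.
#' @param prior A [prior_spec()]; its bounds delimit the search box.
#' @param fixed Named list of parameters to hold fixed, e.g.
#'   `list(m = 0.005)`; Ne entries are named `ne_1..ne_d` or `ne` (shared).
#' @param share_ne Fit one shared Ne for all demes (default `TRUE`).
#' @param restarts Random restarts (default 5).
#' @param n_sim_loci Loci per Monte-Carlo likelihood evaluation.
#' @param max_cycles Maximum coordinate cycles per start.
#' @param reltol Relative-change stopping rule (default 0.001).
#' @param elevations Optional deme elevations.
#' @return An object of class `afs_fit` with `par` (named vector), `ll`,
#'   `restarts` and the evaluation seed.
#' @export
fit_afs <- function(obs, label, samples, prior = prior_spec(),
                    fixed = list(), share_ne = TRUE, restarts = 5,
                    n_sim_loci = 1000, max_cycles = 6, reltol = 0.001,
                    elevations = NULL) {
  d <- length(samples)
  ne_names <- if (share_ne) "ne" else paste0("ne_", seq_len(d))
  par_names <- c("m", ne_names)
  lo <- setNames(c(prior$m_bounds[1], rep(prior$ne_bounds[1], length(ne_names))),
                 par_names)
  hi <- setNames(c(prior$m_bounds[2], rep(prior$ne_bounds[2], length(ne_names))),
                 par_names)
  eval_seed <- next_sim_seed()
  build <- function(par) {
    ne <- if (share_ne) rep(par[["ne"]], d) else unname(par[ne_names])
    demographic_model(label, ne, par[["m"]], elevations)
  }
  obj <- function(par) {
    ex <- expected_afs(build(par), samples, n_sim_loci, seed = eval_seed)
    composite_ll(obs, ex)
  }
  free <- setdiff(par_names, names(fixed))
  best <- NULL
  for (s in seq_len(restarts)) {
    par <- setNames((lo * hi)^0.5, par_names)       # log-midpoint
    par[free] <- exp(runif(length(free), log(lo[free]), log(hi[free])))
    for (nm in names(fixed)) par[nm] <- fixed[[nm]]
    ll <- obj(par)
    for (cycle in seq_len(max_cycles)) {
      old <- par
      for (nm in free) {
        f1 <- function(x) {
          p <- par; p[nm] <- exp(x)
          obj(p)
        }
        opt <- optimize(f1, lower = log(lo[nm]), upper = log(hi[nm]),
                        maximum = TRUE, tol = 0.02)
        if (opt$objective >= ll) {
          par[nm] <- exp(opt$maximum)
          ll <- opt$objective
        }
      }
      if (max(abs(par[free] - old[free]) / pmax(abs(old[free]), 1e-12)) < reltol)
        break
    }
    if (is.null(best) || ll > best$ll)
      best <- list(par = par, ll = ll, start = s)
  }
  structure(list(par = best$par, ll = best$ll, restarts = restarts,
                 label = label, samples = samples, share_ne = share_ne,
                 fixed = fixed, prior = prior, n_sim_loci = n_sim_loci,
                 eval_seed = eval_seed, elevations = elevations,
                 n_obs_loci = if (inherits(obs, "joint_afs")) obs$n_loci else NA),
            class = "afs_fit")
}

#' @export
print.afs_fit <- function(x, digits = 4, ...) {
  cat("Composite-likelihood AFS fit ('", x$label, "', ", x$restarts,
      " restarts)\n", sep = "")
  print(signif(x$par, digits))
  cat("log composite likelihood:", round(x$ll, 2), "\n")
  invisible(x)
}

#' Parametric bootstrap intervals for an AFS fit
#'
#' Simulates datasets at the point estimates, refits each and returns
#' 2.5-97.5 percentile intervals of the refitted parameters.
#'
#' @param fit An [fit_afs()] object.
#' @param n_boot Bootstrap replicates (default 100).
#' @param n_snps Loci per bootstrap dataset; defaults to the observed count.
#' @param restarts Restarts per refit (default 1; the truth-adjacent start
#'   makes more rarely worthwhile).
#' @return A data.frame with parameter, lower and upper columns, of class
#'   `afs_boot`.
#' @export
parametric_bootstrap <- function(fit, n_boot = 100, n_snps = NULL,
                                 restarts = 1) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  if (is.null(n_snps)) n_snps <- fit$n_obs_loci
  if (is.na(n_snps)) stop("supply n_snps (observed locus count unknown)")
  d <- length(fit$samples)
  ne <- if (fit$share_ne) rep(fit$par[["ne"]], d) else
    unname(fit$par[paste0("ne_", seq_len(d))])
  mod <- demographic_model(fit$label, ne, fit$par[["m"]], fit$elevations)
  boots <- matrix(NA_real_, n_boot, length(fit$par),
                  dimnames = list(NULL, names(fit$par)))
  for (b in seq_len(n_boot)) {
    sim <- simulate_dataset(mod, fit$samples, n_snps)
    afs <- minor_afs(sim$genotypes, sim$popmap)
    refit <- fit_afs(afs, fit$label, fit$samples, prior = fit$prior,
                     fixed = fit$fixed, share_ne = fit$share_ne,
                     restarts = restarts, n_sim_loci = fit$n_sim_loci,
                     elevations = fit$elevations)
    boots[b, ] <- refit$par
  }
  qs <- apply(boots, 2, quantile, probs = c(0.025, 0.975))
  structure(data.frame(parameter = colnames(boots),
                       lower = qs[1, ], upper = qs[2, ], row.names = NULL),
            class = c("afs_boot", "data.frame"), samples = boots)
}
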