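# Five spatial gene-flow models on an elevational gradient, and a structured
# coalescent SNP simulator.
#
# Demes are ordered from low to high elevation (deme 1 = lowest, deme d =
# highest). The scalar migration rate m is the per-edge forward rate: the
# proportion of a recipient deme replaced per generation by migrants from one
# donor. Forward topologies:
#   dn  each deme sends migrants to its adjacent lower deme
#   up  each deme sends migrants to its adjacent higher deme
#   ss  both adjacent neighbours (bidirectional stepping stone)
#   am  every other deme (island model)
#   sk  island model plus an extra unidirectional rate m from every other
#       deme into the top deme (source-sink; the top deme is the sink)
# Backward (lineage) rates are the forward edges reversed: a lineage sampled
# in the recipient moves to the donor at the forward rate.

GENE_FLOW_MODELS <- c("dn", "up", "ss", "am", "sk")

#' Build a migration matrix for a gene-flow model
#'
#' @param label One of `"dn"`, `"up"`, `"ss"`, `"am"`, `"sk"`.
#' @param d Number of demes (`>= 2`; `sk` needs `>= 3`).
#' @param m Per-edge migration rate (`> 0`).
#' @param backward If `TRUE` (default) return the backward-time lineage
#'   movement matrix (entry `[i, j]` = rate at which a lineage in deme i
#'   jumps to deme j); otherwise the forward gene-flow matrix (entry
#'   `[i, j]` = rate at which deme i sends migrants to deme j).
#' @return A `d x d` non-negative matrix with zero diagonal.
#' @export
build_migration_matrix <- function(label, d, m, backward = TRUE) {
  label <- match.arg(label, GENE_FLOW_MODELS)
  if (d < 2) stop("at least two demes required")
  if (label == "sk" && d < 3) stop("the source-sink model needs at least 3 demes")
  if (!(m > 0)) stop("migration rate must be positive")
  f <- matrix(0, d, d)
  if (label == "dn") {
    for (i in 2:d) f[i, i - 1] <- m
  } else if (label == "up") {
    for (i in 1:(d - 1)) f[i, i + 1] <- m
  } else if (label == "ss") {
    for (i in 1:(d - 1)) { f[i, i + 1] <- m; f[i + 1, i] <- m }
  } else if (label == "am") {
    f[] <- m; diag(f) <- 0
  } else if (label == "sk") {
    f[] <- m; diag(f) <- 0
    f[seq_len(d - 1), d] <- f[seq_len(d - 1), d] + m
  }
  if (backward) t(f) else f
}

#' Define a demographic model
#'
#' @param label Gene-flow model label (see [build_migration_matrix()]).
#' @param ne Per-deme diploid effective sizes, ordered low to high elevation.
#' @param m Per-edge migration rate.
#' @param elevations Optional deme elevations (m a.s.l.), low to high.
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(label, ne, m, elevations = NULL) {
  d <- length(ne)
  # a single deme is a plain panmictic coalescent (no migration)
  M <- if (d == 1) matrix(0, 1, 1) else build_migration_matrix(label, d, m)
  if (!is.null(elevations)) {
    stopifnot(length(elevations) == d)
    if (is.unsorted(elevations, strictly = TRUE))
      stop("deme elevations must be strictly increasing (low to high)")
  }
  # lineages must share a reachable deme, or the MRCA may never form
  reach <- (M > 0) | diag(d) > 0
  for (i in seq_len(d)) reach <- (reach %*% reach) > 0
  if (!any(colSums(reach) == d))
    stop("no deme is reachable by lineages from every other deme; ",
         "coalescence cannot complete")
  structure(list(label = label, d = d, ne = as.numeric(ne), m = m,
                 M = M, elevations = elevations),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Gene-flow model '", x$label, "': ", x$d, " demes, m = ", x$m,
      ", Ne = ", paste(round(x$ne), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Prior specification for (m, Ne)
#'
#' Migration rate is uniform; each deme's effective size is drawn
#' independently log-uniform.
#'
#' @param m_bounds Uniform bounds for m; default `c(0.001, 0.05)`.
#' @param ne_bounds Log-uniform bounds for Ne; default `c(200, 10000)`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(m_bounds = c(0.001, 0.05), ne_bounds = c(200, 10000)) {
  stopifnot(length(m_bounds) == 2, length(ne_bounds) == 2,
            all(m_bounds > 0), all(ne_bounds > 0),
            m_bounds[1] < m_bounds[2], ne_bounds[1] < ne_bounds[2])
  structure(list(m_bounds = m_bounds, ne_bounds = ne_bounds),
            class = "prior_spec")
}

#' Draw from the prior
#'
#' @param n Number of draws.
#' @param d Number of demes (one independent Ne per deme).
#' @param prior A [prior_spec()].
#' @return A list with vector `m` (length n) and matrix `ne` (n x d).
#' @export
sample_prior <- function(n, d, prior = prior_spec()) {
  m <- runif(n, prior$m_bounds[1], prior$m_bounds[2])
  ne <- matrix(exp(runif(n * d, log(prior$ne_bounds[1]),
                         log(prior$ne_bounds[2]))), nrow = n)
  list(m = m, ne = ne)
}

#' Simulate a SNP dataset under a demographic model
#'
#' Simulates a pool of independent genealogies under the structured
#' coalescent (pairwise coalescence rate 1/(2 Ne_i) within deme i,
#' per-lineage migration by the model's backward matrix) and places each
#' SNP's mutation uniformly at random on the pool's total branch length, so
#' a genealogy carries a SNP with probability proportional to its branch
#' length -- the low-mutation-rate limit of drawing segregating sites from
#' simulated sequences. Every locus is polymorphic in the pooled sample;
#' haplotypes are paired within demes into diploids.
#'
#' @param model A [demographic_model()].
#' @param samples Per-deme diploid sample sizes, low to high elevation.
#' @param n_snps Number of conditioned SNP loci.
#' @param seed Optional integer seed for the simulation stream; when `NULL`
#'   it is drawn from R's RNG (so `set.seed()` governs the result).
#' @param max_events Safety cap on coalescent events per locus.
#' @param pool_factor Genealogy pool size as a multiple of `n_snps`
#'   (default 1); larger pools make loci more nearly independent at
#'   proportional cost.
#' @return A list with `genotypes` (a [geno()] object) and `popmap`.
#' @export
simulate_dataset <- function(model, samples, n_snps, seed = NULL,
                             max_events = 1e8, pool_factor = 1) {
  stopifnot(inherits(model, "demographic_model"),
            length(samples) == model$d, n_snps >= 1)
  if (is.null(seed)) seed <- next_sim_seed()
  calls <- sim_snp_matrix_cpp(as.integer(samples), model$ne, model$M,
                              as.integer(n_snps), as.double(seed), max_events,
                              pool_factor)
  pops <- paste0("P", seq_len(model$d))
  sample_ids <- unlist(lapply(seq_len(model$d), function(i)
    paste0(pops[i], "_", seq_len(samples[i]))))
  rownames(calls) <- sample_ids
  colnames(calls) <- paste0("snp_", seq_len(n_snps))
  elev <- model$elevations %||% seq(1000, by = 500, length.out = model$d)
  pm <- data.frame(sample = sample_ids,
                   population = rep(pops, samples),
                   elevation_m = rep(elev, samples),
                   lat = rep(40, length(sample_ids)),
                   lon = rep(-105.2 - 0.0122 * (rep(elev, samples) - 1500) / 100,
                             length.out = length(sample_ids)))
  list(genotypes = geno(calls, chrom = rep("1", n_snps),
                        pos = seq_len(n_snps)),
       popmap = pm)
}

#' Summary-statistic vector for a simulated or observed dataset
#'
#' A fixed-order vector: pooled expected heterozygosity, pooled number of
#' segregating sites, per-population segregating sites, mean pairwise
#' haplotype differences within each population (unbiased), mean pairwise
#' haplotype differences per population pair, and pairwise Fst per pair.
#'
#' @param g A complete [geno()] object.
#' @param pm Population map (deme ordering follows its population order).
#' @return A named numeric vector.
#' @export
dataset_sumstats <- function(g, pm) {
  calls <- g$calls
  idx <- pop_indices(calls, pm)
  comp <- pop_components(calls, idx)
  pops <- names(idx)
  d <- length(idx)
  pooled_p <- colSums(comp$n * comp$p) / colSums(comp$n)
  het_total <- mean(2 * pooled_p * (1 - pooled_p))
  s_total <- sum(pooled_p > 0 & pooled_p < 1)
  s_pop <- rowSums(comp$p > 0 & comp$p < 1)
  nh <- 2 * comp$n                       # haploid sample sizes
  pi_w <- rowSums(2 * comp$p * (1 - comp$p) * nh / (nh - 1))
  out <- c(het_total = het_total, s_total = s_total,
           setNames(s_pop, paste0("s_", pops)),
           setNames(pi_w, paste0("piw_", pops)))
  if (d >= 2) {
    fst <- pairwise_fst_core(comp$n, comp$p, comp$ho)
    pi_pair <- c(); fst_pair <- c()
    for (j in seq_len(d - 1)) for (k in (j + 1):d) {
      pj <- comp$p[j, ]; pk <- comp$p[k, ]
      pi_pair[paste0("pi_", pops[j], "_", pops[k])] <-
        sum(pj * (1 - pk) + pk * (1 - pj))
      fst_pair[paste0("fst_", pops[j], "_", pops[k])] <- fst[j, k]
    }
    out <- c(out, pi_pair, fst_pair)
  }
  out
}
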