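# Nei-Chesser diversity and differentiation statistics for biallelic SNPs.
#
# Per-locus components follow the Nei & Chesser (1983) unbiased estimators:
# with r populations, per-population sample sizes n_k (diploids), allele
# frequencies p_k, observed heterozygosities h_k, harmonic mean sample size
# nh and Ho = mean(h_k):
#   Hs = nh/(nh-1) * (1 - mean_k(p_k^2 + q_k^2) - Ho/(2 nh))
#   Ht = 1 - (pbar^2 + qbar^2) + Hs/(r nh) - Ho/(2 r nh),  pbar = mean(p_k)
# Multilocus statistics average the components across loci first and then
# form ratios (ratio-of-averages convention).

pop_indices <- function(calls, pm) {
  if (!all(rownames(calls) %in% pm$sample))
    stop("population map does not cover all samples")
  pop <- pm$population[match(rownames(calls), pm$sample)]
  split(seq_len(nrow(calls)), factor(pop, levels = unique(pop)))
}

# per-population per-locus components; complete or missing-tolerant
pop_components <- function(calls, idx) {
  r <- length(idx)
  nl <- ncol(calls)
  n <- p <- ho <- matrix(NA_real_, nrow = r, ncol = nl,
                         dimnames = list(names(idx), colnames(calls)))
  for (k in seq_len(r)) {
    sub <- calls[idx[[k]], , drop = FALSE]
    nk <- colSums(!is.na(sub))
    if (any(nk == 0)) {
      j <- which(nk == 0)[1]
      stop("population ", names(idx)[k], " has no genotyped sample at locus ",
           colnames(calls)[j] %||% j)
    }
    n[k, ] <- nk
    p[k, ] <- colSums(sub, na.rm = TRUE) / (2 * nk)
    ho[k, ] <- colSums(sub == 1L, na.rm = TRUE) / nk
  }
  list(n = n, p = p, ho = ho)
}

#' Per-locus diversity components
#'
#' Computes, for every locus, per-population sample sizes, alternate-allele
#' frequencies, observed heterozygosity and plain expected heterozygosity
#' (2pq), together with the pooled Nei-Chesser components Ho, Hs and Ht and
#' the pooled minor-allele frequency.
#'
#' @param g A [geno()] object.
#' @param pm Population map covering all samples.
#' @return An object of class `locus_stats`: a list with matrices `n`, `p`,
#'   `ho`, `he` (populations x loci) and vectors `maf`, `Ho`, `Hs`, `Ht`.
#' @export
locus_stats <- function(g, pm) {
  calls <- g$calls
  idx <- pop_indices(calls, pm)
  comp <- pop_components(calls, idx)
  r <- length(idx)
  nh <- r / colSums(1 / comp$n)                     # harmonic mean sample size
  Ho <- colMeans(comp$ho)
  hom <- colMeans(comp$p^2 + (1 - comp$p)^2)        # mean_k (p^2 + q^2)
  Hs <- nh / (nh - 1) * (1 - hom - Ho / (2 * nh))
  pbar <- colMeans(comp$p)
  Ht <- 1 - (pbar^2 + (1 - pbar)^2) + Hs / (r * nh) - Ho / (2 * r * nh)
  pooled_p <- colSums(comp$n * comp$p) / colSums(comp$n)
  structure(list(pops = names(idx), n = comp$n, p = comp$p, ho = comp$ho,
                 he = 2 * comp$p * (1 - comp$p),
                 maf = pmin(pooled_p, 1 - pooled_p),
                 Ho = Ho, Hs = Hs, Ht = Ht),
            class = "locus_stats")
}

#' @export
print.locus_stats <- function(x, ...) {
  cat("Per-locus diversity components:", length(x$Ho), "loci,",
      length(x$pops), "populations\n")
  invisible(x)
}

#' Multilocus diversity and differentiation statistics
#'
#' Averages the per-locus components across loci and derives Fis, Fst and
#' Jost's D by the ratio-of-averages convention, plus per-population means of
#' Ho, He (2pq), Hs and Fis.
#'
#' @param ls A [locus_stats()] object.
#' @return An object of class `overall_stats`.
#' @export
overall_stats <- function(ls) {
  r <- length(ls$pops)
  Ho <- mean(ls$Ho); Hs <- mean(ls$Hs); Ht <- mean(ls$Ht)
  if (r >= 2) {
    Fst <- (Ht - Hs) / Ht
    Dest <- (r / (r - 1)) * (Ht - Hs) / (1 - Hs)
  } else {
    Fst <- NA_real_; Dest <- NA_real_
  }
  # per-population unbiased within-population gene diversity
  hs_k <- ls$n / (ls$n - 1) * (ls$he - ls$ho / (2 * ls$n))
  per_pop <- data.frame(population = ls$pops,
                        Ho = rowMeans(ls$ho),
                        He = rowMeans(ls$he),
                        Hs = rowMeans(hs_k),
                        Fis = 1 - rowMeans(ls$ho) / rowMeans(hs_k),
                        row.names = NULL)
  structure(list(n_loci = length(ls$Ho), n_pops = r, maf = mean(ls$maf),
                 Ho = Ho, Hs = Hs, Ht = Ht,
                 Fis = 1 - Ho / Hs, Fst = Fst, Dest = Dest,
                 per_population = per_pop),
            class = "overall_stats")
}

#' @export
print.overall_stats <- function(x, digits = 4, ...) {
  cat("Multilocus statistics over", x$n_loci, "loci,", x$n_pops, "populations\n")
  v <- c(MAF = x$maf, Ho = x$Ho, Hs = x$Hs, Ht = x$Ht,
         Fis = x$Fis, Fst = x$Fst, Dest = x$Dest)
  print(round(v, digits))
  cat("Per population:\n")
  print(cbind(x$per_population[1],
              round(x$per_population[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.overall_stats <- function(x, ...) {
  data.frame(n_loci = x$n_loci, n_pops = x$n_pops, maf = x$maf, Ho = x$Ho,
             Hs = x$Hs, Ht = x$Ht, Fis = x$Fis, Fst = x$Fst, Dest = x$Dest)
}

# fast pairwise Fst core from per-pop component matrices (r = 2 formulas)
pairwise_fst_core <- function(n, p, ho) {
  r <- nrow(p)
  out <- matrix(0, r, r, dimnames = list(rownames(p), rownames(p)))
  for (j in seq_len(r - 1)) for (k in (j + 1):r) {
    nh <- 2 / (1 / n[j, ] + 1 / n[k, ])
    Ho <- (ho[j, ] + ho[k, ]) / 2
    hom <- (p[j, ]^2 + (1 - p[j, ])^2 + p[k, ]^2 + (1 - p[k, ])^2) / 2
    Hs <- nh / (nh - 1) * (1 - hom - Ho / (2 * nh))
    pbar <- (p[j, ] + p[k, ]) / 2
    Ht <- 1 - (pbar^2 + (1 - pbar)^2) + Hs / (2 * nh) - Ho / (4 * nh)
    out[j, k] <- out[k, j] <- (mean(Ht) - mean(Hs)) / mean(Ht)
  }
  out
}

#' Pairwise Fst matrix
#'
#' For every population pair the Nei-Chesser locus components are recomputed
#' with r = 2 restricted to that pair and combined by ratio of averages.
#'
#' @param g A [geno()] object.
#' @param pm Population map.
#' @return An object of class `pairwise_fst`: list with the symmetric `fst`
#'   matrix and its Latter-linearized companion `linearized`
#'   (`f / (1 - f)`).
#' @export
pairwise_fst <- function(g, pm) {
  calls <- g$calls
  idx <- pop_indices(calls, pm)
  if (length(idx) < 2) stop("pairwise Fst needs at least two populations")
  comp <- pop_components(calls, idx)
  fst <- pairwise_fst_core(comp$n, comp$p, comp$ho)
  lin <- fst
  off <- row(fst) != col(fst)
  lin[off] <- linearize_fst(fst[off])
  structure(list(fst = fst, linearized = lin), class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, digits = 4, ...) {
  cat("Pairwise Fst:\n")
  print(round(x$fst, digits))
  invisible(x)
}

#' Latter's linearization of a differentiation value
#'
#' @param f Fst value(s), each `< 1`.
#' @return `f / (1 - f)`, elementwise.
#' @export
linearize_fst <- function(f) {
  if (any(f >= 1)) stop("linearization undefined for f >= 1")
  f / (1 - f)
}

#' Write per-population diversity statistics to CSV
#'
#' Emits one species-level row followed by per-population rows, mirroring a
#' diversity summary table.
#'
#' @param os An [overall_stats()] object.
#' @param path Output CSV path.
#' @export
write_diversity_csv <- function(os, path) {
  top <- data.frame(population = "overall", Ho = os$Ho, He = NA_real_,
                    Hs = os$Hs, Fis = os$Fis)
  extra <- data.frame(population = c("overall", os$per_population$population),
                      rbind(top[-1], os$per_population[-1]),
                      maf = c(os$maf, rep(NA_real_, nrow(os$per_population))),
                      Ht = c(os$Ht, rep(NA_real_, nrow(os$per_population))),
                      Fst = c(os$Fst, rep(NA_real_, nrow(os$per_population))),
                      Dest = c(os$Dest, rep(NA_real_, nrow(os$per_population))))
  write.csv(extra, path, row.names = FALSE)
  invisible(path)
}

#' Write a pairwise Fst matrix to CSV
#' @param pf A [pairwise_fst()] object.
#' @param path Output CSV path.
#' @param linearized Write the linearized matrix instead of Fst.
#' @export
write_pairwise_csv <- function(pf, path, linearized = FALSE) {
  write.csv(if (linearized) pf$linearized else pf$fst, path)
  invisible(path)
}
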