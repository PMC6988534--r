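# Shared fixtures built in code.

# random genotype matrix with optional missingness
random_geno <- function(n_samples, n_loci, miss = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  calls <- matrix(sample(0:2, n_samples * n_loci, replace = TRUE),
                  nrow = n_samples)
  if (miss > 0)
    calls[runif(length(calls)) < miss] <- NA
  rownames(calls) <- paste0("s", seq_len(n_samples))
  geno(calls)
}

# population map assigning samples round-robin elevations
make_popmap <- function(sample_ids, pops, elevations = NULL) {
  stopifnot(length(sample_ids) == length(pops))
  upops <- unique(pops)
  if (is.null(elevations)) elevations <- seq(1500, by = 400,
                                             length.out = length(upops))
  data.frame(sample = sample_ids, population = pops,
             elevation_m = elevations[match(pops, upops)],
             lat = 40 + 0.01 * match(pops, upops),
             lon = -105.3 - 0.05 * match(pops, upops))
}

# write a small VCF from genotype strings (loci x samples)
write_test_vcf <- function(path, gt, chrom = NULL, pos = NULL,
                           alt = NULL, samples = NULL) {
  n_loci <- nrow(gt); n_s <- ncol(gt)
  if (is.null(samples)) samples <- paste0("s", seq_len(n_s))
  if (is.null(chrom)) chrom <- rep("1", n_loci)
  if (is.null(pos)) pos <- seq_len(n_loci)
  if (is.null(alt)) alt <- rep("T", n_loci)
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_len(n_loci))
    lines <- c(lines, paste(c(chrom[i], pos[i], ".", "A", alt[i], ".",
                              "PASS", ".", "GT", gt[i, ]), collapse = "\t"))
  writeLines(lines, path)
  path
}

# brute-force Nei-Chesser transliteration, one locus at a time (independent
# oracle for the vectorized implementation)
naive_locus_stats <- function(calls, pop) {
  pops <- unique(pop)
  r <- length(pops)
  out <- data.frame(Ho = numeric(ncol(calls)), Hs = NA_real_, Ht = NA_real_)
  for (l in seq_len(ncol(calls))) {
    n <- p <- h <- numeric(r)
    for (k in seq_len(r)) {
      gk <- calls[pop == pops[k], l]
      gk <- gk[!is.na(gk)]
      n[k] <- length(gk)
      p[k] <- sum(gk) / (2 * length(gk))
      h[k] <- mean(gk == 1)
    }
    nh <- 1 / mean(1 / n)
    Ho <- mean(h)
    Hs <- nh / (nh - 1) * (1 - mean(p^2 + (1 - p)^2) - Ho / (2 * nh))
    pb <- mean(p)
    Ht <- 1 - (pb^2 + (1 - pb)^2) + Hs / (r * nh) - Ho / (2 * r * nh)
    out$Ho[l] <- Ho; out$Hs[l] <- Hs; out$Ht[l] <- Ht
  }
  out
}

# small single-model reference table with Gaussian statistics (cheap
# substrate for calibration checks of the ABC machinery itself)
gaussian_table <- function(n_rows, n_stats = 6, model = "ss") {
  stats <- matrix(rnorm(n_rows * n_stats), n_rows)
  colnames(stats) <- paste0("ss_g", seq_len(n_stats))
  tab <- data.frame(model = model, m = runif(n_rows, 0.001, 0.05),
                    ne_1 = exp(runif(n_rows, log(200), log(10000))), stats)
  class(tab) <- c("abc_reftable", "data.frame")
  attr(tab, "prior") <- prior_spec()
  sm <- as.matrix(tab[grep("^ss_", names(tab))])
  attr(tab, "ss_center") <- apply(sm, 2, median)
  attr(tab, "ss_scale") <- apply(sm, 2, mad)
  tab
}
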