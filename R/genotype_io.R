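# Genotype containers and VCF / population-map input-output.
#
# Genotypes are stored as an integer matrix of alternate-allele dosages
# (0, 1, 2; NA = missing) with samples in rows and loci in columns, plus the
# locus coordinates needed to round-trip a VCF.

#' Construct a genotype matrix object
#'
#' @param calls Integer matrix, samples x loci; entries 0, 1, 2 (alternate
#'   allele dosage) or `NA` for a missing call.
#' @param chrom,pos Optional per-locus chromosome and position (recycled /
#'   defaulted when absent).
#' @param ref,alt Optional per-locus reference and alternate alleles.
#' @return An object of class `geno`.
#' @export
geno <- function(calls, chrom = NULL, pos = NULL, ref = NULL, alt = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    rownames(calls) <- paste0("sample_", seq_len(nrow(calls)))
  if (is.null(colnames(calls)) && ncol(calls) > 0)
    colnames(calls) <- paste0("locus_", seq_len(ncol(calls)))
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad))
    stop("genotype calls must be 0, 1, 2 or NA")
  nl <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", nl)
  if (is.null(pos)) pos <- seq_len(nl)
  if (is.null(ref)) ref <- rep("A", nl)
  if (is.null(alt)) alt <- rep("T", nl)
  stopifnot(length(chrom) == nl, length(pos) == nl,
            length(ref) == nl, length(alt) == nl)
  structure(list(calls = calls, chrom = as.character(chrom),
                 pos = as.integer(pos), ref = as.character(ref),
                 alt = as.character(alt)),
            class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$calls), "samples x", ncol(x$calls), "loci;",
      sum(is.na(x$calls)), "missing calls\n")
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$calls)

# keep coordinate metadata aligned when subsetting loci
subset_loci <- function(g, keep) {
  geno(g$calls[, keep, drop = FALSE], g$chrom[keep], g$pos[keep],
       g$ref[keep], g$alt[keep])
}

#' Read a population map
#'
#' A population map is a five-column TSV: sample, population, elevation_m,
#' lat, lon.
#'
#' @param path File path.
#' @return A data.frame with those five columns.
#' @export
load_popmap <- function(path) {
  pm <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "population", "elevation_m", "lat", "lon")
  if (!all(need %in% names(pm)))
    stop("population map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(pm$sample))
    stop("duplicated sample ids in population map")
  pm
}

#' Write a population map
#' @param pm Population map data.frame.
#' @param path File path.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(pm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load genotypes from a VCF plus a population map
#'
#' Reads a VCF v4.2 (GT field only; phase is ignored) and encodes each call
#' as the dosage of the record's alternate allele. Multi-allelic records are
#' rejected, and every VCF sample must appear in the population map.
#'
#' @param vcf_path Path to a VCF file.
#' @param popmap_path Path to the population-map TSV (see [load_popmap()]).
#' @return A list with elements `genotypes` (a [geno()] object, sample order
#'   following the VCF header) and `popmap`.
#' @export
load_genotypes <- function(vcf_path, popmap_path) {
  pm <- load_popmap(popmap_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_loci <- nrow(v@gt) %||% 0L
  samples <- colnames(v@gt)[-1]
  missing_pm <- setdiff(samples, pm$sample)
  if (length(missing_pm))
    stop("sample(s) in VCF but absent from population map: ",
         paste(missing_pm, collapse = ", "))
  if (n_loci == 0L) {
    g <- geno(matrix(integer(0), nrow = length(samples), ncol = 0,
                     dimnames = list(samples, NULL)),
              chrom = character(0), pos = integer(0),
              ref = character(0), alt = character(0))
    return(list(genotypes = g, popmap = pm))
  }
  alt <- fix[, "ALT"]
  multi <- is.na(alt) | alt == "." | grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1]
    stop("non-biallelic record at ", fix[i, "CHROM"], ":", fix[i, "POS"])
  }
  gt <- vcfR::extract.gt(v, element = "GT")   # loci x samples, strings
  dos <- gt_to_dosage(gt)
  calls <- t(dos)
  rownames(calls) <- samples
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  colnames(calls) <- ids
  g <- geno(calls, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
            ref = fix[, "REF"], alt = alt)
  list(genotypes = g, popmap = pm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "0/1", "1|0", "./." ... -> dosage of allele 1; any allele code > 1 errors
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  map <- vapply(u, function(s) {
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a) || any(a > 1L) || length(a) != 2L)
      stop("unsupported genotype string: ", s)
    sum(a)
  }, integer(1))
  out <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt))
  dimnames(out) <- dimnames(gt)
  out
}

#' Write genotypes to a VCF
#'
#' Emits a minimal VCF v4.2 with GT-only genotype fields, the inverse of
#' [load_genotypes()].
#'
#' @param g A [geno()] object.
#' @param path Output file path.
#' @export
write_genotypes <- function(g, path) {
  calls <- g$calls
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=elevflow",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(calls)), collapse = "\t")),
             con)
  if (ncol(calls)) {
    code <- c("0/0", "0/1", "1/1")
    gtxt <- matrix("./.", nrow = nrow(calls), ncol = ncol(calls))
    ok <- !is.na(calls)
    gtxt[ok] <- code[calls[ok] + 1L]
    lines <- vapply(seq_len(ncol(calls)), function(j) {
      paste(c(g$chrom[j], g$pos[j], colnames(calls)[j], g$ref[j], g$alt[j],
              ".", "PASS", ".", "GT", gtxt[, j]), collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Filter loci on overall minor allele frequency
#'
#' The minor allele frequency is computed over all samples pooled, excluding
#' missing calls from the denominators; loci with MAF strictly below the
#' threshold are removed.
#'
#' @param g A [geno()] object.
#' @param threshold MAF cut-off in `[0, 0.5]`; default 0.02.
#' @return A [geno()] object with the retained loci.
#' @export
filter_maf <- function(g, threshold = 0.02) {
  if (threshold < 0 || threshold > 0.5)
    stop("MAF threshold must be in [0, 0.5]")
  maf <- overall_maf(g$calls)
  subset_loci(g, which(maf >= threshold))
}

overall_maf <- function(calls) {
  n_called <- colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0] <- NA_real_
  pmin(p, 1 - p)
}

#' Impute missing genotypes from within-population Hardy-Weinberg frequencies
#'
#' Each missing call is replaced by the genotype with maximal Hardy-Weinberg
#' probability given its population's allele frequency at the locus, provided
#' that probability reaches the confidence threshold; loci where any missing
#' call cannot be resolved that confidently (or where a population has no
#' non-missing call) are dropped, so the returned matrix is complete.
#'
#' @param g A [geno()] object.
#' @param pm Population map covering all samples of `g`.
#' @param confidence Minimum genotype probability required to impute;
#'   default 0.70.
#' @return A complete (no-missing) [geno()] object.
#' @export
impute_missing <- function(g, pm, confidence = 0.70) {
  calls <- g$calls
  if (!all(rownames(calls) %in% pm$sample))
    stop("population map does not cover all samples")
  if (!anyNA(calls)) return(g)
  pop <- pm$population[match(rownames(calls), pm$sample)]
  drop <- rep(FALSE, ncol(calls))
  for (pp in unique(pop)) {
    rows <- which(pop == pp)
    sub <- calls[rows, , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    drop <- drop | (n_called == 0)
    p <- colSums(sub, na.rm = TRUE) / (2 * pmax(n_called, 1L))
    miss <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(miss)) {
      pj <- p[miss[, 2]]
      probs <- cbind((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
      best <- max.col(probs, ties.method = "first")
      ok <- probs[cbind(seq_len(nrow(probs)), best)] >= confidence
      sub[miss[ok, , drop = FALSE]] <- (best - 1L)[ok]
      drop[unique(miss[!ok, 2])] <- TRUE
      calls[rows, ] <- sub
    }
  }
  keep <- which(!drop)
  out <- subset_loci(geno(calls, g$chrom, g$pos, g$ref, g$alt), keep)
  stopifnot(!anyNA(out$calls))
  out
}
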