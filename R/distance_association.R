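# Distance matrices among populations and Mantel permutation tests of
# trait-predictor association.

#' Build a population distance matrix
#'
#' Kinds: `"geography"` (Euclidean distance on locally projected
#' coordinates, km, longitude scaled by cos of the mean latitude),
#' `"elevation"` (absolute elevation difference, m), `"environment"`
#' (Euclidean on z-scored site variables, by default mean annual temperature
#' and season length), `"phenotype"` (Euclidean on z-scored trait-category
#' variables) and `"genetic"` (linearized pairwise Fst passed through).
#'
#' @param pm Population map (one row per sample or per population).
#' @param kind One of the kinds above.
#' @param env Site table with columns `population`, and the environment
#'   variables (for `kind = "environment"`).
#' @param env_vars Environment variable names; default
#'   `c("mat_c", "season_days")`.
#' @param traits Trait table (population column plus variables) for
#'   `kind = "phenotype"`.
#' @param trait_vars Trait variable names for the category.
#' @param fst Linearized pairwise Fst matrix for `kind = "genetic"`.
#' @return An object of class `dist_matrix`: symmetric matrix with zero
#'   diagonal, with a `kind` attribute.
#' @export
build_distances <- function(pm, kind = c("geography", "elevation",
                                         "environment", "phenotype",
                                         "genetic"),
                            env = NULL, env_vars = c("mat_c", "season_days"),
                            traits = NULL, trait_vars = NULL, fst = NULL) {
  kind <- match.arg(kind)
  pops <- pop_table(pm)
  if (nrow(pops) < 2) stop("at least two populations required")
  m <- switch(kind,
    geography = {
      lat0 <- mean(pops$lat)
      x <- pops$lon * 111.320 * cos(lat0 * pi / 180)
      y <- pops$lat * 110.574
      as.matrix(dist(cbind(x, y)))
    },
    elevation = as.matrix(dist(pops$elevation_m)),
    environment = {
      if (is.null(env)) stop("environment distances need a site table")
      rows <- match(pops$population, env$population)
      if (anyNA(rows)) stop("site table missing population(s): ",
                            paste(pops$population[is.na(rows)], collapse = ", "))
      as.matrix(dist(scale(as.matrix(env[rows, env_vars]))))
    },
    phenotype = {
      if (is.null(traits)) stop("phenotype distances need a trait table")
      if (is.null(trait_vars))
        trait_vars <- setdiff(names(traits), "population")
      rows <- match(pops$population, traits$population)
      v <- as.matrix(traits[rows, trait_vars, drop = FALSE])
      if (anyNA(v)) stop("trait table incomplete for requested populations")
      as.matrix(dist(scale(v)))
    },
    genetic = {
      if (is.null(fst)) stop("genetic distances need a linearized Fst matrix")
      fst <- as.matrix(fst)
      fst[pops$population, pops$population]
    })
  dimnames(m) <- list(pops$population, pops$population)
  diag(m) <- 0
  structure(m, kind = kind, class = c("dist_matrix", class(m)))
}

pop_table <- function(pm) {
  if (!"population" %in% names(pm)) stop("needs a population column")
  agg <- pm[!duplicated(pm$population), , drop = FALSE]
  agg <- agg[order(agg$elevation_m), , drop = FALSE]
  if ("sample" %in% names(pm)) {
    # per-population means of coordinates/elevation over samples
    for (v in intersect(c("elevation_m", "lat", "lon"), names(pm)))
      agg[[v]] <- tapply(pm[[v]], pm$population, mean)[agg$population]
  }
  rownames(agg) <- NULL
  agg
}

#' Mantel permutation test
#'
#' Pearson correlation of the lower-triangle vectors of two distance
#' matrices, with significance from joint row/column permutations of the
#' second matrix (one-sided, upper tail, with the +1 correction).
#'
#' @param d1,d2 Symmetric distance matrices with matching labels.
#' @param n_perm Number of sampled permutations (default 999).
#' @return An object of class `mantel_result` with `r`, `p` and `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("distance matrices have different population sets")
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  n <- nrow(d1)
  if (n < 3) stop("Mantel test needs at least three populations")
  lower <- lower.tri(d1)
  v1 <- d1[lower]
  if (sd(v1) == 0 || sd(d2[lower]) == 0)
    stop("constant distance matrix; Mantel r undefined")
  r_obs <- stats::cor(v1, d2[lower])
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    stats::cor(v1, d2[idx, idx][lower])
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  structure(list(r = r_obs, p = p, n_perm = n_perm), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel: r =", round(x$r, 4), ", one-sided p =", signif(x$p, 3),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Trait-predictor Mantel association grid
#'
#' One Mantel test per trait category x predictor matrix. A category is
#' testable only when at least three populations have complete values;
#' otherwise its row is reported as `NA`.
#'
#' @param traits Trait table: `population` column plus trait variables.
#' @param categories Named list mapping category name to variable names.
#' @param predictors Named list of predictor distance matrices.
#' @param pm Population map (for the population set).
#' @param n_perm Permutations per test.
#' @return A data.frame with category, predictor, r, p and n_pops.
#' @export
trait_association_suite <- function(traits, categories, predictors, pm,
                                    n_perm = 999) {
  out <- list()
  for (cat_name in names(categories)) {
    vars <- intersect(categories[[cat_name]], names(traits))
    complete <- traits[complete.cases(traits[vars]), c("population", vars)]
    testable <- length(vars) > 0 && nrow(complete) >= 3
    for (pred_name in names(predictors)) {
      if (!testable) {
        out[[length(out) + 1]] <- data.frame(category = cat_name,
                                             predictor = pred_name,
                                             r = NA_real_, p = NA_real_,
                                             n_pops = nrow(complete))
        next
      }
      pd <- as.matrix(predictors[[pred_name]])
      pops <- intersect(complete$population, rownames(pd))
      if (length(pops) < 3) {
        out[[length(out) + 1]] <- data.frame(category = cat_name,
                                             predictor = pred_name,
                                             r = NA_real_, p = NA_real_,
                                             n_pops = length(pops))
        next
      }
      td <- as.matrix(dist(scale(as.matrix(
        complete[match(pops, complete$population), vars, drop = FALSE]))))
      dimnames(td) <- list(pops, pops)
      mt <- mantel_test(td, pd[pops, pops], n_perm = n_perm)
      out[[length(out) + 1]] <- data.frame(category = cat_name,
                                           predictor = pred_name,
                                           r = mt$r, p = mt$p,
                                           n_pops = length(pops))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
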