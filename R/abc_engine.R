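# Approximate Bayesian computation over the spatial gene-flow models:
# reference-table construction, rejection and multinomial-logistic model
# posteriors, leave-one-out cross-validation, gfit-style goodness of fit and
# local-linear parameter estimation.

#' Build an ABC reference table
#'
#' For each model, draws (m, Ne) from the prior, simulates a SNP dataset and
#' records its summary-statistic vector. Standardization constants (per-stat
#' median and MAD over the pooled table) are stored as attributes.
#'
#' @param models Character vector of model labels.
#' @param n_per_model Simulations per model.
#' @param samples Per-deme diploid sample sizes (shared by all models).
#' @param n_snps Conditioned SNPs per simulated dataset.
#' @param prior A [prior_spec()].
#' @param elevations Optional deme elevations.
#' @param progress Print a line per model when `TRUE`.
#' @return A data.frame of class `abc_reftable` with columns `model`, `m`,
#'   `ne_1..ne_d` and the `ss_*` summary statistics.
#' @export
build_reference_table <- function(models, n_per_model, samples, n_snps,
                                  prior = prior_spec(), elevations = NULL,
                                  progress = FALSE) {
  models <- match.arg(models, GENE_FLOW_MODELS, several.ok = TRUE)
  d <- length(samples)
  rows <- vector("list", length(models))
  for (mi in seq_along(models)) {
    lab <- models[mi]
    draws <- sample_prior(n_per_model, d, prior)
    stat_list <- vector("list", n_per_model)
    for (i in seq_len(n_per_model)) {
      mod <- demographic_model(lab, draws$ne[i, ], draws$m[i], elevations)
      sim <- simulate_dataset(mod, samples, n_snps)
      stat_list[[i]] <- dataset_sumstats(sim$genotypes, sim$popmap)
    }
    stats <- do.call(rbind, stat_list)
    colnames(stats) <- paste0("ss_", colnames(stats))
    ne <- draws$ne
    colnames(ne) <- paste0("ne_", seq_len(d))
    rows[[mi]] <- data.frame(model = lab, m = draws$m, ne, stats)
    if (progress) cat("model", lab, ":", n_per_model, "simulations\n")
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("abc_reftable", "data.frame")
  attr(tab, "samples") <- samples
  attr(tab, "n_snps") <- n_snps
  attr(tab, "prior") <- prior
  attr(tab, "elevations") <- elevations
  sm <- as.matrix(tab[grep("^ss_", names(tab))])
  attr(tab, "ss_center") <- apply(sm, 2, median)
  attr(tab, "ss_scale") <- apply(sm, 2, mad)
  tab
}

stat_cols <- function(table) grep("^ss_", names(table), value = TRUE)

param_cols <- function(table) {
  c("m", grep("^ne_", names(table), value = TRUE))
}

# median/MAD standardization shared by all ABC operations; zero-MAD
# statistics carry no distance information and are dropped with a warning
standardize_stats <- function(table, obs = NULL) {
  sc <- stat_cols(table)
  center <- attr(table, "ss_center")
  scale <- attr(table, "ss_scale")
  if (is.null(center) || is.null(scale)) {
    sm <- as.matrix(table[sc])
    center <- apply(sm, 2, median)
    scale <- apply(sm, 2, mad)
  }
  keep <- scale > 0
  if (!all(keep))
    warning("dropping zero-MAD statistic(s) from the distance: ",
            paste(sc[!keep], collapse = ", "))
  Z <- sweep(sweep(as.matrix(table[sc])[, keep, drop = FALSE], 2,
                   center[keep]), 2, scale[keep], "/")
  zo <- NULL
  if (!is.null(obs)) {
    ov <- as_stat_vector(obs, sc)
    if (any(!is.finite(ov))) stop("non-finite observed summary statistic")
    zo <- (ov[keep] - center[keep]) / scale[keep]
  }
  list(Z = Z, z_obs = zo, keep = keep)
}

as_stat_vector <- function(obs, sc) {
  if (is.list(obs) && !is.null(obs$genotypes))
    stop("pass dataset_sumstats() output, not a dataset")
  v <- unlist(obs)
  names(v) <- sub("^ss_", "", names(v))
  want <- sub("^ss_", "", sc)
  if (!all(want %in% names(v))) {
    if (length(v) == length(sc)) names(v) <- want
    else stop("observed statistics do not match the table's layout")
  }
  v[want]
}

accept_rows <- function(dist2, tol) {
  if (!(tol > 0 && tol <= 1)) stop("tolerance must be in (0, 1]")
  n_acc <- ceiling(tol * length(dist2))
  # break boundary ties by table order after a seeded shuffle
  ord <- order(dist2, sample.int(length(dist2)))
  ord[seq_len(n_acc)]
}

#' ABC rejection step and model posterior
#'
#' Accepts the `ceiling(tol * nrow)` reference rows nearest to the observed
#' statistics in Euclidean distance on median/MAD-standardized statistics;
#' each model's rejection posterior probability is its share of the accepted
#' rows.
#'
#' @param obs Observed summary-statistic vector ([dataset_sumstats()]).
#' @param table An [build_reference_table()] table.
#' @param tol Acceptance fraction in `(0, 1]`.
#' @return An object of class `abc_posterior` with elements `prob`,
#'   `accepted` (row indices), `distance` (accepted distances) and `method`.
#' @export
abc_reject <- function(obs, table, tol) {
  st <- standardize_stats(table, obs)
  d2 <- colSums((t(st$Z) - st$z_obs)^2)
  acc <- accept_rows(d2, tol)
  models <- unique(table$model)
  prob <- prop.table(base::table(factor(table$model[acc], levels = models)))
  structure(list(prob = c(prob), accepted = acc, distance = sqrt(d2[acc]),
                 method = "rejection", tol = tol,
                 untestable = character(0)),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, digits = 4, ...) {
  cat("ABC model posterior (", x$method, ", tol = ", x$tol, ")\n", sep = "")
  print(round(x$prob, digits))
  if (length(x$untestable))
    cat("absent from the accepted set (probability 0):",
        paste(x$untestable, collapse = ", "), "\n")
  invisible(x)
}

#' Bayes factors from a model posterior
#'
#' Posterior-odds ratios under equal model priors.
#'
#' @param post An `abc_posterior`.
#' @return A matrix of pairwise Bayes factors `BF[i, j] = P(i) / P(j)`.
#' @export
bayes_factors <- function(post) {
  outer(post$prob, post$prob, "/")
}

#' Regression (soft-max) model posterior
#'
#' Fits a distance-weighted multinomial logistic classifier of model label on
#' the standardized statistics over the accepted rows (Epanechnikov weights)
#' and evaluates it at the observed statistics. Models absent from the
#' accepted set are reported with probability 0 and flagged.
#'
#' @inheritParams abc_reject
#' @param maxit Maximum optimizer iterations for the classifier.
#' @return An `abc_posterior` with `method = "mnlogistic"`.
#' @export
regression_model_probs <- function(obs, table, tol, maxit = 200) {
  st <- standardize_stats(table, obs)
  d2 <- colSums((t(st$Z) - st$z_obs)^2)
  acc <- accept_rows(d2, tol)
  models <- unique(table$model)
  lab <- factor(table$model[acc], levels = models)
  present <- levels(droplevels(lab))
  prob <- setNames(numeric(length(models)), models)
  if (length(present) < 2) {
    prob[present] <- 1
  } else {
    dmax <- max(sqrt(d2[acc]))
    w <- if (dmax > 0) 1 - (sqrt(d2[acc]) / dmax)^2 else rep(1, length(acc))
    w[w <= 0] <- min(w[w > 0], 1e-8)
    df <- data.frame(.model = droplevels(lab), st$Z[acc, , drop = FALSE])
    fit <- nnet::multinom(.model ~ ., data = df, weights = w,
                          trace = FALSE, maxit = maxit, MaxNWts = 10000)
    newd <- as.data.frame(t(st$z_obs))
    colnames(newd) <- colnames(st$Z)
    p <- predict(fit, newdata = newd, type = "probs")
    if (length(p) == 1) { # two-class fit returns P(second level) only
      p <- c(1 - p, p)
      names(p) <- present
    }
    prob[names(p)] <- p
  }
  structure(list(prob = prob / sum(prob), accepted = acc,
                 distance = sqrt(d2[acc]), method = "mnlogistic", tol = tol,
                 untestable = setdiff(models, present)),
            class = "abc_posterior")
}

#' Leave-one-out cross-validation of ABC model selection
#'
#' Holds out `n_cv` reference rows per model as pseudo-observed datasets and
#' classifies each against the table without itself.
#'
#' @param table Reference table.
#' @param n_cv Pseudo-observations per model (default 100).
#' @param tol Acceptance fraction.
#' @param method `"rejection"` or `"mnlogistic"`.
#' @return An object of class `abc_cv`: confusion matrix (rows = true
#'   model), per-model and mean correct-assignment proportions.
#' @export
cross_validate <- function(table, n_cv = 100, tol,
                           method = c("rejection", "mnlogistic")) {
  method <- match.arg(method)
  st <- standardize_stats(table)
  Z <- st$Z
  models <- unique(table$model)
  conf <- matrix(0L, length(models), length(models),
                 dimnames = list(true = models, assigned = models))
  for (lab in models) {
    rows <- which(table$model == lab)
    if (n_cv > length(rows))
      stop("n_cv exceeds rows available for model ", lab)
    held <- sample(rows, n_cv)
    for (i in held) {
      d2 <- colSums((t(Z) - Z[i, ])^2)
      d2[i] <- Inf                       # leave the row itself out
      acc <- accept_rows(d2, tol)
      if (method == "rejection") {
        share <- base::table(factor(table$model[acc], levels = models))
        pick <- models[which.max(share)]
      } else {
        labs <- factor(table$model[acc], levels = models)
        present <- levels(droplevels(labs))
        if (length(present) < 2) pick <- present
        else {
          dacc <- sqrt(d2[acc]); dmax <- max(dacc)
          w <- if (dmax > 0) 1 - (dacc / dmax)^2 else rep(1, length(acc))
          w[w <= 0] <- min(w[w > 0], 1e-8)
          df <- data.frame(.model = droplevels(labs), Z[acc, , drop = FALSE])
          fit <- nnet::multinom(.model ~ ., data = df, weights = w,
                                trace = FALSE, maxit = 200, MaxNWts = 10000)
          newd <- as.data.frame(t(Z[i, ]))
          colnames(newd) <- colnames(Z)
          p <- predict(fit, newdata = newd, type = "probs")
          if (length(p) == 1) {
            p <- c(1 - p, p); names(p) <- present
          }
          pick <- names(p)[which.max(p)]
        }
      }
      conf[lab, pick] <- conf[lab, pick] + 1L
    }
  }
  correct <- diag(conf) / n_cv
  structure(list(confusion = conf, n_cv = n_cv, tol = tol, method = method,
                 correct = correct, mean_correct = mean(correct)),
            class = "abc_cv")
}

#' @export
print.abc_cv <- function(x, ...) {
  cat("ABC cross-validation (", x$method, ", tol = ", x$tol, ", ",
      x$n_cv, " pseudo-observations per model)\n", sep = "")
  print(x$confusion)
  cat("mean correct assignment:", round(x$mean_correct, 4), "\n")
  invisible(x)
}

#' Goodness of fit of one model to observed statistics
#'
#' The observed statistic is the median standardized distance from the
#' observed vector to its accepted set; the null distribution is the same
#' statistic for pseudo-observed rows drawn from the (single-model) table.
#'
#' @param obs Observed summary-statistic vector.
#' @param table Reference table restricted to one model.
#' @param tol Acceptance fraction (default 0.01).
#' @param n_rep Pseudo-observed replicates for the null (default 1000).
#' @return An object of class `abc_gof` with `stat`, `null` and `p`.
#' @export
goodness_of_fit <- function(obs, table, tol = 0.01, n_rep = 1000) {
  if (length(unique(table$model)) != 1)
    stop("goodness of fit expects a single-model table")
  if (n_rep < 1) stop("n_rep must be at least 1")
  st <- standardize_stats(table, obs)
  Z <- st$Z
  n_acc <- ceiling(tol * nrow(Z))
  d2 <- colSums((t(Z) - st$z_obs)^2)
  stat <- median(sqrt(sort(d2, partial = n_acc)[seq_len(n_acc)]))
  pseudo <- sample.int(nrow(Z), n_rep, replace = n_rep > nrow(Z))
  null <- vapply(pseudo, function(i) {
    di <- colSums((t(Z) - Z[i, ])^2)
    di[i] <- Inf
    median(sqrt(sort(di, partial = n_acc)[seq_len(n_acc)]))
  }, numeric(1))
  p <- (1 + sum(null >= stat)) / (n_rep + 1)
  structure(list(stat = stat, null = null, p = p, tol = tol, n_rep = n_rep),
            class = "abc_gof")
}

#' @export
print.abc_gof <- function(x, ...) {
  cat("Goodness of fit: observed median accepted distance =",
      round(x$stat, 4), "; p =", signif(x$p, 3), "\n")
  invisible(x)
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(q) x[which(cw >= q)[1]], numeric(1))
}

#' ABC parameter estimation with local-linear adjustment
#'
#' Rejection acceptance at `tol` followed by a distance-weighted local-linear
#' regression adjustment of each parameter toward the observed statistics
#' (Ne on the log scale), with Epanechnikov weights. Medians and 95%
#' intervals are weighted quantiles of the adjusted sample, clamped to the
#' prior support.
#'
#' @param obs Observed summary-statistic vector.
#' @param table Reference table restricted to the chosen model.
#' @param tol Acceptance fraction (default 0.05).
#' @param adjust Apply the regression adjustment (default `TRUE`).
#' @return An object of class `param_posterior`: per-parameter weighted
#'   sample, `summary` data.frame (median, 2.5% and 97.5% quantiles).
#' @export
estimate_parameters <- function(obs, table, tol = 0.05, adjust = TRUE) {
  if (length(unique(table$model)) != 1)
    stop("parameter estimation expects a single-model table")
  st <- standardize_stats(table, obs)
  d2 <- colSums((t(st$Z) - st$z_obs)^2)
  acc <- accept_rows(d2, tol)
  dacc <- sqrt(d2[acc]); dmax <- max(dacc)
  w <- if (dmax > 0) 1 - (dacc / dmax)^2 else rep(1, length(acc))
  w[w <= 0] <- min(w[w > 0], 1e-8)
  prior <- attr(table, "prior") %||% prior_spec()
  pc <- param_cols(table)
  X <- sweep(st$Z[acc, , drop = FALSE], 2, st$z_obs)   # stats minus observed
  samples <- matrix(NA_real_, length(acc), length(pc),
                    dimnames = list(NULL, pc))
  for (p in pc) {
    theta <- table[[p]][acc]
    lo <- if (p == "m") prior$m_bounds[1] else prior$ne_bounds[1]
    hi <- if (p == "m") prior$m_bounds[2] else prior$ne_bounds[2]
    y <- if (p == "m") theta else log(theta)
    if (adjust) {
      fit <- tryCatch(stats::lm.wfit(cbind(1, X), y, w), error = function(e) NULL)
      if (is.null(fit) || anyNA(fit$coefficients)) {
        warning("degenerate local-linear design for ", p,
                "; using unadjusted rejection sample")
        adj <- y
      } else {
        adj <- fit$coefficients[1] + fit$residuals
      }
    } else adj <- y
    if (p != "m") adj <- exp(adj)
    samples[, p] <- pmin(pmax(adj, lo), hi)
  }
  qs <- t(apply(samples, 2, weighted_quantile, w = w,
                probs = c(0.025, 0.5, 0.975)))
  summary <- data.frame(parameter = pc, median = qs[, 2],
                        lower = qs[, 1], upper = qs[, 3], row.names = NULL)
  structure(list(samples = samples, weights = w, accepted = acc,
                 summary = summary, tol = tol, adjusted = adjust),
            class = "param_posterior")
}

#' @export
print.param_posterior <- function(x, digits = 4, ...) {
  cat("ABC parameter posterior (tol = ", x$tol,
      if (x$adjusted) ", local-linear adjusted" else ", rejection only",
      ")\n", sep = "")
  print(cbind(x$summary[1], signif(x$summary[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' Persist a reference table as CSV plus a JSON sidecar
#'
#' @param table Reference table.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @export
write_reference_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(samples = attr(table, "samples"),
               n_snps = attr(table, "n_snps"),
               elevations = attr(table, "elevations"),
               prior = unclass(attr(table, "prior")),
               ss_center = as.list(attr(table, "ss_center")),
               ss_scale = as.list(attr(table, "ss_scale")))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read a reference table written by [write_reference_table()]
#' @param path CSV path.
#' @return An `abc_reftable`.
#' @export
read_reference_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("abc_reftable", "data.frame")
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  attr(tab, "samples") <- meta$samples
  attr(tab, "n_snps") <- meta$n_snps
  attr(tab, "elevations") <- if (length(meta$elevations))
    unlist(meta$elevations) else NULL
  attr(tab, "prior") <- do.call(prior_spec, meta$prior)
  attr(tab, "ss_center") <- unlist(meta$ss_center)
  attr(tab, "ss_scale") <- unlist(meta$ss_scale)
  tab
}
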