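# Generators for synthetic inputs matching the study's shape: species
# sampling layouts, elevation-shifted survey seasons and linear trait
# clines. Together with simulate_dataset() they let every pipeline stage run
# without field data.

#' Study site characteristics
#'
#' The five survey sites along the Boulder County elevational gradient, with
#' coordinates, mean annual temperature (degrees C) and mean growing-season
#' length (days).
#'
#' @return A data.frame with one row per site.
#' @export
site_table <- function() {
  read.csv(system.file("extdata", "sites.csv", package = "elevflow"),
           stringsAsFactors = FALSE)
}

SPECIES_CONFIGS <- list(
  "A. clavatus" = list(elevations = c(1577, 2195, 2591, 3515),
                       samples = c(22, 21, 22, 22), n_snps = 9454,
                       models = c("dn", "up", "ss", "am")),
  "M. boulderensis" = list(elevations = c(2195, 2591, 3048, 3515),
                           samples = c(21, 18, 8, 19), n_snps = 5501,
                           models = c("dn", "up", "ss", "am")),
  "M. sanguinipes" = list(elevations = c(1577, 2195, 2591, 3048, 3515),
                          samples = c(22, 20, 21, 21, 12), n_snps = 4087,
                          models = c("dn", "up", "ss", "am", "sk")),
  "C. pellucida" = list(elevations = c(2195, 2591, 3048),
                        samples = c(23, 21, 21), n_snps = 6815,
                        models = c("dn", "up", "ss", "am")))

#' Study sampling layout for a species
#'
#' Deme elevations, per-deme diploid sample sizes, SNP count and candidate
#' gene-flow model set for each of the four grasshopper species. The
#' source-sink model is a candidate only for the five-deme widespread
#' species.
#'
#' @param name Species name (e.g. `"A. clavatus"`).
#' @param n_snps Optional override of the SNP count (analyses are routinely
#'   run scaled down).
#' @return An object of class `species_config`.
#' @export
species_config <- function(name, n_snps = NULL) {
  if (!name %in% names(SPECIES_CONFIGS))
    stop("unknown species '", name, "'; valid names: ",
         paste(names(SPECIES_CONFIGS), collapse = ", "))
  cfg <- SPECIES_CONFIGS[[name]]
  cfg$species <- name
  if (!is.null(n_snps)) cfg$n_snps <- n_snps
  structure(cfg, class = "species_config")
}

#' @export
print.species_config <- function(x, ...) {
  cat(x$species, ": ", length(x$elevations), " demes (",
      paste(x$elevations, collapse = "/"), " m), samples ",
      paste(x$samples, collapse = "/"), ", ", x$n_snps, " SNPs, models {",
      paste(x$models, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Generate a synthetic weekly survey table
#'
#' Weekly adult counts are Poisson draws around a Gaussian seasonal
#' abundance curve whose peak shifts later with elevation by
#' `delay_per_100m` days per 100 m.
#'
#' @param elevations Site elevations (m); site names default to `S<elev>`.
#' @param years Survey years (default 2010).
#' @param delay_per_100m Phenological delay in days per 100 m elevation
#'   (default 3).
#' @param season_sd Seasonal spread in days (default 14).
#' @param peak_abundance Expected adults per survey at the seasonal peak
#'   (default 100).
#' @param base_peak_day Peak day of year at the lowest site (default 180).
#' @param days Survey days of year (weekly grid); defaults to a weekly grid
#'   covering three seasonal standard deviations around every site's peak.
#' @param species Species label for the table (default "synthetic").
#' @return A survey data.frame (site, elevation_m, species, year, week,
#'   day_of_year, adult_count).
#' @export
gen_survey_data <- function(elevations, years = 2010, delay_per_100m = 3,
                            season_sd = 14, peak_abundance = 100,
                            base_peak_day = 180, days = NULL,
                            species = "synthetic") {
  stopifnot(season_sd > 0)
  if (is.null(days)) {
    span <- base_peak_day +
      delay_per_100m * (max(elevations) - min(elevations)) / 100
    days <- seq(floor(base_peak_day - 3 * season_sd),
                ceiling(span + 3 * season_sd), by = 7)
  }
  weeks <- length(days)
  out <- list()
  for (yr in years) for (i in seq_along(elevations)) {
    e <- elevations[i]
    peak <- base_peak_day + delay_per_100m * (e - min(elevations)) / 100
    mu <- peak_abundance * exp(-(days - peak)^2 / (2 * season_sd^2))
    out[[length(out) + 1]] <- data.frame(
      site = paste0("S", e), elevation_m = e, species = species, year = yr,
      week = seq_len(weeks), day_of_year = days,
      adult_count = rpois(weeks, mu))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate synthetic population trait means on an elevational cline
#'
#' Trait means are linear in elevation (slope per km) plus Gaussian noise.
#'
#' @param pm Population map or a data.frame with population and elevation_m.
#' @param slopes Named vector: per-trait slope per km of elevation.
#' @param noise_sd Gaussian noise standard deviation (single value or per
#'   trait; default 0).
#' @param intercepts Optional named intercepts (default 0).
#' @return A trait table: population column plus one column per trait.
#' @export
gen_trait_clines <- function(pm, slopes, noise_sd = 0, intercepts = NULL) {
  pops <- pop_table(pm)
  if (is.null(names(slopes)))
    names(slopes) <- paste0("trait_", seq_along(slopes))
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, length(slopes))
  if (is.null(intercepts)) intercepts <- rep(0, length(slopes))
  out <- data.frame(population = pops$population)
  km <- pops$elevation_m / 1000
  for (i in seq_along(slopes))
    out[[names(slopes)[i]]] <- intercepts[i] + slopes[i] * km +
      rnorm(nrow(pops), 0, noise_sd[i])
  out
}
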