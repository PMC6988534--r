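# Phenological overlap among sites from weekly adult-count surveys.
#
# Pianka's symmetric niche-overlap index on weekly abundance proportions is
# used as an ecological ceiling on between-site mating and gene flow;
# percentile dates (day of year of the 15th / 85th percentile adult)
# summarize each site's season.

#' Pianka's symmetric niche-overlap index
#'
#' `O = sum(p_j * p_k) / sqrt(sum(p_j^2) * sum(p_k^2))` on weekly
#' proportions aligned to a common week grid.
#'
#' @param p_j,p_k Weekly proportion vectors on the same week grid, each
#'   summing to 1.
#' @return Overlap in `[0, 1]`.
#' @export
pianka_overlap <- function(p_j, p_k) {
  if (length(p_j) != length(p_k))
    stop("proportion vectors must share one week grid")
  if (abs(sum(p_j) - 1) > 1e-8 || abs(sum(p_k) - 1) > 1e-8)
    stop("proportions must each sum to 1 (all-zero seasons are undefined)")
  sum(p_j * p_k) / sqrt(sum(p_j^2) * sum(p_k^2))
}

#' Day of year of a percentile adult
#'
#' First-crossing convention: the day of the first survey at which the
#' cumulative proportion of adults reaches the percentile.
#'
#' @param counts Adult counts per survey (non-negative, total `>= 1`).
#' @param days Day of year of each survey, increasing.
#' @param q Percentile(s) in (0, 1); default `c(0.15, 0.85)`.
#' @return Named numeric vector of days of year.
#' @export
percentile_dates <- function(counts, days, q = c(0.15, 0.85)) {
  stopifnot(length(counts) == length(days), all(counts >= 0))
  if (sum(counts) < 1) stop("no adults observed; percentile dates undefined")
  cum <- cumsum(counts) / sum(counts)
  setNames(vapply(q, function(qq) days[which(cum >= qq)[1]], numeric(1)),
           paste0("p", round(100 * q)))
}

#' Phenological overlap and percentile dates for a survey table
#'
#' For every species-year, weekly proportions are computed per site on the
#' union of surveyed weeks (zero where a site was surveyed but recorded no
#' adults; unsurveyed weeks are absent, not zero-filled), and Pianka overlap
#' is scored for all site pairs. Sites with zero total adults in a season
#' are skipped with a warning.
#'
#' @param st Survey data.frame with columns site, elevation_m, species,
#'   year, week, day_of_year, adult_count.
#' @return A list with `overlap` (species, year, site pair, overlap,
#'   elevational separation; sorted by separation within species-year) and
#'   `percentiles` (species, year, site, elevation_m, p15, p85).
#' @export
overlap_pipeline <- function(st) {
  need <- c("site", "elevation_m", "species", "year", "week", "day_of_year",
            "adult_count")
  if (!all(need %in% names(st)))
    stop("survey table must have columns: ", paste(need, collapse = ", "))
  if (any(st$adult_count < 0)) stop("adult counts must be non-negative")
  ov <- list(); pc <- list()
  for (sp in unique(st$species)) for (yr in unique(st$year[st$species == sp])) {
    sub <- st[st$species == sp & st$year == yr, ]
    sites <- unique(sub$site)
    weeks <- sort(unique(sub$week))
    props <- list(); elev <- c()
    for (s in sites) {
      ss <- sub[sub$site == s, ]
      total <- sum(ss$adult_count)
      elev[s] <- ss$elevation_m[1]
      if (total < 1) {
        warning("site ", s, " has no adults for ", sp, " in ", yr,
                "; skipped")
        next
      }
      wk <- setNames(rep(0, length(weeks)), weeks)
      agg <- tapply(ss$adult_count, ss$week, sum)
      wk[names(agg)] <- agg
      props[[s]] <- wk / sum(wk)
      pq <- percentile_dates(ss$adult_count[order(ss$day_of_year)],
                             sort(ss$day_of_year))
      pc[[length(pc) + 1]] <- data.frame(species = sp, year = yr, site = s,
                                         elevation_m = elev[s],
                                         p15 = pq[["p15"]], p85 = pq[["p85"]])
    }
    usable <- names(props)
    if (length(usable) >= 2) {
      prs <- utils::combn(usable, 2)
      for (ci in seq_len(ncol(prs))) {
        a <- prs[1, ci]; b <- prs[2, ci]
        ov[[length(ov) + 1]] <- data.frame(
          species = sp, year = yr, site_a = a, site_b = b,
          overlap = pianka_overlap(props[[a]], props[[b]]),
          elev_sep = abs(elev[a] - elev[b]))
      }
    }
  }
  overlap <- if (length(ov)) do.call(rbind, ov) else
    data.frame(species = character(0), year = integer(0),
               site_a = character(0), site_b = character(0),
               overlap = numeric(0), elev_sep = numeric(0))
  if (nrow(overlap))
    overlap <- overlap[order(overlap$species, overlap$year,
                             overlap$elev_sep), ]
  percentiles <- if (length(pc)) do.call(rbind, pc) else
    data.frame(species = character(0), year = integer(0), site = character(0),
               elevation_m = numeric(0), p15 = numeric(0), p85 = numeric(0))
  rownames(overlap) <- rownames(percentiles) <- NULL
  list(overlap = overlap, percentiles = percentiles)
}
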