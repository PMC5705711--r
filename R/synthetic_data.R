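#' Configuration for the synthetic study generator
#'
#' Defaults emulate a monitoring study of a bromeliad-dwelling frog on an
#' isolated mountaintop: 143 bromeliad sites split across three altitudinal
#' zones (47 high / 48 medium / 48 low), zone-dependent occupancy (0.66 at
#' high and medium elevation, 0.14 at low), detection that depends on
#' observer experience (0.61 experienced, 0.38 inexperienced), and monthly
#' survey bouts of 4-6 consecutive nights over four months. Latent occupancy
#' is closed over the season. Site covariates (bromeliad size, rosette
#' volume, leaf and neighbour counts) are drawn from simple realistic
#' distributions and, by default, carry no effect — they act as nuisance
#' candidates for model selection.
#'
#' @param n_sites_per_zone Named integer vector, sites per zone
#'   (low/medium/high).
#' @param zone_psi Named occupancy probability per zone.
#' @param observer_p Named per-visit detection probability by observer
#'   experience (`high`/`low`).
#' @param occasions_per_month Length-2 integer range; each month's number of
#'   nights is drawn uniformly from it.
#' @param months Character vector of month labels (one survey bout each).
#' @param elevation_ranges List of length-2 numeric ranges (m a.s.l.) per
#'   zone; must be disjoint and ordered low < medium < high.
#' @param observer_assignment `"alternate"` (teams swap nightly) or
#'   `"random"`.
#' @param neighbours If `TRUE`, also generate a neighbouring-bromeliad
#'   history sharing each site's latent state (for pooling tests).
#' @return A validated `study_config` list.
#' @export
study_config <- function(n_sites_per_zone = c(low = 48, medium = 48, high = 47),
                         zone_psi = c(low = 0.14, medium = 0.66, high = 0.66),
                         observer_p = c(high = 0.61, low = 0.38),
                         occasions_per_month = c(4, 6),
                         months = c("Feb", "Mar", "Apr", "May"),
                         elevation_ranges = list(low = c(1704, 1815),
                                                 medium = c(1838, 1925),
                                                 high = c(1998, 2060)),
                         observer_assignment = c("alternate", "random"),
                         neighbours = FALSE) {
  observer_assignment <- match.arg(observer_assignment)
  zones <- names(n_sites_per_zone)
  stopifnot(length(zones) >= 1, !is.null(zones),
            setequal(zones, names(zone_psi)),
            setequal(zones, names(elevation_ranges)),
            all(n_sites_per_zone >= 1),
            all(zone_psi > 0), all(zone_psi <= 1),
            all(observer_p > 0), all(observer_p <= 1),
            length(occasions_per_month) == 2,
            occasions_per_month[1] >= 1,
            occasions_per_month[2] >= occasions_per_month[1],
            length(months) >= 1)
  # elevation bands must be disjoint and in increasing order
  bands <- do.call(rbind, elevation_ranges[zones])
  if (any(bands[, 2] <= bands[, 1])) stop("degenerate elevation range")
  ord <- order(bands[, 1])
  if (any(diff(as.vector(t(bands[ord, ]))) < 0))
    stop("elevation ranges must be disjoint")
  structure(list(n_sites_per_zone = n_sites_per_zone, zone_psi = zone_psi,
                 observer_p = observer_p,
                 occasions_per_month = as.integer(occasions_per_month),
                 months = months, elevation_ranges = elevation_ranges,
                 observer_assignment = observer_assignment,
                 neighbours = neighbours),
            class = "study_config")
}

#' Generate a synthetic occupancy study
#'
#' Draws a complete study-shaped dataset from known parameters: latent
#' occupancy per site from its zone's psi, nightly detections at occupied
#' sites from the assigned observer's p, occasion counts per month from the
#' configured range. Everything needed to recompute any probability used in
#' generation is returned in the `truth` record, so parameter-recovery and
#' coverage tests can compare estimates against the generating values.
#'
#' @param config A [study_config()].
#' @param seed Integer seed; the same seed reproduces the study exactly.
#' @return A `synthetic_study`: `history` (a `detection_history`), optional
#'   `neighbour_history`, `site_covs`, `survey_covs`, and `truth` (latent
#'   states `z`, generating parameters, occasion schedule, seed).
#' @export
generate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))

  zones <- names(config$n_sites_per_zone)
  zone_of_site <- rep(zones, times = config$n_sites_per_zone)
  S <- length(zone_of_site)
  site_ids <- sprintf("site_%03d", seq_len(S))

  occ_range <- seq(config$occasions_per_month[1], config$occasions_per_month[2])
  occ_per_month <- if (length(occ_range) == 1) {
    rep(occ_range, length(config$months))
  } else {
    sample(occ_range, length(config$months), replace = TRUE)
  }
  occ_labels <- unlist(mapply(function(m, k) paste(m, seq_len(k), sep = "_"),
                              config$months, occ_per_month, SIMPLIFY = FALSE))
  K <- length(occ_labels)

  # observer experience per occasion (teams swap nightly) or at random
  exp_levels <- names(config$observer_p)
  observer <- switch(config$observer_assignment,
    alternate = rep(exp_levels, length.out = K),
    random = sample(exp_levels, K, replace = TRUE))

  # site covariates
  elev <- numeric(S)
  for (zn in zones) {
    idx <- zone_of_site == zn
    rng <- config$elevation_ranges[[zn]]
    elev[idx] <- round(stats::runif(sum(idx), rng[1], rng[2]), 1)
  }
  site_covs <- data.frame(
    site = site_ids,
    zone = zone_of_site,
    elevation = elev,
    bromeliad_size = round(stats::rlnorm(S, log(1500), 0.4), 1),  # height x width, cm^2
    rosette_volume = round(stats::rlnorm(S, log(900), 0.5), 1),
    n_leaves = stats::rpois(S, 12),
    n_neighbours = stats::rpois(S, 2),
    stringsAsFactors = FALSE
  )

  # latent occupancy, closed across the season
  psi_site <- config$zone_psi[zone_of_site]
  z <- stats::rbinom(S, 1, psi_site)

  p_occ <- config$observer_p[observer]                 # per occasion
  draw_history <- function() {
    m <- matrix(stats::rbinom(S * K, 1, rep(p_occ, each = S)), nrow = S)
    m * z
  }
  hist_mat <- draw_history()
  history <- detection_history(hist_mat, site_ids = site_ids,
                               occasion_labels = occ_labels)
  neighbour_history <- NULL
  if (isTRUE(config$neighbours)) {
    neighbour_history <- detection_history(draw_history(), site_ids = site_ids,
                                           occasion_labels = occ_labels)
  }

  survey_covs <- data.frame(
    site = rep(site_ids, each = K),
    occ = rep(occ_labels, times = S),
    observer_experience = rep(observer, times = S),
    time_after_dusk = round(stats::runif(S * K, 10, 240)),
    stringsAsFactors = FALSE
  )

  structure(list(
    history = history,
    neighbour_history = neighbour_history,
    site_covs = site_covs,
    survey_covs = survey_covs,
    truth = list(z = stats::setNames(z, site_ids),
                 zone_psi = config$zone_psi,
                 observer_p = config$observer_p,
                 observer_by_occasion = stats::setNames(observer, occ_labels),
                 occasions_per_month = stats::setNames(occ_per_month, config$months),
                 seed = seed)
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic occupancy study\n")
  print(x$history)
  cat(sprintf("  true occupied sites: %d of %d\n",
              sum(x$truth$z), length(x$truth$z)))
  invisible(x)
}

#' Generate paired before/after studies for a power experiment
#'
#' Period 1 is drawn from `config`; period 2 reuses the same sites, site
#' covariates and survey schedule but redraws latent occupancy with every
#' zone's psi scaled to `psi * (1 - effect)` (independent draws — the
#' generating law of a proportional decline). Detection parameters are
#' unchanged.
#'
#' @param config A [study_config()].
#' @param effect Proportional decline R in (0, 1); `psi2 = psi1 (1 - R)` per
#'   zone must stay in (0, 1).
#' @param seed Integer seed (period 2 uses `seed + 1`).
#' @return List with `period1` and `period2`, both `synthetic_study` objects.
#' @export
generate_two_period <- function(config = study_config(), effect, seed = 1) {
  stopifnot(inherits(config, "study_config"))
  psi2 <- config$zone_psi * (1 - effect)
  if (any(psi2 <= 0) || any(psi2 >= 1))
    stop("period-2 occupancy psi*(1-R) outside (0,1) for zone(s): ",
         paste(names(psi2)[psi2 <= 0 | psi2 >= 1], collapse = ", "))
  period1 <- generate_study(config, seed = seed)

  # period 2 keeps period 1's sites, covariates and survey schedule; only the
  # latent states and detections are redrawn
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed + 1)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  h1 <- period1$history
  S <- nrow(h1$matrix); K <- ncol(h1$matrix)
  zone_of_site <- period1$site_covs$zone
  z2 <- stats::rbinom(S, 1, psi2[zone_of_site])
  observer <- period1$truth$observer_by_occasion
  p_occ <- config$observer_p[observer]
  m2 <- matrix(stats::rbinom(S * K, 1, rep(p_occ, each = S)), nrow = S) * z2
  period2 <- period1
  period2$history <- detection_history(m2, site_ids = h1$site_ids,
                                       occasion_labels = h1$occasion_labels)
  period2$neighbour_history <- NULL
  period2$truth$z <- stats::setNames(z2, h1$site_ids)
  period2$truth$zone_psi <- psi2
  period2$truth$seed <- seed + 1
  list(period1 = period1, period2 = period2)
}

#' Write a synthetic study to disk
#'
#' Emits the deterministic CSV formats of the I/O layer (history and
#' covariate tables) plus a `truth.json` ledger of the generating
#' parameters.
#'
#' @param study A `synthetic_study`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_history(study$history, file.path(outdir, "history.csv"))
  if (!is.null(study$neighbour_history))
    write_history(study$neighbour_history, file.path(outdir, "history_neighbour.csv"))
  utils::write.csv(study$site_covs, file.path(outdir, "site_covs.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$survey_covs, file.path(outdir, "survey_covs.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(study$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
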