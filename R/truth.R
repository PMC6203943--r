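#' Per-species ground-truth parameters for the logbook generator
#'
#' Bundles the parameters of the two-part (delta) catch model for one shark
#' species: fixed effects on the logit scale for the probability of a
#' non-zero catch, fixed effects on the log scale for the mean of positive
#' CPUE (sharks per 1,000 hooks), vessel random-intercept standard
#' deviations for each part, and the gamma shape of positive CPUE.
#'
#' Fixed effects are reference-coded maps: the `intercept` is the linear
#' predictor at the reference cell (year equal to the first simulated year,
#' January, foreign fleet, observer absent) and each named vector gives the
#' offsets of the non-reference levels; levels absent from a map have zero
#' effect.
#'
#' @param beta_binomial named list with elements `intercept` (scalar) and
#'   optionally `year`, `month`, `fleet`, `observer` (named numeric
#'   vectors), all on the logit scale.
#' @param beta_gamma same structure on the log scale for positive CPUE.
#' @param sigma_vessel_binomial,sigma_vessel_gamma standard deviations
#'   (>= 0) of the per-vessel random intercepts, logit and log scale.
#' @param gamma_shape shape parameter (> 0) of the gamma distribution of
#'   positive CPUE; the variance of positive CPUE in a covariate cell is
#'   mean^2 / shape.
#' @param mean_weight_kg mean individual weight (kg) used to turn retained
#'   counts into retained weights.
#' @param weight_cv lognormal coefficient-of-variation of the per-set mean
#'   individual weight.
#' @return an object of class `species_params`.
#' @seealso [logbook_truth()], [generate_logbook()]
#' @export
species_params <- function(beta_binomial = list(intercept = 0.5),
                           beta_gamma = list(intercept = 2.0),
                           sigma_vessel_binomial = 0.5,
                           sigma_vessel_gamma = 0.4,
                           gamma_shape = 2,
                           mean_weight_kg = 15,
                           weight_cv = 0.3) {
  for (nm in c("beta_binomial", "beta_gamma")) {
    b <- get(nm)
    if (!is.list(b) || is.null(b$intercept) || !is.finite(b$intercept)) {
      stop_config("`%s` must be a list with a finite `intercept`", nm)
    }
    extra <- setdiff(names(b), c("intercept", "year", "month", "fleet", "observer"))
    if (length(extra)) {
      stop_config("unknown term(s) in `%s`: %s", nm, paste(extra, collapse = ", "))
    }
  }
  if (sigma_vessel_binomial < 0) stop_config("`sigma_vessel_binomial` must be >= 0")
  if (sigma_vessel_gamma < 0) stop_config("`sigma_vessel_gamma` must be >= 0")
  if (!is.finite(gamma_shape) || gamma_shape <= 0) {
    stop_config("`gamma_shape` must be > 0")
  }
  if (mean_weight_kg <= 0) stop_config("`mean_weight_kg` must be > 0")
  structure(
    list(beta_binomial = beta_binomial, beta_gamma = beta_gamma,
         sigma_vessel_binomial = sigma_vessel_binomial,
         sigma_vessel_gamma = sigma_vessel_gamma,
         gamma_shape = gamma_shape, mean_weight_kg = mean_weight_kg,
         weight_cv = weight_cv),
    class = "species_params"
  )
}

# Default effect patterns: a mid-series rise with a late peak for blue
# sharks, a flatter series for makos, a mild seasonal cycle, fleet
# contrasts matching the observed per-fleet zero-catch rates, and a small
# positive observer effect (more complete reporting when observed).
default_year_effects <- function(scale = 1) {
  v <- c(0.00, 0.05, 0.15, 0.45, 0.50, 0.30, 0.35, 0.50,
         0.30, 0.20, 0.90, 0.70, 0.50, 0.55, 0.60)
  stats::setNames(scale * v, as.character(2001:2015))
}

default_month_effects <- function(amplitude = 0.3) {
  m <- 2:12
  stats::setNames(round(amplitude * sin(2 * pi * (m - 1) / 12), 3),
                  as.character(m))
}

default_blue_params <- function() {
  species_params(
    beta_binomial = list(
      intercept = stats::qlogis(0.71),      # foreign fleet: 29% zero sets
      year = default_year_effects(),
      month = default_month_effects(),
      fleet = c(local = stats::qlogis(0.63) - stats::qlogis(0.71)),
      observer = c(yes = 0.20, unknown = 0.05)
    ),
    beta_gamma = list(
      intercept = log(11),                  # positive CPUE ~ 11 / 1,000 hooks
      year = default_year_effects(0.8),
      month = default_month_effects(0.2),
      fleet = c(local = 0.25),
      observer = c(yes = 0.15, unknown = 0.0)
    ),
    sigma_vessel_binomial = 0.5,
    sigma_vessel_gamma = 0.4,
    gamma_shape = 2,
    mean_weight_kg = 10.5
  )
}

default_mako_params <- function() {
  species_params(
    beta_binomial = list(
      intercept = stats::qlogis(0.60),      # foreign fleet: 40% zero sets
      year = default_year_effects(0.5),
      month = default_month_effects(0.2),
      fleet = c(local = stats::qlogis(0.68) - stats::qlogis(0.60)),
      observer = c(yes = 0.20, unknown = 0.05)
    ),
    beta_gamma = list(
      intercept = log(8),
      year = default_year_effects(0.4),
      month = default_month_effects(0.15),
      fleet = c(local = 0.15),
      observer = c(yes = 0.15, unknown = 0.0)
    ),
    sigma_vessel_binomial = 0.5,
    sigma_vessel_gamma = 0.4,
    gamma_shape = 2,
    mean_weight_kg = 21
  )
}

#' Ground truth for a synthetic longline logbook
#'
#' Defines the full data-generating process for a set-by-set longline
#' logbook: fleet sizes and set allocation, per-fleet hooks-per-line
#' distributions (truncated normal on the plausible effort range), observer
#' coverage rules, spatial allocation over the four analysis areas, and the
#' two-part catch model per species (see [species_params()]). Defaults
#' reproduce the study fishery's nominal structure: 29,018 sets split
#' 16,810 local / 12,208 foreign across 61 and 49 vessels, hooks per line
#' 1,282 +/- 250 (local) and 2,493 +/- 597 (foreign), years 2000-2015, and
#' near-complete observer coverage on foreign vessels after 2002.
#'
#' @param n_sets total number of longline sets to simulate.
#' @param years integer vector of calendar years sampled uniformly.
#' @param n_vessels_by_fleet named integer vector `c(local=, foreign=)`.
#' @param p_foreign probability a set belongs to the foreign fleet.
#' @param hooks_mean_sd_by_fleet list with `local` and `foreign` elements,
#'   each `c(mean, sd)` of hooks per line before truncation.
#' @param hooks_range truncation bounds for hooks per line; the defaults
#'   equal the cleaning filter so uncorrupted data pass it by construction.
#' @param species named list of [species_params()]; defaults cover blue
#'   shark and shortfin mako with independent parameter sets.
#' @param observer list of per-fleet observer-status probabilities
#'   (`local`, `foreign_pre`, `foreign_post`, each over yes/no/unknown) and
#'   the first year `post_year` at which the foreign fleet switches to its
#'   post-coverage regime.
#' @param area_weights sampling probabilities of the four analysis areas.
#' @param area_boxes per-area lon/lat bounding boxes positions are drawn
#'   uniformly from; must lie inside the assignment region of each area so
#'   the generated area label is the assignment truth.
#' @param target_probs per-fleet probabilities over declared target species.
#' @param weight_other_meanlog,weight_other_sdlog lognormal parameters (per
#'   fleet meanlog) of non-shark retained weight per set (kg).
#' @param seed RNG seed; generation is deterministic given the truth.
#' @return an object of class `logbook_truth`.
#' @export
logbook_truth <- function(n_sets = 29018,
                          years = 2000:2015,
                          n_vessels_by_fleet = c(local = 61, foreign = 49),
                          p_foreign = 12208 / 29018,
                          hooks_mean_sd_by_fleet = list(local = c(1282, 250),
                                                        foreign = c(2493, 597)),
                          hooks_range = c(310, 3800),
                          species = list(blue = default_blue_params(),
                                         mako = default_mako_params()),
                          observer = list(
                            local = c(yes = 0.20, no = 0.70, unknown = 0.10),
                            foreign_pre = c(yes = 0.30, no = 0.60, unknown = 0.10),
                            foreign_post = c(yes = 0.95, no = 0.03, unknown = 0.02),
                            post_year = 2003),
                          area_weights = c(West = 0.15, Southwest = 0.20,
                                           South = 0.40, East = 0.25),
                          area_boxes = default_area_boxes(),
                          target_probs = list(
                            local = c(tuna = 0.5, swordfish = 0.3, shark = 0.2),
                            foreign = c(tuna = 1)),
                          weight_other_meanlog = c(local = log(400),
                                                   foreign = log(2000)),
                          weight_other_sdlog = 0.6,
                          seed = 1L) {
  if (!is.numeric(n_sets) || length(n_sets) != 1L || n_sets < 0 ||
      n_sets != round(n_sets)) {
    stop_config("`n_sets` must be a single non-negative integer")
  }
  if (!length(years) || any(years != round(years))) {
    stop_config("`years` must be integer calendar years")
  }
  if (!all(c("local", "foreign") %in% names(n_vessels_by_fleet)) ||
      any(n_vessels_by_fleet < 1)) {
    stop_config("`n_vessels_by_fleet` needs at least one vessel per fleet")
  }
  if (p_foreign < 0 || p_foreign > 1) stop_config("`p_foreign` must be in [0, 1]")
  for (fl in c("local", "foreign")) {
    ms <- hooks_mean_sd_by_fleet[[fl]]
    if (is.null(ms) || length(ms) != 2L || ms[2] <= 0) {
      stop_config("`hooks_mean_sd_by_fleet$%s` must be c(mean, sd) with sd > 0", fl)
    }
    if (ms[1] < hooks_range[1] || ms[1] > hooks_range[2]) {
      stop_config("`hooks_mean_sd_by_fleet$%s`: mean %.0f outside the plausible range [%g, %g]",
                  fl, ms[1], hooks_range[1], hooks_range[2])
    }
  }
  if (!length(species) || is.null(names(species))) {
    stop_config("`species` must be a named list of species_params objects")
  }
  for (sp in names(species)) {
    if (!inherits(species[[sp]], "species_params")) {
      stop_config("`species$%s` is not a species_params object", sp)
    }
  }
  if (abs(sum(area_weights) - 1) > 1e-8 || any(area_weights < 0)) {
    stop_config("`area_weights` must be non-negative and sum to 1")
  }
  if (!setequal(names(area_weights), names(area_boxes))) {
    stop_config("`area_boxes` must name the same areas as `area_weights`")
  }
  structure(
    list(n_sets = as.integer(n_sets), years = as.integer(years),
         n_vessels_by_fleet = n_vessels_by_fleet, p_foreign = p_foreign,
         hooks_mean_sd_by_fleet = hooks_mean_sd_by_fleet,
         hooks_range = hooks_range, species = species, observer = observer,
         area_weights = area_weights, area_boxes = area_boxes,
         target_probs = target_probs,
         weight_other_meanlog = weight_other_meanlog,
         weight_other_sdlog = weight_other_sdlog,
         seed = as.integer(seed)),
    class = "logbook_truth"
  )
}

# Boxes sit strictly inside each area's assignment region (half-open
# boundaries at 20E/26E and 33S), so the drawn area label is ground truth.
default_area_boxes <- function() {
  list(
    West      = list(lon = c(12.0, 19.99), lat = c(-32.99, -29.0)),
    Southwest = list(lon = c(12.0, 19.99), lat = c(-38.0, -33.01)),
    South     = list(lon = c(20.0, 25.99), lat = c(-38.0, -34.0)),
    East      = list(lon = c(26.0, 35.0),  lat = c(-36.0, -27.5))
  )
}

#' @export
print.logbook_truth <- function(x, ...) {
  cat("<logbook_truth>\n")
  cat(sprintf("  sets: %d across years %d-%d\n", x$n_sets,
              min(x$years), max(x$years)))
  cat(sprintf("  vessels: %d local, %d foreign (P[foreign set] = %.2f)\n",
              x$n_vessels_by_fleet[["local"]],
              x$n_vessels_by_fleet[["foreign"]], x$p_foreign))
  cat(sprintf("  species: %s\n", paste(names(x$species), collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
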