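# Shared fixtures: compact truth builders, a hand-rolled valid logbook
# row, and independent brute-force oracles used against the package's
# vectorised implementations.

# A truth object with both species sharing one simplified parameter set;
# effects default to zero so tests switch on exactly what they probe.
sim_truth <- function(n_sets, nv_local = 3, nv_foreign = 3, p_foreign = 0.5,
                      years = 2000:2003,
                      b_int = 0.5, b_year = NULL, b_month = NULL,
                      b_fleet = NULL, b_obs = NULL, sigma_b = 0,
                      g_int = log(15), g_year = NULL, g_month = NULL,
                      g_fleet = NULL, g_obs = NULL, sigma_g = 0,
                      shape = 2, seed = 1L, ...) {
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  sp <- species_params(
    beta_binomial = drop_null(list(intercept = b_int, year = b_year,
                                   month = b_month, fleet = b_fleet,
                                   observer = b_obs)),
    beta_gamma = drop_null(list(intercept = g_int, year = g_year,
                                month = g_month, fleet = g_fleet,
                                observer = g_obs)),
    sigma_vessel_binomial = sigma_b, sigma_vessel_gamma = sigma_g,
    gamma_shape = shape
  )
  logbook_truth(n_sets = n_sets, years = years,
                n_vessels_by_fleet = c(local = nv_local, foreign = nv_foreign),
                p_foreign = p_foreign,
                species = list(blue = sp, mako = sp), seed = seed, ...)
}

# One fully valid logbook row with overridable fields.
valid_record <- function(n = 1, year = 2005, month = 6, day = 10,
                         vessel_id = "L001", fleet = "local",
                         observer = "no", latitude = -35, longitude = 22,
                         hooks = 1282, count_blue = 5, count_mako = 2,
                         weight_blue = 52.5, weight_mako = 42,
                         weight_other = 300, target = "tuna") {
  data.frame(set_id = sprintf("T%04d", seq_len(n)), year = year,
             month = month, day = day, vessel_id = vessel_id, fleet = fleet,
             observer = observer, latitude = latitude, longitude = longitude,
             hooks = hooks, count_blue = count_blue, count_mako = count_mako,
             weight_blue = weight_blue, weight_mako = weight_mako,
             weight_other = weight_other, target = target,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Brute-force per-point area classifier, written as plain nested ifs so it
# shares nothing with assign_area()'s vectorised logic.
bf_area <- function(lat, lon) {
  if (lon < 10 || lon >= 36.5 || lat < -40) return(NA_character_)
  if (lon < 20) {
    if (lat > -28.6) return(NA_character_)
    if (lat >= -33) return("West") else return("Southwest")
  }
  if (lat > -26.85) return(NA_character_)
  if (lon < 26) return("South")
  "East"
}

# Brute-force cleaning: first failing rule per record in the fixed
# attribution order, independent of evaluate_rules().
bf_first_fail <- function(rec, year_range = c(2000, 2015),
                          hooks_range = c(310, 3800), cap = 801) {
  req <- c("set_id", "year", "month", "day", "vessel_id", "fleet",
           "observer", "latitude", "longitude", "hooks", "count_blue",
           "count_mako", "weight_blue", "weight_mako", "weight_other")
  if (any(vapply(req, function(f) is.na(rec[[f]]), logical(1)))) {
    return("missing_field")
  }
  if (rec$year < year_range[1] || rec$year > year_range[2]) return("year")
  if (is.na(bf_area(rec$latitude, rec$longitude))) return("position")
  if (rec$hooks < hooks_range[1] || rec$hooks > hooks_range[2]) return("hooks")
  if (rec$count_blue > cap || rec$count_mako > cap) return("count_cap")
  if (rec$count_blue + rec$count_mako >= rec$hooks) return("sharks_vs_hooks")
  NA_character_
}
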