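#' Simulate a set-by-set longline logbook with known ground truth
#'
#' Draws a logbook under the exact probabilistic inverse of the two-part
#' (delta) catch model fitted downstream: per set, a Bernoulli encounter
#' indicator with probability `plogis(linear predictor)` on the logit
#' scale, and, conditional on an encounter, a positive CPUE (sharks per
#' 1,000 hooks) from a gamma distribution with mean `exp(linear
#' predictor)` and the species' constant shape. Retained counts are
#' back-derived as `round(CPUE * hooks / 1000)` and coerced to at least 1
#' on an encounter, since an encounter must be visible in a retained-count
#' logbook. Vessel random intercepts are drawn once per vessel, per
#' species, per model part, from centred normals with the truth's SDs.
#'
#' @param truth a [logbook_truth()] object; `truth$seed` fixes the RNG, so
#'   identical truths generate byte-identical tables.
#' @return a list with `records` (data.frame, one row per set with the
#'   logbook schema columns plus a generator-truth `area` label) and
#'   `truth` (the input, augmented with the realised per-vessel intercepts
#'   in `$vessel_effects`).
#' @examples
#' sim <- generate_logbook(logbook_truth(n_sets = 100, seed = 7))
#' head(sim$records)
#' @export
generate_logbook <- function(truth) {
  if (!inherits(truth, "logbook_truth")) {
    stop_config("`truth` must be a logbook_truth object")
  }
  n <- truth$n_sets
  if (n == 0L) {
    return(list(records = empty_logbook(names(truth$species)), truth = truth))
  }
  with_seed(truth$seed, {
    fleet <- ifelse(stats::runif(n) < truth$p_foreign, "foreign", "local")
    vessel_pool <- list(
      local = sprintf("L%03d", seq_len(truth$n_vessels_by_fleet[["local"]])),
      foreign = sprintf("F%03d", seq_len(truth$n_vessels_by_fleet[["foreign"]]))
    )
    vessel_id <- character(n)
    for (fl in c("local", "foreign")) {
      idx <- fleet == fl
      vessel_id[idx] <- sample(vessel_pool[[fl]], sum(idx), replace = TRUE)
    }

    year <- sample(truth$years, n, replace = TRUE)
    month <- sample(1:12, n, replace = TRUE)
    day <- sample(1:28, n, replace = TRUE)

    areas <- names(truth$area_weights)
    area <- sample(areas, n, replace = TRUE, prob = truth$area_weights)
    latitude <- longitude <- numeric(n)
    for (a in areas) {
      idx <- area == a
      box <- truth$area_boxes[[a]]
      longitude[idx] <- stats::runif(sum(idx), box$lon[1], box$lon[2])
      latitude[idx] <- stats::runif(sum(idx), box$lat[1], box$lat[2])
    }

    hooks <- integer(n)
    for (fl in c("local", "foreign")) {
      idx <- fleet == fl
      ms <- truth$hooks_mean_sd_by_fleet[[fl]]
      hooks[idx] <- as.integer(round(rtruncnorm(sum(idx), ms[1], ms[2],
                                                truth$hooks_range[1],
                                                truth$hooks_range[2])))
    }
    hooks <- pmin(pmax(hooks, as.integer(truth$hooks_range[1])),
                  as.integer(truth$hooks_range[2]))

    observer <- character(n)
    obs_cfg <- truth$observer
    draw_obs <- function(p, k) sample(names(p), k, replace = TRUE, prob = p)
    idx <- fleet == "local"
    observer[idx] <- draw_obs(obs_cfg$local, sum(idx))
    idx <- fleet == "foreign" & year < obs_cfg$post_year
    observer[idx] <- draw_obs(obs_cfg$foreign_pre, sum(idx))
    idx <- fleet == "foreign" & year >= obs_cfg$post_year
    observer[idx] <- draw_obs(obs_cfg$foreign_post, sum(idx))

    target <- character(n)
    for (fl in c("local", "foreign")) {
      idx <- fleet == fl
      p <- truth$target_probs[[fl]]
      target[idx] <- sample(names(p), sum(idx), replace = TRUE, prob = p)
    }

    records <- data.frame(
      set_id = sprintf("S%06d", seq_len(n)), year = year, month = month,
      day = day, vessel_id = vessel_id, fleet = fleet, observer = observer,
      latitude = latitude, longitude = longitude, hooks = hooks,
      stringsAsFactors = FALSE
    )

    vessel_effects <- list()
    all_vessels <- c(vessel_pool$local, vessel_pool$foreign)
    for (sp in names(truth$species)) {
      pars <- truth$species[[sp]]
      b_bin <- stats::setNames(
        stats::rnorm(length(all_vessels), 0, pars$sigma_vessel_binomial),
        all_vessels)
      b_gam <- stats::setNames(
        stats::rnorm(length(all_vessels), 0, pars$sigma_vessel_gamma),
        all_vessels)
      vessel_effects[[sp]] <- list(binomial = b_bin, gamma = b_gam)

      eta_b <- linear_predictor(pars$beta_binomial, records) +
        unname(b_bin[vessel_id])
      encounter <- stats::runif(n) < stats::plogis(eta_b)

      eta_g <- linear_predictor(pars$beta_gamma, records) +
        unname(b_gam[vessel_id])
      mu <- exp(eta_g)
      cpue <- stats::rgamma(n, shape = pars$gamma_shape,
                            rate = pars$gamma_shape / mu)
      count <- as.integer(round(cpue * hooks / 1000))
      count[encounter & count == 0L] <- 1L
      count[!encounter] <- 0L

      sdlog <- sqrt(log(1 + pars$weight_cv^2))
      w_ind <- pars$mean_weight_kg *
        stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      weight <- ifelse(count > 0L, round(count * w_ind, 1), 0)

      records[[paste0("count_", sp)]] <- count
      records[[paste0("weight_", sp)]] <- weight
    }

    records$weight_other <- round(stats::rlnorm(
      n, meanlog = truth$weight_other_meanlog[fleet],
      sdlog = truth$weight_other_sdlog), 1)
    records$target <- target
    records$area <- area

    truth$vessel_effects <- vessel_effects
    list(records = records[, c(required_logbook_fields, "area")],
         truth = truth)
  })
}

# Reference-coded linear predictor for one model part.
linear_predictor <- function(beta, records) {
  eta <- rep(beta$intercept, nrow(records))
  lookup <- function(map, values) {
    if (is.null(map)) return(0)
    v <- map[as.character(values)]
    v[is.na(v)] <- 0
    unname(v)
  }
  eta <- eta + lookup(beta$year, records$year)
  eta <- eta + lookup(beta$month, records$month)
  eta <- eta + lookup(beta$fleet, records$fleet)
  eta + lookup(beta$observer, records$observer)
}

empty_logbook <- function(species = c("blue", "mako")) {
  df <- data.frame(
    set_id = character(0), year = integer(0), month = integer(0),
    day = integer(0), vessel_id = character(0), fleet = character(0),
    observer = character(0), latitude = numeric(0), longitude = numeric(0),
    hooks = integer(0), count_blue = integer(0), count_mako = integer(0),
    weight_blue = numeric(0), weight_mako = numeric(0),
    weight_other = numeric(0), target = character(0), area = character(0),
    stringsAsFactors = FALSE
  )
  df
}

#' Inject anomalous records for exercising the cleaning rules
#'
#' Corrupts disjoint, randomly chosen subsets of records, one subset per
#' anomaly class, mimicking the defect classes that logbook cleaning must
#' reject: positions outside the study region, out-of-range dates or
#' effort, implausibly large counts, more sharks than hooks, and missing
#' required fields.
#'
#' @param records a logbook data.frame.
#' @param rates named numeric vector or list mapping a subset of
#'   `c("position_out_of_region", "year_out_of_range", "hooks_out_of_range",
#'   "count_over_cap", "sharks_ge_hooks", "missing_field")` to the fraction
#'   of records to corrupt (each in `[0, 1]`, jointly at most 1).
#' @param seed RNG seed; corruption is deterministic given the seed.
#' @return list with `records` (corrupted copy) and `corrupted_ids` (named
#'   list of `set_id`s per class, for oracle tests).
#' @export
inject_anomalies <- function(records, rates, seed = 1L) {
  assert_logbook(records)
  rates <- unlist(rates)
  classes <- c("position_out_of_region", "year_out_of_range",
               "hooks_out_of_range", "count_over_cap", "sharks_ge_hooks",
               "missing_field")
  if (length(rates)) {
    bad <- setdiff(names(rates), classes)
    if (length(bad)) stop_config("unknown anomaly class(es): %s",
                                 paste(bad, collapse = ", "))
    if (any(rates < 0 | rates > 1)) stop_config("anomaly rates must be in [0, 1]")
    if (sum(rates) > 1 + 1e-12) {
      stop_config("total corruption fraction %.3f exceeds 1", sum(rates))
    }
  }
  n <- nrow(records)
  counts <- vapply(rates, function(r) as.integer(round(r * n)), integer(1))
  if (!length(counts) || sum(counts) == 0L) {
    return(list(records = records,
                corrupted_ids = stats::setNames(list(), character(0))))
  }
  with_seed(seed, {
    pool <- sample.int(n, sum(counts))          # disjoint across classes
    offset <- 0L
    corrupted <- list()
    for (cls in names(counts)) {
      k <- counts[[cls]]
      if (k == 0L) next
      idx <- pool[(offset + 1L):(offset + k)]
      offset <- offset + k
      records <- corrupt_records(records, idx, cls)
      corrupted[[cls]] <- records$set_id[idx]
    }
    list(records = records, corrupted_ids = corrupted)
  })
}

corrupt_records <- function(records, idx, cls) {
  k <- length(idx)
  switch(cls,
    position_out_of_region = {
      records$latitude[idx] <- stats::runif(k, 5, 15)    # north of the region
      records
    },
    year_out_of_range = {
      records$year[idx] <- sample(c(1996:1999, 2016:2019), k, replace = TRUE)
      records
    },
    hooks_out_of_range = {
      low <- sample(c(TRUE, FALSE), k, replace = TRUE)
      records$hooks[idx] <- ifelse(low, sample(50:309, k, replace = TRUE),
                                   sample(3801:6000, k, replace = TRUE))
      records
    },
    count_over_cap = {
      # keep hooks in range but ensure count exceeds the 801 cap while
      # staying below hooks, so only the cap rule fires
      small <- idx[records$hooks[idx] < 1000L]
      records$hooks[small] <- 3000L
      records$count_mako[idx] <- 0L
      records$count_blue[idx] <- vapply(records$hooks[idx], function(h) {
        sample(802:(h - 1L), 1L)
      }, integer(1))
      records
    },
    sharks_ge_hooks = {
      records$count_blue[idx] <- records$hooks[idx] +
        sample(0:100, k, replace = TRUE)
      records
    },
    missing_field = {
      field <- sample(c("hooks", "latitude", "month"), k, replace = TRUE)
      for (f in unique(field)) {
        records[[f]][idx[field == f]] <- NA
      }
      records
    },
    stop_config("unknown anomaly class '%s'", cls)
  )
}
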