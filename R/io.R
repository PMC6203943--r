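#' Read and write logbook tables
#'
#' Logbooks are exchanged as plain UTF-8 CSV with '.' as the decimal
#' separator and one row per longline set; columns are the logbook schema
#' fields (`set_id`, `year`, `month`, `day`, `vessel_id`, `fleet`,
#' `observer`, `latitude`, `longitude`, `hooks`, `count_blue`,
#' `count_mako`, `weight_blue`, `weight_mako`, `weight_other`, `target`)
#' plus any derived columns such as `area` and `rfmo`.
#'
#' @param records a logbook data.frame.
#' @param path file path.
#' @return `read_logbook` returns the logbook data.frame;
#'   `write_logbook` returns `path` invisibly.
#' @export
write_logbook <- function(records, path) {
  assert_logbook(records)
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_logbook
#' @export
read_logbook <- function(path) {
  records <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    na.strings = c("", "NA")),
    error = function(e) stop_config("cannot parse logbook CSV '%s': %s",
                                    path, conditionMessage(e))
  )
  assert_logbook(records)
  num_cols <- c("year", "month", "day", "latitude", "longitude", "hooks",
                "count_blue", "count_mako", "weight_blue", "weight_mako",
                "weight_other")
  for (col in num_cols) {
    suppressWarnings(v <- as.numeric(records[[col]]))
    bad <- which(is.na(v) & !is.na(records[[col]]))
    if (length(bad)) {
      stop_config("logbook CSV '%s': non-numeric value in column '%s' at row %d",
                  path, col, bad[1])
    }
    records[[col]] <- v
  }
  records
}

#' Save or load generator ground truth as a JSON sidecar
#'
#' The full parameter set of a [logbook_truth()] (including any realised
#' vessel effects) is serialised so that simulated datasets can travel with
#' their data-generating truth for recovery tests.
#'
#' @param truth a [logbook_truth()] object.
#' @param path file path of the JSON sidecar.
#' @return `read_truth` returns the `logbook_truth`; `write_truth` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  if (!inherits(truth, "logbook_truth")) {
    stop_config("`truth` must be a logbook_truth object")
  }
  # named atomic vectors must serialise as JSON objects, not bare arrays
  to_jsonable <- function(x) {
    if (inherits(x, "species_params")) x <- unclass(x)
    if (is.list(x)) lapply(x, to_jsonable)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  out <- to_jsonable(unclass(truth))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_named <- function(x) if (is.list(x)) unlist(x) else x
  species <- lapply(raw$species, function(sp) {
    species_params(
      beta_binomial = lapply(sp$beta_binomial, num_named),
      beta_gamma = lapply(sp$beta_gamma, num_named),
      sigma_vessel_binomial = sp$sigma_vessel_binomial,
      sigma_vessel_gamma = sp$sigma_vessel_gamma,
      gamma_shape = sp$gamma_shape,
      mean_weight_kg = sp$mean_weight_kg,
      weight_cv = sp$weight_cv
    )
  })
  truth <- logbook_truth(
    n_sets = raw$n_sets, years = raw$years,
    n_vessels_by_fleet = unlist(raw$n_vessels_by_fleet),
    p_foreign = raw$p_foreign,
    hooks_mean_sd_by_fleet = lapply(raw$hooks_mean_sd_by_fleet, unlist),
    hooks_range = unlist(raw$hooks_range), species = species,
    observer = c(lapply(raw$observer[c("local", "foreign_pre", "foreign_post")],
                        unlist),
                 list(post_year = raw$observer$post_year)),
    area_weights = unlist(raw$area_weights),
    area_boxes = lapply(raw$area_boxes, function(b) lapply(b, unlist)),
    target_probs = lapply(raw$target_probs, unlist),
    weight_other_meanlog = unlist(raw$weight_other_meanlog),
    weight_other_sdlog = raw$weight_other_sdlog,
    seed = raw$seed
  )
  if (!is.null(raw$vessel_effects)) {
    truth$vessel_effects <- lapply(raw$vessel_effects, function(sp)
      lapply(sp, num_named))
  }
  truth
}
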