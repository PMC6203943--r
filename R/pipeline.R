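#' Configuration for an end-to-end standardization run
#'
#' Collects every tunable of the pipeline: the RNG seed, the input (a
#' logbook CSV path, or a [logbook_truth()] to simulate from), cleaning
#' rules, area scheme, model options and the species/areas to analyse.
#'
#' @param seed integer seed fixed before any stochastic step.
#' @param input path to a logbook CSV, or `NULL` to simulate.
#' @param truth a [logbook_truth()] used when `input` is `NULL`.
#' @param cleaning a [cleaning_rules()] object.
#' @param scheme an [area_scheme()].
#' @param model list of model options: `stepwise` (logical),
#'   `candidate_terms`, `fixed_terms` (used when `stepwise = FALSE`),
#'   `policy` (prediction policy), `bias_correct`, `ratio_threshold`,
#'   `min_sets` and `min_positive` (minimum data for fitting an area).
#' @param species species to analyse.
#' @param areas analysis areas to fit.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, input = NULL, truth = NULL,
                       cleaning = cleaning_rules(), scheme = area_scheme(),
                       model = list(), species = c("blue", "mako"),
                       areas = c("West", "Southwest", "South", "East")) {
  defaults <- list(stepwise = TRUE,
                   candidate_terms = c("month", "fleet", "observer"),
                   fixed_terms = c("year", "month", "fleet", "observer"),
                   policy = "reference", bias_correct = FALSE,
                   ratio_threshold = 3, min_sets = 100, min_positive = 50)
  model <- utils::modifyList(defaults, model)
  if (is.null(input) && is.null(truth)) truth <- logbook_truth(seed = seed)
  if (!is.null(input) && !file.exists(input)) {
    stop_config("input logbook '%s' does not exist", input)
  }
  structure(list(seed = as.integer(seed), input = input, truth = truth,
                 cleaning = cleaning, scheme = scheme, model = model,
                 species = species, areas = areas),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised top-level keys: `seed`, `input`, `truth_file` (JSON sidecar
#' from [write_truth()]), `cleaning` (arguments of [cleaning_rules()]),
#' `scheme` (arguments of [area_scheme()]), `model`, `species`, `areas`.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scheme <- do.call(area_scheme, y$scheme %||% list())
  cleaning_args <- y$cleaning %||% list()
  for (k in c("year_range", "hooks_range")) {
    if (!is.null(cleaning_args[[k]])) cleaning_args[[k]] <- unlist(cleaning_args[[k]])
  }
  cleaning_args$scheme <- scheme
  truth <- if (!is.null(y$truth_file)) read_truth(y$truth_file) else NULL
  model <- y$model %||% list()
  if (!is.null(model$candidate_terms)) model$candidate_terms <- unlist(model$candidate_terms)
  if (!is.null(model$fixed_terms)) model$fixed_terms <- unlist(model$fixed_terms)
  run_config(seed = y$seed %||% 1L, input = y$input, truth = truth,
             cleaning = do.call(cleaning_rules, cleaning_args),
             scheme = scheme, model = model,
             species = unlist(y$species %||% c("blue", "mako")),
             areas = unlist(y$areas %||% c("West", "Southwest", "South", "East")))
}

pipeline_log <- function(path, stage, fmt, ...) {
  line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, sprintf(fmt, ...))
  cat(line, "\n", sep = "", file = path, append = TRUE)
  message(line)
}

summarize_fit <- function(fit) {
  list(part = fit$spec$part, species = fit$spec$species,
       area = fit$spec$area, fixed_terms = fit$spec$fixed_terms,
       random = fit$spec$random,
       coefficients = as.list(fit$coefficients),
       se = as.list(sqrt(pmax(0, diag(fit$covariance)))),
       sigma_vessel = fit$sigma_vessel, shape = fit$shape,
       loglik = fit$loglik, bic = fit$bic, n_obs = fit$n_obs,
       n_par = fit$n_par, converged = fit$converged,
       warnings = fit$warnings)
}

#' Run the full standardization pipeline
#'
#' Executes simulate/ingest, clean, stratify, fit (per species and area:
#' binomial and gamma submodels, with forward BIC selection over the
#' candidate terms), index construction and descriptive reporting,
#' writing every artifact into `out_dir`. Stages never mutate earlier
#' outputs; a failing stage halts with a stage-named error and partial
#' outputs are retained for inspection. Given the same configuration and
#' seed the run is reproducible.
#'
#' Areas with too little data for a species (fewer than
#' `model$min_sets` sets, fewer than `model$min_positive` positive sets,
#' or fewer than two year levels) yield an explicit insufficient-data
#' record in `index_status.json` instead of an index series.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @return invisibly, a list with the cleaning report, fits, index series
#'   and report tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) stop_config("`config` must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "log.txt")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  records <- stage("ingest", {
    if (is.null(config$input)) {
      truth <- config$truth
      truth$seed <- config$seed
      sim <- generate_logbook(truth)
      write_logbook(sim$records, file.path(out_dir, "logbook.csv"))
      write_truth(sim$truth, file.path(out_dir, "truth.json"))
      pipeline_log(log_file, "simulate", "generated %d sets", nrow(sim$records))
      sim$records
    } else {
      recs <- read_logbook(config$input)
      pipeline_log(log_file, "ingest", "read %d sets from %s", nrow(recs),
                   config$input)
      recs
    }
  })

  report <- stage("clean", {
    rep <- clean_records(records, config$cleaning)
    write_logbook(rep$retained, file.path(out_dir, "cleaned.csv"))
    write_cleaning_report(rep, file.path(out_dir, "cleaning_report.json"),
                          quarantine_csv = file.path(out_dir, "quarantine.csv"))
    pipeline_log(log_file, "clean", "retained %d of %d sets (%.1f%%)",
                 rep$n_retained, rep$n_input, 100 * rep$retained_fraction)
    rep
  })

  cleaned <- stage("stratify", {
    strat <- add_strata(report$retained, config$scheme)
    write_logbook(strat, file.path(out_dir, "stratified.csv"))
    pipeline_log(log_file, "stratify", "areas: %s",
                 paste(sprintf("%s=%d", names(table(strat$area)),
                               table(strat$area)), collapse = ", "))
    strat
  })

  fits <- list()
  series_list <- list()
  status <- list()
  for (sp in config$species) {
    for (a in config$areas) {
      key <- paste(sp, a, sep = "_")
      sub <- cleaned[!is.na(cleaned$area) & cleaned$area == a, , drop = FALSE]
      pos <- sub[sub[[paste0("count_", sp)]] > 0, , drop = FALSE]
      if (nrow(sub) < config$model$min_sets ||
          nrow(pos) < config$model$min_positive ||
          length(unique(sub$year)) < 2L ||
          length(unique(pos$year)) < 2L) {
        status[[key]] <- list(species = sp, area = a,
                              status = "insufficient data",
                              n_sets = nrow(sub), n_positive = nrow(pos))
        pipeline_log(log_file, "fit", "%s/%s: insufficient data (%d sets, %d positive)",
                     sp, a, nrow(sub), nrow(pos))
        next
      }
      res <- stage(paste0("fit:", key), {
        if (isTRUE(config$model$stepwise)) {
          sb <- stepwise_select(sub, "binomial",
                                config$model$candidate_terms, sp, a)
          sg <- stepwise_select(pos, "gamma",
                                config$model$candidate_terms, sp, a)
          utils::write.csv(rbind(cbind(part = "binomial", sb$table),
                                 cbind(part = "gamma", sg$table)),
                           file.path(out_dir, sprintf("bic_table_%s.csv", key)),
                           row.names = FALSE)
          list(binomial = sb$best, gamma = sg$best)
        } else {
          list(
            binomial = fit_binomial_glmm(
              sub, model_spec("binomial", sp, config$model$fixed_terms,
                              random = TRUE, area = a)),
            gamma = fit_gamma_glmm(
              pos, model_spec("gamma", sp, config$model$fixed_terms,
                              random = TRUE, area = a))
          )
        }
      })
      fits[[key]] <- res
      jsonlite::write_json(
        list(binomial = summarize_fit(res$binomial),
             gamma = summarize_fit(res$gamma)),
        file.path(out_dir, sprintf("fit_%s.json", key)),
        auto_unbox = TRUE, digits = NA, null = "null")
      pipeline_log(log_file, "fit", "%s/%s: binomial BIC %.1f, gamma BIC %.1f",
                   sp, a, res$binomial$bic, res$gamma$bic)

      idx <- stage(paste0("index:", key), {
        predict_year_effects(res$binomial, res$gamma,
                             policy = config$model$policy,
                             bias_correct = isTRUE(config$model$bias_correct),
                             ratio_threshold = config$model$ratio_threshold)
      })
      series_list[[key]] <- idx
      write_index_series(idx, file.path(out_dir, sprintf("index_%s.csv", key)))
      status[[key]] <- list(species = sp, area = a, status = "ok",
                            n_sets = nrow(sub), n_positive = nrow(pos),
                            n_years = nrow(idx),
                            n_flagged = sum(idx$anomaly_flag))
      pipeline_log(log_file, "index", "%s/%s: %d years, %d flagged",
                   sp, a, nrow(idx), sum(idx$anomaly_flag))
    }
  }
  jsonlite::write_json(status, file.path(out_dir, "index_status.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (length(series_list)) {
    all_series <- do.call(rbind, lapply(series_list, as.data.frame))
    utils::write.csv(all_series, file.path(out_dir, "index.csv"),
                     row.names = FALSE)
  }

  tables <- stage("report", {
    tabs <- list(
      effort_by_year = effort_summary(cleaned, "year"),
      effort_by_month = effort_summary(cleaned, "month"),
      effort_by_fleet = effort_summary(cleaned, "fleet"),
      shark_ratio = shark_ratio(cleaned, c("year", "fleet")),
      composition = composition(cleaned, by = "fleet")
    )
    for (nm in names(tabs)) {
      utils::write.csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    pipeline_log(log_file, "report", "wrote %d summary tables", length(tabs))
    tabs
  })

  invisible(list(cleaning = report, fits = fits, index = series_list,
                 status = status, tables = tables, out_dir = out_dir))
}
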