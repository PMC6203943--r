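#' Record-validity rules for logbook cleaning
#'
#' The filters retain sets with: dates inside the study period (2000-2015
#' by default), fishing effort of 310-3,800 hooks per line (inclusive), at
#' most 801 retained blue sharks or shortfin makos per set (inclusive;
#' optionally applied to the combined total), strictly fewer sharks (both
#' species combined) than hooks, a setting position inside the study
#' region, and no missing required field. The missing/mismatch rule also
#' stands in for upstream checks on fields (depth, set duration) that are
#' not modelled here.
#'
#' @param year_range inclusive `c(min, max)` calendar years.
#' @param hooks_range inclusive `c(min, max)` hooks per line.
#' @param count_cap maximum retained sharks per set (inclusive).
#' @param cap_scope `"per_species"` (default) applies `count_cap` to each
#'   species separately; `"combined"` applies it to their sum.
#' @param scheme [area_scheme()] defining the study region for the
#'   position filter.
#' @return object of class `cleaning_rules`.
#' @export
cleaning_rules <- function(year_range = c(2000, 2015),
                           hooks_range = c(310, 3800),
                           count_cap = 801,
                           cap_scope = c("per_species", "combined"),
                           scheme = area_scheme()) {
  cap_scope <- match.arg(cap_scope)
  if (year_range[1] > year_range[2]) stop_config("year_range: min > max")
  if (hooks_range[1] > hooks_range[2]) stop_config("hooks_range: min > max")
  if (count_cap < 0) stop_config("count_cap must be non-negative")
  structure(list(year_range = year_range, hooks_range = hooks_range,
                 count_cap = count_cap, cap_scope = cap_scope,
                 scheme = scheme),
            class = "cleaning_rules")
}

# Fixed attribution order: a record failing several rules is tallied once,
# under the first failing rule.
cleaning_rule_order <- c("missing_field", "year", "position", "hooks",
                         "count_cap", "sharks_vs_hooks")

# Per-rule pass indicators (NA-safe: NA fields fail missing_field and are
# treated as passes elsewhere so attribution stays with the first rule).
evaluate_rules <- function(records, rules) {
  req <- setdiff(required_logbook_fields, c("target"))  # target not modelled
  missing_any <- Reduce(`|`, lapply(req, function(f) is.na(records[[f]])))
  if (length(missing_any) == 0L) missing_any <- logical(0)
  safe <- function(x) ifelse(is.na(x), TRUE, x)
  pos_ok <- rep(TRUE, nrow(records))
  has_pos <- !is.na(records$latitude) & !is.na(records$longitude)
  if (any(has_pos)) {
    pos_ok[has_pos] <- in_study_region(records$latitude[has_pos],
                                       records$longitude[has_pos],
                                       rules$scheme)
  }
  cap_ok <- if (rules$cap_scope == "per_species") {
    safe(records$count_blue <= rules$count_cap) &
      safe(records$count_mako <= rules$count_cap)
  } else {
    safe(records$count_blue + records$count_mako <= rules$count_cap)
  }
  list(
    missing_field = !missing_any,
    year = safe(records$year >= rules$year_range[1] &
                  records$year <= rules$year_range[2]),
    position = pos_ok,
    hooks = safe(records$hooks >= rules$hooks_range[1] &
                   records$hooks <= rules$hooks_range[2]),
    count_cap = cap_ok,
    sharks_vs_hooks = safe(records$count_blue + records$count_mako <
                             records$hooks)
  )
}

#' Apply the logbook cleaning filters
#'
#' Retains exactly the records passing every rule in [cleaning_rules()]
#' and produces an auditable report: input/retained counts, the retained
#' fraction, and per-rule rejection tallies under a fixed attribution
#' order (`missing_field`, `year`, `position`, `hooks`, `count_cap`,
#' `sharks_vs_hooks`), so a record failing several rules is counted once.
#'
#' @param records logbook data.frame.
#' @param rules a [cleaning_rules()] object.
#' @return object of class `cleaning_report`: list with `n_input`,
#'   `n_retained`, `retained_fraction` (0 for empty input by convention),
#'   `rejections_by_rule` (named integer vector over the rule order),
#'   `retained` (cleaned data.frame) and `rejected` (rejected rows with a
#'   `rejected_by` column, suitable for a quarantine CSV).
#' @examples
#' sim <- generate_logbook(logbook_truth(n_sets = 50, seed = 1))
#' rep <- clean_records(sim$records, cleaning_rules())
#' rep$retained_fraction
#' @export
clean_records <- function(records, rules = cleaning_rules()) {
  assert_logbook(records)
  n <- nrow(records)
  pass <- evaluate_rules(records, rules)
  first_fail <- rep(NA_character_, n)
  for (rule in rev(cleaning_rule_order)) {
    first_fail[!pass[[rule]]] <- rule
  }
  keep <- is.na(first_fail)
  tallies <- stats::setNames(integer(length(cleaning_rule_order)),
                             cleaning_rule_order)
  tab <- table(first_fail[!keep])
  tallies[names(tab)] <- as.integer(tab)
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$rejected_by <- first_fail[!keep]
  structure(
    list(n_input = n, n_retained = sum(keep),
         retained_fraction = if (n == 0L) 0 else sum(keep) / n,
         rejections_by_rule = tallies,
         retained = records[keep, , drop = FALSE],
         rejected = rejected, rules = rules),
    class = "cleaning_report"
  )
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat(sprintf("  input: %d sets; retained: %d (%.1f%%)\n", x$n_input,
              x$n_retained, 100 * x$retained_fraction))
  rej <- x$rejections_by_rule[x$rejections_by_rule > 0]
  if (length(rej)) {
    cat("  rejections:\n")
    for (nm in names(rej)) cat(sprintf("    %-16s %d\n", nm, rej[[nm]]))
  }
  invisible(x)
}

#' Serialise a cleaning report
#'
#' Writes the audit counts to JSON and, optionally, the rejected rows to a
#' quarantine CSV.
#'
#' @param report a `cleaning_report`.
#' @param path JSON output path.
#' @param quarantine_csv optional path for the rejected rows.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path, quarantine_csv = NULL) {
  if (!inherits(report, "cleaning_report")) {
    stop_config("`report` must be a cleaning_report")
  }
  jsonlite::write_json(
    list(n_input = report$n_input, n_retained = report$n_retained,
         retained_fraction = report$retained_fraction,
         rejections_by_rule = as.list(report$rejections_by_rule)),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(quarantine_csv) && nrow(report$rejected)) {
    utils::write.csv(report$rejected, quarantine_csv, row.names = FALSE,
                     na = "")
  }
  invisible(path)
}
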