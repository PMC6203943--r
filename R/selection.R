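#' Forward BIC selection of fixed effects
#'
#' Starting from the base model (year plus the vessel random intercept,
#' both always retained so an annual index can be extracted), candidate
#' terms are added one at a time; at each step the term lowering BIC the
#' most is included, and selection stops when no addition lowers BIC.
#' Fits that fail to converge are excluded from the comparison but
#' recorded in the evaluation table. The search is deterministic given
#' the data: error structure and link are fixed (binomial-logit,
#' gamma-log) and only fixed terms are searched.
#'
#' @param records the data for the part being fitted (all cleaned sets
#'   for the binomial part; the positive subset for the gamma part).
#' @param part `"binomial"` or `"gamma"`.
#' @param candidate_terms subset of `c("month", "fleet", "observer")`.
#' @param species shark species label.
#' @param area optional area label (metadata only).
#' @param control optimizer settings.
#' @return list with `best` (the selected `shark_glmm` fit), `spec` (its
#'   [model_spec()]) and `table`, a data.frame of every evaluated model
#'   (formula string, bic, loglik, converged, step, selected).
#' @export
stepwise_select <- function(records, part = c("binomial", "gamma"),
                            candidate_terms = c("month", "fleet", "observer"),
                            species = "blue", area = NULL,
                            control = glmm_control()) {
  part <- match.arg(part)
  if (length(candidate_terms) &&
      !all(candidate_terms %in% c("month", "fleet", "observer"))) {
    stop_config("candidate_terms must be a subset of month, fleet, observer")
  }
  fit_one <- function(terms) {
    spec <- model_spec(part, species, fixed_terms = terms, random = TRUE,
                       area = area)
    fit <- tryCatch(fit_glmm(records, spec, control), error = function(e) e)
    fit
  }
  describe <- function(terms) {
    paste0(if (part == "binomial") "presence" else "cpue", " ~ ",
           paste(terms, collapse = " + "), " + (1|vessel)")
  }
  current_terms <- "year"
  current <- fit_one(current_terms)
  if (inherits(current, "error")) {
    stop_config("base model failed to fit: %s", conditionMessage(current))
  }
  rows <- data.frame(model = describe(current_terms), bic = current$bic,
                     loglik = current$loglik, converged = current$converged,
                     step = 0L, selected = FALSE, stringsAsFactors = FALSE)
  remaining <- candidate_terms
  step <- 0L
  repeat {
    if (!length(remaining)) break
    step <- step + 1L
    trials <- lapply(remaining, function(term) fit_one(c(current_terms, term)))
    ok <- vapply(trials, function(f)
      inherits(f, "shark_glmm") && f$converged, logical(1))
    bics <- vapply(seq_along(trials), function(i)
      if (ok[i]) trials[[i]]$bic else NA_real_, numeric(1))
    rows <- rbind(rows, data.frame(
      model = vapply(remaining, function(t) describe(c(current_terms, t)),
                     character(1)),
      bic = bics,
      loglik = vapply(seq_along(trials), function(i)
        if (inherits(trials[[i]], "shark_glmm")) trials[[i]]$loglik
        else NA_real_, numeric(1)),
      converged = ok, step = step, selected = FALSE,
      stringsAsFactors = FALSE))
    if (!any(ok) || min(bics, na.rm = TRUE) >= current$bic) break
    pick <- which.min(bics)
    current <- trials[[pick]]
    current_terms <- c(current_terms, remaining[pick])
    remaining <- remaining[-pick]
  }
  rows$selected <- rows$model == describe(current_terms)
  list(best = current, spec = current$spec, table = rows)
}
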