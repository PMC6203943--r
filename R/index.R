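#' Back-transform a link-scale estimate and its standard error
#'
#' First-order delta method from the logit or log scale to the
#' observation scale: for the logit, `estimate = plogis(c)` with
#' `se * estimate * (1 - estimate)`; for the log, `estimate = exp(c)`
#' with `se * estimate`.
#'
#' @param coefficient estimate on the link scale.
#' @param se its standard error (>= 0).
#' @param link `"logit"` or `"log"`.
#' @return list with `estimate` and `se`.
#' @examples
#' backtransform(0, 0.5, "logit")  # estimate 0.5, se 0.125
#' @export
backtransform <- function(coefficient, se, link = c("logit", "log")) {
  link <- match.arg(link)
  if (any(se < 0)) stop_config("`se` must be non-negative")
  if (link == "logit") {
    est <- stats::plogis(coefficient)
    list(estimate = est, se = se * est * (1 - est))
  } else {
    est <- exp(coefficient)
    list(estimate = est, se = se * est)
  }
}

#' Propagate error through the product of the two submodel predictions
#'
#' The standardized index is the product of the back-transformed
#' encounter probability and positive-catch mean. The two submodels are
#' fit on disjoint information (presence/absence vs positive magnitude),
#' so the first-order delta method for a product of independent
#' estimates applies: `se = sqrt(mu^2 se_p^2 + p^2 se_mu^2)`.
#'
#' @param p encounter probability in `[0, 1]`.
#' @param se_p its standard error (>= 0).
#' @param mu positive-catch mean (> 0), sharks per 1,000 hooks.
#' @param se_mu its standard error (>= 0).
#' @return the standard error of `p * mu`.
#' @export
propagate_product_error <- function(p, se_p, mu, se_mu) {
  if (any(p < 0 | p > 1)) stop_config("`p` must be in [0, 1]")
  if (any(mu <= 0)) stop_config("`mu` must be positive")
  if (any(se_p < 0) || any(se_mu < 0)) stop_config("standard errors must be >= 0")
  sqrt(mu^2 * se_p^2 + p^2 * se_mu^2)
}

#' Flag anomalous year-on-year index increments
#'
#' Post-hoc screen for sudden changes of scale in an annual index: year
#' `t` is flagged when the index changes by more than `ratio_threshold`
#' fold relative to year `t - 1` in either direction. A small floor is
#' added to both values so near-zero indices do not produce unstable
#' ratios.
#'
#' @param series an `index_series` data.frame (uses `year` and `index`)
#'   or a numeric index vector in year order.
#' @param ratio_threshold flag when the fold change exceeds this (> 1).
#' @param floor additive stabiliser for near-zero indices.
#' @return data.frame with `year`, `ratio` (fold change from the previous
#'   year, always >= 1) and `direction` for each flagged year; zero rows
#'   when fewer than two years are supplied or nothing is flagged.
#' @examples
#' flag_anomalies(c(5, 5.2, 4, 191))  # the 4 -> 191 jump is flagged
#' @export
flag_anomalies <- function(series, ratio_threshold = 3, floor = 1e-6) {
  if (ratio_threshold <= 1) stop_config("`ratio_threshold` must be > 1")
  if (is.data.frame(series)) {
    ord <- order(series$year)
    idx <- series$index[ord]
    yrs <- series$year[ord]
  } else {
    idx <- as.numeric(series)
    yrs <- seq_along(idx)
  }
  empty <- data.frame(year = numeric(0), ratio = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (length(idx) < 2L) return(empty)
  prev <- idx[-length(idx)] + floor
  cur <- idx[-1] + floor
  up <- cur / prev
  down <- prev / cur
  ratio <- pmax(up, down)
  hit <- which(ratio > ratio_threshold)
  if (!length(hit)) return(empty)
  data.frame(year = yrs[hit + 1], ratio = ratio[hit],
             direction = ifelse(up[hit] >= down[hit], "increase", "decrease"),
             stringsAsFactors = FALSE)
}

# Prediction of one submodel's year effect on the response scale under a
# policy. "reference": all other categorical effects at their reference
# level and the random intercept at 0 (link-scale SE from the coefficient
# covariance, back-transformed by the delta method). "population": average
# the response-scale prediction over the observed joint distribution of
# the other factors, with the delta-method SE of the weighted average.
predict_submodel_years <- function(fit, policy, bias_correct = FALSE) {
  spec <- fit$spec
  if (!("year" %in% spec$fixed_terms) || is.null(fit$xlevels$year)) {
    stop_config("the %s fit does not contain a year effect", spec$part)
  }
  if (!fit$converged) {
    stop_config("the %s fit did not converge; refusing to build an index",
                spec$part)
  }
  link <- spec$link
  years <- fit$xlevels$year
  beta <- fit$coefficients
  V <- fit$covariance
  out <- data.frame(year = as.integer(years), estimate = NA_real_,
                    se = NA_real_)

  if (policy == "reference") {
    for (i in seq_along(years)) {
      cvec <- stats::setNames(numeric(length(beta)), names(beta))
      cvec["(Intercept)"] <- 1
      coef_name <- paste0("year", years[i])
      if (coef_name %in% names(beta)) cvec[coef_name] <- 1
      eta <- sum(cvec * beta)
      se_eta <- sqrt(max(0, drop(t(cvec) %*% V %*% cvec)))
      if (bias_correct && link == "log") {
        est <- exp(eta + se_eta^2 / 2)
        out$estimate[i] <- est
        out$se[i] <- se_eta * est
      } else {
        bt <- backtransform(eta, se_eta, link)
        out$estimate[i] <- bt$estimate
        out$se[i] <- bt$se
      }
    }
    return(out)
  }

  # population-average policy
  covars <- fit$covariate_data
  if (is.null(covars) || ncol(covars) == 0L) {
    combos <- data.frame(row.names = 1)
    weights <- 1
  } else {
    key <- do.call(paste, c(covars, sep = "\r"))
    first <- !duplicated(key)
    combos <- covars[first, , drop = FALSE]
    weights <- as.numeric(table(key)[key[first]])
  }
  terms_used <- fit$terms_used %||% spec$fixed_terms
  form <- if (length(terms_used)) stats::reformulate(terms_used) else ~ 1
  for (i in seq_along(years)) {
    newdata <- combos
    newdata$year <- factor(years[i], levels = fit$xlevels$year)
    Xc <- stats::model.matrix(form, newdata)
    Xc <- Xc[, names(beta), drop = FALSE]
    eta <- drop(Xc %*% beta)
    if (link == "logit") {
      resp <- stats::plogis(eta)
      dresp <- resp * (1 - resp)
    } else {
      resp <- exp(eta + if (bias_correct) diag(Xc %*% V %*% t(Xc)) / 2 else 0)
      dresp <- resp
    }
    w <- weights / sum(weights)
    out$estimate[i] <- sum(w * resp)
    grad <- drop(crossprod(Xc, w * dresp))
    out$se[i] <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
  }
  out
}

#' Standardized annual abundance index from the two fitted submodels
#'
#' Builds the standardized CPUE index by year as the product of the
#' back-transformed year predictions of the binomial (encounter
#' probability) and gamma (positive-catch mean) submodels, with the
#' delta-method standard error of the product, and flags anomalous
#' year-on-year increments post hoc.
#'
#' Two prediction policies are available for the non-year factors:
#' `"reference"` (default) evaluates each year at the reference cell
#' (January, foreign fleet, observer absent, random intercept 0);
#' `"population"` averages response-scale predictions over the observed
#' joint distribution of the other factors in each submodel's data.
#'
#' @param fit_binomial converged binomial `shark_glmm` containing year.
#' @param fit_gamma converged gamma `shark_glmm` containing year.
#' @param policy `"reference"` or `"population"`.
#' @param bias_correct apply the lognormal mean correction
#'   `exp(c + se^2/2)` when back-transforming from the log scale.
#' @param ratio_threshold fold-change threshold for [flag_anomalies()].
#' @return an `index_series` data.frame: `species`, `area`, `year`,
#'   `p_hat`, `se_p`, `mu_hat`, `se_mu`, `index = p_hat * mu_hat`
#'   (sharks per 1,000 hooks), `se_index`, `anomaly_flag`.
#' @export
predict_year_effects <- function(fit_binomial, fit_gamma,
                                 policy = c("reference", "population"),
                                 bias_correct = FALSE,
                                 ratio_threshold = 3) {
  policy <- match.arg(policy)
  if (fit_binomial$spec$part != "binomial" || fit_gamma$spec$part != "gamma") {
    stop_config("arguments must be the binomial and gamma fits, in that order")
  }
  pb <- predict_submodel_years(fit_binomial, policy)
  pg <- predict_submodel_years(fit_gamma, policy, bias_correct = bias_correct)
  years <- intersect(pb$year, pg$year)
  if (!length(years)) stop_config("the two fits share no year levels")
  pb <- pb[match(years, pb$year), ]
  pg <- pg[match(years, pg$year), ]
  series <- data.frame(
    species = fit_binomial$spec$species,
    area = fit_binomial$spec$area %||% NA_character_,
    year = years,
    p_hat = pb$estimate, se_p = pb$se,
    mu_hat = pg$estimate, se_mu = pg$se,
    stringsAsFactors = FALSE
  )
  series$index <- series$p_hat * series$mu_hat
  series$se_index <- propagate_product_error(series$p_hat, series$se_p,
                                             series$mu_hat, series$se_mu)
  flags <- flag_anomalies(series, ratio_threshold = ratio_threshold)
  series$anomaly_flag <- series$year %in% flags$year
  class(series) <- c("index_series", "data.frame")
  attr(series, "policy") <- policy
  series
}

#' Write an index series as tidy CSV
#'
#' @param series an `index_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_index_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
plot.index_series <- function(x, ...) {
  up <- x$index + x$se_index
  lo <- pmax(0, x$index - x$se_index)
  plot(x$year, x$index, type = "b", pch = 16, ylim = c(0, max(up)),
       xlab = "Year", ylab = "Sharks / 1,000 hooks",
       main = sprintf("%s%s", x$species[1],
                      if (!is.na(x$area[1])) paste0(" - ", x$area[1]) else ""),
       ...)
  graphics::arrows(x$year, lo, x$year, up, angle = 90, code = 3,
                   length = 0.03)
  if (any(x$anomaly_flag)) {
    graphics::points(x$year[x$anomaly_flag], x$index[x$anomaly_flag],
                     col = "red", pch = 1, cex = 2)
  }
  invisible(x)
}
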