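#' Catch per unit effort of a longline set
#'
#' CPUE is expressed throughout as retained sharks per 1,000 hooks:
#' `count * 1000 / hooks`.
#'
#' @param records logbook data.frame.
#' @param species `"blue"` or `"mako"` (any species with a
#'   `count_<species>` column).
#' @return numeric vector of CPUE values (0 for zero-catch sets).
#' @examples
#' compute_cpue(data.frame(count_blue = 10, hooks = 2000), "blue")  # 5
#' @export
compute_cpue <- function(records, species) {
  col <- paste0("count_", species)
  if (!col %in% names(records)) stop_config("no column '%s' in records", col)
  if (any(!is.na(records$hooks) & records$hooks <= 0)) {
    stop_config("hooks must be positive to define CPUE")
  }
  records[[col]] * 1000 / records$hooks
}

#' Specification of one hurdle submodel
#'
#' A submodel is either the binomial (logit link) presence/absence part or
#' the gamma (log link) positive-catch part, with reference-coded
#' categorical fixed effects drawn from year, month, fleet and observer,
#' and optionally a per-vessel random intercept. Year must be retained
#' whenever an annual index is to be extracted.
#'
#' @param part `"binomial"` or `"gamma"`.
#' @param species shark species label.
#' @param fixed_terms ordered subset of `c("year","month","fleet","observer")`.
#' @param random if `TRUE`, include a vessel random intercept.
#' @param area optional analysis-area label carried as metadata.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(part = c("binomial", "gamma"), species = "blue",
                       fixed_terms = c("year", "month", "fleet", "observer"),
                       random = TRUE, area = NULL) {
  part <- match.arg(part)
  allowed <- c("year", "month", "fleet", "observer")
  if (!length(fixed_terms) || !all(fixed_terms %in% allowed)) {
    stop_config("fixed_terms must be a non-empty subset of %s",
                paste(allowed, collapse = ", "))
  }
  structure(list(part = part,
                 link = if (part == "binomial") "logit" else "log",
                 species = species, fixed_terms = unique(fixed_terms),
                 random = isTRUE(random), area = area),
            class = "model_spec")
}

#' Parse a formula-like model string
#'
#' Accepts the compact syntax used in pipeline configs, e.g.
#' `"presence ~ year + month + fleet + (1|vessel)"` or
#' `"cpue ~ year + fleet"`. The response (`presence` or `cpue`) selects
#' the binomial or gamma part.
#'
#' @param text the model string.
#' @param species species label passed through to [model_spec()].
#' @param area optional area label.
#' @return a [model_spec()].
#' @export
parse_model_formula <- function(text, species = "blue", area = NULL) {
  sides <- strsplit(text, "~", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop_config("model string must contain '~': %s", text)
  lhs <- trimws(sides[1])
  part <- switch(lhs, presence = "binomial", cpue = "gamma",
                 stop_config("unknown response '%s' (use presence or cpue)", lhs))
  terms <- trimws(strsplit(sides[2], "+", fixed = TRUE)[[1]])
  random <- any(grepl("\\(\\s*1\\s*\\|\\s*vessel\\s*\\)", terms))
  fixed <- terms[!grepl("\\|", terms)]
  model_spec(part, species, fixed_terms = fixed, random = random, area = area)
}

# -- model frame -------------------------------------------------------------

# Treatment-coded design with first-level references (year = first year,
# month January, fleet foreign, observer no) per the variable orderings.
glmm_frame <- function(records, spec) {
  assert_logbook(records)
  df <- data.frame(
    year = factor(records$year, levels = sort(unique(records$year))),
    month = factor(records$month, levels = sort(unique(records$month))),
    fleet = factor(records$fleet,
                   levels = intersect(c("foreign", "local"),
                                      unique(records$fleet))),
    observer = factor(records$observer,
                      levels = intersect(c("no", "unknown", "yes"),
                                         unique(records$observer))),
    vessel = factor(records$vessel_id),
    stringsAsFactors = FALSE
  )
  if (spec$part == "binomial") {
    df$y <- as.numeric(records[[paste0("count_", spec$species)]] > 0)
  } else {
    df$y <- compute_cpue(records, spec$species)
    if (any(df$y <= 0)) {
      stop_config("gamma part requires strictly positive CPUE: fit it on the positive subset only")
    }
  }
  # factors constant in this subset carry no contrast; they drop out of
  # the design (their effect is absorbed by the intercept)
  terms_used <- spec$fixed_terms[vapply(spec$fixed_terms, function(t)
    nlevels(df[[t]]) >= 2L, logical(1))]
  form <- if (length(terms_used)) stats::reformulate(terms_used) else ~ 1
  X <- stats::model.matrix(form, df)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop_config("design matrix is rank deficient (aliased: %s)",
                paste(dropped, collapse = ", "))
  }
  xlevels <- lapply(df[spec$fixed_terms], levels)
  list(df = df, X = X, y = df$y, vessel = df$vessel, xlevels = xlevels,
       terms_used = terms_used)
}

#' Optimizer settings for the mixed-model fitters
#'
#' @param tol relative tolerance of the outer quasi-Newton optimization.
#' @param maxit outer iteration cap.
#' @param inner_tol,inner_maxit convergence tolerance and cap of the
#'   per-vessel Newton mode search.
#' @param sigma_lower hard lower bound for the vessel SD during
#'   optimization.
#' @param sigma_boundary vessel SDs below this are treated as a boundary
#'   estimate: the fit is finalized through the fixed-effects GLM path
#'   with `sigma_vessel = 0` (the log-sigma profile is flat below this
#'   scale and such an SD is indistinguishable from zero on the link
#'   scale).
#' @param separation_bound attach a separation warning when any |fixed
#'   coefficient| exceeds this.
#' @return list of control settings.
#' @export
glmm_control <- function(tol = 1e-8, maxit = 1000, inner_tol = 1e-11,
                         inner_maxit = 100, sigma_lower = 1e-6,
                         sigma_boundary = 1e-3, separation_bound = 15) {
  list(tol = tol, maxit = maxit, inner_tol = inner_tol,
       inner_maxit = inner_maxit, sigma_lower = sigma_lower,
       sigma_boundary = sigma_boundary,
       separation_bound = separation_bound)
}

# -- Laplace machinery -------------------------------------------------------

# Inner Newton step for the per-vessel random-intercept modes. The joint
# log-density is concave in b for both families (l2 < 0), so damped
# Newton with step halving converges from any start.
solve_modes <- function(eta0, y, gi, G, sigma, aux, family, b, control) {
  pen_loglik <- function(b) {
    sum(family$loglik(y, eta0 + b[gi], aux)) - sum(b^2) / (2 * sigma^2)
  }
  h_cur <- pen_loglik(b)
  for (it in seq_len(control$inner_maxit)) {
    d <- family$derivs(y, eta0 + b[gi], aux)
    S <- rowsum(cbind(d$l1, d$l2), gi)
    grad <- S[, 1] - b / sigma^2
    A <- 1 / sigma^2 - S[, 2]
    if (max(abs(grad)) < control$inner_tol * (1 + abs(h_cur))) break
    step <- grad / A
    lambda <- 1
    repeat {
      b_new <- b + lambda * step
      h_new <- pen_loglik(b_new)
      if (h_new >= h_cur - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    b <- b_new
    h_cur <- h_new
  }
  b
}

# Laplace-approximated marginal log-likelihood and its exact gradient at
# theta = c(beta, log sigma[, log shape]). Modes are cached in `state` and
# warm-started between evaluations.
laplace_loglik <- function(theta, X, y, gi, G, family, state, control,
                           want_grad = FALSE) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1])
  aux <- if (family$has_shape) theta[p + 2] else NULL
  eta0 <- drop(X %*% beta)
  b <- solve_modes(eta0, y, gi, G, sigma, aux, family, state$b, control)
  state$b <- b
  eta <- eta0 + b[gi]
  d <- family$derivs(y, eta, aux)
  S <- rowsum(cbind(d$l2, d$l3), gi)
  A <- 1 / sigma^2 - S[, 1]
  S3 <- S[, 2]
  ll <- sum(family$loglik(y, eta, aux)) - sum(b^2) / (2 * sigma^2) -
    G * log(sigma) - 0.5 * sum(log(A))
  if (!want_grad) return(ll)

  Ag <- A[gi]
  w <- d$l1 + 0.5 * d$l3 / Ag + 0.5 * (S3[gi] / Ag^2) * d$l2
  grad_beta <- drop(crossprod(X, w))
  grad_s <- sum(b^2 / sigma^2 - 1 + 1 / (sigma^2 * A) +
                  S3 * b / (sigma^2 * A^2))
  grad <- c(grad_beta, grad_s)
  if (family$has_shape) {
    Dg <- rowsum(family$dloglik_daux(y, eta, aux), gi)[, 1]
    grad_t <- sum(Dg) - 0.5 * sum((A - 1 / sigma^2) / A) +
      0.5 * sum(S3 * b / (sigma^2 * A^2))
    grad <- c(grad, grad_t)
  }
  list(loglik = ll, gradient = grad, modes = b)
}

# Central finite differences of the analytic gradient give the observed
# information; cheap (2 * dim gradient calls) and accurate to ~1e-6.
laplace_hessian <- function(theta, X, y, gi, G, family, state, control) {
  dim_t <- length(theta)
  H <- matrix(0, dim_t, dim_t)
  for (j in seq_len(dim_t)) {
    h <- 1e-5 * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    gp <- laplace_loglik(tp, X, y, gi, G, family, state, control, TRUE)$gradient
    gm <- laplace_loglik(tm, X, y, gi, G, family, state, control, TRUE)$gradient
    H[, j] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

# -- fixed-effects-only reductions (ordinary GLM) ---------------------------

fit_glm_only <- function(frame, spec, control) {
  df <- frame$df
  form <- if (length(frame$terms_used)) {
    stats::reformulate(frame$terms_used, response = "y")
  } else {
    y ~ 1
  }
  if (spec$part == "binomial") {
    fit <- stats::glm(form, data = df, family = stats::binomial("logit"))
    coefs <- stats::coef(fit)
    V <- stats::vcov(fit)
    loglik <- as.numeric(stats::logLik(fit))
    shape <- NULL
    vcov_all <- V
    par_names <- names(coefs)
  } else {
    fit <- stats::glm(form, data = df, family = stats::Gamma("log"))
    coefs <- stats::coef(fit)
    mu <- stats::fitted(fit)
    shape <- gamma_shape_ml(df$y, mu)
    loglik <- sum(stats::dgamma(df$y, shape = shape, rate = shape / mu,
                                log = TRUE))
    # log link: Fisher information for beta is shape * X'X; beta and shape
    # scores are orthogonal in expectation, so the covariance is block
    # diagonal with var(log k) = 1 / (n k^2 (trigamma(k) - 1/k)).
    V <- solve(crossprod(frame$X)) / shape
    n <- nrow(df)
    var_log_shape <- 1 / (n * shape^2 * (trigamma(shape) - 1 / shape))
    vcov_all <- rbind(cbind(V, 0), c(rep(0, ncol(V)), var_log_shape))
    par_names <- c(names(coefs), "log_shape")
    dimnames(V) <- list(names(coefs), names(coefs))
  }
  dimnames(vcov_all) <- list(par_names, par_names)
  list(coefficients = coefs, vcov_fixed = V, vcov = vcov_all,
       sigma_vessel = 0, shape = shape, loglik = loglik,
       vessel_modes = stats::setNames(rep(0, nlevels(frame$vessel)),
                                      levels(frame$vessel)),
       converged = fit$converged, boundary = FALSE)
}

# ML shape for a gamma GLM with log link: coefficient estimates do not
# depend on the shape, so k solves
#   log k - digamma(k) = mean(y/mu - log(y/mu)) - 1.
gamma_shape_ml <- function(y, mu) {
  rhs <- mean(y / mu - log(y / mu)) - 1
  f <- function(logk) {
    k <- exp(logk)
    log(k) - digamma(k) - rhs
  }
  exp(stats::uniroot(f, c(-30, 30), tol = 1e-12)$root)
}

# -- public fitters ----------------------------------------------------------

fit_glmm <- function(records, spec, control = glmm_control()) {
  family <- if (spec$part == "binomial") family_binomial_logit()
            else family_gamma_log()
  frame <- glmm_frame(records, spec)
  n <- nrow(frame$X)
  p <- ncol(frame$X)
  n_par <- p + as.integer(spec$random) + as.integer(family$has_shape)
  warnings_out <- character(0)

  if (!spec$random) {
    res <- fit_glm_only(frame, spec, control)
  } else {
    if (nlevels(frame$vessel) < 2L) {
      stop_config("a vessel random intercept needs at least 2 vessels")
    }
    gi <- as.integer(frame$vessel)
    G <- nlevels(frame$vessel)
    state <- new.env(parent = emptyenv())
    state$b <- rep(0, G)
    theta0 <- c(rep(0, p), log(0.5), if (family$has_shape) 0)
    lower <- c(rep(-Inf, p), log(control$sigma_lower),
               if (family$has_shape) log(1e-8))
    negll <- function(th) -laplace_loglik(th, frame$X, frame$y, gi, G,
                                          family, state, control)
    neggr <- function(th) -laplace_loglik(th, frame$X, frame$y, gi, G,
                                          family, state, control, TRUE)$gradient
    opt <- stats::nlminb(theta0, negll, neggr, lower = lower,
                         control = list(rel.tol = control$tol,
                                        iter.max = control$maxit,
                                        eval.max = 5 * control$maxit))
    theta <- opt$par
    sigma <- exp(theta[p + 1])
    if (sigma < control$sigma_boundary) {
      # variance component on the boundary: below sigma_boundary a vessel
      # SD is indistinguishable from zero on the link scale, the profile
      # in log sigma is flat, and the Laplace objective equals the GLM
      # likelihood, so finalize through the fixed-effects path with
      # sigma_vessel = 0.
      res <- fit_glm_only(frame, spec, control)
      res$boundary <- TRUE
    } else {
      fin <- laplace_loglik(theta, frame$X, frame$y, gi, G, family, state,
                            control, TRUE)
      H <- laplace_hessian(theta, frame$X, frame$y, gi, G, family, state,
                           control)
      par_names <- c(colnames(frame$X), "log_sigma_vessel",
                     if (family$has_shape) "log_shape")
      vcov_all <- tryCatch(solve(-H), error = function(e) NULL)
      if (is.null(vcov_all) || any(!is.finite(vcov_all)) ||
          any(diag(vcov_all) < -1e-8)) {
        # fall back to a pseudo-inverse and flag the fit
        sv <- svd(-H)
        pos <- sv$d > max(sv$d) * 1e-12
        vcov_all <- sv$v[, pos, drop = FALSE] %*%
          (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
        warnings_out <- c(warnings_out,
                          "observed information is singular; covariance from pseudo-inverse")
      }
      dimnames(vcov_all) <- list(par_names, par_names)
      res <- list(
        coefficients = stats::setNames(theta[seq_len(p)], colnames(frame$X)),
        vcov_fixed = vcov_all[seq_len(p), seq_len(p), drop = FALSE],
        vcov = vcov_all,
        sigma_vessel = sigma,
        shape = if (family$has_shape) exp(theta[p + 2]) else NULL,
        loglik = fin$loglik,
        vessel_modes = stats::setNames(fin$modes, levels(frame$vessel)),
        converged = opt$convergence == 0,
        boundary = FALSE
      )
      if (max(abs(fin$gradient)) > 1e-3 * (1 + abs(fin$loglik))) {
        res$converged <- FALSE
      }
    }
  }

  if (any(abs(res$coefficients) > control$separation_bound)) {
    warnings_out <- c(warnings_out,
                      "possible separation: |coefficient| exceeds the configured bound")
  }
  structure(
    list(spec = spec, coefficients = res$coefficients,
         covariance = res$vcov_fixed, vcov_all = res$vcov,
         sigma_vessel = res$sigma_vessel, shape = res$shape,
         loglik = res$loglik, n_obs = n, n_par = n_par,
         bic = -2 * res$loglik + n_par * log(n),
         converged = res$converged, boundary = res$boundary,
         vessel_modes = res$vessel_modes, xlevels = frame$xlevels,
         terms_used = frame$terms_used,
         covariate_data = frame$df[setdiff(frame$terms_used, "year")],
         warnings = warnings_out),
    class = "shark_glmm"
  )
}

#' Fit the binomial presence/absence submodel
#'
#' Models the probability of a non-zero catch with a logit link,
#' categorical fixed effects and (optionally) a per-vessel random
#' intercept integrated out of the likelihood by Laplace approximation:
#' the per-vessel integrand is expanded to second order around its mode,
#' found by damped Newton iterations. The marginal likelihood is
#' maximized by quasi-Newton (`nlminb`) over the fixed coefficients and
#' log vessel SD from fixed starting values (zeros; log sigma = log 0.5),
#' and the coefficient covariance is the inverse observed information.
#' With no random term the fit reduces exactly to ordinary logistic
#' regression via `stats::glm`.
#'
#' @param records cleaned logbook data.frame.
#' @param spec a [model_spec()] with `part = "binomial"`.
#' @param control optimizer settings from `glmm_control()`.
#' @return object of class `shark_glmm`: coefficients (link scale),
#'   `covariance` (fixed effects), `vcov_all` (all parameters),
#'   `sigma_vessel`, `loglik`, `bic` (with every estimated parameter,
#'   variance components included, counted in the penalty), `converged`,
#'   and `vessel_modes` (predicted random intercepts).
#' @export
fit_binomial_glmm <- function(records, spec = model_spec("binomial"),
                              control = glmm_control()) {
  if (spec$part != "binomial") stop_config("spec$part must be 'binomial'")
  fit_glmm(records, spec, control)
}

#' Fit the gamma positive-catch submodel
#'
#' Models positive CPUE (sharks per 1,000 hooks, strictly positive) on the
#' subset of sets with a catch, with a log link, constant gamma shape
#' estimated jointly by maximum likelihood, and the same Laplace-
#' approximated vessel random intercept as the binomial part. Passing any
#' set with zero catch is an error: the hurdle contract assigns zeros to
#' the binomial part only.
#'
#' @param records logbook data.frame restricted to positive sets for the
#'   species.
#' @param spec a [model_spec()] with `part = "gamma"`.
#' @inheritParams fit_binomial_glmm
#' @return a `shark_glmm` (see [fit_binomial_glmm()]) with `shape`.
#' @export
fit_gamma_glmm <- function(records, spec = model_spec("gamma"),
                           control = glmm_control()) {
  if (spec$part != "gamma") stop_config("spec$part must be 'gamma'")
  fit_glmm(records, spec, control)
}

#' @export
print.shark_glmm <- function(x, ...) {
  cat(sprintf("<shark_glmm: %s part, %s%s>\n", x$spec$part, x$spec$species,
              if (!is.null(x$spec$area)) paste0(", ", x$spec$area) else ""))
  cat(sprintf("  fixed terms: %s\n", paste(x$spec$fixed_terms, collapse = " + ")))
  cat(sprintf("  n = %d, logLik = %.2f, BIC = %.2f (p = %d)\n",
              x$n_obs, x$loglik, x$bic, x$n_par))
  if (x$spec$random) {
    cat(sprintf("  vessel SD = %.4f%s\n", x$sigma_vessel,
                if (x$boundary) " (boundary)" else ""))
  }
  if (!is.null(x$shape)) cat(sprintf("  gamma shape = %.4f\n", x$shape))
  if (!x$converged) cat("  ** did not converge **\n")
  for (w in x$warnings) cat(sprintf("  warning: %s\n", w))
  invisible(x)
}

#' @export
coef.shark_glmm <- function(object, ...) object$coefficients

#' @export
vcov.shark_glmm <- function(object, ...) object$covariance

#' @export
logLik.shark_glmm <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_obs,
            class = "logLik")
}
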