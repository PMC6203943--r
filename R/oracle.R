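#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Computes the exact (to quadrature accuracy) marginal log-likelihood of
#' a hurdle submodel at supplied parameter values by integrating the
#' per-vessel random intercept with adaptive Gauss-Hermite quadrature:
#' each vessel's integrand is centred at its mode (located with
#' `stats::optimize`, independently of the Laplace fitter's Newton
#' machinery) and scaled by the local curvature before applying the
#' quadrature rule. Densities are evaluated with `dbinom`/`dgamma`, so the
#' routine shares no likelihood code with the fitter it audits. Intended
#' for small instances; refuses more than 20 vessels.
#'
#' @param records logbook data.frame (for the gamma part, the positive
#'   subset).
#' @param spec a [model_spec()].
#' @param parameters list with `coefficients` (named vector matching the
#'   design columns), `sigma_vessel` (>= 0) and, for the gamma part,
#'   `shape`.
#' @param n_nodes number of quadrature nodes (>= 20).
#' @return the marginal log-likelihood (scalar).
#' @export
marginal_loglik_oracle <- function(records, spec, parameters, n_nodes = 50) {
  frame <- glmm_frame(records, spec)
  G <- nlevels(frame$vessel)
  if (G > 20L) stop_config("quadrature oracle is for small instances (<= 20 vessels), got %d", G)
  if (n_nodes < 20L) stop_config("n_nodes must be >= 20")
  beta <- parameters$coefficients
  if (is.null(names(beta)) || !setequal(names(beta), colnames(frame$X))) {
    stop_config("parameters$coefficients must be named to match the design: %s",
                paste(colnames(frame$X), collapse = ", "))
  }
  sigma <- parameters$sigma_vessel
  eta0 <- drop(frame$X %*% beta[colnames(frame$X)])
  y <- frame$y
  gi <- as.integer(frame$vessel)

  obs_loglik <- if (spec$part == "binomial") {
    function(idx, b) sum(stats::dbinom(y[idx], 1,
                                       stats::plogis(eta0[idx] + b),
                                       log = TRUE))
  } else {
    k <- parameters$shape
    if (is.null(k) || k <= 0) stop_config("gamma part needs parameters$shape > 0")
    function(idx, b) {
      mu <- exp(eta0[idx] + b)
      sum(stats::dgamma(y[idx], shape = k, rate = k / mu, log = TRUE))
    }
  }

  if (sigma == 0) {
    return(sum(vapply(seq_len(G), function(g) obs_loglik(gi == g, 0),
                      numeric(1))))
  }

  gh <- pracma::gaussHermite(n_nodes)
  total <- 0
  for (g in seq_len(G)) {
    idx <- gi == g
    h <- function(b) obs_loglik(idx, b) + stats::dnorm(b, 0, sigma, log = TRUE)
    opt <- stats::optimize(h, interval = c(-8, 8) * max(sigma, 1),
                           maximum = TRUE, tol = 1e-10)
    m <- opt$maximum
    d <- 1e-4 * (1 + abs(m))
    h2 <- (h(m + d) - 2 * opt$objective + h(m - d)) / d^2
    s <- if (is.finite(h2) && h2 < 0) 1 / sqrt(-h2) else sigma
    hb <- vapply(m + sqrt(2) * s * gh$x, h, numeric(1))
    total <- total + logsumexp(log(gh$w) + gh$x^2 + hb) +
      log(sqrt(2) * s)
  }
  total
}
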