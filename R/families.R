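# Link-scale derivative bundles for the two hurdle parts. Each family
# exposes the per-observation log-likelihood and its first three
# derivatives in eta (needed for the Laplace objective and its exact
# gradient), plus, for the gamma, the derivative in the auxiliary
# parameter t = log(shape).

log1pexp <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

family_binomial_logit <- function() {
  list(
    name = "binomial", link = "logit", has_shape = FALSE,
    loglik = function(y, eta, aux) y * eta - log1pexp(eta),
    derivs = function(y, eta, aux) {
      p <- stats::plogis(eta)
      w <- p * (1 - p)
      list(l1 = y - p, l2 = -w, l3 = -w * (1 - 2 * p))
    },
    dloglik_daux = NULL
  )
}

family_gamma_log <- function() {
  list(
    name = "gamma", link = "log", has_shape = TRUE,
    # aux = log(shape); density: shape k, mean exp(eta)
    loglik = function(y, eta, aux) {
      k <- exp(aux)
      k * aux - lgamma(k) + (k - 1) * log(y) - k * eta - k * y * exp(-eta)
    },
    derivs = function(y, eta, aux) {
      k <- exp(aux)
      r <- y * exp(-eta)
      list(l1 = k * (r - 1), l2 = -k * r, l3 = k * r)
    },
    # d loglik / d t with t = log k (chain rule through k)
    dloglik_daux = function(y, eta, aux) {
      k <- exp(aux)
      r <- y * exp(-eta)
      k * (aux + 1 - digamma(k) + log(y) - eta - r)
    }
  )
}
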