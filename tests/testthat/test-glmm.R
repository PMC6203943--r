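test_that("CPUE is counts per 1,000 hooks", {
  expect_equal(compute_cpue(data.frame(count_blue = 10, hooks = 2000), "blue"), 5)
  expect_equal(compute_cpue(data.frame(count_blue = 0, hooks = 1282), "blue"), 0)
  r <- generate_logbook(sim_truth(n_sets = 500, seed = 41))$records
  brute <- vapply(seq_len(nrow(r)),
                  function(i) r$count_blue[i] * 1000 / r$hooks[i], numeric(1))
  expect_equal(compute_cpue(r, "blue"), brute)
  expect_error(compute_cpue(data.frame(count_blue = 1, hooks = 0), "blue"),
               "positive")
})

test_that("intercept-only fixed-effect fits match their closed forms", {
  r <- valid_record(n = 100)
  r$count_blue <- c(rep(1L, 30), rep(0L, 70))
  r$weight_blue <- ifelse(r$count_blue > 0, 10, 0)
  fb <- fit_binomial_glmm(r, model_spec("binomial", "blue", "year",
                                        random = FALSE))
  expect_equal(unname(coef(fb)), stats::qlogis(0.30), tolerance = 1e-8)

  set.seed(42)
  rp <- valid_record(n = 80)
  rp$count_blue <- rpois(80, 20) + 1L
  rp$hooks <- sample(800:2500, 80, TRUE)
  fg <- fit_gamma_glmm(rp, model_spec("gamma", "blue", "year", random = FALSE))
  expect_equal(exp(unname(coef(fg))), mean(compute_cpue(rp, "blue")),
               tolerance = 1e-8)
  # shape ML cross-checked against an established estimator
  glmfit <- stats::glm(compute_cpue(rp, "blue") ~ 1, family = stats::Gamma("log"))
  expect_equal(fg$shape, MASS::gamma.shape(glmfit)$alpha, tolerance = 1e-4)
})

test_that("the Laplace loglik matches adaptive quadrature on small instances", {
  truth <- sim_truth(n_sets = 400, nv_local = 4, nv_foreign = 4,
                     sigma_b = 0.8, sigma_g = 0.6, b_fleet = c(local = -0.5),
                     g_fleet = c(local = 0.3), seed = 43)
  r <- generate_logbook(truth)$records
  spec <- model_spec("binomial", "blue", c("year", "fleet"))
  fit <- fit_binomial_glmm(r, spec)
  expect_true(fit$converged)
  ll <- marginal_loglik_oracle(r, spec,
    list(coefficients = coef(fit), sigma_vessel = fit$sigma_vessel), 50)
  expect_lt(abs(fit$loglik - ll) / fit$n_obs, 1e-3)

  pos <- r[r$count_blue > 0, ]
  specg <- model_spec("gamma", "blue", c("year", "fleet"))
  fg <- fit_gamma_glmm(pos, specg)
  expect_true(fg$converged)
  llg <- marginal_loglik_oracle(pos, specg,
    list(coefficients = coef(fg), sigma_vessel = fg$sigma_vessel,
         shape = fg$shape), 50)
  expect_lt(abs(fg$loglik - llg) / fg$n_obs, 1e-3)
})

test_that("the quadrature oracle is self-consistent and matches Monte Carlo", {
  truth <- sim_truth(n_sets = 120, nv_local = 3, nv_foreign = 2,
                     sigma_b = 0.7, seed = 44)
  r <- generate_logbook(truth)$records
  spec <- model_spec("binomial", "blue", "year")
  frame <- sharkCPUE:::glmm_frame(r, spec)
  beta <- stats::setNames(c(0.4, 0.1, -0.2, 0.3), colnames(frame$X))
  pars <- list(coefficients = beta, sigma_vessel = 0.7)
  l50 <- marginal_loglik_oracle(r, spec, pars, 50)
  l100 <- marginal_loglik_oracle(r, spec, pars, 100)
  expect_lt(abs(l50 - l100), 1e-8)

  # sigma = 0 degenerates to the independent-observation likelihood
  eta <- drop(frame$X %*% beta)
  ll0 <- sum(stats::dbinom(frame$y, 1, stats::plogis(eta), log = TRUE))
  expect_equal(marginal_loglik_oracle(r, spec,
    list(coefficients = beta, sigma_vessel = 0)), ll0, tolerance = 1e-12)

  # direct Monte-Carlo integration of the vessel effect
  set.seed(45)
  gi <- as.integer(frame$vessel)
  per_vessel <- vapply(seq_len(nlevels(frame$vessel)), function(g) {
    idx <- gi == g
    z <- rnorm(2e5, 0, 0.7)
    pmat <- stats::plogis(outer(eta[idx], z, "+"))
    yv <- frame$y[idx]
    lmat <- yv * log(pmat) + (1 - yv) * log1p(-pmat)
    contrib <- colSums(lmat)
    w <- exp(contrib - max(contrib))
    c(max(contrib) + log(mean(w)),
      stats::sd(w) / (sqrt(length(w)) * mean(w)))
  }, numeric(2))
  mc <- sum(per_vessel[1, ])
  mc_se <- sqrt(sum(per_vessel[2, ]^2))
  expect_lt(abs(l50 - mc), 3 * mc_se)
  expect_error(marginal_loglik_oracle(
    generate_logbook(sim_truth(1000, nv_local = 15, nv_foreign = 15,
                               seed = 1))$records, spec, pars),
    "small instances")
})

test_that("without vessel heterogeneity the mixed fit collapses to the GLM", {
  # On sigma = 0 data the ML vessel SD lands on the boundary for about
  # half of realised datasets (elsewhere it sits at a small positive
  # value, exactly as glmer estimates on the same data); whenever it is
  # on the boundary the mixed fit must reproduce the GLM exactly.
  n_boundary <- 0L
  for (i in 1:8) {
    truth <- sim_truth(n_sets = 1500, nv_local = 10, nv_foreign = 10,
                       sigma_b = 0, sigma_g = 0, seed = 460 + i)
    r <- generate_logbook(truth)$records
    mixed <- fit_binomial_glmm(r, model_spec("binomial", "blue", "year"))
    plain <- fit_binomial_glmm(r, model_spec("binomial", "blue", "year",
                                             random = FALSE))
    expect_lt(mixed$sigma_vessel, 0.2)
    if (mixed$boundary) {
      n_boundary <- n_boundary + 1L
      expect_identical(mixed$sigma_vessel, 0)
      expect_lt(max(abs(coef(mixed) - coef(plain))), 1e-4)
      # the variance component still counts as estimated in the BIC
      expect_equal(mixed$n_par, plain$n_par + 1L)
    }
  }
  expect_gte(n_boundary, 1L)
})

test_that("adding a fixed term never lowers the maximized loglik", {
  truth <- sim_truth(n_sets = 1500, nv_local = 6, nv_foreign = 6,
                     sigma_b = 0.4, b_fleet = c(local = -0.5), seed = 47)
  r <- generate_logbook(truth)$records
  base <- fit_binomial_glmm(r, model_spec("binomial", "blue", "year"))
  bigger <- fit_binomial_glmm(r, model_spec("binomial", "blue",
                                            c("year", "fleet")))
  expect_gte(bigger$loglik, base$loglik - 1e-6)
  # BIC bookkeeping: every estimated parameter counts
  expect_equal(base$bic, -2 * base$loglik + base$n_par * log(base$n_obs))
  expect_equal(base$n_par, length(coef(base)) + 1L)
})

test_that("the fitter agrees with lme4 and glmmTMB on a shared dataset", {
  truth <- sim_truth(n_sets = 2000, nv_local = 8, nv_foreign = 8,
                     sigma_b = 0.5, sigma_g = 0.4,
                     b_fleet = c(local = -0.4), g_fleet = c(local = 0.3),
                     seed = 48)
  r <- generate_logbook(truth)$records
  df <- data.frame(y = as.numeric(r$count_blue > 0),
                   year = factor(r$year),
                   fleet = factor(r$fleet, c("foreign", "local")),
                   vessel = factor(r$vessel_id))
  fit <- fit_binomial_glmm(r, model_spec("binomial", "blue",
                                         c("year", "fleet")))
  ref <- lme4::glmer(y ~ year + fleet + (1 | vessel), df,
                     family = stats::binomial())
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-5)
  expect_lt(max(abs(coef(fit) - lme4::fixef(ref))), 5e-3)
  expect_equal(fit$sigma_vessel,
               sqrt(unname(unlist(lme4::VarCorr(ref)))), tolerance = 1e-3)

  pos <- r$count_blue > 0
  dg <- df[pos, ]
  dg$y <- compute_cpue(r, "blue")[pos]
  fg <- fit_gamma_glmm(r[pos, ], model_spec("gamma", "blue",
                                            c("year", "fleet")))
  refg <- glmmTMB::glmmTMB(y ~ year + fleet + (1 | vessel), dg,
                           family = stats::Gamma(link = "log"))
  expect_equal(fg$loglik, as.numeric(stats::logLik(refg)), tolerance = 1e-5)
  expect_lt(max(abs(coef(fg) - glmmTMB::fixef(refg)$cond)), 5e-3)
  # glmmTMB parameterises the gamma by CV = 1/sqrt(shape)
  expect_equal(fg$shape, 1 / stats::sigma(refg)^2, tolerance = 1e-3)
})

test_that("the gamma part refuses zero-catch sets", {
  r <- generate_logbook(sim_truth(n_sets = 200, seed = 49))$records
  expect_error(fit_gamma_glmm(r, model_spec("gamma", "blue", "year")),
               "positive")
})

test_that("model strings parse to specs", {
  spec <- parse_model_formula("presence ~ year + month + fleet + (1|vessel)")
  expect_equal(spec$part, "binomial")
  expect_equal(spec$fixed_terms, c("year", "month", "fleet"))
  expect_true(spec$random)
  spec2 <- parse_model_formula("cpue ~ year")
  expect_equal(spec2$part, "gamma")
  expect_false(spec2$random)
  expect_error(parse_model_formula("count ~ year"), "unknown response")
})
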