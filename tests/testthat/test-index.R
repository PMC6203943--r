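test_that("back-transformation follows the delta method on both links", {
  bt <- backtransform(0, 0.5, "logit")
  expect_equal(bt$estimate, 0.5)
  expect_equal(bt$se, 0.125)
  bt2 <- backtransform(0, 0.37, "log")
  expect_equal(bt2$estimate, 1)
  expect_equal(bt2$se, 0.37)
  expect_error(backtransform(0, -0.1, "log"), "non-negative")
})

test_that("delta-method SEs track Monte-Carlo SDs in the moderate regime", {
  set.seed(71)
  z <- rnorm(1e6)
  # log link at c = 1.2, se = 0.3
  mc_sd <- stats::sd(exp(1.2 + 0.3 * z))
  delta <- backtransform(1.2, 0.3, "log")$se
  expect_lt(abs(delta - mc_sd) / mc_sd, 0.10)
  # logit link at c = 0, se = 0.5
  mc_sd_l <- stats::sd(stats::plogis(0 + 0.5 * z))
  delta_l <- backtransform(0, 0.5, "logit")$se
  expect_lt(abs(delta_l - mc_sd_l) / mc_sd_l, 0.10)
})

test_that("product-error propagation matches its limits and Monte Carlo", {
  expect_equal(propagate_product_error(0.5, 0, 10, 0), 0)
  expect_equal(propagate_product_error(1, 0, 20, 3), 3)
  set.seed(72)
  p <- pmin(1, pmax(0, rnorm(1e6, 0.6, 0.05)))
  mu <- pmax(1e-9, rnorm(1e6, 20, 3))
  mc_sd <- stats::sd(p * mu)
  delta <- propagate_product_error(0.6, 0.05, 20, 3)
  expect_lt(abs(delta - mc_sd) / mc_sd, 0.10)
  expect_error(propagate_product_error(1.2, 0, 1, 0), "\\[0, 1\\]")
  # scale equivariance: rescaling the gamma part rescales index and SE
  expect_equal(propagate_product_error(0.6, 0.05, 200, 30), 10 * delta)
})

test_that("constant series are unflagged; the 4 -> 191 jump is flagged", {
  expect_equal(nrow(flag_anomalies(rep(5, 10))), 0L)
  s <- data.frame(year = 2008:2013,
                  index = c(6, 5, 4, 191, 120, 57))
  fl <- flag_anomalies(s, ratio_threshold = 3)
  expect_true(2011 %in% fl$year)
  expect_equal(fl$ratio[fl$year == 2011], 191 / 4, tolerance = 1e-4)
  expect_equal(nrow(flag_anomalies(s[1, , drop = FALSE])), 0L)
})

test_that("flags agree with a brute-force consecutive-ratio scan", {
  set.seed(73)
  for (rep in 1:20) {
    idx <- exp(rnorm(12, 1, 1.2))
    fl <- flag_anomalies(idx, ratio_threshold = 3)
    brute <- which(vapply(2:12, function(t) {
      r <- (idx[t] + 1e-6) / (idx[t - 1] + 1e-6)
      r > 3 || 1 / r > 3
    }, logical(1))) + 1
    expect_equal(fl$year, as.numeric(brute))
  }
})

make_degenerate_binomial <- function(gamma_fit) {
  years <- gamma_fit$xlevels$year
  cn <- c("(Intercept)", paste0("year", years[-1]))
  structure(list(
    spec = model_spec("binomial", gamma_fit$spec$species, "year",
                      random = FALSE, area = gamma_fit$spec$area),
    coefficients = stats::setNames(c(40, rep(0, length(cn) - 1)), cn),
    covariance = matrix(0, length(cn), length(cn), dimnames = list(cn, cn)),
    sigma_vessel = 0, shape = NULL, loglik = 0, n_obs = 1, n_par = length(cn),
    bic = 0, converged = TRUE, boundary = FALSE,
    vessel_modes = numeric(0), xlevels = list(year = years),
    covariate_data = data.frame(), warnings = character(0)),
    class = "shark_glmm")
}

test_that("a certain encounter collapses the index to the gamma prediction", {
  r <- generate_logbook(sim_truth(n_sets = 1500, nv_local = 5, nv_foreign = 5,
                                  sigma_g = 0.3,
                                  g_year = c("2001" = 0.4, "2002" = -0.3,
                                             "2003" = 0.6), seed = 74))$records
  pos <- r[r$count_blue > 0, ]
  fg <- fit_gamma_glmm(pos, model_spec("gamma", "blue", "year"))
  fb <- make_degenerate_binomial(fg)
  series <- predict_year_effects(fb, fg)
  expect_equal(series$p_hat, rep(1, nrow(series)))
  expect_equal(series$se_p, rep(0, nrow(series)))
  expect_equal(series$index, series$mu_hat)
  expect_equal(series$se_index, series$se_mu)
  # structural invariants
  expect_equal(series$index, series$p_hat * series$mu_hat)
  expect_true(all(series$index <= series$mu_hat + 1e-12))
})

test_that("both prediction policies agree when only year enters the model", {
  truth <- sim_truth(n_sets = 2000, nv_local = 6, nv_foreign = 6,
                     sigma_b = 0.3, sigma_g = 0.3,
                     b_year = c("2001" = 0.3, "2002" = -0.2, "2003" = 0.5),
                     g_year = c("2001" = 0.2, "2002" = -0.4, "2003" = 0.3),
                     seed = 75)
  r <- generate_logbook(truth)$records
  fb <- fit_binomial_glmm(r, model_spec("binomial", "blue", "year"))
  fg <- fit_gamma_glmm(r[r$count_blue > 0, ], model_spec("gamma", "blue", "year"))
  ref <- predict_year_effects(fb, fg, policy = "reference")
  pop <- predict_year_effects(fb, fg, policy = "population")
  expect_equal(ref$index, pop$index, tolerance = 1e-10)
  expect_equal(ref$se_index, pop$se_index, tolerance = 1e-10)
})

test_that("the population policy averages over the observed factor mix", {
  truth <- sim_truth(n_sets = 2500, nv_local = 6, nv_foreign = 6,
                     sigma_b = 0.3, sigma_g = 0.3,
                     b_fleet = c(local = -0.8), g_fleet = c(local = 0.5),
                     seed = 76)
  r <- generate_logbook(truth)$records
  fb <- fit_binomial_glmm(r, model_spec("binomial", "blue", c("year", "fleet")))
  fg <- fit_gamma_glmm(r[r$count_blue > 0, ],
                       model_spec("gamma", "blue", c("year", "fleet")))
  ref <- predict_year_effects(fb, fg, policy = "reference")
  pop <- predict_year_effects(fb, fg, policy = "population")
  # reference = foreign fleet; population mixes in the local contrast
  expect_false(isTRUE(all.equal(ref$p_hat, pop$p_hat)))
  w_local <- mean(r$fleet == "local")
  expected_p <- stats::plogis(coef(fb)[["(Intercept)"]]) * (1 - w_local) +
    stats::plogis(coef(fb)[["(Intercept)"]] + coef(fb)[["fleetlocal"]]) * w_local
  expect_equal(pop$p_hat[pop$year == 2000], expected_p, tolerance = 1e-10)
})

test_that("index series round-trip to CSV", {
  s <- structure(data.frame(species = "blue", area = "West",
                            year = 2000:2002, p_hat = c(0.5, 0.6, 0.7),
                            se_p = 0.02, mu_hat = c(10, 12, 9), se_mu = 1,
                            index = c(5, 7.2, 6.3), se_index = 0.9,
                            anomaly_flag = FALSE),
                 class = c("index_series", "data.frame"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_index_series(s, f)
  back <- utils::read.csv(f)
  expect_equal(back$index, s$index)
  expect_equal(back$year, s$year)
})
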