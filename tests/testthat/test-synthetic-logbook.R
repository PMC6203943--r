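test_that("an empty truth yields an empty logbook with the full schema", {
  sim <- generate_logbook(sim_truth(n_sets = 0))
  expect_s3_class(sim$records, "data.frame")
  expect_equal(nrow(sim$records), 0L)
  expect_true(all(sharkCPUE:::required_logbook_fields %in% names(sim$records)))
})

test_that("generation is byte-identical given truth and seed", {
  truth <- sim_truth(n_sets = 300, sigma_b = 0.5, sigma_g = 0.4, seed = 9)
  a <- generate_logbook(truth)
  b <- generate_logbook(truth)
  expect_identical(a$records, b$records)
  c <- generate_logbook(sim_truth(n_sets = 300, sigma_b = 0.5,
                                  sigma_g = 0.4, seed = 10))
  expect_false(identical(a$records, c$records))
})

test_that("a zero logit intercept gives a 50% encounter rate", {
  sim <- generate_logbook(sim_truth(n_sets = 10000, b_int = 0, seed = 2))
  frac <- mean(sim$records$count_blue > 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("per-fleet hooks-per-line distributions match the two fleets", {
  # foreign 2,493 +/- 597 and local 1,282 +/- 250 hooks per line, truncated
  # to the plausible effort range
  sim <- generate_logbook(sim_truth(n_sets = 10000, p_foreign = 0.5, seed = 3))
  r <- sim$records
  for (fl in c("local", "foreign")) {
    ms <- if (fl == "local") c(1282, 250) else c(2493, 597)
    hooks <- r$hooks[r$fleet == fl]
    target <- sharkCPUE:::truncnorm_mean(ms[1], ms[2], 310, 3800)
    se <- stats::sd(hooks) / sqrt(length(hooks))
    expect_lt(abs(mean(hooks) - target), 3 * se)
    expect_true(all(hooks >= 310 & hooks <= 3800))
  }
})

test_that("intercept-only truth reproduces the local-fleet zero-set rate", {
  # 37% of 16,810 sets with no blue sharks
  b0 <- stats::qlogis(1 - 0.37)
  sim <- generate_logbook(sim_truth(n_sets = 16810, b_int = b0, seed = 4))
  zero_frac <- mean(sim$records$count_blue == 0)
  expect_lt(abs(zero_frac - 0.37), 3 * sqrt(0.37 * 0.63 / 16810))
})

test_that("weights are zero exactly when counts are zero", {
  r <- generate_logbook(sim_truth(n_sets = 2000, seed = 5))$records
  for (sp in c("blue", "mako")) {
    cnt <- r[[paste0("count_", sp)]]
    wt <- r[[paste0("weight_", sp)]]
    expect_true(all((wt == 0) == (cnt == 0)))
    expect_true(all(cnt >= 0) && all(wt >= 0))
  }
  expect_true(all(r$month %in% 1:12) && all(r$hooks > 0))
})

test_that("positive-set CPUE converges to the gamma mean", {
  mu0 <- 15
  sim <- generate_logbook(sim_truth(n_sets = 8000, b_int = 2,
                                    g_int = log(mu0), seed = 6))
  r <- sim$records
  cpue <- compute_cpue(r, "blue")
  pos <- cpue[cpue > 0]
  se <- stats::sd(pos) / sqrt(length(pos))
  # 0.25 slack bounds the count-rounding error on the CPUE scale
  expect_lt(abs(mean(pos) - mu0), 3 * se + 0.25)
})

test_that("zero anomaly rates return the input unchanged", {
  r <- generate_logbook(sim_truth(n_sets = 200, seed = 7))$records
  out <- inject_anomalies(r, rates = list(), seed = 1)
  expect_identical(out$records, r)
  out2 <- inject_anomalies(r, rates = c(hooks_out_of_range = 0), seed = 1)
  expect_identical(out2$records, r)
})

test_that("each anomaly class corrupts exactly its stated fraction", {
  r <- generate_logbook(sim_truth(n_sets = 1000, seed = 8))$records
  out <- inject_anomalies(r, rates = c(hooks_out_of_range = 0.10), seed = 2)
  bad <- out$records$hooks < 310 | out$records$hooks > 3800
  expect_equal(sum(bad), 100L)
  expect_setequal(out$records$set_id[bad], out$corrupted_ids$hooks_out_of_range)

  out2 <- inject_anomalies(r, rates = c(sharks_ge_hooks = 0.05), seed = 3)
  ge <- with(out2$records, count_blue + count_mako >= hooks)
  expect_equal(sum(ge), 50L)
  expect_setequal(out2$records$set_id[ge], out2$corrupted_ids$sharks_ge_hooks)
})

test_that("anomaly classes are disjoint and deterministic given the seed", {
  r <- generate_logbook(sim_truth(n_sets = 1000, seed = 8))$records
  rates <- c(position_out_of_region = 0.02, year_out_of_range = 0.02,
             hooks_out_of_range = 0.03, count_over_cap = 0.02,
             sharks_ge_hooks = 0.02, missing_field = 0.02)
  a <- inject_anomalies(r, rates, seed = 5)
  b <- inject_anomalies(r, rates, seed = 5)
  expect_identical(a, b)
  ids <- unlist(a$corrupted_ids)
  expect_equal(length(ids), length(unique(ids)))
  expect_equal(length(ids), sum(round(rates * 1000)))
  expect_error(inject_anomalies(r, c(missing_field = 0.7, year_out_of_range = 0.6)),
               "exceeds 1")
  expect_error(inject_anomalies(r, c(bogus_rule = 0.1)), "unknown anomaly")
})

test_that("logbook and truth round-trip through CSV and JSON", {
  truth <- sim_truth(n_sets = 50, sigma_b = 0.3, sigma_g = 0.2, seed = 12)
  sim <- generate_logbook(truth)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_logbook(sim$records, csv)
  back <- read_logbook(csv)
  expect_equal(back$hooks, sim$records$hooks)
  expect_equal(back$latitude, sim$records$latitude, tolerance = 1e-12)
  expect_equal(back$count_blue, sim$records$count_blue)

  js <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, js)
  truth2 <- read_truth(js)
  expect_equal(truth2$n_sets, truth$n_sets)
  expect_equal(truth2$species$blue$beta_binomial$intercept,
               truth$species$blue$beta_binomial$intercept)
  expect_equal(truth2$species$blue$gamma_shape, truth$species$blue$gamma_shape)
  # regenerating from the restored truth reproduces the dataset
  resim <- generate_logbook(truth2)
  expect_equal(resim$records$count_blue, sim$records$count_blue)
})
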