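test_that("growth rate from doubling time follows ln(2)/Td", {
  expect_equal(growth_rate_from_doubling(27), log(2) / 27)
  expect_equal(round(growth_rate_from_doubling(27), 3), 0.026)
  expect_equal(growth_rate_from_doubling(log(2)), 1)
  for (td in c(10, 24, 27, 48)) {
    expect_equal(growth_rate_from_doubling(td) * td, log(2))
  }
  expect_error(growth_rate_from_doubling(0), "positive")
  expect_error(growth_rate_from_doubling(-3), "positive")
})

test_that("residuals vanish on self-generated noise-free data", {
  p <- model_params(r = growth_rate_from_doubling(27), alpha = 0.484,
                    beta = 1, gamma = 0.01)
  d <- generate_dataset("celltype_therapy", p, make_design("TREATMENT"),
                        phenotype_state(0.7), noise_sd = 0, seed = 7)
  res <- residual_vector("celltype_therapy", p, d)
  expect_length(res, 2 * 2 * 3)  # 2 replicates x 3 post-initial times x 2 phenotypes
  expect_lt(max(abs(res)), 1e-6)
})

test_that("residual layout is (replicate, time, phenotype) and counts right", {
  recs <- data.frame(time_h = c(0, 48, 0, 48),
                     replicate = c("a", "a", "b", "b"),
                     freq_adrn = c(0.5, 0.6, 0.5, 0.7),
                     freq_mes = c(0.5, 0.4, 0.5, 0.3))
  d <- frequency_dataset(recs)
  p <- model_params(r = 0.026, alpha = 0.484, beta = 1)
  res <- residual_vector("baseline", p, d)
  expect_length(res, 4)  # one post-initial time per replicate, both phenotypes

  # perturbing replicate b's observation changes only the last two entries
  recs2 <- recs
  recs2$freq_adrn[4] <- 0.65; recs2$freq_mes[4] <- 0.35
  res2 <- residual_vector("baseline", p, frequency_dataset(recs2))
  expect_equal(res2[1:2], res[1:2])
  expect_false(any(res2[3:4] == res[3:4]))
  # complementary phenotypes give mirrored residual pairs
  expect_equal(res[1], -res[2])

  # single replicate, single post-initial time: length 2
  d1 <- frequency_dataset(recs[1:2, ])
  expect_length(residual_vector("baseline", p, d1), 2)
  # ADRN-only layout halves the vector
  expect_length(residual_vector("baseline", p, d, residuals = "adrn"), 2)

  # a wrong generating parameter leaves a positive sum of squares
  d_gen <- generate_dataset("baseline",
                            model_params(r = 0.026, alpha = 0.6, beta = 1),
                            make_design("CONTROL"), phenotype_state(0.85),
                            noise_sd = 0, seed = 1)
  rss <- sum(residual_vector("baseline", p, d_gen)^2)
  expect_gt(rss, 1e-8)
})

test_that("noise-free baseline fits recover the generating coefficients", {
  dat <- generate_scenario("untreated_baseline", seed = 11, noise_sd = 0)
  fit <- fit_model(baseline_fit_spec(), dat)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["alpha"]], 0.484, tolerance = 1e-3)
  expect_equal(fit$estimates[["beta"]], 1.00, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-12)
})

test_that("noise-free therapy fits recover the generating death rate", {
  dat <- generate_scenario("treated_celltype", seed = 11, noise_sd = 0)
  fit <- fit_model(celltype_fit_spec(untreated_ref()), dat)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["gamma"]], 0.01, tolerance = 1e-3)
})

test_that("a generating beta above the cap drives the estimate to the bound", {
  p <- model_params(r = growth_rate_from_doubling(27), alpha = 0.99,
                    beta = 1.26)
  d <- rbind(
    as.data.frame(generate_dataset("baseline", p, make_design("CONTROL"),
                                   phenotype_state(0.85), 0, seed = 3,
                                   replicate_prefix = "c")),
    as.data.frame(generate_dataset(
      "baseline", p,
      sampling_design("RECOVERY", c(96, 168, 264)),
      phenotype_state(0.4), 0, seed = 4, replicate_prefix = "s")))
  d <- frequency_dataset(d)

  capped <- fit_model(baseline_fit_spec(), d)
  expect_equal(capped$estimates[["beta"]], 1, tolerance = 1e-6)

  unbounded <- fit_model(baseline_fit_spec(beta_upper = Inf), d)
  expect_equal(unbounded$estimates[["beta"]], 1.26, tolerance = 1e-2)
  # alpha = 0.99 sits on a nearly flat ridge against beta; recovery is coarse
  expect_equal(unbounded$estimates[["alpha"]], 0.99, tolerance = 0.03)
  expect_lte(unbounded$rss, capped$rss + 1e-12)
})

test_that("fitting never increases the objective above its starting value", {
  dat <- generate_scenario("untreated_baseline", seed = 21, noise_sd = 0.02)
  spec <- baseline_fit_spec()
  start_params <- model_params(r = growth_rate_from_doubling(27),
                               alpha = spec$start[["alpha"]],
                               beta = spec$start[["beta"]])
  rss0 <- sum(residual_vector("baseline", start_params, dat)^2)
  fit <- fit_model(spec, dat)
  expect_lte(fit$rss, rss0)
})

test_that("an all-fixed spec evaluates the residuals with k = 0", {
  dat <- generate_scenario("untreated_baseline", seed = 5, noise_sd = 0.02)
  p <- model_params(r = growth_rate_from_doubling(27), alpha = 0.484, beta = 1)
  spec <- fit_spec("baseline", free = character(0),
                   fixed = c(r = p[["r"]], alpha = 0.484, beta = 1))
  fit <- fit_model(spec, dat)
  expect_equal(fit$k, 0)
  expect_true(fit$converged)
  expect_equal(fit$rss, sum(residual_vector("baseline", p, dat)^2))
})

test_that("fit specs are validated", {
  expect_error(fit_spec("baseline", free = "alpha",
                        fixed = c(r = 0.026, alpha = 0.5, beta = 1)),
               "both free and fixed")
  expect_error(fit_spec("baseline", free = c("alpha", "beta", "gamma"),
                        fixed = c(r = 0.026)), "not used by model")
  expect_error(fit_spec("baseline", free = "alpha", fixed = c(r = 0.026)),
               "either free or fixed")
  expect_error(fit_spec("baseline", free = c("alpha", "beta"),
                        fixed = c(r = 0.026), start = c(alpha = 1.5)),
               "within the bounds")
})

test_that("dataset invariants are enforced at construction", {
  bad <- data.frame(time_h = c(0, 48), replicate = "a",
                    freq_adrn = c(0.6, 0.6), freq_mes = c(0.5, 0.4))
  expect_error(frequency_dataset(bad), "row")
  single_time <- data.frame(time_h = 48, replicate = "a",
                            freq_adrn = 0.6, freq_mes = 0.4)
  expect_error(frequency_dataset(single_time), "at least 2 distinct times")
})
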