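test_that("per-capita growth terms match the model equations", {
  p <- model_params(r = 0.026, alpha = 0.484, beta = 0.8)

  # ADRN fixation: gA vanishes, gM = r(1 - beta)
  g <- per_capita_growth("baseline", phenotype_state(1, 0), p)
  expect_equal(g[["gA"]], 0)
  expect_equal(g[["gM"]], 0.026 * (1 - 0.8))

  # direct evaluation at the simplex midpoint
  p2 <- model_params(r = 0.026, alpha = 0.484, beta = 1)
  g2 <- per_capita_growth("baseline", phenotype_state(0.5), p2)
  expect_equal(g2[["gA"]], 0.006708, tolerance = 1e-12)
  expect_equal(g2[["gM"]], 0)

  # the therapy death term shifts gA by exactly gamma and gM not at all
  p3 <- model_params(r = 0.026, alpha = 0.484, beta = 1, gamma = 0.0123)
  g_on <- per_capita_growth("celltype_therapy", phenotype_state(0.6), p3, TRUE)
  g_off <- per_capita_growth("celltype_therapy", phenotype_state(0.6), p3, FALSE)
  expect_equal(g_off[["gA"]] - g_on[["gA"]], 0.0123)
  expect_equal(g_on[["gM"]], g_off[["gM"]])

  # cell-state model additionally removes zeta from the ADRN bracket
  p4 <- model_params(r = 0.026, alpha = 0.484, beta = 1,
                     gamma = 0.0123, zeta = 0.002)
  g4 <- per_capita_growth("cellstate_therapy", phenotype_state(0.6), p4, TRUE)
  expect_equal(g_on[["gA"]] - g4[["gA"]], 0.002)
})

test_that("mean fitness is the frequency-weighted average", {
  s <- phenotype_state(0.3)
  expect_equal(mean_fitness(s, 0.02, 0.02), 0.02)           # equal fitness
  expect_equal(mean_fitness(phenotype_state(1, 0), 0.5, -3), 0.5)
  expect_equal(mean_fitness(phenotype_state(0.5), 0.006708, 0), 0.003354)
})

test_that("replicator field matches hand-computed values and fixed points", {
  p <- model_params(r = 0.026, alpha = 0.484, beta = 1)
  sch <- treatment_schedule()

  d <- replicator_rhs("baseline", 0, phenotype_state(0.5), p, sch)
  expect_equal(d[["xA"]], 0.001677, tolerance = 1e-12)
  expect_equal(d[["xM"]], -0.001677, tolerance = 1e-12)

  # extinct phenotype stays extinct in every model without influx
  for (m in c("baseline", "baseline_transitions", "celltype_therapy")) {
    pm <- params_for(m, model_params(r = 0.03, alpha = 0.5, beta = 0.9,
                                     tau1 = 1e-4, tau2 = 1e-4, gamma = 0.01))
    d0 <- replicator_rhs(m, 50, phenotype_state(0, 1), pm,
                         treatment_schedule(0, 100))
    expect_equal(d0[["xA"]], 0)
  }

  # neutrality: alpha = beta = 1 gives a zero field everywhere
  pn <- model_params(r = 0.026, alpha = 1, beta = 1)
  for (xA in c(0.1, 0.5, 0.9)) {
    expect_equal(unname(replicator_rhs("baseline", 0, phenotype_state(xA), pn, sch)),
                 c(0, 0))
  }
})

test_that("frequencies are conserved: derivatives sum to zero for all models", {
  set.seed(42)
  sch <- treatment_schedule(c(24, 264), c(96, 336))
  for (i in 1:40) {
    p <- rand_params()
    s <- rand_state()
    for (m in model_ids()) {
      pm <- params_for(m, p)
      for (t in c(50, 150)) {  # therapy on at 50, off at 150
        d <- replicator_rhs(m, t, s, pm, sch)
        expect_lt(abs(d[["xA"]] + d[["xM"]]), 1e-12)
      }
    }
  }
})

test_that("selection favors ADRN whenever beta = 1 and alpha < 1", {
  p <- model_params(r = 0.026, alpha = 0.484, beta = 1)
  for (xA in seq(0.05, 0.95, by = 0.1)) {
    d <- replicator_rhs("baseline", 0, phenotype_state(xA), p)
    expect_gt(d[["xA"]], 0)
  }
})

test_that("therapy models reduce to baseline when the forcing is absent", {
  s <- phenotype_state(0.37)
  base <- model_params(r = 0.026, alpha = 0.484, beta = 0.9)
  d_base <- replicator_rhs("baseline", 10, s, base)

  # empty schedule: bitwise-identical fields
  p_ct <- model_params(r = 0.026, alpha = 0.484, beta = 0.9, gamma = 0.05)
  p_cs <- model_params(r = 0.026, alpha = 0.484, beta = 0.9,
                       gamma = 0.05, zeta = 0.01)
  expect_identical(replicator_rhs("celltype_therapy", 10, s, p_ct), d_base)
  expect_identical(replicator_rhs("cellstate_therapy", 10, s, p_cs), d_base)

  # zero transition rates: transitions model equals baseline
  p_tr <- model_params(r = 0.026, alpha = 0.484, beta = 0.9)
  expect_identical(replicator_rhs("baseline_transitions", 10, s, p_tr), d_base)
})

test_that("cell-state switching moves exactly zeta*xA from ADRN to MES", {
  sch <- treatment_schedule(0, 100)
  s <- phenotype_state(0.6)
  p_ct <- model_params(r = 0.026, alpha = 0.484, beta = 1, gamma = 0.01)
  p_cs <- model_params(r = 0.026, alpha = 0.484, beta = 1,
                       gamma = 0.01, zeta = 0.004)
  d_ct <- replicator_rhs("celltype_therapy", 50, s, p_ct, sch)
  d_cs <- replicator_rhs("cellstate_therapy", 50, s, p_cs, sch)
  expect_equal(d_cs[["xA"]], d_ct[["xA"]] - 0.004 * 0.6, tolerance = 1e-14)
  expect_equal(d_cs[["xM"]], d_ct[["xM"]] + 0.004 * 0.6, tolerance = 1e-14)
  expect_lt(abs(d_cs[["xA"]] + d_cs[["xM"]]), 1e-15)
})

test_that("contracts reject invalid states, models, and parameter sets", {
  p <- model_params(r = 0.026, alpha = 0.5, beta = 1)
  expect_error(per_capita_growth("baseline", c(0.5, 0.6), p), "simplex")
  expect_error(per_capita_growth("logistic", phenotype_state(0.5), p),
               "unknown model")
  expect_error(phenotype_state(0.5, 0.5001), "sum to 1")
  expect_error(phenotype_state(-0.1, 1.1), "non-negative")
  expect_error(model_params(r = -1), "positive")
  # smuggling a switching rate into the baseline model is rejected
  p_bad <- model_params(r = 0.026, alpha = 0.5, beta = 1, zeta = 0.01)
  expect_error(validate_params("baseline", p_bad), "must be zero")
  expect_silent(validate_params("cellstate_therapy", p_bad))
})

test_that("treatment schedules use half-open intervals", {
  sch <- treatment_schedule(c(24, 264), c(96, 336))
  expect_equal(therapy_on(sch, c(23.9, 24, 95.9, 96, 264, 336)),
               c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_false(therapy_on(treatment_schedule(), 50))
  expect_error(treatment_schedule(10, 10), "end > start")
  expect_error(treatment_schedule(c(0, 5), c(10, 20)), "non-overlapping")
})
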