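# Independent fixed-step Euler integrator, written directly from the model
# equations. Deliberately does not call the package's rhs machinery so it can
# serve as an oracle for the adaptive integrator.
euler_oracle <- function(model, params, schedule, x0, t0, t_end, dt = 0.001) {
  xA <- x0[[1]]; xM <- x0[[2]]
  r <- params[["r"]]; al <- params[["alpha"]]; be <- params[["beta"]]
  tau1 <- params[["tau1"]]; tau2 <- params[["tau2"]]
  gam <- params[["gamma"]]; zet <- params[["zeta"]]
  n <- round((t_end - t0) / dt)
  t <- t0
  s_on <- schedule$on_start; s_off <- schedule$on_end
  for (i in seq_len(n)) {
    on <- length(s_on) && any(t >= s_on & t < s_off)
    fA <- r * (1 - xA - al * xM)
    fM <- r * (1 - be * xA - xM)
    if (model == "baseline_transitions") {
      fA <- fA - tau1 * xA + tau2 * xM
      fM <- fM + tau1 * xA - tau2 * xM
    }
    if (on && model %in% c("celltype_therapy", "cellstate_therapy")) {
      fA <- fA - gam
    }
    phi <- xA * fA + xM * fM
    dA <- xA * (fA - phi)
    dM <- xM * (fM - phi)
    if (on && model == "cellstate_therapy") {
      dA <- dA - zet * xA
      dM <- dM + zet * xA
    }
    xA <- xA + dt * dA
    xM <- xM + dt * dM
    t <- t0 + i * dt
  }
  c(xA = xA, xM = xM)
}

# random simplex state away from the boundary
rand_state <- function() {
  xA <- stats::runif(1, 0.05, 0.95)
  phenotype_state(xA)
}

# random parameter set in a biologically plausible range
rand_params <- function() {
  model_params(r = stats::runif(1, 0.01, 0.05),
               alpha = stats::runif(1, 0, 1.3),
               beta = stats::runif(1, 0, 1.3),
               tau1 = stats::runif(1, 0, 1e-3),
               tau2 = stats::runif(1, 0, 1e-3),
               gamma = stats::runif(1, 0, 0.02),
               zeta = stats::runif(1, 0, 0.02))
}

# restrict a full random parameter set to the rates a model uses
params_for <- function(model, p) {
  keep <- c("r", "alpha", "beta",
            switch(model,
                   baseline = character(0),
                   baseline_transitions = c("tau1", "tau2"),
                   celltype_therapy = "gamma",
                   cellstate_therapy = c("gamma", "zeta")))
  args <- as.list(unclass(p)[keep])
  do.call(model_params, args)
}

untreated_ref <- function() {
  c(r = growth_rate_from_doubling(27), alpha = 0.484, beta = 1.00)
}
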