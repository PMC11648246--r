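#' Per-capita growth terms of the replicator models
#'
#' Evaluates, for each phenotype, the full bracketed per-capita term of the
#' model's differential equation excluding the mean-fitness term `phi`.
#' For the baseline model these are
#' `gA = r (1 - xA - alpha xM)` and `gM = r (1 - beta xA - xM)`;
#' the transitions model adds `-tau1 xA + tau2 xM` to `gA` (and its negative
#' to `gM`); the cell-type therapy model subtracts `gamma` from `gA` while
#' therapy is on; the cell-state therapy model subtracts `gamma + zeta` from
#' `gA` (the matching `+ zeta xA` influx into MES lives in [replicator_rhs()],
#' outside the per-capita bracket).
#'
#' @param model Model identifier, see [model_ids()].
#' @param state A [phenotype_state()] (or numeric `c(xA, xM)` on the simplex).
#' @param params A [model_params()] vector valid for `model`.
#' @param therapy_on Logical: is therapy currently on?
#' @return Named numeric vector `c(gA =, gM =)`.
#' @export
per_capita_growth <- function(model, state, params, therapy_on = FALSE) {
  model <- match_model(model)
  state <- as_simplex_state(state)
  validate_params(model, params)
  xA <- state[["xA"]]; xM <- state[["xM"]]
  r <- params[["r"]]
  gA <- r * (1 - xA - params[["alpha"]] * xM)
  gM <- r * (1 - params[["beta"]] * xA - xM)
  if (model == "baseline_transitions") {
    flux <- -params[["tau1"]] * xA + params[["tau2"]] * xM
    gA <- gA + flux
    gM <- gM - flux
  }
  if (model == "celltype_therapy" && therapy_on) {
    gA <- gA - params[["gamma"]]
  }
  if (model == "cellstate_therapy" && therapy_on) {
    gA <- gA - params[["gamma"]] - params[["zeta"]]
  }
  c(gA = gA, gM = gM)
}

# simplex guard shared by the dynamics and simulator layers; states further
# than `tol` from the simplex are rejected, never renormalized
as_simplex_state <- function(state, tol = 1e-6) {
  if (inherits(state, "phenotype_state")) return(state)
  stopifnot(is.numeric(state), length(state) == 2L)
  if (is.null(names(state))) names(state) <- c("xA", "xM")
  if (!all(is.finite(state)) || any(state < -tol) ||
      abs(sum(state) - 1) > tol) {
    stop("state is off the frequency simplex: (",
         paste(signif(state, 8), collapse = ", "), ")", call. = FALSE)
  }
  state
}

#' Mean population fitness
#'
#' The frequency-weighted average `phi = xA gA + xM gM` of the per-capita
#' fitness terms. For the cell-state therapy model the caller must pass the
#' ADRN term with the switching rate `zeta` added back (`gA' = fA - gamma`),
#' so that the `-zeta xA` outflow and `+zeta xA` influx cancel in the full
#' system and the simplex is conserved; [replicator_rhs()] does this.
#'
#' @param state A [phenotype_state()] (or numeric pair on the simplex).
#' @param gA,gM Per-capita fitness terms for ADRN and MES.
#' @return The scalar mean fitness.
#' @export
mean_fitness <- function(state, gA, gM) {
  state <- as_simplex_state(state)
  state[["xA"]] * gA + state[["xM"]] * gM
}

#' Right-hand side of the replicator models
#'
#' Returns `(dxA/dt, dxM/dt)` at time `t`. Therapy status is looked up in
#' `schedule` (half-open on-intervals). For every model the two derivatives
#' sum to zero: frequencies stay on the simplex along any trajectory.
#'
#' @inheritParams per_capita_growth
#' @param t Time in hours post-seeding.
#' @param schedule A [treatment_schedule()].
#' @return Named numeric vector `c(xA =, xM =)` of time derivatives.
#' @examples
#' p <- model_params(r = 0.026, alpha = 0.484, beta = 1)
#' replicator_rhs("baseline", 0, phenotype_state(0.5), p, treatment_schedule())
#' @export
replicator_rhs <- function(model, t, state, params,
                           schedule = treatment_schedule()) {
  model <- match_model(model)
  on <- therapy_on(schedule, t)
  rhs_at(model, state, params, on)
}

# core field evaluation with the therapy flag already resolved (the simulator
# resolves the flag once per schedule segment rather than per step)
rhs_at <- function(model, state, params, on) {
  state <- as_simplex_state(state)
  g <- per_capita_growth(model, state, params, therapy_on = on)
  gA_phi <- g[["gA"]]
  if (model == "cellstate_therapy" && on) {
    # phi excludes the -zeta outflow so the switching flux cancels exactly
    gA_phi <- gA_phi + params[["zeta"]]
  }
  phi <- mean_fitness(state, gA_phi, g[["gM"]])
  dxA <- state[["xA"]] * (g[["gA"]] - phi)
  dxM <- state[["xM"]] * (g[["gM"]] - phi)
  if (model == "cellstate_therapy" && on) {
    influx <- params[["zeta"]] * state[["xA"]]
    dxM <- dxM + influx
  }
  c(xA = dxA, xM = dxM)
}
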