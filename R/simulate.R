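#' Integrate a replicator model over time
#'
#' Adaptive-step integration (lsoda, via \pkg{deSolve}) of any of the four
#' models, with the integration split at every treatment on/off switch point
#' so that no step straddles a discontinuity in the forcing. No
#' renormalization is applied during integration: drift off the simplex
#' beyond `1e-6` is an error, not a silent correction.
#'
#' @inheritParams replicator_rhs
#' @param x0 Initial [phenotype_state()].
#' @param t0 Initial time (hours); by convention the first observation time of
#'   the dataset being fitted, with `x0` equal to that observation.
#' @param eval_times Strictly increasing times `>= t0` at which to report the
#'   state (`t0` itself need not be included; it is always reported).
#' @param rtol,atol Relative and absolute integration tolerances. Frequencies
#'   are O(1), so the defaults sit far below any measurement noise floor.
#' @return A `replifit_trajectory`: data.frame with columns `time`, `xA`,
#'   `xM` and attributes `model`, `params`, `schedule`.
#' @examples
#' p <- model_params(r = growth_rate_from_doubling(27), alpha = 0.484, beta = 1)
#' simulate_model("baseline", p, treatment_schedule(),
#'                phenotype_state(0.85), t0 = 48, eval_times = c(72, 96))
#' @export
simulate_model <- function(model, params, schedule, x0, t0, eval_times,
                           rtol = 1e-8, atol = 1e-10) {
  model <- match_model(model)
  validate_params(model, params)
  x0 <- as_simplex_state(x0)
  stopifnot(inherits(schedule, "treatment_schedule"),
            is.numeric(eval_times), length(eval_times) >= 1L)
  eval_times <- as.numeric(eval_times)
  if (any(eval_times < t0)) stop("eval_times must be >= t0", call. = FALSE)
  if (is.unsorted(eval_times, strictly = TRUE)) {
    stop("eval_times must be strictly increasing", call. = FALSE)
  }
  t_end <- max(eval_times)

  # force a mesh break at every on/off switch inside (t0, t_end)
  switches <- sort(unique(c(schedule$on_start, schedule$on_end)))
  switches <- switches[switches > t0 & switches < t_end]
  breaks <- sort(unique(c(t0, switches, t_end)))

  out_t <- t0
  out_x <- matrix(unclass(x0), nrow = 1,
                  dimnames = list(NULL, c("xA", "xM")))
  state <- unclass(x0)

  deriv <- fast_deriv(model, params)
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    on <- therapy_on(schedule, (a + b) / 2)
    seg_times <- sort(unique(c(a, eval_times[eval_times > a & eval_times <= b], b)))
    sol <- deSolve::ode(
      y = state, times = seg_times,
      func = deriv, parms = on, method = "lsoda", rtol = rtol, atol = atol
    )
    if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(seg_times)) {
      stop("integration failed near t = ", utils::tail(sol[, 1], 1),
           " h", call. = FALSE)
    }
    keep <- sol[-1, , drop = FALSE]
    out_t <- c(out_t, keep[, "time"])
    out_x <- rbind(out_x, keep[, c("xA", "xM"), drop = FALSE])
    state <- c(xA = unname(keep[nrow(keep), "xA"]),
               xM = unname(keep[nrow(keep), "xM"]))
  }

  drift <- abs(rowSums(out_x) - 1)
  if (any(drift > 1e-6)) {
    stop("trajectory drifted off the simplex (max |xA+xM-1| = ",
         signif(max(drift), 3), ")", call. = FALSE)
  }

  traj <- data.frame(time = out_t, xA = out_x[, "xA"], xM = out_x[, "xM"])
  # report exactly t0 and the requested eval times
  traj <- traj[traj$time %in% c(t0, eval_times), , drop = FALSE]
  rownames(traj) <- NULL
  structure(traj, model = model, params = params, schedule = schedule,
            class = c("replifit_trajectory", "data.frame"))
}

# validation-free derivative closure for the integrator hot loop; `parms`
# carries the therapy flag resolved once per schedule segment. Must stay in
# lockstep with rhs_at(), which the oracle-equivalence tests enforce.
fast_deriv <- function(model, params) {
  r <- params[["r"]]; a <- params[["alpha"]]; b <- params[["beta"]]
  tau1 <- params[["tau1"]]; tau2 <- params[["tau2"]]
  gamma <- params[["gamma"]]; zeta <- params[["zeta"]]
  trans <- model == "baseline_transitions"
  ct <- model == "celltype_therapy"
  cs <- model == "cellstate_therapy"
  function(t, y, parms) {
    on <- parms
    xA <- y[[1L]]; xM <- y[[2L]]
    gA <- r * (1 - xA - a * xM)
    gM <- r * (1 - b * xA - xM)
    if (trans) {
      flux <- -tau1 * xA + tau2 * xM
      gA <- gA + flux
      gM <- gM - flux
    }
    if (on && (ct || cs)) gA <- gA - gamma
    phi <- xA * gA + xM * gM          # phi excludes the -zeta outflow
    dxA <- xA * (gA - phi)
    dxM <- xM * (gM - phi)
    if (on && cs) {
      dxA <- dxA - zeta * xA
      dxM <- dxM + zeta * xA
    }
    list(c(dxA, dxM))
  }
}

#' Long-run frequency of a model
#'
#' Integrates for `horizon` hours and returns the end state, failing unless
#' the field has effectively vanished there (`max |dx/dt| < tol`).
#'
#' @inheritParams simulate_model
#' @param horizon Integration length in hours.
#' @param tol Convergence tolerance on the field at the end state.
#' @return The end [phenotype_state()].
#' @export
equilibrium_frequency <- function(model, params, x0, horizon = 5000,
                                  tol = 1e-10) {
  traj <- simulate_model(model, params, treatment_schedule(), x0,
                         t0 = 0, eval_times = horizon)
  end <- c(xA = traj$xA[nrow(traj)], xM = traj$xM[nrow(traj)])
  end[end < 0 & end > -1e-9] <- 0  # integrator round-off at boundary fixed points
  f <- rhs_at(match_model(model), end, params, on = FALSE)
  if (max(abs(f)) >= tol) {
    stop("no equilibrium within horizon = ", horizon,
         " h (max |dx/dt| = ", signif(max(abs(f)), 3), ")", call. = FALSE)
  }
  phenotype_state(end[["xA"]], end[["xM"]], tol = 1e-6)
}
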