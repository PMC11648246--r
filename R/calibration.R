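#' Intrinsic growth rate from a doubling time
#'
#' `r = ln(2) / Td`. The SK-N-BE(2) cell line doubles in about 27 h, giving
#' `r` of roughly 0.026 per hour.
#'
#' @param doubling_time Doubling time in hours, > 0.
#' @return Per-hour growth rate.
#' @examples
#' growth_rate_from_doubling(27)  # ~0.0257/h
#' @export
growth_rate_from_doubling <- function(doubling_time) {
  stopifnot(is.numeric(doubling_time), length(doubling_time) == 1L)
  if (!is.finite(doubling_time) || doubling_time <= 0) {
    stop("doubling_time must be a positive number of hours", call. = FALSE)
  }
  log(2) / doubling_time
}

#' Residual vector of a model against a frequency dataset
#'
#' For each replicate, the model is simulated from that replicate's first
#' observation (initial time and state fixed at the data, not fitted);
#' residuals are `predicted - observed` for both phenotype frequencies at
#' every subsequent observation time, concatenated in deterministic
#' (replicate, time, phenotype) order. Both frequencies enter by default —
#' they are complementary, which the AIC accounting must keep in mind — and
#' `residuals = "adrn"` restricts to the ADRN frequency only.
#'
#' @inheritParams simulate_model
#' @param data A [frequency_dataset()]; its attached schedule provides the
#'   therapy forcing.
#' @param residuals `"both"` (default) or `"adrn"`.
#' @return Numeric residual vector, with attributes `observed` and
#'   `predicted` (the aligned flattened vectors, used for pooled R-squared).
#' @export
residual_vector <- function(model, params, data, residuals = c("both", "adrn")) {
  residuals <- match.arg(residuals)
  model <- match_model(model)
  validate_params(model, params)
  stopifnot(inherits(data, "frequency_dataset"))
  schedule <- dataset_schedule(data)

  res <- obs <- pred <- numeric(0)
  for (rep_id in sort(unique(data$replicate))) {
    d <- data[data$replicate == rep_id, , drop = FALSE]
    d <- d[order(d$time_h), , drop = FALSE]
    x0 <- phenotype_state(d$freq_adrn[1], d$freq_mes[1], tol = 1e-6)
    traj <- simulate_model(model, params, schedule, x0,
                           t0 = d$time_h[1], eval_times = d$time_h[-1])
    fit <- traj[match(d$time_h[-1], traj$time), , drop = FALSE]
    for (i in seq_len(nrow(fit))) {
      if (residuals == "both") {
        res  <- c(res, fit$xA[i] - d$freq_adrn[i + 1], fit$xM[i] - d$freq_mes[i + 1])
        obs  <- c(obs, d$freq_adrn[i + 1], d$freq_mes[i + 1])
        pred <- c(pred, fit$xA[i], fit$xM[i])
      } else {
        res  <- c(res, fit$xA[i] - d$freq_adrn[i + 1])
        obs  <- c(obs, d$freq_adrn[i + 1])
        pred <- c(pred, fit$xA[i])
      }
    }
  }
  structure(res, observed = obs, predicted = pred)
}

#' Specify a model fit
#'
#' Which parameters are free, which are fixed at what values, box bounds, and
#' starting values. The four study configurations are: baseline with free
#' `alpha, beta` bounded above by 1; the transitions model adding free
#' `tau1, tau2` on `[0, Inf)`; the cell-type therapy model with only `gamma`
#' free (`r, alpha, beta` fixed at the untreated estimates); and the
#' cell-state therapy model with free `gamma, zeta`. A variant of the
#' baseline fit leaves `beta` unbounded above.
#'
#' @param model Model identifier.
#' @param free Character vector of free parameter names.
#' @param fixed Named numeric vector/list of fixed parameters (must include
#'   every model parameter not in `free`; `r` is always required).
#' @param lower,upper Named bounds for the free parameters; defaults are 0
#'   and, for `alpha`/`beta`, an upper bound of 1 (`Inf` for the rates).
#' @param start Named starting values for the free parameters; defaults
#'   `alpha = 0.5`, `beta = 1`, `tau1 = tau2 = 0`, `gamma = 0.005`,
#'   `zeta = 0`.
#' @return A `fit_spec` object.
#' @export
fit_spec <- function(model, free, fixed = c(), lower = NULL, upper = NULL,
                     start = NULL) {
  model <- match_model(model)
  stopifnot(is.character(free))
  fixed <- unlist(fixed)
  if (length(intersect(free, names(fixed)))) {
    stop("parameters cannot be both free and fixed: ",
         paste(intersect(free, names(fixed)), collapse = ", "), call. = FALSE)
  }
  allowed <- c("r", "alpha", "beta", model_extra_params(model))
  bad <- setdiff(c(free, names(fixed)), allowed)
  if (length(bad)) {
    stop("parameter(s) not used by model '", model, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!setequal(c(free, names(fixed)), allowed)) {
    stop("every parameter of model '", model,
         "' must be either free or fixed: need ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  def_lower <- c(r = 1e-8, alpha = 0, beta = 0, tau1 = 0, tau2 = 0,
                 gamma = 0, zeta = 0)
  def_upper <- c(r = Inf, alpha = 1, beta = 1, tau1 = Inf, tau2 = Inf,
                 gamma = Inf, zeta = Inf)
  def_start <- c(r = growth_rate_from_doubling(27), alpha = 0.5, beta = 1,
                 tau1 = 0, tau2 = 0, gamma = 0.005, zeta = 0)
  lo <- def_lower[free]; hi <- def_upper[free]; st <- def_start[free]
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  if (!is.null(start)) st[names(start)] <- unlist(start)
  if (any(st < lo | st > hi)) {
    stop("starting values must lie within the bounds", call. = FALSE)
  }
  structure(list(model = model, free = free, fixed = fixed,
                 lower = lo, upper = hi, start = st),
            class = "fit_spec")
}

spec_full_params <- function(spec, free_values) {
  vals <- c(spec$fixed, stats::setNames(as.numeric(free_values), spec$free))
  do.call(model_params, as.list(vals[intersect(param_names(), names(vals))]))
}

#' Fit a replicator model to a frequency dataset
#'
#' Bounded Levenberg-Marquardt least squares (via \pkg{minpack.lm}) on the
#' residual vector of [residual_vector()]. Deterministic given the starting
#' values; optional jittered multi-start for noisy data. Non-convergence is
#' flagged (`converged = FALSE`), never a silent success; an all-fixed spec
#' simply evaluates the residuals (`k = 0`).
#'
#' @param spec A [fit_spec()].
#' @param data A [frequency_dataset()].
#' @param residuals Passed to [residual_vector()].
#' @param n_starts Number of starts; starts beyond the first jitter the
#'   starting point uniformly within the bounds (deterministically, from
#'   `jitter_seed`), and the best final RSS wins.
#' @param jitter_seed Integer seed for the multi-start jitter.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return A `fit_result`: list with `estimates` (all model parameters,
#'   fitted and fixed), `free`, `rss`, `n_obs`, `k`, `r2`, `aic`,
#'   `converged`, `n_iter`, `model`, `message`.
#' @examples
#' \donttest{
#' dat <- generate_scenario("untreated_baseline", seed = 1, noise_sd = 0)
#' fit <- fit_model(baseline_fit_spec(), dat)
#' fit$estimates[c("alpha", "beta")]
#' }
#' @export
fit_model <- function(spec, data, residuals = c("both", "adrn"),
                      n_starts = 1L, jitter_seed = 1L, maxiter = 500L) {
  stopifnot(inherits(spec, "fit_spec"), inherits(data, "frequency_dataset"))
  residuals <- match.arg(residuals)

  resid_fn <- function(free_values) {
    params <- spec_full_params(spec, free_values)
    as.numeric(residual_vector(spec$model, params, data, residuals = residuals))
  }

  if (length(spec$free) == 0L) {
    res <- residual_vector(spec$model, spec_full_params(spec, numeric(0)),
                           data, residuals = residuals)
    return(make_fit_result(spec, numeric(0), res, converged = TRUE,
                           n_iter = 0L, message = "all parameters fixed"))
  }

  starts <- list(spec$start)
  if (n_starts > 1L) {
    rng <- local_rng(jitter_seed)
    for (i in seq_len(n_starts - 1L)) {
      lo <- spec$lower; hi <- pmin(spec$upper, pmax(2 * abs(spec$start), 1))
      starts[[i + 1L]] <- stats::setNames(
        lo + rng(length(spec$free)) * (hi - lo), spec$free)
    }
  }

  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-10,
                                     ptol = 1e-10, gtol = 1e-10)
  for (st in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = spec$lower, upper = spec$upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) e)
    if (inherits(out, "error")) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)

  est <- stats::setNames(as.numeric(best$par), spec$free)
  res <- residual_vector(spec$model, spec_full_params(spec, est), data,
                         residuals = residuals)
  converged <- best$info %in% 1:4
  make_fit_result(spec, est, res, converged = converged,
                  n_iter = best$niter, message = best$message)
}

# uniform(0,1) generator isolated from the global RNG stream
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    u <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    u
  }
}

make_fit_result <- function(spec, est, res, converged, n_iter, message = "") {
  rss <- sum(res^2)
  n_obs <- length(res)
  k <- length(spec$free)
  obs <- attr(res, "observed"); pred <- attr(res, "predicted")
  r2 <- r_squared(obs, pred)
  aic <- if (rss > 0) aic_ls(rss, n_obs, k) else -Inf
  estimates <- spec_full_params(spec, est)
  structure(list(model = spec$model, estimates = estimates, free = spec$free,
                 rss = rss, n_obs = n_obs, k = k, r2 = r2, aic = aic,
                 converged = converged, n_iter = n_iter, message = message,
                 spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> model:", x$model, "\n")
  est <- unclass(x$estimates)
  tab <- data.frame(
    parameter = names(est),
    estimate_per_hour = as.numeric(est),
    estimate_per_day = as.numeric(est) * c(24, 1, 1, 24, 24, 24, 24),
    role = ifelse(names(est) %in% x$free, "fitted", "fixed")
  )
  # alpha and beta are dimensionless; only the rates carry a time unit
  tab$estimate_per_day[tab$parameter %in% c("alpha", "beta")] <- NA
  print(tab, row.names = FALSE, digits = 6)
  cat(sprintf("rss = %.6g, n = %d, k = %d, R2 = %.4f, AIC = %.3f\n",
              x$rss, x$n_obs, x$k, x$r2, x$aic))
  cat("converged:", x$converged, "in", x$n_iter, "iterations\n")
  invisible(x)
}

#' Ready-made fit specifications for the four study configurations
#'
#' @param r Fixed intrinsic growth rate (per hour).
#' @param beta_upper Upper bound for `beta` (set `Inf` for the unbounded
#'   variant of the baseline fit).
#' @param untreated Named vector with the untreated estimates `r`, `alpha`,
#'   `beta` to hold fixed in the therapy fits.
#' @return A [fit_spec()].
#' @name study_fit_specs
NULL

#' @rdname study_fit_specs
#' @export
baseline_fit_spec <- function(r = growth_rate_from_doubling(27),
                              beta_upper = 1) {
  fit_spec("baseline", free = c("alpha", "beta"), fixed = c(r = r),
           upper = c(beta = beta_upper))
}

#' @rdname study_fit_specs
#' @export
transitions_fit_spec <- function(r = growth_rate_from_doubling(27)) {
  fit_spec("baseline_transitions", free = c("alpha", "beta", "tau1", "tau2"),
           fixed = c(r = r))
}

#' @rdname study_fit_specs
#' @export
celltype_fit_spec <- function(untreated) {
  fit_spec("celltype_therapy", free = "gamma",
           fixed = untreated[c("r", "alpha", "beta")])
}

#' @rdname study_fit_specs
#' @export
cellstate_fit_spec <- function(untreated) {
  fit_spec("cellstate_therapy", free = c("gamma", "zeta"),
           fixed = untreated[c("r", "alpha", "beta")])
}
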