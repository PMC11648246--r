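#' Model identifiers
#'
#' The four replicator-dynamics models of ADRN/MES frequency dynamics:
#' \describe{
#'   \item{`"baseline"`}{untreated competition between the two phenotypes with
#'     logistic-style frequency-dependent fitness.}
#'   \item{`"baseline_transitions"`}{baseline plus background phenotype
#'     transition rates `tau1` (ADRN to MES) and `tau2` (MES to ADRN).}
#'   \item{`"celltype_therapy"`}{baseline plus a therapy-induced per-capita
#'     death rate `gamma` acting on ADRN cells while therapy is on (the
#'     cell-type hypothesis: no inter-conversion).}
#'   \item{`"cellstate_therapy"`}{cell-type model plus a facultative
#'     ADRN-to-MES switching rate `zeta` active only while therapy is on
#'     (the cell-state hypothesis).}
#' }
#'
#' @return Character vector of the four model identifiers.
#' @export
model_ids <- function() {
  c("baseline", "baseline_transitions", "celltype_therapy", "cellstate_therapy")
}

match_model <- function(model) {
  if (!is.character(model) || length(model) != 1L || !model %in% model_ids()) {
    stop("unknown model id: ", paste(model, collapse = ", "),
         " (must be one of ", paste(model_ids(), collapse = ", "), ")",
         call. = FALSE)
  }
  model
}

#' Construct a phenotype frequency state
#'
#' A point on the 1-simplex: the frequencies of the ADRN and MES phenotypes.
#'
#' @param xA ADRN frequency in \[0, 1\].
#' @param xM MES frequency; defaults to `1 - xA`.
#' @param tol Tolerance on `xA + xM = 1` at construction.
#' @return Named numeric vector `c(xA =, xM =)` of class `phenotype_state`.
#' @examples
#' phenotype_state(0.85)
#' @export
phenotype_state <- function(xA, xM = 1 - xA, tol = 1e-9) {
  stopifnot(is.numeric(xA), is.numeric(xM), length(xA) == 1L, length(xM) == 1L)
  if (!is.finite(xA) || !is.finite(xM) || xA < 0 || xM < 0) {
    stop("phenotype frequencies must be finite and non-negative", call. = FALSE)
  }
  if (abs(xA + xM - 1) > tol) {
    stop("phenotype frequencies must sum to 1 (got ", xA + xM, ")", call. = FALSE)
  }
  structure(c(xA = unname(xA), xM = unname(xM)), class = "phenotype_state")
}

param_names <- function() c("r", "alpha", "beta", "tau1", "tau2", "gamma", "zeta")

#' Construct a full parameter set for the replicator models
#'
#' Holds every rate used across the four models. All rates share one internal
#' time unit (per hour). Parameters not used by a given model must be zero;
#' [validate_params()] enforces this.
#'
#' @param r Intrinsic per-capita growth rate (per hour, > 0).
#' @param alpha Frequency effect of MES on ADRN (dimensionless, >= 0).
#' @param beta Frequency effect of ADRN on MES (dimensionless, >= 0).
#' @param tau1 Background ADRN-to-MES transition rate (per hour, >= 0).
#' @param tau2 Background MES-to-ADRN transition rate (per hour, >= 0).
#' @param gamma Therapy-induced ADRN death rate while therapy is on (per hour, >= 0).
#' @param zeta Therapy-induced ADRN-to-MES switching rate while therapy is on
#'   (per hour, >= 0).
#' @return Named numeric vector of class `model_params`.
#' @examples
#' model_params(r = growth_rate_from_doubling(27), alpha = 0.484, beta = 1)
#' @export
model_params <- function(r, alpha = 0, beta = 0, tau1 = 0, tau2 = 0,
                         gamma = 0, zeta = 0) {
  p <- c(r = r, alpha = alpha, beta = beta, tau1 = tau1, tau2 = tau2,
         gamma = gamma, zeta = zeta)
  if (!all(is.finite(p))) stop("all rates must be finite", call. = FALSE)
  if (r <= 0) stop("intrinsic growth rate r must be positive", call. = FALSE)
  if (any(p[-1] < 0)) stop("rates must be non-negative", call. = FALSE)
  structure(p, class = "model_params")
}

# parameters each model is allowed to use (beyond r, alpha, beta)
model_extra_params <- function(model) {
  switch(match_model(model),
    baseline             = character(0),
    baseline_transitions = c("tau1", "tau2"),
    celltype_therapy     = "gamma",
    cellstate_therapy    = c("gamma", "zeta")
  )
}

#' Validate a parameter set against a model identifier
#'
#' Rates that the model does not use must be exactly zero, so that a parameter
#' vector cannot silently smuggle, say, a switching rate into the baseline model.
#'
#' @param model A model identifier, see [model_ids()].
#' @param params A [model_params()] vector.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(model, params) {
  model <- match_model(model)
  stopifnot(inherits(params, "model_params") || (is.numeric(params) &&
            all(param_names() %in% names(params))))
  unused <- setdiff(c("tau1", "tau2", "gamma", "zeta"), model_extra_params(model))
  bad <- unused[params[unused] != 0]
  if (length(bad)) {
    stop("parameters unused by model '", model, "' must be zero: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(params)
}

#' Construct a piecewise on/off treatment schedule
#'
#' Therapy forcing for the treated models: `gamma(t)` and `zeta(t)` are active
#' exactly when `t` lies in one of the half-open on-intervals
#' `[start, end)` (hours post-seeding). At `t = end` therapy is off. An empty
#' schedule denotes the untreated condition.
#'
#' @param on_start,on_end Numeric vectors of equal length: interval starts and
#'   ends in hours. Intervals must be non-overlapping, strictly increasing,
#'   with `end > start`.
#' @return Object of class `treatment_schedule`.
#' @examples
#' # two 72 h cisplatin rounds separated by a 7-day drug holiday
#' treatment_schedule(c(24, 264), c(96, 336))
#' @export
treatment_schedule <- function(on_start = numeric(0), on_end = numeric(0)) {
  stopifnot(is.numeric(on_start), is.numeric(on_end),
            length(on_start) == length(on_end))
  if (length(on_start)) {
    if (any(on_end <= on_start)) {
      stop("each on-interval must have end > start", call. = FALSE)
    }
    if (is.unsorted(on_start, strictly = TRUE) ||
        any(on_start[-1] < on_end[-length(on_end)])) {
      stop("on-intervals must be strictly increasing and non-overlapping",
           call. = FALSE)
    }
  }
  structure(list(on_start = as.numeric(on_start), on_end = as.numeric(on_end)),
            class = "treatment_schedule")
}

#' Is therapy on at time t?
#'
#' @param schedule A [treatment_schedule()].
#' @param t Time(s) in hours post-seeding.
#' @return Logical vector: `TRUE` where `t` falls in a half-open on-interval.
#' @export
therapy_on <- function(schedule, t) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  if (!length(schedule$on_start)) return(rep(FALSE, length(t)))
  vapply(t, function(ti) {
    any(ti >= schedule$on_start & ti < schedule$on_end)
  }, logical(1))
}

#' @export
print.treatment_schedule <- function(x, ...) {
  if (!length(x$on_start)) {
    cat("<treatment_schedule> untreated (no on-intervals)\n")
  } else {
    cat("<treatment_schedule> therapy on during:\n")
    for (i in seq_along(x$on_start)) {
      cat(sprintf("  [%g, %g) h\n", x$on_start[i], x$on_end[i]))
    }
  }
  invisible(x)
}
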