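#' Coefficient of determination for a fitted trajectory
#'
#' Pooled `R^2 = 1 - RSS/TSS` over all residual entries (both phenotype
#' frequencies, all replicates), with the total sum of squares taken about
#' the mean of the pooled observed vector.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return The pooled R-squared (<= 1; can be negative for fits worse than
#'   the observed mean).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted), length(observed) >= 2L)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) {
    stop("zero total sum of squares: observed values are all identical",
         call. = FALSE)
  }
  1 - sum((predicted - observed)^2) / tss
}

#' Akaike information criterion for a least-squares fit
#'
#' The least-squares form `AIC = n log(RSS/n) + 2k` (no small-sample
#' correction), with `n` the length of the residual vector and `k` the
#' number of free parameters. Lower is better. Note that adding a parameter
#' that leaves the RSS unchanged raises the AIC by exactly 2.
#'
#' @param rss Residual sum of squares, > 0.
#' @param n_obs Number of residual entries, > 0.
#' @param k Number of free parameters, >= 0.
#' @return The AIC value.
#' @examples
#' aic_ls(0.01, 10, 2)  # 10*log(0.001) + 4
#' @export
aic_ls <- function(rss, n_obs, k) {
  stopifnot(is.numeric(rss), is.numeric(n_obs), is.numeric(k),
            n_obs > 0, k >= 0)
  if (rss <= 0) {
    stop("AIC is undefined at rss = 0 (log divergence); ",
         "report the fit as perfect instead", call. = FALSE)
  }
  n_obs * log(rss / n_obs) + 2 * k
}

#' Rank competing model fits by AIC
#'
#' @param entries Named list of [fit_model()] results fitted on the same
#'   dataset and residual layout. Ties in AIC are broken by smaller `k`,
#'   then by the order of the entries.
#' @return A `model_comparison`: data.frame (label, model, k, rss, r2, aic,
#'   delta_aic) sorted by ascending AIC, with attribute `best` (the winning
#'   label).
#' @export
compare_models <- function(entries) {
  stopifnot(is.list(entries), length(entries) >= 1L)
  if (is.null(names(entries)) || any(names(entries) == "")) {
    stop("entries must be a named list of fit results", call. = FALSE)
  }
  stopifnot(all(vapply(entries, inherits, logical(1), "fit_result")))
  n_obs <- vapply(entries, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1L) {
    stop("fits compare different residual layouts (n_obs differ); ",
         "AIC ranking requires the same dataset", call. = FALSE)
  }
  tab <- data.frame(
    label = names(entries),
    model = vapply(entries, `[[`, character(1), "model"),
    k = vapply(entries, `[[`, numeric(1), "k"),
    rss = vapply(entries, `[[`, numeric(1), "rss"),
    r2 = vapply(entries, `[[`, numeric(1), "r2"),
    aic = vapply(entries, `[[`, numeric(1), "aic")
  )
  ord <- order(tab$aic, tab$k, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  structure(tab, best = tab$label[1],
            class = c("model_comparison", "data.frame"))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> best by AIC:", attr(x, "best"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Profile sweep over a fixed switching rate
#'
#' Re-fits the cell-state therapy model with the ADRN-to-MES switching rate
#' `zeta` pinned at each grid value and only the therapy death rate `gamma`
#' free, tracing how goodness of fit degrades as switching is forced. Grid
#' values share the model's internal per-hour unit.
#'
#' @param data A treated [frequency_dataset()].
#' @param untreated Named vector of fixed untreated estimates
#'   (`r`, `alpha`, `beta`).
#' @param grid Increasing vector of fixed `zeta` values; default 21 equally
#'   spaced points from 0 to 0.02.
#' @param residuals Passed to [fit_model()].
#' @return A `sweep_result`: data.frame (zeta, gamma_hat, rss, r2, aic,
#'   converged) with the per-point fit objects in attribute `fits`. A failed
#'   grid-point fit is recorded as a row of `NA`s, not a fatal error.
#' @export
zeta_sweep <- function(data, untreated, grid = seq(0, 0.02, length.out = 21),
                       residuals = "both") {
  stopifnot(is.numeric(grid), length(grid) >= 1L)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  if (any(grid < 0)) stop("zeta values must be non-negative", call. = FALSE)
  fits <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    spec <- fit_spec("cellstate_therapy", free = "gamma",
                     fixed = c(untreated[c("r", "alpha", "beta")],
                               zeta = grid[i]))
    fit <- tryCatch(fit_model(spec, data, residuals = residuals),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(zeta = grid[i], gamma_hat = NA_real_,
                              rss = NA_real_, r2 = NA_real_, aic = NA_real_,
                              converged = FALSE)
    } else {
      fits[[i]] <- fit
      rows[[i]] <- data.frame(zeta = grid[i],
                              gamma_hat = fit$estimates[["gamma"]],
                              rss = fit$rss, r2 = fit$r2, aic = fit$aic,
                              converged = fit$converged)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, fits = fits, class = c("sweep_result", "data.frame"))
}
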