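#' Read and write frequency datasets as CSV
#'
#' The interchange schema has columns `time_h` (numeric), `replicate`
#' (string), `freq_adrn`, `freq_mes` (numeric) and `condition` (string,
#' constant per file). The treatment schedule is not stored in the CSV and
#' is supplied separately (it is experiment metadata, not per-row data).
#' Rows violating the simplex constraint are rejected with their row
#' numbers.
#'
#' @param path File path.
#' @param schedule [treatment_schedule()] to attach on read.
#' @param data A [frequency_dataset()] to write.
#' @return `read_frequency_csv()`: a [frequency_dataset()];
#'   `write_frequency_csv()`: `path`, invisibly.
#' @export
read_frequency_csv <- function(path, schedule = treatment_schedule()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("time_h", "replicate", "freq_adrn", "freq_mes", "condition")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("time_h", "freq_adrn", "freq_mes")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("non-numeric value in column '", col, "' at data row(s) ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    }
    df[[col]] <- v
  }
  cond <- unique(df$condition)
  if (length(cond) != 1L || !cond %in% c("UNTREATED", "TREATED")) {
    stop("condition column must be a single value, UNTREATED or TREATED",
         call. = FALSE)
  }
  frequency_dataset(df[, c("time_h", "replicate", "freq_adrn", "freq_mes")],
                    condition = cond, schedule = schedule)
}

#' @rdname read_frequency_csv
#' @export
write_frequency_csv <- function(data, path) {
  stopifnot(inherits(data, "frequency_dataset"))
  out <- as.data.frame(data)
  out$condition <- attr(data, "condition")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fit result to and from JSON
#'
#' Estimates are stored both per hour (the internal unit) and per day for
#' the rate parameters, so reports bridge the two conventions.
#'
#' @param fit A `fit_result` from [fit_model()].
#' @param path File path.
#' @return `write_fit_json()`: `path`, invisibly; `read_fit_json()`: a list
#'   mirroring the fit result fields (not a refittable object).
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  est <- unclass(fit$estimates)
  rates <- setdiff(names(est), c("alpha", "beta"))
  out <- list(
    model = fit$model,
    free = fit$free,
    estimates_per_hour = as.list(est),
    estimates_per_day = as.list(est[rates] * 24),
    rss = fit$rss, n_obs = fit$n_obs, k = fit$k,
    r2 = fit$r2, aic = fit$aic,
    converged = fit$converged, n_iter = fit$n_iter
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a zeta sweep or model comparison table as CSV
#'
#' @param x A `sweep_result` or `model_comparison`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
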