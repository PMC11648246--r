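#' Construct a frequency dataset
#'
#' Replicate-labelled observed phenotype frequencies at discrete sampling
#' times — the gated flow-cytometry summary data the models are fitted to.
#' Each row is one measurement of the ADRN/MES frequency pair; rows must sit
#' on the simplex and each replicate needs at least two distinct times.
#'
#' @param records data.frame with columns `time_h` (hours post-seeding),
#'   `replicate` (label), `freq_adrn`, `freq_mes` (each in \[0, 1\], summing
#'   to 1 within `1e-6` per row).
#' @param condition `"UNTREATED"` or `"TREATED"`.
#' @param schedule The [treatment_schedule()] in force during the experiment
#'   (empty for untreated data).
#' @return A `frequency_dataset`: the records data.frame (ordered by
#'   replicate, then time) with attributes `condition` and `schedule`.
#' @export
frequency_dataset <- function(records,
                              condition = c("UNTREATED", "TREATED"),
                              schedule = treatment_schedule()) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(records), inherits(schedule, "treatment_schedule"))
  need <- c("time_h", "replicate", "freq_adrn", "freq_mes")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records$replicate <- as.character(records$replicate)
  bad <- which(abs(records$freq_adrn + records$freq_mes - 1) > 1e-6 |
               records$freq_adrn < 0 | records$freq_mes < 0)
  if (length(bad)) {
    stop("frequencies must be non-negative and sum to 1; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_times <- tapply(records$time_h, records$replicate,
                    function(t) length(unique(t)))
  if (any(n_times < 2)) {
    stop("each replicate needs at least 2 distinct times; offending: ",
         paste(names(n_times)[n_times < 2], collapse = ", "), call. = FALSE)
  }
  ord <- order(records$replicate, records$time_h)
  records <- records[ord, need, drop = FALSE]
  rownames(records) <- NULL
  structure(records, condition = condition, schedule = schedule,
            class = c("frequency_dataset", "data.frame"))
}

#' @export
print.frequency_dataset <- function(x, ...) {
  cat("<frequency_dataset> ", attr(x, "condition"), ", ",
      length(unique(x$replicate)), " replicate(s), ", nrow(x), " records\n",
      sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

dataset_schedule <- function(data) {
  sch <- attr(data, "schedule")
  if (is.null(sch)) treatment_schedule() else sch
}
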