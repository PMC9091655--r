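#' Read a cohort covariate table
#'
#' The cohort table holds one row per patient with at minimum the patient
#' identifier, the clinical risk score (`grace_score`), the event indicator
#' (`event`, 0/1) and the follow-up time in months (`time_months`).  Any
#' additional column is preserved as a generic covariate.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` of class `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort_table(df)
}

#' Validate and class a data frame as a cohort table
#'
#' @param df a data frame with at least columns `id`, `grace_score`,
#'   `event`, `time_months`.
#' @return `df` with class `cohort_table` prepended.
#' @export
as_cohort_table <- function(df) {
  required <- c("id", "grace_score", "event", "time_months")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort table: missing required column(s): ",
         paste(sQuote(missing), collapse = ", "))
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop("cohort table: duplicate patient id(s): ",
         paste(dup, collapse = ", "))
  if (!all(df$event %in% c(0, 1)))
    stop("cohort table: event indicator must be 0 or 1")
  if (any(!is.finite(df$time_months) | df$time_months <= 0))
    stop("cohort table: follow-up time must be positive; offending id(s): ",
         paste(df$id[!is.finite(df$time_months) | df$time_months <= 0],
               collapse = ", "))
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort a `cohort_table` (or plain data frame with the required
#'   columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
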