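#' Beat-to-beat RR interval series
#'
#' Container for a raw Holter-style beat list: one row per detected beat,
#' holding the time of the beat (seconds from recording start, at the end of
#' the interval it terminates), the preceding RR interval in milliseconds and
#' a beat label.  Labels follow the usual Holter annotation coarsening:
#' `"normal"`, `"ectopic"`, `"artifact"`, `"unknown"`.
#'
#' @param patient_id single identifier (coerced to character).
#' @param beat_times numeric vector of beat times in seconds, strictly
#'   increasing.
#' @param intervals numeric vector of RR intervals in milliseconds.  Must be
#'   positive except for beats labelled `"artifact"`.
#' @param labels character vector of beat labels; recycled from `"normal"`
#'   when omitted.
#' @return An object of class `rr_series`: a list with fields `patient_id`,
#'   `beat_times`, `intervals`, `labels`.
#' @seealso [read_rr_file()], [filter_nn()]
#' @export
rr_series <- function(patient_id, beat_times, intervals,
                      labels = rep("normal", length(intervals))) {
  beat_times <- as.numeric(beat_times)
  intervals <- as.numeric(intervals)
  labels <- as.character(labels)
  n <- length(intervals)
  if (length(beat_times) != n || length(labels) != n)
    stop("rr_series: beat_times, intervals and labels must have equal length")
  if (n == 0L) stop("rr_series: empty series")
  bad_lab <- setdiff(unique(labels), c("normal", "ectopic", "artifact", "unknown"))
  if (length(bad_lab))
    stop("rr_series: invalid beat label(s): ", paste(bad_lab, collapse = ", "))
  if (any(!is.finite(beat_times)))
    stop("rr_series: non-finite beat times")
  if (any(diff(beat_times) <= 0))
    stop("rr_series: beat times not strictly increasing at row ",
         which(diff(beat_times) <= 0)[1] + 1L)
  if (any(intervals <= 0 & labels != "artifact"))
    stop("rr_series: non-positive interval not labelled artifact at row ",
         which(intervals <= 0 & labels != "artifact")[1])
  structure(list(patient_id = as.character(patient_id)[1],
                 beat_times = beat_times,
                 intervals = intervals,
                 labels = labels),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat("RR series", sQuote(x$patient_id), "-", length(x$intervals), "beats,",
      sprintf("%.1f", utils::tail(x$beat_times, 1) / 60), "min\n")
  tab <- table(x$labels)
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  mean RR:", sprintf("%.1f ms", mean(x$intervals[x$labels == "normal"])), "\n")
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Read a per-patient RR interval file
#'
#' Reads the plain-text RR dialect used throughout the package: a CSV with
#' header `t_sec,rr_ms,label` (the `label` column may be absent, defaulting
#' to `"normal"`).  Rows are never dropped: beats with a non-positive RR are
#' kept and relabelled `"artifact"` so that every exclusion downstream is
#' explicit.
#'
#' @param path path to the CSV file.
#' @param patient_id identifier to attach; defaults to the file name without
#'   extension.
#' @return An [rr_series] object.
#' @export
read_rr_file <- function(path, patient_id = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("t_sec", "rr_ms")) {
    if (!col %in% names(df))
      stop("read_rr_file: missing required column ", sQuote(col), " in ", path)
  }
  if (!"label" %in% names(df)) df$label <- "normal"
  t_sec <- as.numeric(df$t_sec)
  rr_ms <- as.numeric(df$rr_ms)
  if (any(!is.finite(t_sec)))
    stop("read_rr_file: non-numeric t_sec at row ", which(!is.finite(t_sec))[1])
  nonmono <- which(diff(t_sec) <= 0)
  if (length(nonmono))
    stop("read_rr_file: beat times not strictly increasing at row ",
         nonmono[1] + 1L)
  lab <- as.character(df$label)
  lab[!is.finite(rr_ms) | rr_ms <= 0] <- "artifact"
  rr_ms[!is.finite(rr_ms)] <- -1  # kept, flagged artifact
  rr_series(patient_id, t_sec, rr_ms, lab)
}

#' Write an RR series to its CSV dialect
#'
#' @param rr an [rr_series] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rr_file <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  utils::write.csv(data.frame(t_sec = rr$beat_times, rr_ms = rr$intervals,
                              label = rr$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
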