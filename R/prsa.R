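#' PRSA configuration
#'
#' Settings for phase-rectified signal averaging (PRSA) of an NN interval
#' series.  PRSA extracts quasi-periodic modulation from a noisy,
#' non-stationary series by aligning windows at "anchor" beats and
#' averaging.  For deceleration capacity the anchors are heart-rate
#' decelerations: beats whose RR interval is longer than the preceding one,
#' but by no more than `max_relative_increase` (larger jumps are treated as
#' artifacts, the canonical 5% rule).
#'
#' Deceleration capacity condenses the averaged profile `X(k)` into a single
#' number using the four central wavelet coefficients `k = -2, -1, 0, 1`.
#' Two conventions are supported:
#' \describe{
#'   \item{`"signed"`}{`DC = (X(0) + X(1) - X(-1) - X(-2)) / 4`, the
#'     canonical Haar-wavelet contrast.  This is the default: it measures
#'     the deceleration-related modulation in milliseconds and yields the
#'     familiar 0--10 ms clinical range.}
#'   \item{`"as_printed"`}{`DC = (X(0) + X(1) + X(-1) + X(-2)) / 4`, an
#'     all-plus variant occasionally seen in print.  On a stationary series
#'     it returns approximately the mean RR interval rather than a
#'     modulation amplitude; it is retained behind this flag for audits
#'     only.}
#' }
#'
#' @param direction only `"deceleration"` is implemented (anchors are RR
#'   lengthenings).
#' @param max_relative_increase anchor artifact bound as a fraction of the
#'   preceding interval (default 0.05).
#' @param L window half-length in beats (default 2, the minimum housing the
#'   four DC coefficients; larger values expose the full PRSA curve).
#' @param formula_convention `"signed"` (default) or `"as_printed"`.
#' @return An object of class `prsa_config`.
#' @export
prsa_config <- function(direction = "deceleration",
                        max_relative_increase = 0.05,
                        L = 2L,
                        formula_convention = c("signed", "as_printed")) {
  direction <- match.arg(direction)
  formula_convention <- match.arg(formula_convention)
  if (!is.numeric(max_relative_increase) ||
      max_relative_increase <= 0 || max_relative_increase >= 1)
    stop("prsa_config: max_relative_increase must be in (0, 1)")
  L <- as.integer(L)
  if (L < 2L) stop("prsa_config: L must be >= 2")
  structure(list(direction = direction,
                 max_relative_increase = max_relative_increase,
                 L = L,
                 formula_convention = formula_convention),
            class = "prsa_config")
}

#' Filter an RR series to normal-to-normal (NN) intervals
#'
#' Keeps beats that are labelled `"normal"`, fall inside physiologic bounds
#' and differ from the last *accepted* beat by at most `max_rel_change`
#' (sequential artifact filter, standard Holter practice).  Removed beats
#' set a gap flag on their successor so that downstream windowed statistics
#' never span a discontinuity.
#'
#' @param rr an [rr_series].
#' @param bounds length-2 numeric, physiologic interval bounds in ms
#'   (default 300--2000).
#' @param max_rel_change maximum relative change versus the last accepted
#'   beat (default 0.20).
#' @return An object of class `nn_series`: list with `patient_id`, `times`
#'   (s), `intervals` (ms) and `gap_flags` (logical; `TRUE` marks a
#'   discontinuity immediately before that beat).
#' @export
filter_nn <- function(rr, bounds = c(300, 2000), max_rel_change = 0.2) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  ok <- rr$labels == "normal" & x >= bounds[1] & x <= bounds[2]
  n <- length(x)
  acc <- logical(n)
  last <- NA_real_
  for (i in seq_len(n)) {
    if (ok[i] && (is.na(last) || abs(x[i] - last) / last <= max_rel_change)) {
      acc[i] <- TRUE
      last <- x[i]
    }
  }
  keep <- which(acc)
  if (!length(keep))
    stop("filter_nn: no analyzable NN intervals")
  structure(list(patient_id = rr$patient_id,
                 times = rr$beat_times[keep],
                 intervals = x[keep],
                 gap_flags = c(FALSE, diff(keep) > 1L)),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat("NN series", sQuote(x$patient_id), "-", length(x$intervals), "beats,",
      sum(x$gap_flags), "gaps, mean NN",
      sprintf("%.1f ms", mean(x$intervals)), "\n")
  invisible(x)
}

#' Select PRSA anchor beats
#'
#' Beat `i` (1-based) is a deceleration anchor iff
#' `RR[i] > RR[i-1]`, `RR[i] <= (1 + max_relative_increase) * RR[i-1]`,
#' neither beat carries a gap flag, and the full averaging window
#' `[i - L, i + L - 1]` lies inside the series without crossing a gap.
#'
#' @param nn an `nn_series` from [filter_nn()].
#' @param cfg a [prsa_config].
#' @return Integer vector of anchor indices (possibly empty), strictly
#'   increasing, referencing beats of `nn`.
#' @export
select_anchors <- function(nn, cfg = prsa_config()) {
  stopifnot(inherits(nn, "nn_series"), inherits(cfg, "prsa_config"))
  x <- nn$intervals
  n <- length(x)
  L <- cfg$L
  if (n < 2L) return(integer(0))
  i <- 2:n
  cand <- i[x[i] > x[i - 1L] &
            x[i] <= (1 + cfg$max_relative_increase) * x[i - 1L] &
            !nn$gap_flags[i] & !nn$gap_flags[i - 1L]]
  cand <- cand[cand - L >= 1L & cand + L - 1L <= n]
  if (!length(cand)) return(integer(0))
  # a gap at position j means a discontinuity between beats j-1 and j, so a
  # window [i-L, i+L-1] is contiguous iff no gap flag in (i-L, i+L-1]
  cg <- cumsum(nn$gap_flags)
  ngaps <- cg[cand + L - 1L] - cg[cand - L + 1L] + nn$gap_flags[cand - L + 1L]
  cand[ngaps == 0L]
}

#' Phase-rectified averaging profile and deceleration capacity
#'
#' Averages the NN series over windows centred at the anchors:
#' `X(k) = mean over anchors i of RR[i + k]`, for `k = -L, ..., L - 1`,
#' then condenses the four central coefficients into the deceleration
#' capacity according to the configured convention (see [prsa_config]).
#'
#' @param nn an `nn_series` from [filter_nn()].
#' @param anchors integer anchor indices from [select_anchors()].
#' @param cfg a [prsa_config].
#' @return An object of class `prsa_profile`: list with `X` (named numeric,
#'   names `-L ... L-1`), `anchor_count`, `dc_ms` and `config`.
#' @export
prsa_profile <- function(nn, anchors, cfg = prsa_config()) {
  stopifnot(inherits(nn, "nn_series"), inherits(cfg, "prsa_config"))
  if (!length(anchors)) {
    cond <- structure(class = c("dcgrace_no_anchors", "error", "condition"),
                      list(message = "prsa_profile: no anchors",
                           call = sys.call(), anchor_count = 0L))
    stop(cond)
  }
  L <- cfg$L
  ks <- (-L):(L - 1L)
  X <- vapply(ks, function(k) mean(nn$intervals[anchors + k]), numeric(1))
  names(X) <- as.character(ks)
  dc <- switch(cfg$formula_convention,
               signed = (X["0"] + X["1"] - X["-1"] - X["-2"]) / 4,
               as_printed = (X["0"] + X["1"] + X["-1"] + X["-2"]) / 4)
  structure(list(X = X, anchor_count = length(anchors),
                 dc_ms = unname(dc), config = cfg),
            class = "prsa_profile")
}

#' Compute deceleration capacity from a raw RR series
#'
#' Convenience composition of [filter_nn()], [select_anchors()] and
#' [prsa_profile()].  Deterministic for fixed input and configuration.
#'
#' @param rr an [rr_series].
#' @param cfg a [prsa_config].
#' @param bounds,max_rel_change NN filter parameters, see [filter_nn()].
#' @param min_duration minimum usable NN span in seconds (default 60).
#' @return A `prsa_profile`; the capacity itself is its `dc_ms` field.
#' @examples
#' rr <- rr_series("demo", cumsum(c(800, 804, 800, 808, 800, 804)) / 1000,
#'                 c(800, 804, 800, 808, 800, 804))
#' deceleration_capacity(rr)$dc_ms  # 1 ms
#' @export
deceleration_capacity <- function(rr, cfg = prsa_config(),
                                  bounds = c(300, 2000),
                                  max_rel_change = 0.2,
                                  min_duration = 60) {
  nn <- filter_nn(rr, bounds = bounds, max_rel_change = max_rel_change)
  span <- nn$times[length(nn$times)] - nn$times[1]
  if (span < min_duration)
    stop("deceleration_capacity: usable NN span ", round(span, 1),
         " s is below the required ", min_duration, " s")
  prsa_profile(nn, select_anchors(nn, cfg), cfg)
}

#' @export
print.prsa_profile <- function(x, ...) {
  cat("PRSA profile (", x$config$formula_convention, " convention)\n", sep = "")
  cat("  anchors:", x$anchor_count, "\n")
  cat("  DC:", sprintf("%.3f ms", x$dc_ms), "\n")
  cat("  X(k), k = -2..1:",
      paste(sprintf("%.2f", x$X[as.character(-2:1)]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.prsa_profile <- function(x, ...) {
  k <- as.integer(names(x$X))
  graphics::plot(k, x$X, type = "b", pch = 19,
                 xlab = "beat offset k from anchor",
                 ylab = "mean RR (ms)",
                 main = sprintf("PRSA profile, DC = %.2f ms (%d anchors)",
                                x$dc_ms, x$anchor_count), ...)
  graphics::abline(v = -0.5, lty = 3)
  invisible(x)
}

#' Deceleration-capacity risk stratification
#'
#' Trichotomizes deceleration capacity at the established 2.5 ms and 4.5 ms
#' prognostic cutpoints: low risk above 4.5 ms, intermediate risk in
#' (2.5, 4.5], high risk at or below 2.5 ms (each boundary belongs to the
#' lower band).
#'
#' @param dc_ms numeric vector of deceleration capacities in milliseconds.
#' @param thresholds length-2 numeric, the high/intermediate and
#'   intermediate/low cutpoints (default `c(2.5, 4.5)`).
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
dc_risk_group <- function(dc_ms, thresholds = c(2.5, 4.5)) {
  if (any(!is.finite(dc_ms)))
    stop("dc_risk_group: non-finite deceleration capacity")
  out <- ifelse(dc_ms > thresholds[2], "low",
                ifelse(dc_ms > thresholds[1], "intermediate", "high"))
  factor(out, levels = c("low", "intermediate", "high"))
}
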