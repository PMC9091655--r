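#' Time-domain heart rate variability panel
#'
#' Computes the standard 24-h time-domain descriptors from an NN series:
#' \describe{
#'   \item{SDNN}{sample standard deviation of all NN intervals (ms).}
#'   \item{SDANN}{sample standard deviation of the per-segment mean NN over
#'     consecutive `segment_length` windows anchored at the start of the
#'     recording; the final incomplete window is dropped.}
#'   \item{rMSSD}{root mean square of successive NN differences (ms);
#'     pairs spanning a gap are excluded.}
#'   \item{pNN50}{percentage of successive differences exceeding 50 ms,
#'     same pair rule.}
#'   \item{mean_hr}{60000 / mean NN (beats per minute); defined through the
#'     mean interval rather than beats per elapsed time so that recording
#'     gaps do not bias it.}
#' }
#'
#' @param nn an `nn_series` from [filter_nn()].
#' @param segment_length SDANN segment length in seconds (default 300).
#' @return Object of class `hrv_time`: list with fields `sdnn`, `sdann`,
#'   `rmssd`, `pnn50`, `mean_hr`.
#' @export
hrv_time_domain <- function(nn, segment_length = 300) {
  stopifnot(inherits(nn, "nn_series"))
  x <- nn$intervals
  n <- length(x)
  if (n < 2L) stop("hrv_time_domain: need >= 2 NN intervals for SDNN")
  sdnn <- stats::sd(x)
  rel_t <- nn$times - nn$times[1]
  n_seg <- floor(rel_t[n] / segment_length)
  if (n_seg < 2L)
    stop("hrv_time_domain: need >= 2 complete segments for SDANN (have ",
         n_seg, ")")
  keep <- rel_t < n_seg * segment_length  # drop the incomplete tail
  seg_means <- tapply(x[keep], floor(rel_t[keep] / segment_length), mean)
  sdann <- stats::sd(seg_means)
  d <- diff(x)
  valid <- !nn$gap_flags[-1]  # pair (i, i+1) invalid when a gap precedes i+1
  d <- d[valid]
  if (!length(d)) stop("hrv_time_domain: no valid successive pairs for rMSSD")
  rmssd <- sqrt(mean(d^2))
  pnn50 <- 100 * mean(abs(d) > 50)
  structure(list(sdnn = sdnn, sdann = sdann, rmssd = rmssd, pnn50 = pnn50,
                 mean_hr = 60000 / mean(x)),
            class = "hrv_time")
}

#' @export
print.hrv_time <- function(x, ...) {
  cat(sprintf("SDNN %.1f ms | SDANN %.1f ms | rMSSD %.1f ms | pNN50 %.1f%% | HR %.1f bpm\n",
              x$sdnn, x$sdann, x$rmssd, x$pnn50, x$mean_hr))
  invisible(x)
}

#' Lomb-Scargle periodogram of an unevenly sampled series
#'
#' Classic normalised-by-nothing Lomb-Scargle power at the requested
#' frequencies, computed on the mean-removed values.  Used internally for
#' HRV band powers; exported because it is generally useful for beat-time
#' series.
#'
#' @param t sample times (seconds).
#' @param y sample values.
#' @param freqs frequencies in Hz at which to evaluate (must be > 0).
#' @return Numeric vector of raw Lomb powers, one per frequency.
#' @export
lomb_scargle <- function(t, y, freqs) {
  y <- y - mean(y)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
}

#' Frequency-domain heart rate variability (LF, HF, LF/HF)
#'
#' Band powers of the NN-interval tachogram, treated as an unevenly sampled
#' signal (interval value versus beat time) and analysed with the
#' Lomb-Scargle periodogram -- no resampling or interpolation.  The
#' periodogram is evaluated on a grid from `1/span` to the mean Nyquist
#' frequency with oversampling factor `ofac`, and scaled so that the total
#' gridded power equals the series variance (a Parseval constraint); a band
#' power is then the share of variance falling inside the band, in ms^2.
#'
#' Default band edges follow the standard short/long-term HRV convention:
#' LF 0.04--0.15 Hz, HF 0.15--0.40 Hz (LF half-open on the right so no
#' frequency is counted twice).
#'
#' @param nn an `nn_series` from [filter_nn()]; at least 5 minutes of usable data.
#' @param lf_band,hf_band length-2 numeric band edges in Hz.
#' @param ofac frequency oversampling factor (default 2).
#' @return Object of class `hrv_freq`: list with `lf`, `hf` (ms^2), `lf_hf`
#'   (ratio, `NA` when HF power is zero) and `band_edges`.
#' @export
hrv_spectral <- function(nn, lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40),
                         ofac = 2) {
  stopifnot(inherits(nn, "nn_series"))
  t <- nn$times
  y <- nn$intervals
  span <- t[length(t)] - t[1]
  if (span < 300)
    stop("hrv_spectral: need >= 5 minutes of usable NN data (have ",
         round(span, 1), " s)")
  v <- stats::var(y) * (length(y) - 1) / length(y)
  if (v == 0) {
    return(structure(list(lf = 0, hf = 0, lf_hf = NA_real_,
                          band_edges = c(lf = lf_band, hf = hf_band)),
                     class = "hrv_freq"))
  }
  fmax <- 1 / (2 * mean(diff(t)))
  df <- 1 / (ofac * span)
  freqs <- seq(df, fmax, by = df)
  P <- lomb_scargle(t, y, freqs)
  dens <- P / sum(P)
  lf <- v * sum(dens[freqs >= lf_band[1] & freqs < lf_band[2]])
  hf <- v * sum(dens[freqs >= hf_band[1] & freqs <= hf_band[2]])
  structure(list(lf = lf, hf = hf,
                 lf_hf = if (hf > 0) lf / hf else NA_real_,
                 band_edges = c(lf = lf_band, hf = hf_band)),
            class = "hrv_freq")
}

#' @export
print.hrv_freq <- function(x, ...) {
  cat(sprintf("LF %.1f ms^2 | HF %.1f ms^2 | LF/HF %s\n", x$lf, x$hf,
              if (is.na(x$lf_hf)) "NA" else sprintf("%.2f", x$lf_hf)))
  invisible(x)
}

#' Full HRV panel from a raw RR series
#'
#' Applies the NN filter and returns both the time-domain and the
#' frequency-domain panels.
#'
#' @inheritParams deceleration_capacity
#' @param segment_length SDANN segment length in seconds.
#' @return List with elements `time` ([hrv_time_domain()] result) and
#'   `freq` ([hrv_spectral()] result).
#' @export
hrv_panel <- function(rr, bounds = c(300, 2000), max_rel_change = 0.2,
                      segment_length = 300) {
  nn <- filter_nn(rr, bounds = bounds, max_rel_change = max_rel_change)
  list(time = hrv_time_domain(nn, segment_length = segment_length),
       freq = hrv_spectral(nn))
}
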