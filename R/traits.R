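# TraitSeries: a named, unit-bearing time series of one measurement for one
# plant — the common currency of all downstream analysis.

#' Create a trait series
#'
#' @param time_h Numeric timestamps in hours, strictly increasing.
#' @param values Numeric measurements, same length as `time_h`.
#' @param plant Plant identifier.
#' @param trait Trait name (e.g. `"mr_length"`).
#' @param units Unit string (e.g. `"mm"`).
#' @return A `trait_series` object.
#' @export
trait_series <- function(time_h, values, plant = "", trait = "",
                         units = "") {
  if (length(time_h) != length(values))
    stop("time_h and values must have equal length")
  if (length(time_h) > 1L && any(diff(time_h) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(time_h = as.numeric(time_h), values = as.numeric(values),
                 plant = plant, trait = trait, units = units),
            class = "trait_series")
}

#' @export
print.trait_series <- function(x, ...) {
  cat(sprintf("<trait_series> %s [%s], plant %s: %d samples over %.1f h\n",
              x$trait, x$units, as.character(x$plant), length(x$values),
              diff(range(x$time_h))))
  invisible(x)
}

#' @export
as.data.frame.trait_series <- function(x, ...) {
  data.frame(plant = x$plant, trait = x$trait, units = x$units,
             time_h = x$time_h, value = x$values)
}

#' Growth speed (temporal derivative)
#'
#' Finite differences of a length series: `diff(value) / diff(time)`,
#' reported at interval midpoints.
#'
#' @param series A `trait_series` with at least 2 samples.
#' @return A `trait_series` of length `n - 1` in `<units>/h`.
#' @export
growth_speed <- function(series) {
  stopifnot(inherits(series, "trait_series"), length(series$values) >= 2L)
  dv <- diff(series$values); dt <- diff(series$time_h)
  trait_series((series$time_h[-1] + series$time_h[-length(series$time_h)]) / 2,
               dv / dt, plant = series$plant,
               trait = paste0(series$trait, "_speed"),
               units = paste0(series$units, "/h"))
}

#' Detrend a series with a running median
#'
#' Subtracts a centred running-median filter (edges use a shrinking window),
#' leaving rhythmic residuals while removing slow trends.
#'
#' @param series A `trait_series`.
#' @param window_h Filter window in hours (default 12); must span at least 3
#'   samples. For spectral work use one full period of the slowest rhythm of
#'   interest (e.g. 24 for circadian analysis) so the filter passes it
#'   unattenuated.
#' @param trim_edges Drop the half-window margins at both ends where the
#'   centred filter is not fully supported (recommended before a Fourier
#'   transform; default `FALSE` keeps the shrinking-window edges).
#' @return A `trait_series` of residuals.
#' @export
detrend_series <- function(series, window_h = 12, trim_edges = FALSE) {
  x <- series$values; n <- length(x)
  dt <- if (n > 1L) median(diff(series$time_h)) else 1
  half <- max(1L, floor(window_h / dt / 2))
  if (2L * half + 1L < 3L) stop("window must span at least 3 samples")
  med <- vapply(seq_len(n), function(i) {
    median(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  keep <- if (trim_edges && n > 2L * half + 2L)
    (half + 1L):(n - half) else seq_len(n)
  trait_series(series$time_h[keep], (x - med)[keep], plant = series$plant,
               trait = paste0(series$trait, "_detrended"),
               units = series$units)
}

#' One-sided amplitude spectrum of a uniformly sampled series
#'
#' Computes the FFT amplitude spectrum (amplitude `2|X_k|/N` for non-DC bins)
#' with frequencies in 1/h and a derived period column. Use it on detrended
#' growth speeds to expose circadian (24-h) and ultradian (12-h) rhythms.
#'
#' @param series A `trait_series` with uniform timestamps.
#' @return Data frame with `frequency` (1/h), `amplitude` (series units) and
#'   `period` (h), ascending in frequency, DC bin excluded.
#' @export
fourier_spectrum <- function(series) {
  x <- series$values; n <- length(x)
  if (n < 4L) stop("series too short for a spectrum")
  dts <- diff(series$time_h)
  if (max(abs(dts - dts[1])) > 1e-6 * dts[1])
    stop("non-uniform timestamps; the FFT requires uniform sampling")
  dt <- dts[1]
  X <- fft(x)
  k <- seq_len(floor(n / 2))
  amp <- 2 * Mod(X[k + 1]) / n
  freq <- k / (n * dt)
  data.frame(frequency = freq, amplitude = amp, period = 1 / freq)
}

#' Spectral amplitude nearest a target period
#'
#' @param spectrum Data frame from [fourier_spectrum()].
#' @param period_h Target period in hours.
#' @return Amplitude at the nearest frequency bin.
#' @export
amplitude_at_period <- function(spectrum, period_h) {
  spectrum$amplitude[which.min(abs(spectrum$period - period_h))]
}

#' Enforce a monotonic growth constraint
#'
#' Length-like traits cannot decrease; the running maximum
#' `out[i] = max(in[1..i])` removes physically impossible dips.
#'
#' @param series A `trait_series`.
#' @return The monotone `trait_series`.
#' @export
enforce_monotonic <- function(series) {
  out <- series
  out$values <- cummax(series$values)
  out
}

#' Temporal persistence validation
#'
#' A detected structure is accepted only if its longest contiguous presence
#' run lasts strictly longer than `min_persist_h` (6 h by default), filtering
#' out transient misdetections and false starts.
#'
#' @param presence Logical vector, one entry per frame.
#' @param dt Frame interval, minutes.
#' @param min_persist_h Persistence threshold, hours.
#' @return `TRUE` if accepted.
#' @export
temporal_validation <- function(presence, dt, min_persist_h = 6) {
  stopifnot(dt > 0)
  if (!any(presence)) return(FALSE)
  r <- rle(as.logical(presence))
  longest <- max(r$lengths[r$values])
  # a run of k frames spans (k - 1) intervals of dt minutes
  (longest - 1) * dt / 60 > min_persist_h
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Two-sided test on the rank statistic U. For small samples (both groups at
#' most 8) the null distribution is enumerated exactly over all
#' `choose(nA+nB, nA)` labelings (ties handled by half-counting), otherwise
#' the normal approximation with tie correction is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return List with `U` (for group `a`) and `p` (two-sided).
#' @export
mann_whitney_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  U <- u_stat(a, b)
  if (na <= 8L && nb <= 8L) {
    pool <- c(a, b)
    combs <- utils::combn(na + nb, na)
    mu <- na * nb / 2
    us <- apply(combs, 2, function(ix) u_stat(pool[ix], pool[-ix]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
  } else {
    p <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
  list(U = U, p = p)
}

#' Mann-Whitney comparison at configurable time intervals
#'
#' Compares two experimental groups at each requested timepoint of a trait,
#' reporting the raw p per timepoint and Benjamini-Hochberg adjusted q across
#' timepoints.
#'
#' @param series_a,series_b Lists of `trait_series` (one per plant).
#' @param at_h Timepoints (hours) at which to compare; values are taken from
#'   the nearest sample of each series.
#' @return Data frame `time_h`, `n_a`, `n_b`, `U`, `p`, `q`.
#' @export
compare_groups_over_time <- function(series_a, series_b, at_h) {
  pick <- function(s, t) s$values[which.min(abs(s$time_h - t))]
  rows <- lapply(at_h, function(t) {
    va <- vapply(series_a, pick, numeric(1), t = t)
    vb <- vapply(series_b, pick, numeric(1), t = t)
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (length(va) == 0L || length(vb) == 0L)
      return(data.frame(time_h = t, n_a = length(va), n_b = length(vb),
                        U = NA_real_, p = NA_real_))
    mw <- mann_whitney_compare(va, vb)
    data.frame(time_h = t, n_a = length(va), n_b = length(vb),
               U = mw$U, p = mw$p)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}
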