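# Germination kinetics: event detection from tracked seeds, cumulative
# curve, and 4-parameter Hill model fit.

#' Four-parameter Hill germination model
#'
#' `G(t) = G0 + Gmax * t^n / (t50^n + t^n)`: `G0` base germination level
#' (percent), `Gmax` maximum additional germination (percent), `n` steepness,
#' `t50` time to half of `Gmax` (hours). At `t = t50` the value is exactly
#' `G0 + Gmax / 2`.
#'
#' @param t Time(s) in hours.
#' @param G0,Gmax,n,t50 Model parameters.
#' @return Germination percentage(s).
#' @export
hill_curve <- function(t, G0, Gmax, n, t50) {
  G0 + Gmax * t^n / (t50^n + t^n)
}

#' Time of maximum germination rate (TMGR)
#'
#' Closed form of the inflection of the Hill curve:
#' `TMGR = t50 * ((n - 1) / (n + 1))^(1/n)`, defined for `n > 1` (for
#' `n <= 1` the rate is maximal at t = 0 and TMGR is `NA`). TMGR is always
#' below `t50`.
#'
#' @param t50,n Hill parameters.
#' @return TMGR in hours, or `NA` when `n <= 1`.
#' @export
tmgr_closed_form <- function(t50, n) {
  if (n <= 1) return(NA_real_)
  t50 * ((n - 1) / (n + 1))^(1 / n)
}

#' Detect germination events and build the cumulative curve
#'
#' A seed germinates at the first frame where root pixels (class 1) appear
#' within its expanded seed box and persist according to
#' [temporal_validation()]. The curve is the cumulative percentage of tracked
#' seeds germinated at each frame (never decreasing, at most 100).
#'
#' @param tracks Track list from [track_plants()] (QC-removed tracks are
#'   skipped).
#' @param seq The `frame_sequence`.
#' @param margin Pixels by which the seed bounding box is expanded when
#'   looking for the radicle (default 12).
#' @param min_persist_h Persistence threshold for a valid emergence, hours.
#' @return A `trait_series` of percent germinated vs hours, with attributes
#'   `events` (data frame `track`, `frame`, `time_h`; `NA` frame = never) and
#'   `n_seeds`.
#' @export
germination_curve <- function(tracks, seq, margin = 12L, min_persist_h = 6) {
  use <- Filter(function(tr) tr$status != "qc_removed", tracks)
  if (length(use) == 0L) stop("no tracked seeds")
  nfr <- length(seq$frames)
  nr <- nrow(seq$frames[[1]]); nc <- ncol(seq$frames[[1]])
  events <- data.frame(track = vapply(use, `[[`, integer(1), "id"),
                       frame = NA_integer_, time_h = NA_real_)
  for (i in seq_along(use)) {
    bb <- use[[i]]$seed_bbox
    rr <- max(1L, bb[1] - margin):min(nr, bb[3] + margin)
    cc <- max(1L, bb[2] - margin):min(nc, bb[4] + margin)
    presence <- vapply(seq$frames, function(f)
      any(f[rr, cc] == 1L), logical(1))
    if (!any(presence)) next
    # first run that satisfies the persistence rule
    r <- rle(presence)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & ((r$lengths - 1) * seq$dt / 60 > min_persist_h)
    # a run still open at the sequence end is provisionally accepted if it
    # could not yet have reached the threshold
    open_end <- r$values & (ends == nfr) &
      ((r$lengths - 1) * seq$dt / 60 <= min_persist_h)
    k <- which(ok | open_end)
    if (length(k)) {
      events$frame[i] <- starts[k[1]]
      events$time_h[i] <- (starts[k[1]] - 1) * seq$dt / 60
    }
  }
  pct <- vapply(seq_len(nfr), function(t)
    100 * sum(!is.na(events$frame) & events$frame <= t) / nrow(events),
    numeric(1))
  out <- trait_series(seq$time_h, pct, plant = "all",
                      trait = "germination", units = "%")
  attr(out, "events") <- events
  attr(out, "n_seeds") <- nrow(events)
  out
}

#' Fit the Hill germination model
#'
#' Trust-region least squares (Levenberg-Marquardt) fit of the 4-parameter
#' Hill function to a cumulative germination curve. Initialization: `G0` =
#' first value, `Gmax` = observed range, `t50` = time of half-range crossing,
#' `n = 4`; bounds keep all parameters in their valid domains. The reported
#' `final_germination` is the fitted plateau `G0 + Gmax` clamped to the
#' observed maximum.
#'
#' @param curve A `trait_series` (percent vs hours), non-decreasing, with at
#'   least 8 points.
#' @return A `germination_fit`: list with `G0`, `Gmax`, `n`, `t50`, `TMGR`,
#'   `final_germination`, `fitted` (function of hours) and `rss`.
#' @export
fit_hill <- function(curve) {
  stopifnot(inherits(curve, "trait_series"))
  t <- curve$time_h; y <- curve$values
  if (length(y) < 8L) stop("need at least 8 points to fit the Hill model")
  if (any(diff(y) < -1e-9)) stop("curve must be non-decreasing")
  if (max(y) <= 0) stop("degenerate curve: no germination observed")
  rng <- max(y) - min(y)
  t50_0 <- t[which(y >= min(y) + rng / 2)[1]]
  if (!is.finite(t50_0) || t50_0 <= 0) t50_0 <- max(t) / 2
  df <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ G0 + Gmax * t^n / (t50^n + t^n), data = df,
    start = list(G0 = max(min(y), 1e-6), Gmax = max(rng, 1e-3), n = 4,
                 t50 = t50_0),
    lower = c(0, 1e-8, 0.1, 1e-6), upper = c(100, 100, 50, max(t) * 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- as.list(coef(fit))
  structure(list(
    G0 = p$G0, Gmax = p$Gmax, n = p$n, t50 = p$t50,
    TMGR = tmgr_closed_form(p$t50, p$n),
    final_germination = min(p$G0 + p$Gmax, max(y)),
    fitted = function(h) hill_curve(h, p$G0, p$Gmax, p$n, p$t50),
    rss = sum(residuals(fit)^2)
  ), class = "germination_fit")
}

#' @export
print.germination_fit <- function(x, ...) {
  cat(sprintf(
    "<germination_fit> G0 = %.2f%%, Gmax = %.2f%%, n = %.2f, t50 = %.2f h, TMGR = %.2f h, final = %.1f%%\n",
    x$G0, x$Gmax, x$n, x$t50, x$TMGR, x$final_germination))
  invisible(x)
}
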