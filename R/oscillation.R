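# Local maxima of a (noise-free) series with a prominence criterion.
# Adjacent maxima separated by a valley shallower than `prom` are merged,
# keeping the higher one; returns indices into x.
find_peaks <- function(x, prom) {
  n <- length(x)
  if (n < 3) {
    return(integer())
  }
  d <- diff(x)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  if (length(idx) == 0) {
    return(integer())
  }
  repeat {
    if (length(idx) < 2) break
    sep <- rep(TRUE, length(idx) - 1)
    for (k in seq_len(length(idx) - 1)) {
      v <- min(x[idx[k]:idx[k + 1]])
      sep[k] <- (min(x[idx[k]], x[idx[k + 1]]) - v) >= prom
    }
    if (all(sep)) break
    k <- which(!sep)[1]
    drop <- if (x[idx[k]] < x[idx[k + 1]]) k else k + 1
    idx <- idx[-drop]
  }
  idx[x[idx] - min(x) >= prom]
}

# Sub-grid refinement of a peak time by a 3-point parabola.
refine_peak_time <- function(t, x, i) {
  if (i <= 1 || i >= length(x)) {
    return(t[i])
  }
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (denom >= 0) {
    return(t[i])
  }
  t[i] + 0.5 * (x[i - 1] - x[i + 1]) / denom * (t[i] - t[i - 1])
}

#' Detect a sustained limit cycle
#'
#' Integrates past a transient and inspects the `PP` series in an analysis
#' window. A sustained cycle is accepted when, within the window, the
#' peak-to-peak amplitude of `PP` exceeds `amp_frac * tot`, at least three
#' peaks (prominence `amp_frac * tot`) occur, the inter-peak intervals are
#' regular (coefficient of variation below `reg_tol`), and the oscillation is
#' not decaying (late-window peak-to-peak amplitude at least 90% of the
#' early-window one). `PP` is the canonical species because it stays active
#' in every oscillatory topology; the period is the mean inter-peak interval
#' of `PP`. When the window is too short to hold three peaks, or the
#' intervals have not yet settled, the window is doubled up to
#' `max_doublings` times before the result is declared inconclusive.
#'
#' @param model An `sw_model`.
#' @param nt Optional phosphate-donor override.
#' @param init Initial condition; default `OO = 2.1, PP = 1.9` (an asymmetric
#'   start off the invariant diagonal, the standard choice for oscillation
#'   runs).
#' @param transient Transient cut (AU time), default 1000.
#' @param window Analysis window length (AU time), default 1000.
#' @param dt Output spacing, default 0.1; automatically refined if the
#'   detected period is short.
#' @param amp_frac Amplitude threshold as a fraction of `tot`, default 1e-3;
#'   separates sustained cycles from damped ringing.
#' @param reg_tol Maximum coefficient of variation of inter-peak intervals,
#'   default 0.05.
#' @param max_doublings Maximum number of window doublings, default 3.
#' @param rtol,atol Integration tolerances.
#' @return An object of class `sw_cycle` with `status` one of `"cycle"`,
#'   `"none"`, `"inconclusive"`; for accepted cycles also `period`,
#'   `regularity`, `n_peaks`, `asymmetry` (fraction of the cycle `PP` spends
#'   above its mid-range), `switch_fraction` (fraction of the cycle in which
#'   `PP` changes fast — small for relaxation oscillations, ~0.87 for a
#'   sinusoid) and `envelope` (per-species min/max tibble).
#' @examples
#' \donttest{
#' detect_limit_cycle(preset("BD1"), nt = 4)
#' }
#' @export
detect_limit_cycle <- function(model, nt = NULL,
                               init = c(OO = 2.1, PP = 1.9),
                               transient = 1000, window = 1000, dt = 0.1,
                               amp_frac = 1e-3, reg_tol = 0.05,
                               max_doublings = 3,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "sw_model"))
  tot <- model$tot
  prom <- amp_frac * tot
  nt_val <- nt %||% model$nt
  w <- window
  tr <- transient
  for (attempt in 0:max_doublings) {
    res <- cycle_attempt(model, nt_val, init, tr, w, dt, prom, reg_tol,
      rtol, atol
    )
    if (res$status %in% c("cycle", "none")) {
      return(res)
    }
    # window too short, intervals unsettled, or amplitude still relaxing:
    # double both the transient and the analysis window and retry
    w <- 2 * w
    tr <- 2 * tr
  }
  structure(
    list(
      status = "inconclusive", period = NA_real_, regularity = NA_real_,
      n_peaks = NA_integer_, asymmetry = NA_real_,
      switch_fraction = NA_real_, envelope = NULL,
      window = w / 2, nt = nt_val, model = model$name
    ),
    class = "sw_cycle"
  )
}

cycle_attempt <- function(model, nt_val, init, transient, window, dt, prom,
                          reg_tol, rtol, atol) {
  none <- function() {
    structure(
      list(
        status = "none", period = NA_real_, regularity = NA_real_,
        n_peaks = 0L, asymmetry = NA_real_, switch_fraction = NA_real_,
        envelope = NULL,
        window = window, nt = nt_val, model = model$name
      ),
      class = "sw_cycle"
    )
  }
  inconclusive <- function() {
    structure(list(status = "retry"), class = "sw_cycle")
  }
  traj <- simulate_timecourse(model,
    init = init, t_end = transient + window,
    dt = dt, nt = nt_val, rtol = rtol, atol = atol
  )
  wnd <- traj[traj$time >= transient, ]
  x <- wnd$PP
  rng <- max(x) - min(x)
  if (rng <= prom) {
    return(none())
  }
  peaks <- find_peaks(x, prom)
  if (length(peaks) < 3) {
    return(inconclusive())
  }
  pt <- vapply(peaks, function(i) refine_peak_time(wnd$time, x, i), 0)
  intervals <- diff(pt)
  period <- mean(intervals)
  # resample if the grid is too coarse for the detected period
  if (period < 20 * dt) {
    return(cycle_attempt(model, nt_val, init, transient, window,
      dt = period / 40,
      prom, reg_tol, rtol, atol
    ))
  }
  regularity <- stats::sd(intervals) / period
  if (!is.finite(regularity) || regularity > reg_tol) {
    return(inconclusive())
  }
  # guard against slowly damped ringing: amplitude must not be decaying
  third <- ceiling(length(x) / 3)
  amp_first <- diff(range(x[seq_len(third)]))
  amp_last <- diff(range(x[(length(x) - third + 1):length(x)]))
  if (amp_last < 0.9 * amp_first || amp_last <= prom) {
    return(inconclusive())
  }
  # statistics over whole periods: from first to last refined peak
  span <- wnd$time >= pt[1] & wnd$time <= pt[length(pt)]
  mid <- (max(x[span]) + min(x[span])) / 2
  asymmetry <- mean(x[span] > mid)
  # relaxation character: fraction of the cycle during which PP changes
  # fast (|dPP/dt| above 20% of its maximum); small for slow build-up with
  # abrupt switching, large (~0.87) for a sinusoid
  slope <- abs(diff(x[span])) / diff(wnd$time[span])
  switch_fraction <- mean(slope > 0.2 * max(slope))
  env <- tibble::tibble(
    species = CONFORMATIONS,
    min = vapply(CONFORMATIONS, function(s) min(wnd[[s]][span]), 0),
    max = vapply(CONFORMATIONS, function(s) max(wnd[[s]][span]), 0)
  )
  structure(
    list(
      status = "cycle", period = period, regularity = regularity,
      n_peaks = length(peaks), asymmetry = asymmetry,
      switch_fraction = switch_fraction, envelope = env,
      window = window, nt = nt_val, model = model$name
    ),
    class = "sw_cycle"
  )
}

#' @export
print.sw_cycle <- function(x, ...) {
  cat("<sw_cycle> model ", x$model, ", nt = ", format(x$nt), ": ", x$status,
    sep = ""
  )
  if (identical(x$status, "cycle")) {
    cat(
      "; period = ", format(x$period, digits = 5),
      ", PP amplitude = [",
      format(x$envelope$min[x$envelope$species == "PP"], digits = 4), ", ",
      format(x$envelope$max[x$envelope$species == "PP"], digits = 4), "]",
      sep = ""
    )
  }
  cat("\n")
  invisible(x)
}

#' @describeIn detect_limit_cycle Per-species oscillation envelope as a tibble.
#' @param x,object An `sw_cycle`.
#' @param ... Unused.
#' @export
tidy.sw_cycle <- function(x, ...) {
  if (is.null(x$envelope)) {
    return(tibble::tibble(
      species = character(), min = numeric(), max = numeric()
    ))
  }
  dplyr::mutate(x$envelope, nt = x$nt, model = x$model)
}

#' @describeIn detect_limit_cycle One-row summary (status, period, regularity,
#'   asymmetry).
#' @export
glance.sw_cycle <- function(x, ...) {
  tibble::tibble(
    model = x$model, nt = x$nt, status = x$status, period = x$period,
    regularity = x$regularity, n_peaks = x$n_peaks,
    asymmetry = x$asymmetry, switch_fraction = x$switch_fraction
  )
}
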