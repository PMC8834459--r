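#' Dual-filter specification
#'
#' Parameters of the trajectory smoother: a fourth-order low-pass
#' Butterworth at 25 Hz applied zero-phase (forward-backward), followed by
#' robust local quadratic regression (rloess) with a span of 0.1 of the
#' series length. These defaults follow a residual-analysis choice typical
#' for 240 Hz kicking data.
#'
#' @param butter_order Butterworth order (default 4).
#' @param cutoff_hz Low-pass cutoff in Hz (default 25).
#' @param rloess_span Loess span as a fraction of series length (default
#'   0.1).
#' @param rloess_iterations Bisquare robustification iterations (default 5).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(butter_order = 4, cutoff_hz = 25, rloess_span = 0.1,
                        rloess_iterations = 5) {
  if (rloess_span <= 0 || rloess_span > 1) abort("rloess_span must be in (0, 1]")
  if (cutoff_hz <= 0) abort("cutoff_hz must be positive")
  structure(list(butter_order = butter_order, cutoff_hz = cutoff_hz,
                 rloess_span = rloess_span,
                 rloess_iterations = rloess_iterations),
            class = "filter_spec")
}

# Zero-phase Butterworth low-pass on one numeric vector. Odd (point-mirror)
# reflection padding at both ends suppresses endpoint transients, which
# matters because ball contact sits at the very last sample of a kick cycle.
butter_zero_phase <- function(x, rate, order = 4, cutoff = 25) {
  if (cutoff >= rate / 2) abort("cutoff must be below the Nyquist frequency")
  n <- length(x)
  # remove the line through the endpoints before filtering: the filter then
  # acts on a signal that vanishes at both ends, which kills the IIR
  # start-up transient and makes constants and rigid shifts pass exactly
  trend <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  x0 <- x - trend
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  p <- min(n - 1, 9 * order)
  xe <- c(2 * x0[1] - x0[(p + 1):2], x0, 2 * x0[n] - x0[(n - 1):(n - p)])
  fwd <- as.numeric(signal::filter(bf, xe))
  bwd <- rev(as.numeric(signal::filter(bf, rev(fwd))))
  bwd[(p + 1):(p + n)] + trend
}

# Robust local quadratic regression (rloess): for each sample, a weighted
# quadratic is fitted over the q nearest neighbours (q = span * n) with
# tricube distance weights, then the whole pass is repeated with bisquare
# robustness weights computed from the residual median (scale 6 * MAD), five
# times. Guards: windows whose robustness weights all vanish fall back to
# plain tricube weights (so structured lack-of-fit cannot disable whole
# windows), and robustification stops early when the residual scale is
# negligible relative to the signal range (noiseless input).
rloess_smooth <- function(x, span = 0.1, iterations = 5) {
  n <- length(x)
  q <- min(n, max(ceiling(span * n), 5))
  half <- q %/% 2
  idx <- seq_len(n)
  # precompute window bounds (q nearest neighbours, clipped at the edges)
  lo <- pmax(1L, pmin(idx - half, n - q + 1L))
  hi <- lo + q - 1L
  rw <- rep(1, n)
  fit <- x
  for (iter in 0:iterations) {
    for (i in idx) {
      win <- lo[i]:hi[i]
      d <- abs(win - i)
      dmax <- max(d) * 1.0001
      w <- (1 - (d / dmax)^3)^3 * rw[win]
      if (sum(w > 0) < 4) w <- (1 - (d / dmax)^3)^3
      tc <- win - i
      # near the series edges the neighbourhood is one-sided; a local cubic
      # there cancels the O(h^3) endpoint bias a quadratic would leave on
      # high-jerk segments (order upgrade, standard boundary correction)
      one_sided <- abs((hi[i] - i) - (i - lo[i])) > half %/% 2
      Xm <- if (one_sided && q >= 6) cbind(1, tc, tc^2, tc^3) else {
        cbind(1, tc, tc^2)
      }
      XtW <- t(Xm * w)
      beta <- tryCatch(solve(XtW %*% Xm, XtW %*% x[win]),
                       error = function(e) NULL)
      fit[i] <- if (is.null(beta)) {
        sum(w * x[win]) / sum(w)
      } else beta[1]
    }
    if (iter == iterations) break
    r <- x - fit
    s <- 6 * median(abs(r))
    if (s <= 1e-9 * max(diff(range(x)), 1e-12)) break
    rw <- pmax(0, 1 - (r / s)^2)^2
  }
  fit
}

#' Smooth a 3D trajectory with the dual filter
#'
#' Applies, independently per axis, a zero-phase fourth-order Butterworth
#' low-pass and then robust loess (see [filter_spec()]). Output length
#' equals input length; constants pass through unchanged.
#'
#' @param traj Trajectory tibble (`marker`, `frame`, `time_s`, `X`, `Y`,
#'   `Z`), uniformly sampled per marker.
#' @param spec A [filter_spec()].
#' @param rate Sampling rate in Hz (default 240).
#' @return The trajectory tibble with smoothed `X`, `Y`, `Z`.
#' @export
smooth_dual <- function(traj, spec = filter_spec(), rate = 240) {
  assert_cols(traj, c("marker", "frame", "X", "Y", "Z"), "trajectory")
  smooth_axis <- function(x) {
    rloess_smooth(
      butter_zero_phase(x, rate, spec$butter_order, spec$cutoff_hz),
      spec$rloess_span, spec$rloess_iterations)
  }
  min_len <- 3 * spec$butter_order
  traj %>%
    arrange(.data$marker, .data$frame) %>%
    group_by(.data$marker) %>%
    mutate(.n = dplyr::n()) %>%
    ungroup() %>%
    (function(df) {
      if (any(df$.n < min_len)) {
        abort(sprintf("trajectory too short to filter: need >= %d samples (3 x filter order)",
                      min_len))
      }
      df
    }) %>%
    group_by(.data$marker) %>%
    mutate(X = smooth_axis(.data$X), Y = smooth_axis(.data$Y),
           Z = smooth_axis(.data$Z)) %>%
    ungroup() %>%
    select(-".n")
}
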