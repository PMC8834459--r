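#' Pointwise median and 95% confidence interval across trials
#'
#' For each point of the normalized grid, the across-trial median with a
#' distribution-free 95% CI from binomial order statistics: the narrowest
#' symmetric pair of ranks `(l, n+1-l)` whose exact coverage reaches 0.95
#' (for n = 30 this is the 10th and 21st order statistics, coverage 95.7%).
#' When no such pair exists (n < 6) a seeded percentile bootstrap of the
#' median is used instead.
#'
#' @param curves Numeric matrix, trials x grid points (>= 5 trials).
#' @param conf Confidence level (default 0.95).
#' @param boot_n Bootstrap resamples for the small-n fallback (default
#'   2000).
#' @param boot_seed Seed for the bootstrap fallback (default 20220121).
#' @return Tibble `point`, `median`, `lo`, `hi` plus attribute
#'   `"method"` (`"order-statistic"` or `"bootstrap"`).
#' @export
median_ci_curves <- function(curves, conf = 0.95, boot_n = 2000,
                             boot_seed = 20220121) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (n < 5) abort("median CI needs >= 5 trials")
  l <- median_ci_ranks(n, conf)
  if (!is.na(l)) {
    sorted <- apply(curves, 2, sort)
    out <- tibble(point = seq_len(ncol(curves)),
                  median = apply(curves, 2, median),
                  lo = sorted[l, ], hi = sorted[n + 1 - l, ])
    attr(out, "method") <- "order-statistic"
    return(out)
  }
  inform(sprintf("n = %d too small for an order-statistic interval; percentile bootstrap (%d resamples, seed %d)",
                 n, boot_n, boot_seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(boot_seed)
  idx <- matrix(sample.int(n, n * boot_n, replace = TRUE), boot_n, n)
  a <- (1 - conf) / 2
  row_medians <- function(m) {
    # sort within rows in one pass, then read the middle column(s)
    s <- matrix(m[order(row(m), m)], nrow(m), ncol(m), byrow = TRUE)
    k <- ncol(m)
    if (k %% 2 == 1) s[, (k + 1) / 2] else (s[, k / 2] + s[, k / 2 + 1]) / 2
  }
  qs <- apply(curves, 2, function(col) {
    meds <- row_medians(matrix(col[idx], boot_n, n))
    quantile(meds, c(a, 1 - a), names = FALSE, type = 7)
  })
  out <- tibble(point = seq_len(ncol(curves)),
                median = apply(curves, 2, median),
                lo = qs[1, ], hi = qs[2, ])
  attr(out, "method") <- "bootstrap"
  out
}

# Largest l such that P(l <= Bin(n, 1/2) <= n - l) >= conf, i.e. the
# narrowest symmetric order-statistic interval [x_(l), x_(n+1-l)] with exact
# coverage >= conf; NA when even the widest pair fails.
median_ci_ranks <- function(n, conf = 0.95) {
  best <- NA_integer_
  for (l in seq_len(floor(n / 2))) {
    cov <- pbinom(n - l, n, 0.5) - pbinom(l - 1, n, 0.5)
    if (cov >= conf) best <- l else break
  }
  best
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Flag percent intervals where two methods' CIs do not overlap
#'
#' Given pointwise median-CI bands for the two methods on the same grid,
#' returns the maximal contiguous percent intervals where the bands are
#' disjoint (the time-series significance rule: non-overlapping 95% CIs).
#' The result is symmetric in its arguments.
#'
#' @param band_a,band_b Tibbles from [median_ci_curves()] with columns
#'   `lo`, `hi` on the same grid; a `percent` column is used for labelling
#'   when present, else grid index 1..n maps to percents directly.
#' @param percent Optional integer vector of percent labels for the grid.
#' @return Tibble `from`, `to` (percent bounds, inclusive).
#' @export
flag_nonoverlap <- function(band_a, band_b, percent = NULL) {
  if (nrow(band_a) != nrow(band_b)) abort("bands must share the grid")
  percent <- percent %||% band_a$percent %||% seq_len(nrow(band_a))
  disjoint <- band_a$hi < band_b$lo | band_b$hi < band_a$lo
  runs_to_intervals(disjoint, percent)
}

runs_to_intervals <- function(flag, percent) {
  if (!any(flag)) return(tibble(from = integer(), to = integer()))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(from = percent[starts[keep]], to = percent[ends[keep]])
}

#' Format flagged percent intervals the way results are reported
#'
#' Multi-point intervals read "from 16 to 18%"; single points read
#' "20% instant".
#'
#' @param intervals Tibble `from`, `to` from [flag_nonoverlap()].
#' @return Character vector, one entry per interval (empty when none).
#' @export
format_percent_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(character())
  purrr::map2_chr(intervals$from, intervals$to, function(a, b) {
    if (a == b) sprintf("%d%% instant", a) else sprintf("from %d to %d%%", a, b)
  })
}

#' Phase-resolved MAE table
#'
#' Mean absolute error between reference and test normalized kick-cycle
#' curves, pooled over all grid points of all trials within each phase
#' (support 1-65%, contact 66-100%, whole cycle 1-100%), per marker and
#' axis. Positions are reported in centimetres and resultant velocity in
#' m/s. `All` is the unweighted mean of the three axis MAEs and the
#' `Overall` row the unweighted mean across markers.
#'
#' @param manual,automatic Curve tibbles (`trial`, `marker`, `percent`,
#'   `X`, `Y`, `Z`, `speed`) on the same trials/grid; `manual` is the
#'   reference.
#' @return Tibble `marker`, `phase`, `X`, `Y`, `Z`, `All`, `VEL` with
#'   phases `support`, `contact`, `whole`.
#' @export
phase_mae_table <- function(manual, automatic) {
  key <- c("trial", "marker", "percent")
  assert_cols(manual, c(key, "X", "Y", "Z", "speed"), "manual curves")
  assert_cols(automatic, c(key, "X", "Y", "Z", "speed"), "automatic curves")
  paired <- dplyr::inner_join(manual, automatic, by = key,
                              suffix = c("_m", "_a"))
  if (nrow(paired) != nrow(filter(manual, .data$percent >= 0))) {
    abort("manual and automatic curves do not align on trial/marker/percent")
  }
  paired <- filter(paired, .data$percent >= 1) %>%
    mutate(phase = phase_of(.data$percent))
  if (anyNA(paired$phase)) abort("missing phase labels")
  per_phase <- function(df, phase_name) {
    df %>%
      group_by(.data$marker) %>%
      summarise(
        X = mean(abs(.data$X_m - .data$X_a)) * 100,
        Y = mean(abs(.data$Y_m - .data$Y_a)) * 100,
        Z = mean(abs(.data$Z_m - .data$Z_a)) * 100,
        VEL = mean(abs(.data$speed_m - .data$speed_a)),
        .groups = "drop") %>%
      mutate(All = (.data$X + .data$Y + .data$Z) / 3, phase = phase_name)
  }
  out <- bind_rows(
    per_phase(filter(paired, .data$phase == "support"), "support"),
    per_phase(filter(paired, .data$phase == "contact"), "contact"),
    per_phase(paired, "whole"))
  overall <- out %>%
    group_by(.data$phase) %>%
    summarise(across(c("X", "Y", "Z", "All", "VEL"), mean),
              .groups = "drop") %>%
    mutate(marker = "overall")
  lv <- c(intersect(MARKER_ORDER, out$marker),
          setdiff(unique(out$marker), MARKER_ORDER), "overall")
  bind_rows(out, overall) %>%
    mutate(marker = factor(.data$marker, levels = lv),
           phase = factor(.data$phase,
                          levels = c("support", "contact", "whole"))) %>%
    arrange(.data$phase, .data$marker) %>%
    mutate(marker = as.character(.data$marker)) %>%
    select("marker", "phase", "X", "Y", "Z", "All", "VEL")
}
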