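#' Combine per-trial kick cycles into one archive
#'
#' @param cycles List of [kick_cycle()] objects.
#' @return List with combined `curves`, `angles` and `scalars` tibbles.
#' @export
bind_cycles <- function(cycles) {
  list(curves = bind_rows(purrr::map(cycles, "curves")),
       angles = bind_rows(purrr::map(cycles, "angles")),
       scalars = bind_rows(purrr::map(cycles, "scalars")))
}

#' Full method-agreement comparison of manual vs automatic tracking
#'
#' Runs the whole agreement battery on matched per-trial kick cycles from a
#' reference method ("manual") and a test method ("automatic"):
#' * pointwise Cohen's d profiles (overall/min/max) per marker for the x, y,
#'   z position curves and the resultant velocity curves;
#' * phase-resolved MAE tables (support / contact / whole cycle; positions
#'   in cm, velocity in m/s);
#' * pointwise median-CI non-overlap flagging per marker and quantity, with
#'   intervals formatted as reported (e.g. "from 16 to 18%");
#' * Pearson r (with Fisher CI, magnitude label), ICC(2,1) and ratio limits
#'   of agreement for the single-point measures (joint ROMs, impact speed);
#' * average shared variance between the position matrices and between the
#'   velocity matrices.
#'
#' @param manual,automatic Archives from [bind_cycles()] (or single
#'   [kick_cycle()]s) with matching trial identifiers.
#' @param flag_min_trials Minimum trials for the CI-overlap analysis
#'   (default 5); with fewer trials the non-overlap table is empty.
#' @return Object of class `agreement_report`.
#' @export
compare_methods <- function(manual, automatic, flag_min_trials = 5) {
  if (inherits(manual, "kick_cycle")) manual <- bind_cycles(list(manual))
  if (inherits(automatic, "kick_cycle")) automatic <- bind_cycles(list(automatic))
  trials <- sort(unique(manual$curves$trial))
  if (!setequal(trials, unique(automatic$curves$trial))) {
    abort("manual and automatic archives must share trial identifiers")
  }
  markers <- intersect(MARKER_ORDER, unique(manual$curves$marker))
  n_trials <- length(trials)

  to_matrix <- function(curves, m, col) {
    df <- filter(curves, .data$marker == m) %>%
      arrange(.data$trial, .data$percent)
    matrix(df[[col]], nrow = n_trials, byrow = TRUE)
  }

  # --- effect-size profiles (Table 1 layout) ---------------------------
  es_rows <- purrr::map(markers, function(m) {
    row <- tibble(marker = m)
    for (q in c("X", "Y", "Z", "speed")) {
      if (n_trials < 2) abort("effect-size profiles need >= 2 trials")
      es <- effect_size_profile(to_matrix(manual$curves, m, q),
                                to_matrix(automatic$curves, m, q))
      nm <- if (q == "speed") "vel" else tolower(q)
      row[[paste0(nm, "_overall")]] <- es$overall
      row[[paste0(nm, "_min")]] <- es$min
      row[[paste0(nm, "_max")]] <- es$max
    }
    row
  })
  effect_sizes <- bind_rows(es_rows)

  # --- MAE table (Table 2 layout) --------------------------------------
  mae <- phase_mae_table(manual$curves, automatic$curves)

  # --- pointwise CI non-overlap ----------------------------------------
  nonoverlap <- tibble(marker = character(), quantity = character(),
                       intervals = character())
  if (n_trials >= flag_min_trials) {
    combos <- tidyr::expand_grid(marker = markers,
                                 quantity = c("X", "Y", "Z", "speed"))
    nonoverlap <- purrr::pmap(combos, function(marker, quantity) {
      bm <- median_ci_curves(to_matrix(manual$curves, marker, quantity))
      ba <- median_ci_curves(to_matrix(automatic$curves, marker, quantity))
      iv <- flag_nonoverlap(bm, ba, percent = 0:100)
      tibble(marker = marker, quantity = quantity,
             intervals = paste(format_percent_intervals(iv), collapse = "; "))
    }) %>% bind_rows() %>% filter(nzchar(.data$intervals))
  }

  # --- single-point measures: ROMs and impact speed --------------------
  meas <- intersect(unique(manual$scalars$measure),
                    unique(automatic$scalars$measure))
  scalar_stats <- purrr::map(meas, function(ms) {
    mm <- filter(manual$scalars, .data$measure == ms) %>% arrange(.data$trial)
    aa <- filter(automatic$scalars, .data$measure == ms) %>% arrange(.data$trial)
    x <- mm$value; y <- aa$value
    na_row <- function(cond) {
      warn(sprintf("measure '%s': %s; statistics flagged NA", ms,
                   conditionMessage(cond)))
      NULL
    }
    pr <- tryCatch(pearson_with_ci(x, y), error = na_row)
    if (is.null(pr)) {
      pr <- tibble(r = NA_real_, ci_half_width = NA_real_, p = NA_real_,
                   label = "undefined")
    }
    ic <- tryCatch(icc21(x, y),
                   error = function(e) tibble(icc = NA_real_, p = NA_real_))
    rl <- tryCatch(rloa(x, y),
                   error = function(e) tibble(ratio = NA_real_,
                                              factor = NA_real_,
                                              label = NA_character_))
    mean_ci <- function(v) {
      hw <- stats::qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v))
      sprintf("%.2f [%.2f; %.2f]", mean(v), mean(v) - hw, mean(v) + hw)
    }
    tibble(measure = ms, n = length(x),
           r = pr$r, r_ci_half_width = pr$ci_half_width, r_p = pr$p,
           r_label = pr$label,
           icc = ic$icc, icc_p = ic$p,
           rloa = rl$label, rloa_ratio = rl$ratio, rloa_factor = rl$factor,
           manual_mean = mean_ci(x), automatic_mean = mean_ci(y))
  }) %>% bind_rows()

  # --- average shared variance of the full matrices --------------------
  flatten_q <- function(arch, cols) {
    df <- arch$curves %>% arrange(.data$trial, .data$marker, .data$percent)
    unlist(df[cols], use.names = FALSE)
  }
  shared <- bind_rows(
    shared_variance(flatten_q(manual, c("X", "Y", "Z")),
                    flatten_q(automatic, c("X", "Y", "Z"))) %>%
      mutate(signal = "position"),
    shared_variance(flatten_q(manual, "speed"),
                    flatten_q(automatic, "speed")) %>%
      mutate(signal = "velocity")) %>%
    select("signal", "r2", "label", "p")

  n_comparisons <- nrow(effect_sizes) * 12 + nrow(mae) * 5 +
    length(markers) * 4 * 101 + nrow(scalar_stats) * 3
  inform(sprintf("agreement battery: %d comparisons, no multiplicity correction applied",
                 n_comparisons))

  structure(list(effect_sizes = effect_sizes, mae = mae,
                 nonoverlap = nonoverlap, scalar_stats = scalar_stats,
                 shared_variance = shared, n_trials = n_trials,
                 n_comparisons = n_comparisons),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d trials\n", x$n_trials))
  cat("\nMAE by phase (positions cm, velocity m/s):\n")
  print(as.data.frame(x$mae), digits = 3)
  cat("\nEffect-size profiles (overall/min/max):\n")
  print(as.data.frame(x$effect_sizes), digits = 2)
  if (nrow(x$nonoverlap) > 0) {
    cat("\nNon-overlapping 95% CI intervals:\n")
    print(as.data.frame(x$nonoverlap))
  }
  if (nrow(x$scalar_stats) > 0) {
    cat("\nSingle-point measures:\n")
    print(as.data.frame(x$scalar_stats[, c("measure", "r", "r_label", "icc",
                                           "rloa")]), digits = 2)
  }
  cat("\nShared variance:\n")
  print(as.data.frame(x$shared_variance), digits = 2)
  invisible(x)
}

#' @rdname compare_methods
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @export
tidy.agreement_report <- function(x, ...) x$scalar_stats

#' @rdname compare_methods
#' @export
glance.agreement_report <- function(x, ...) {
  ov <- filter(x$mae, .data$marker == "overall", .data$phase == "whole")
  tibble(n_trials = x$n_trials,
         mae_position_cm = ov$All, mae_velocity_ms = ov$VEL,
         r2_position = x$shared_variance$r2[x$shared_variance$signal == "position"],
         r2_velocity = x$shared_variance$r2[x$shared_variance$signal == "velocity"],
         n_flagged_intervals = nrow(x$nonoverlap))
}

#' Write an agreement report to disk
#'
#' Emits the machine-readable JSON of the full report plus human-readable
#' CSV tables mirroring the published layouts: `effect_sizes.csv` (marker
#' rows; x/y/z position and velocity overall/min/max columns) and `mae.csv`
#' (marker rows; X/Y/Z/All/VEL columns in support/contact/whole blocks).
#'
#' @param report An [compare_methods()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_agreement_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- report
  class(payload) <- NULL
  jsonlite::write_json(payload, file.path(dir, "agreement_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write.csv(report$effect_sizes, file.path(dir, "effect_sizes.csv"),
            row.names = FALSE)
  mae_wide <- report$mae %>%
    tidyr::pivot_wider(names_from = "phase",
                       values_from = c("X", "Y", "Z", "All", "VEL"),
                       names_glue = "{phase}_{.value}")
  ord <- c("marker", as.vector(t(outer(c("support", "contact", "whole"),
                                       c("X", "Y", "Z", "All", "VEL"),
                                       paste, sep = "_"))))
  write.csv(mae_wide[, ord], file.path(dir, "mae.csv"), row.names = FALSE)
  write.csv(report$scalar_stats, file.path(dir, "scalar_stats.csv"),
            row.names = FALSE)
  invisible(dir)
}
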