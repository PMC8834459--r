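#' Export marker trajectories to TRC
#'
#' Writes the conventional tab-separated motion-capture text format:
#' two header lines (`PathFileType`, DataRate/CameraRate/NumFrames/
#' NumMarkers/Units...), marker-name and X/Y/Z column rows, then one row per
#' frame (`Frame#`, `Time`, X1 Y1 Z1 ...). Positions are written in
#' millimetres.
#'
#' @param traj Trajectory tibble (`marker`, `frame`, `X`, `Y`, `Z` metres).
#' @param path Output `.trc` path.
#' @param rate Sampling rate in Hz.
#' @return Invisibly, `path`.
#' @export
write_trc <- function(traj, path, rate = 240) {
  assert_cols(traj, c("marker", "frame", "X", "Y", "Z"), "trajectory")
  markers <- unique(traj$marker)
  frames <- sort(unique(traj$frame))
  wide <- matrix(NA_real_, length(frames), 3 * length(markers))
  for (mi in seq_along(markers)) {
    df <- filter(traj, .data$marker == markers[mi]) %>% arrange(.data$frame)
    rows <- match(df$frame, frames)
    wide[rows, 3 * mi - 2] <- df$X * 1000
    wide[rows, 3 * mi - 1] <- df$Y * 1000
    wide[rows, 3 * mi]     <- df$Z * 1000
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                     "Units", "OrigDataRate", "OrigDataStartFrame",
                     "OrigNumFrames"), collapse = "\t"), con)
  writeLines(paste(c(rate, rate, length(frames), length(markers), "mm",
                     rate, 1, length(frames)), collapse = "\t"), con)
  hdr <- c("Frame#", "Time", as.vector(rbind(markers, "", "")))
  writeLines(paste(hdr, collapse = "\t"), con)
  sub <- c("", "", as.vector(vapply(seq_along(markers), function(i) {
    paste0(c("X", "Y", "Z"), i)
  }, character(3))))
  writeLines(paste(sub, collapse = "\t"), con)
  writeLines("", con)
  for (r in seq_along(frames)) {
    writeLines(paste(c(r, sprintf("%.8f", frames[r] / rate),
                       sprintf("%.6f", wide[r, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a TRC file written by [write_trc()]
#'
#' @param path `.trc` path.
#' @return Trajectory tibble (`marker`, `frame`, `time_s`, `X`, `Y`, `Z`;
#'   metres) with the data rate in attribute `"rate"`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(lines[3], "\t")[[1]]
  rate <- as.numeric(meta[1])
  hdr <- strsplit(lines[4], "\t")[[1]]
  markers <- hdr[seq(3, length(hdr), by = 3)]
  body <- lines[-(1:6)]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t")
  mat <- do.call(rbind, purrr::map(cells, as.numeric))
  out <- purrr::imap(markers, function(m, i) {
    tibble(marker = m, frame = as.integer(round(mat[, 2] * rate)),
           time_s = mat[, 2],
           X = mat[, 3 * i] / 1000, Y = mat[, 3 * i + 1] / 1000,
           Z = mat[, 3 * i + 2] / 1000)
  }) %>% bind_rows() %>% arrange(.data$marker, .data$frame)
  attr(out, "rate") <- rate
  out
}
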