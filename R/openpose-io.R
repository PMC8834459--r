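#' Read OpenPose-style keypoint JSON
#'
#' Parses per-frame multi-person 2D pose detections in the OpenPose output
#' format: a JSON object with key `"people"`, each person holding
#' `"pose_keypoints_2d"`, a flat vector of 75 numbers (x, y, confidence for
#' each of the 25 BODY_25 keypoints). Undetected keypoints are encoded as
#' `(0, 0, 0)` and are treated as missing downstream via the confidence
#' threshold.
#'
#' @param path Path to a single JSON file.
#' @param camera_id Camera identifier attached to every row.
#' @param frame Frame index (0-based). If `NULL`, parsed from a
#'   `*_{frame:012d}_keypoints.json` file name, or taken from a `"frame"` field
#'   for consolidated files.
#' @return A tibble with columns `camera_id`, `frame`, `person`, `keypoint`
#'   (0-24), `x`, `y`, `confidence`; one row per keypoint per person.
#' @export
read_openpose_json <- function(path, camera_id = "cam", frame = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  consolidated <- (is.data.frame(obj) && all(c("frame", "people") %in% names(obj))) ||
    (is.list(obj) && is.null(names(obj)) && length(obj) > 0 &&
       !is.null(obj[[1]]$frame))
  if (consolidated) {
    # consolidated one-file-per-camera array: [{frame, people}, ...]
    if (is.data.frame(obj)) obj <- purrr::transpose(obj)
    frames <- purrr::map(obj, function(entry) {
      people_to_tibble(entry$people, camera_id, as.integer(entry$frame))
    })
    return(bind_rows(frames))
  }
  if (is.null(frame)) frame <- frame_from_filename(path)
  people_to_tibble(obj$people, camera_id, as.integer(frame))
}

frame_from_filename <- function(path) {
  m <- regmatches(basename(path),
                  regexec("_([0-9]{6,12})_keypoints\\.json$", basename(path)))[[1]]
  if (length(m) < 2) {
    abort(sprintf("cannot parse frame index from file name '%s'; pass `frame`",
                  basename(path)))
  }
  as.integer(m[2])
}

people_to_tibble <- function(people, camera_id, frame) {
  if (is.null(people) || length(people) == 0) {
    return(tibble(camera_id = character(), frame = integer(),
                  person = integer(), keypoint = integer(),
                  x = double(), y = double(), confidence = double()))
  }
  kps <- if (is.data.frame(people)) people$pose_keypoints_2d else {
    purrr::map(people, "pose_keypoints_2d")
  }
  rows <- purrr::imap(kps, function(flat, i) {
    flat <- as.numeric(flat)
    if (length(flat) != 75) {
      abort(sprintf("frame %d person %d: pose_keypoints_2d has %d values, expected 75",
                    frame, i, length(flat)))
    }
    m <- matrix(flat, ncol = 3, byrow = TRUE)
    tibble(camera_id = camera_id, frame = frame, person = as.integer(i),
           keypoint = 0:24, x = m[, 1], y = m[, 2], confidence = m[, 3])
  })
  bind_rows(rows)
}

#' Read a directory of per-frame OpenPose JSON files
#'
#' @param dir Directory containing `*_keypoints.json` files for one camera.
#' @inheritParams read_openpose_json
#' @return Combined keypoint tibble sorted by frame (see
#'   [read_openpose_json()]).
#' @export
read_openpose_dir <- function(dir, camera_id = "cam") {
  files <- list.files(dir, pattern = "_keypoints\\.json$", full.names = TRUE)
  if (length(files) == 0) abort(sprintf("no *_keypoints.json files in '%s'", dir))
  bind_rows(purrr::map(files, read_openpose_json, camera_id = camera_id)) %>%
    arrange(.data$frame, .data$person, .data$keypoint)
}

#' Write pose frames as OpenPose-style JSON
#'
#' Inverse of [read_openpose_json()]: writes one
#' `{prefix}_{frame:012d}_keypoints.json` file per frame (`consolidated =
#' FALSE`) or a single JSON array for the camera (`consolidated = TRUE`).
#'
#' @param frames Keypoint tibble for a single camera.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param consolidated Write one array file instead of per-frame files.
#' @return Invisibly, the written file path(s).
#' @export
write_openpose_json <- function(frames, dir, prefix = "cam",
                                consolidated = FALSE) {
  assert_cols(frames, c("frame", "person", "keypoint", "x", "y", "confidence"),
              "pose frames")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frame_people <- function(df) {
    people <- df %>%
      arrange(.data$person, .data$keypoint) %>%
      group_by(.data$person) %>%
      summarise(kp = list(as.numeric(rbind(.data$x, .data$y, .data$confidence))),
                .groups = "drop")
    purrr::map(people$kp, ~ list(pose_keypoints_2d = .x))
  }
  split_frames <- split(frames, frames$frame)
  if (consolidated) {
    payload <- purrr::imap(split_frames, function(df, f) {
      list(frame = as.integer(f), people = frame_people(df))
    })
    path <- file.path(dir, paste0(prefix, "_keypoints.json"))
    jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  paths <- purrr::imap_chr(split_frames, function(df, f) {
    path <- file.path(dir, sprintf("%s_%012d_keypoints.json", prefix,
                                   as.integer(f)))
    jsonlite::write_json(list(people = frame_people(df)), path,
                         auto_unbox = TRUE, digits = NA)
    path
  })
  invisible(unname(paths))
}

#' Write person-resolved tracks as wide CSV
#'
#' One row per frame per person, columns `frame`, `person_id`, then
#' `x_k`, `y_k`, `c_k` for keypoints k = 0..24.
#'
#' @param tracks Track tibble from [build_tracks()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tracks_csv <- function(tracks, path) {
  assert_cols(tracks, c("frame", "person_id", "keypoint", "x", "y",
                        "confidence"), "tracks")
  wide <- tracks %>%
    select("frame", "person_id", "keypoint", "x", "y", "confidence") %>%
    tidyr::pivot_wider(names_from = "keypoint",
                       values_from = c("x", "y", "confidence"),
                       names_sep = "_")
  names(wide) <- sub("^confidence_", "c_", names(wide))
  ord <- c("frame", "person_id",
           as.vector(outer(c("x", "y", "c"), 0:24, paste, sep = "_")))
  write.csv(wide[, ord], path, row.names = FALSE)
  invisible(path)
}

#' Read tracks written by [write_tracks_csv()]
#'
#' @param path CSV path.
#' @return Long track tibble (`frame`, `person_id`, `keypoint`, `x`, `y`,
#'   `confidence`).
#' @export
read_tracks_csv <- function(path) {
  wide <- as_tibble(read.csv(path, check.names = FALSE))
  long <- wide %>%
    tidyr::pivot_longer(-c("frame", "person_id"),
                        names_to = c("what", "keypoint"), names_sep = "_",
                        values_to = "value") %>%
    mutate(keypoint = as.integer(.data$keypoint)) %>%
    tidyr::pivot_wider(names_from = "what", values_from = "value") %>%
    rename(confidence = "c") %>%
    mutate(frame = as.integer(.data$frame),
           person_id = as.integer(.data$person_id)) %>%
    arrange(.data$frame, .data$person_id, .data$keypoint)
  long
}
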