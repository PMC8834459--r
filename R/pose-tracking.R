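#' Centre of mass of a 2D pose
#'
#' The unweighted mean pixel position of all keypoints whose detection
#' confidence reaches `min_confidence`. This is the per-pose summary used to
#' chain detections across frames: a pose in frame t is associated with the
#' pose in frame t+1 whose centre of mass is nearest in Euclidean distance.
#'
#' @param pose Either a 25 x 3 matrix (columns x, y, confidence) or a tibble
#'   with columns `x`, `y`, `confidence`.
#' @param min_confidence Keypoints below this confidence are excluded
#'   (default 0.1, which drops undetected parts encoded as `(0, 0, 0)`).
#' @return Numeric vector `c(x, y)` in pixels.
#' @export
pose_centroid <- function(pose, min_confidence = 0.1) {
  if (is.data.frame(pose)) pose <- cbind(pose$x, pose$y, pose$confidence)
  keep <- pose[, 3] >= min_confidence
  if (!any(keep)) abort("empty pose: no keypoint at or above min_confidence")
  pt <- c(mean(pose[keep, 1]), mean(pose[keep, 2]))
  if (!all(is.finite(pt))) abort("empty pose: non-finite centroid")
  pt
}

# Per-person centroids for one frame of the keypoint tibble.
frame_centroids <- function(frame_df, min_confidence = 0.1) {
  frame_df %>%
    filter(.data$confidence >= min_confidence) %>%
    group_by(.data$person) %>%
    summarise(cx = mean(.data$x), cy = mean(.data$y), n_kp = dplyr::n(),
              .groups = "drop")
}

#' Associate poses between consecutive frames
#'
#' Nearest-centroid association: centres of mass of the poses in frame t act
#' as fixed cluster centres (a single K-means assignment step) and each pose
#' in frame t+1 is matched to the nearest centre, subject to one-to-one
#' assignment. The default resolves conflicts greedily in ascending distance
#' order; `method = "optimal"` minimises the total distance over all
#' one-to-one assignments (exact enumeration, intended for the small pose
#' counts of a pitch scene). Ties break toward the lower pose index in frame
#' t+1. When pose counts differ, the surplus poses are left unmatched.
#'
#' @param frame_t,frame_t1 Keypoint tibbles for one frame each (columns
#'   `person`, `x`, `y`, `confidence`).
#' @param min_confidence Confidence threshold for centroid computation.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return Tibble with columns `from` (person in t), `to` (person in t+1),
#'   `distance` (pixels); unmatched poses are absent.
#' @export
associate_frames <- function(frame_t, frame_t1, min_confidence = 0.1,
                             method = c("greedy", "optimal")) {
  method <- match.arg(method)
  ct <- frame_centroids(frame_t, min_confidence)
  ct1 <- frame_centroids(frame_t1, min_confidence)
  empty <- tibble(from = integer(), to = integer(), distance = double())
  if (nrow(ct) == 0 || nrow(ct1) == 0) return(empty)
  d <- outer(seq_len(nrow(ct)), seq_len(nrow(ct1)), function(i, j) {
    sqrt((ct$cx[i] - ct1$cx[j])^2 + (ct$cy[i] - ct1$cy[j])^2)
  })
  if (any(!is.finite(d))) abort("empty pose: non-finite centroid distance")
  pairs <- if (method == "greedy") assign_greedy(d) else assign_optimal(d)
  tibble(from = ct$person[pairs[, 1]], to = ct1$person[pairs[, 2]],
         distance = d[pairs]) %>% arrange(.data$from)
}

# Greedy one-to-one assignment in ascending distance order; ties resolved by
# row then column index (deterministic).
assign_greedy <- function(d) {
  nr <- nrow(d); nc <- ncol(d)
  ord <- order(d, slice.index(d, 1), slice.index(d, 2))
  used_r <- logical(nr); used_c <- logical(nc)
  out <- matrix(integer(), 0, 2)
  for (k in ord) {
    i <- (k - 1) %% nr + 1
    j <- (k - 1) %/% nr + 1
    if (!used_r[i] && !used_c[j]) {
      used_r[i] <- TRUE; used_c[j] <- TRUE
      out <- rbind(out, c(i, j))
      if (all(used_r) || all(used_c)) break
    }
  }
  out
}

# Exact minimum-total-distance one-to-one assignment by enumeration over
# permutations of the smaller side. Scenes here hold at most a handful of
# people; guard against combinatorial blow-up.
assign_optimal <- function(d) {
  nr <- nrow(d); nc <- ncol(d)
  transposed <- nr > nc
  if (transposed) d <- t(d)
  k <- nrow(d); m <- ncol(d)
  if (k > 8) abort("optimal assignment supports at most 8 poses per frame")
  perms <- permutations_of(m, k)
  costs <- vapply(perms, function(p) sum(d[cbind(seq_len(k), p)]), numeric(1))
  best <- perms[[which.min(costs)]]
  out <- cbind(seq_len(k), best)
  if (transposed) out <- out[, 2:1, drop = FALSE]
  out
}

permutations_of <- function(n, k) {
  if (k == 0) return(list(integer()))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in remaining) rec(c(prefix, v), setdiff(remaining, v))
  }
  rec(integer(), seq_len(n))
  out
}

#' Chain per-frame poses into per-person tracks
#'
#' Walks the frame sequence of one camera, associating each frame's poses
#' with the next frame's by [associate_frames()]. A pose with no predecessor
#' starts a new track with a fresh `person_id`; a track that finds no
#' successor terminates (a detection gap therefore splits a person into two
#' tracks). Frame indices must be processable in increasing order; missing
#' frame indices terminate all active tracks.
#'
#' @param frames Keypoint tibble for one camera (multiple frames).
#' @param min_confidence Confidence threshold for centroids.
#' @param method Assignment method, see [associate_frames()].
#' @return Tibble `frame`, `person_id`, `keypoint`, `x`, `y`, `confidence`.
#' @export
build_tracks <- function(frames, min_confidence = 0.1,
                         method = c("greedy", "optimal")) {
  method <- match.arg(method)
  assert_cols(frames, c("frame", "person", "keypoint", "x", "y", "confidence"),
              "pose frames")
  frame_ids <- sort(unique(frames$frame))
  by_frame <- split(frames, factor(frames$frame, levels = frame_ids))
  cents <- purrr::map(by_frame, frame_centroids,
                      min_confidence = min_confidence)
  next_id <- 1L
  active <- integer()        # person index in current frame -> person_id
  out <- vector("list", length(by_frame))
  for (fi in seq_along(by_frame)) {
    df <- by_frame[[fi]]
    persons <- sort(unique(df$person))
    contiguous <- fi > 1 && frame_ids[fi] == frame_ids[fi - 1] + 1L
    ids <- integer(length(persons))
    names(ids) <- persons
    if (contiguous && length(active) > 0 && length(persons) > 0) {
      ct <- cents[[fi - 1]]; ct1 <- cents[[fi]]
      d <- outer(seq_len(nrow(ct)), seq_len(nrow(ct1)), function(i, j) {
        sqrt((ct$cx[i] - ct1$cx[j])^2 + (ct$cy[i] - ct1$cy[j])^2)
      })
      if (any(!is.finite(d))) abort("empty pose: non-finite centroid distance")
      pairs <- if (method == "greedy") assign_greedy(d) else assign_optimal(d)
      mp <- tibble(from = ct$person[pairs[, 1]], to = ct1$person[pairs[, 2]])
      mp <- mp[as.character(mp$from) %in% names(active), , drop = FALSE]
      ids[as.character(mp$to)] <- active[as.character(mp$from)]
    }
    fresh <- ids == 0L
    if (any(fresh)) {
      ids[fresh] <- seq.int(next_id, length.out = sum(fresh))
      next_id <- next_id + sum(fresh)
    }
    active <- ids
    out[[fi]] <- df %>% mutate(person_id = unname(ids[as.character(.data$person)]))
  }
  bind_rows(out) %>%
    select("frame", "person_id", "person", "keypoint", "x", "y",
           "confidence") %>%
    arrange(.data$frame, .data$person_id, .data$keypoint)
}

#' Select one track from a multi-person scene
#'
#' Picks the kicker's track as the longest track, optionally restricted to
#' tracks whose mean centroid lies inside a pixel region of interest, and
#' reports the choice.
#'
#' @param tracks Track tibble from [build_tracks()].
#' @param roi Optional `c(xmin, xmax, ymin, ymax)` region in pixels.
#' @param min_confidence Confidence threshold for centroids.
#' @return The subset of `tracks` belonging to the selected person.
#' @export
select_subject_track <- function(tracks, roi = NULL, min_confidence = 0.1) {
  stats <- tracks %>%
    filter(.data$confidence >= min_confidence) %>%
    group_by(.data$person_id) %>%
    summarise(n_frames = dplyr::n_distinct(.data$frame),
              cx = mean(.data$x), cy = mean(.data$y), .groups = "drop")
  if (!is.null(roi)) {
    inside <- stats$cx >= roi[1] & stats$cx <= roi[2] &
      stats$cy >= roi[3] & stats$cy <= roi[4]
    if (any(inside)) stats <- stats[inside, ]
  }
  chosen <- stats$person_id[which.max(stats$n_frames)]
  inform(sprintf("selected track person_id=%d (%d frames)", chosen,
                 max(stats$n_frames)))
  filter(tracks, .data$person_id == chosen)
}

#' Extract per-marker 2D pixel series from a track
#'
#' Projects a person's track onto the anatomical marker set via a
#' marker-name to BODY_25 index map. Samples whose detection confidence falls
#' below `min_confidence` are flagged `missing`; downstream reconstruction
#' interpolates gaps up to `max_gap` frames and refuses longer ones.
#'
#' @param track Track tibble for a single `person_id`.
#' @param keypoint_map Named integer vector, marker name -> keypoint index
#'   (0-24); default [default_keypoint_map()].
#' @param min_confidence Confidence threshold.
#' @return Tibble `marker`, `frame`, `x`, `y`, `confidence`, `missing`.
#' @export
extract_marker_series <- function(track, keypoint_map = default_keypoint_map(),
                                  min_confidence = 0.1) {
  if (nrow(track) == 0) abort("track is empty")
  if (any(keypoint_map < 0 | keypoint_map > 24)) {
    abort("keypoint_map indices must be in [0, 24]")
  }
  map_df <- tibble(marker = names(keypoint_map),
                   keypoint = as.integer(keypoint_map))
  track %>%
    dplyr::inner_join(map_df, by = "keypoint",
                      relationship = "many-to-many") %>%
    mutate(missing = .data$confidence < min_confidence) %>%
    select("marker", "frame", "x", "y", "confidence", "missing") %>%
    arrange(.data$marker, .data$frame)
}

#' Fill short gaps in a marker pixel series
#'
#' Linear interpolation of `x` and `y` over runs of missing samples of at
#' most `max_gap` frames; longer gaps raise an error since 3D reconstruction
#' needs continuous input.
#'
#' @param series Marker series from [extract_marker_series()].
#' @param max_gap Longest run of missing frames to bridge (default 5).
#' @return `series` with gaps filled and `missing` updated.
#' @export
interpolate_gaps <- function(series, max_gap = 5L) {
  fill_one <- function(df) {
    miss <- df$missing
    if (!any(miss)) return(df)
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- r$values & (r$lengths > max_gap |
                         starts == 1L | ends == nrow(df))
    if (any(bad)) {
      abort(sprintf(
        "marker '%s': gap of %d frame(s) exceeds max_gap=%d or touches the series edge",
        df$marker[1], max(r$lengths[bad]), max_gap))
    }
    ok <- which(!miss)
    df$x[miss] <- approx(df$frame[ok], df$x[ok], xout = df$frame[miss])$y
    df$y[miss] <- approx(df$frame[ok], df$y[ok], xout = df$frame[miss])$y
    n_gap <- sum(miss)
    inform(sprintf("marker '%s': interpolated %d missing frame(s)",
                   df$marker[1], n_gap))
    df$missing <- FALSE
    df
  }
  series %>%
    dplyr::group_split(.data$marker) %>%
    purrr::map(fill_one) %>%
    bind_rows() %>%
    select("marker", "frame", "x", "y", "confidence", "missing")
}
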