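#' Simulate a multi-person 2D pose scene with known identities
#'
#' Generates `n_people` independent full-pose random walks in the image
#' plane with ground-truth identity labels, for exercising the tracking
#' associator. Each person's 25-keypoint pose is a fixed template around a
#' walking centroid; per-frame centroid displacement is bounded by
#' `displacement_px`, and people start `spacing_px` apart, so with
#' `spacing_px > 2 * displacement_px` nearest-centroid association is
#' guaranteed to recover the true identities (the solvable regime).
#' The within-frame pose order is shuffled so detection order carries no
#' identity information.
#'
#' @param n_people Number of people.
#' @param frames Number of frames.
#' @param spacing_px Initial centroid spacing in pixels.
#' @param displacement_px Maximum per-frame centroid displacement (pixels).
#' @param seed Integer seed.
#' @param drift Per-person constant drift is drawn within the displacement
#'   budget when `TRUE` (default), making walks directional.
#' @param shuffle Shuffle within-frame person order (default `TRUE`).
#' @return List: `frames` (keypoint tibble as from [read_openpose_json()]),
#'   `truth` (tibble `frame`, `person`, `true_id`).
#' @export
simulate_multiperson <- function(n_people, frames, spacing_px = 400,
                                 displacement_px = 10, seed = 1,
                                 drift = TRUE, shuffle = TRUE) {
  set.seed(child_seed(seed, "multiperson"))
  # fixed pose template: a 25-point stick figure within ~120 px
  tmpl_x <- c(0, 0, -20, -30, -35, 20, 30, 35, 0, -12, -14, -15, 12, 14, 15,
              -5, 5, -10, 10, 18, 22, 10, -18, -22, -10) * 1.2
  tmpl_y <- c(-60, -40, -38, -10, 15, -38, -10, 15, 0, 2, 40, 80, 2, 40, 80,
              -65, -65, -60, -60, 90, 90, 84, 90, 90, 84)
  centroids <- purrr::map(seq_len(n_people), function(i) {
    start <- c(200 + (i - 1) * spacing_px, 500 + 30 * ((i - 1) %% 2))
    dr <- if (drift) runif(2, -0.3, 0.3) * displacement_px else c(0, 0)
    steps <- matrix(runif(2 * frames, -1, 1), ncol = 2)
    mag <- sqrt(rowSums(steps^2))
    big <- mag > 0
    scale <- stats::runif(frames, 0, 1) * displacement_px
    steps[big, ] <- steps[big, ] / mag[big] * scale[big]
    steps <- sweep(steps, 2, dr, "+")
    lim <- pmin(sqrt(rowSums(steps^2)), displacement_px)
    nz <- sqrt(rowSums(steps^2)) > 0
    steps[nz, ] <- steps[nz, ] / sqrt(rowSums(steps[nz, , drop = FALSE]^2)) *
      lim[nz]
    pos <- apply(steps, 2, cumsum)
    sweep(pos, 2, start, "+")
  })
  rows <- vector("list", frames)
  truth <- vector("list", frames)
  for (f in seq_len(frames)) {
    order_p <- if (shuffle) sample(n_people) else seq_len(n_people)
    per_person <- purrr::imap(order_p, function(true_id, slot) {
      c0 <- centroids[[true_id]][f, ]
      tibble(camera_id = "cam", frame = f - 1L, person = as.integer(slot),
             keypoint = 0:24, x = c0[1] + tmpl_x, y = c0[2] + tmpl_y,
             confidence = 0.9)
    })
    rows[[f]] <- bind_rows(per_person)
    truth[[f]] <- tibble(frame = f - 1L, person = seq_len(n_people),
                         true_id = order_p)
  }
  list(frames = bind_rows(rows), truth = bind_rows(truth))
}

#' Count identity swaps of tracked poses against ground truth
#'
#' Joins the tracker's `person_id` assignment with the scene's true
#' identities and counts the frames at which a true person's assigned track
#' differs from that person's modal track (plus any frame where one track
#' covers two true people).
#'
#' @param tracks Track tibble from [build_tracks()].
#' @param truth Truth tibble from [simulate_multiperson()].
#' @return Integer swap count (0 means perfect identity preservation).
#' @export
identity_swaps <- function(tracks, truth) {
  m <- tracks %>%
    distinct(.data$frame, .data$person, .data$person_id) %>%
    dplyr::inner_join(truth, by = c("frame", "person"))
  modal <- m %>%
    dplyr::count(.data$true_id, .data$person_id) %>%
    group_by(.data$true_id) %>%
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select("true_id", modal_id = "person_id")
  m2 <- left_join(m, modal, by = "true_id")
  swaps <- sum(m2$person_id != m2$modal_id)
  dup <- m %>%
    distinct(.data$true_id, .data$person_id) %>%
    dplyr::count(.data$person_id) %>%
    filter(.data$n > 1)
  swaps + sum(dup$n - 1)
}
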