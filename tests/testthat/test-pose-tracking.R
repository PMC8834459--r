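test_that("pose centroid is the mean of confident keypoints", {
  expect_equal(pose_centroid(const_pose(100, 200)), c(100, 200))

  two <- const_pose(0, 0, conf = 0)
  two[1, ] <- c(0, 0, 1)
  two[2, ] <- c(10, 20, 1)
  expect_equal(pose_centroid(two), c(5, 10))

  k <- 0:24
  spread <- cbind(k, 2 * k, rep(0.9, 25))
  expect_equal(pose_centroid(spread, min_confidence = 0.1), c(12, 24))

  expect_error(pose_centroid(const_pose(5, 5, conf = 0)), "empty pose")
})

test_that("pose centroid is translation-equivariant", {
  set.seed(11)
  for (i in 1:20) {
    pose <- cbind(runif(25, 0, 1900), runif(25, 0, 1000), runif(25))
    v <- runif(2, -50, 50)
    shifted <- pose
    shifted[, 1] <- shifted[, 1] + v[1]
    shifted[, 2] <- shifted[, 2] + v[2]
    expect_equal(pose_centroid(shifted), pose_centroid(pose) + v)
  }
})

test_that("association matches nearest centroids one-to-one", {
  t0 <- frame_at(0, list(A = c(0, 0), B = c(100, 0)))
  t1 <- frame_at(1, list(P = c(1, 0), Q = c(99, 0)))
  mp <- associate_frames(t0, t1)
  expect_equal(mp$to[mp$from == 1], 1)  # A -> P
  expect_equal(mp$to[mp$from == 2], 2)  # B -> Q

  t0 <- frame_at(0, list(A = c(0, 0)))
  t1 <- frame_at(1, list(P = c(3, 4), Q = c(6, 8)))
  mp <- associate_frames(t0, t1)
  expect_equal(nrow(mp), 1)
  expect_equal(mp$to, 1L)
  expect_equal(mp$distance, 5)

  # count mismatch: greedy gives P to the globally nearest pose A
  t0 <- frame_at(0, list(A = c(0, 0), B = c(2, 0)))
  t1 <- frame_at(1, list(P = c(1, 0)))
  mp <- associate_frames(t0, t1)
  expect_equal(nrow(mp), 1)
  expect_equal(mp$from, 1L)

  expect_equal(nrow(associate_frames(frame_at(0, list()), t1)), 0)
})

test_that("association is permutation-equivariant and matches brute force", {
  brute_assoc <- function(ct, ct1) {
    d <- outer(seq_len(nrow(ct)), seq_len(nrow(ct1)), function(i, j) {
      sqrt((ct$cx[i] - ct1$cx[j])^2 + (ct$cy[i] - ct1$cy[j])^2)
    })
    used_r <- rep(FALSE, nrow(d)); used_c <- rep(FALSE, ncol(d))
    out <- NULL
    repeat {
      dd <- d; dd[used_r, ] <- Inf; dd[, used_c] <- Inf
      if (!any(is.finite(dd))) break
      k <- which(dd == min(dd), arr.ind = TRUE)
      k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
      out <- rbind(out, k)
      used_r[k[1]] <- TRUE; used_c[k[2]] <- TRUE
    }
    out
  }
  set.seed(21)
  for (rep in 1:100) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    c1 <- purrr::map(seq_len(n1), ~ runif(2, 0, 1500))
    c2 <- purrr::map(seq_len(n2), ~ runif(2, 0, 1500))
    f1 <- frame_at(0, c1); f2 <- frame_at(1, c2)
    mp <- associate_frames(f1, f2)
    bf <- brute_assoc(frame_at(0, c1) |> kinekick:::frame_centroids(),
                      frame_at(1, c2) |> kinekick:::frame_centroids())
    expect_equal(nrow(mp), nrow(bf))
    expect_setequal(paste(mp$from, mp$to), paste(bf[, 1], bf[, 2]))

    # shuffling pose order in frame t+1 must not change the geometry of
    # the matching (same centroid pairs)
    perm <- sample(n2)
    f2p <- frame_at(1, c2[perm])
    mpp <- associate_frames(f1, f2p)
    expect_setequal(paste(mp$from, round(purrr::map_dbl(c2, 1)[mp$to])),
                    paste(mpp$from, round(purrr::map_dbl(c2[perm], 1)[mpp$to])))
  }
})

test_that("optimal assignment minimises total distance", {
  # greedy picks (1,1) at cost 1 then forces (2,2) at cost 10 (total 11);
  # optimal takes 2 + 3 = 5
  t0 <- frame_at(0, list(c(0, 0), c(1.5, 0)))
  t1 <- frame_at(1, list(c(1, 0), c(-2, 0)))
  greedy <- associate_frames(t0, t1, method = "greedy")
  optim <- associate_frames(t0, t1, method = "optimal")
  expect_true(sum(optim$distance) <= sum(greedy$distance))
})

test_that("tracks chain without identity swaps on separated walkers", {
  pos <- purrr::map(1:100, function(f) {
    list(c(100 + 5 * f, 300), c(600 + 5 * f, 300))
  })
  tracks <- build_tracks(walking_frames(pos))
  expect_equal(dplyr::n_distinct(tracks$person_id), 2)
  lens <- tracks |> dplyr::distinct(frame, person_id) |>
    dplyr::count(person_id)
  expect_equal(lens$n, c(100, 100))
  # identity constancy: person_id of the left walker never jumps
  left <- tracks |> dplyr::filter(keypoint == 0, x < 400 + 5 * frame)
  expect_equal(dplyr::n_distinct(left$person_id), 1)
})

test_that("single person yields a single full-length track", {
  pos <- purrr::map(1:10, ~ list(c(500 + .x, 400)))
  tracks <- build_tracks(walking_frames(pos))
  expect_equal(dplyr::n_distinct(tracks$person_id), 1)
  expect_equal(sort(unique(tracks$frame)), 0:9)
})

test_that("detection gaps terminate a track and start a new one", {
  pos <- purrr::map(1:10, ~ list(c(500, 400)))
  frames <- walking_frames(pos) |>
    dplyr::filter(!(frame %in% c(5, 6)))
  tracks <- build_tracks(frames)
  lens <- tracks |> dplyr::distinct(frame, person_id) |>
    dplyr::count(person_id) |> dplyr::arrange(-n)
  expect_equal(lens$n, c(5, 3))
})

test_that("marker series extraction projects and flags missing samples", {
  pos <- purrr::map(1:100, ~ list(c(300 + .x, 200)))
  frames <- walking_frames(pos) |>
    dplyr::mutate(x = ifelse(keypoint == 10, x + 7, x),
                  confidence = ifelse(keypoint == 10 & frame %in% 40:42,
                                      0, confidence))
  track <- build_tracks(frames)
  ser <- extract_marker_series(track, keypoint_map = c(knee = 10L))
  expect_equal(nrow(ser), 100)
  expect_equal(ser$frame[ser$missing], 40:42)
  expect_equal(ser$x[ser$frame == 10 & !ser$missing], 300 + 11 + 7)

  expect_error(extract_marker_series(track, keypoint_map = c(bad = 30L)),
               "\\[0, 24\\]")
  expect_error(extract_marker_series(track[0, ]), "empty")
})

test_that("short gaps interpolate linearly, long gaps refuse", {
  ser <- tibble::tibble(marker = "knee", frame = 0:19,
                        x = 2 * (0:19), y = 100 - (0:19),
                        confidence = 0.9, missing = FALSE)
  ser$missing[ser$frame %in% 8:10] <- TRUE
  ser$x[ser$missing] <- 0
  filled <- suppressMessages(interpolate_gaps(ser))
  expect_false(any(filled$missing))
  expect_equal(filled$x, 2 * (0:19))

  ser$missing[ser$frame %in% 5:12] <- TRUE
  expect_error(suppressMessages(interpolate_gaps(ser)), "max_gap")
})

test_that("subject selection picks the longest track in the region", {
  pos <- purrr::map(1:30, function(f) {
    out <- list(c(400, 300))
    if (f <= 10) out <- c(out, list(c(1500, 800)))
    out
  })
  tracks <- build_tracks(walking_frames(pos))
  sel <- suppressMessages(select_subject_track(tracks))
  expect_equal(dplyr::n_distinct(sel$frame), 30)
  roi_sel <- suppressMessages(
    select_subject_track(tracks, roi = c(1200, 1900, 600, 1000)))
  expect_equal(dplyr::n_distinct(roi_sel$frame), 10)
})
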