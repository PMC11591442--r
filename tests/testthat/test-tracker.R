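test_that("tracks are born above eta with sequential ids", {
  dets <- det_rows(det_row(1, -1, 0, 0, 50, 40, 0.9, "lie"),
                   det_row(1, -1, 200, 0, 250, 40, 0.9, "stand"),
                   det_row(1, -1, 400, 0, 450, 40, 0.9, "eat"))
  tr <- byte_tracker()
  tracker_step(tr, 1, dets)
  rec <- track_records(tr)
  expect_equal(sort(rec$id), 1:3)

  # conf <= eta never spawns
  tr2 <- byte_tracker()
  tracker_step(tr2, 1, det_row(1, -1, 0, 0, 50, 40, 0.7, "lie"))
  expect_equal(nrow(track_records(tr2)), 0L)

  # out-of-order frames are a sequencing error
  expect_error(tracker_step(tr, 3, det_row(3, -1, 0, 0, 50, 40, 0.9, "lie")),
               "out-of-order")
})

test_that("unmatched tracks pass through lost and are removed after 30 frames", {
  tr <- byte_tracker()
  tracker_step(tr, 1, det_row(1, -1, 0, 0, 50, 40, 0.9, "lie"))
  none <- det_row(1, -1, 0, 0, 1, 1, 0.9, "lie")[0, ]
  for (f in 2:31) {
    none0 <- none; if (nrow(none0)) none0$frame <- f
    tracker_step(tr, f, none0)
  }
  expect_equal(tr$tracks[[1]]$status, "lost")
  expect_equal(tr$tracks[[1]]$frames_lost, 30L)
  tracker_step(tr, 32, none)
  expect_equal(tr$tracks[[1]]$status, "removed")
})

test_that("a 31-frame dropout splits identity; a 30-frame one does not", {
  mk <- function(gap) {
    present <- c(1:10, (11 + gap):80)
    det_row(present, -1, 100, 100, 160, 140, 0.9, "stand")
  }
  res30 <- run_sequence(mk(30), interpolate = FALSE, n_frames = 80)
  expect_equal(nrow(res30$tracks), 1L)
  res31 <- run_sequence(mk(31), interpolate = FALSE, n_frames = 80)
  expect_equal(nrow(res31$tracks), 2L)
  expect_equal(res31$tracks$status, c("removed", "active"))
})

test_that("interpolation follows the linear box form and its limits", {
  base <- rbind(det_row(10, 1, 0, 0, 10, 10, 0.8, "lie"),
                det_row(20, 1, 10, 10, 20, 20, 0.6, "stand"))
  out <- interpolate_tracks(base, max_gap = 20)
  mid <- out[out$frame == 15, ]
  expect_equal(unlist(mid[c("left", "top", "right", "bottom")]),
               c(left = 5, top = 5, right = 15, bottom = 15))
  at12 <- out[out$frame == 12, ]
  expect_equal(unlist(at12[c("left", "top", "right", "bottom")]),
               c(left = 2, top = 2, right = 12, bottom = 12))
  expect_equal(at12$class, "lie")                    # nearest endpoint
  expect_equal(out$class[out$frame == 16], "stand")
  expect_equal(out$class[out$frame == 15], "lie")    # tie -> earlier
  # endpoints untouched, nothing outside the matched span
  expect_equal(out[out$frame == 10, -9], base[1, -9], ignore_attr = TRUE)
  expect_equal(range(out$frame), c(10, 20))
  expect_equal(sum(out$interp), 9L)

  # gaps beyond max_gap stay open
  wide <- rbind(det_row(10, 1, 0, 0, 10, 10), det_row(40, 1, 0, 0, 10, 10))
  expect_equal(nrow(interpolate_tracks(wide, max_gap = 20)), 2L)
  expect_equal(nrow(interpolate_tracks(wide, max_gap = 29)), 31L)
})

test_that("interpolation adds rows only inside gaps, preserving ids and counts", {
  set.seed(11)
  scene <- simulate_scene(sim_preset("day_high", n_pigs = 8, n_frames = 120,
                                     seed = 11))
  res <- run_sequence(scene$dets, interpolate = FALSE, n_frames = 120)
  before <- res$records
  after <- interpolate_tracks(before, max_gap = 20)
  expect_setequal(unique(after$id), unique(before$id))
  expect_equal(after[after$interp == 0L, names(before)],
               before[order(before$frame, before$id), ],
               ignore_attr = TRUE)
  added <- after[after$interp == 1L, ]
  for (id in unique(added$id)) {
    h <- before[before$id == id, ]
    expect_true(all(added$frame[added$id == id] > min(h$frame)))
    expect_true(all(added$frame[added$id == id] < max(h$frame)))
  }
})

test_that("a full sequence on clean lanes yields per-pig tracks, no switches", {
  dets <- lanes_dets(2, 60)
  res <- run_sequence(dets, n_frames = 60)
  expect_equal(nrow(res$tracks), 2L)
  gt <- dets
  gt$id <- rep(1:2, each = 60)
  rep <- evaluate_tracking(gt, res$records)
  expect_equal(rep$ids, 0L)
  expect_equal(rep$mota, 1)

  # a 5-frame dropout inside max_gap leaves no frame gaps after tracking
  drop <- dets[!(dets$frame %in% 20:24 & dets$top == 200), ]
  res2 <- run_sequence(drop, n_frames = 60)
  expect_equal(nrow(res2$tracks), 2L)
  for (id in res2$tracks$id) {
    f <- sort(res2$records$frame[res2$records$id == id])
    expect_equal(f, seq(min(f), max(f)))
  }
})

test_that("track ids are unique and behavior counters conserve matched rows", {
  scene <- simulate_scene(sim_preset("day_medium", n_pigs = 9, n_frames = 150,
                                     seed = 4))
  res <- run_sequence(scene$dets, n_frames = 150)
  expect_equal(anyDuplicated(res$tracks$id), 0L)
  expect_equal(res$tracks$id, seq_len(nrow(res$tracks)))
  matched <- res$records[res$records$interp == 0L, ]
  for (k in seq_len(nrow(res$tracks))) {
    A <- unlist(res$tracks[k, pig_classes()])
    expect_equal(sum(A), sum(matched$id == res$tracks$id[k]))
  }
})

test_that("strict counter reset zeroes an unmatched track's budget", {
  dets <- det_row(c(1:10, 15:20), -1, 100, 100, 160, 140, 0.9, "eat")
  res <- run_sequence(dets, n_frames = 20, strict_reset = TRUE)
  expect_equal(nrow(res$tracks), 1L)
  expect_equal(unname(unlist(res$tracks[1, pig_classes()])),
               c(0L, 0L, 6L, 0L))   # only frames after the last loss remain
  res2 <- run_sequence(dets, n_frames = 20)
  expect_equal(unname(unlist(res2$tracks[1, pig_classes()])),
               c(0L, 0L, 16L, 0L))
})
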