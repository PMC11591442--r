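test_that("perfect tracking gives unit metrics and zero switches", {
  gt <- rbind(det_row(1:10, 1, 0, 0, 50, 40),
              det_row(1:10, 2, 200, 0, 250, 40))
  rep <- evaluate_tracking(gt, gt)
  expect_equal(rep$hota, 1)
  expect_equal(rep$mota, 1)
  expect_equal(rep$idf1, 1)
  expect_equal(rep$ids, 0L)
  expect_equal(rep$counts$TP, 20L)
  expect_equal(rep$counts$FP + rep$counts$FN, 0L)

  # identity relabeling is free of switches
  relab <- gt; relab$id <- ifelse(gt$id == 1, 7L, 9L)
  rep2 <- evaluate_tracking(gt, relab)
  expect_equal(rep2$ids, 0L)
  expect_equal(rep2$idf1, 1)
})

test_that("frame matching counts FP, FN and mid-sequence id switches", {
  gt <- det_row(1:10, 1, 0, 0, 50, 40)
  pred <- rbind(det_row(1:5, 1, 0, 0, 50, 40),
                det_row(6:10, 2, 0, 0, 50, 40))
  mf <- match_frames(gt, pred, 0.5)
  expect_equal(sum(mf$counts$IDS), 1L)
  expect_equal(sum(mf$counts$TP), 10L)

  spurious <- rbind(pred, det_row(1:10, 3, 500, 500, 550, 540))
  mf2 <- match_frames(gt, spurious, 0.5)
  expect_equal(sum(mf2$counts$FP), 10L)
  expect_equal(sum(mf2$counts$TP + mf2$counts$FN), sum(mf2$counts$g_t))

  expect_error(match_frames(gt, det_row(1, -1, 0, 0, 50, 40), 0.5),
               "identities")
})

test_that("MOTA and IDF1 follow their formulas on constructed counts", {
  counts <- data.frame(TP = 8, FP = 1, FN = 1, IDS = 0, g_t = 10)
  expect_equal(mota(counts), 0.8)
  expect_equal(mota(data.frame(TP = 1, FP = 12, FN = 3, IDS = 2, g_t = 4)),
               1 - 17 / 4)   # formula permits negative values
  expect_error(mota(data.frame(TP = 0, FP = 0, FN = 0, IDS = 0, g_t = 0)),
               "undefined")
  expect_equal(idf1(list(IDTP = 8, IDFP = 2, IDFN = 2)), 0.8)
  expect_equal(idf1(list(IDTP = 0, IDFP = 3, IDFN = 3)), 0)
  expect_error(idf1(list(IDTP = 0, IDFP = 0, IDFN = 0)), "undefined")
})

test_that("metrics agree with brute-force oracles on small scenes", {
  scenes <- list()
  # two objects, one mid-sequence swap
  gt <- rbind(det_row(1:4, 1, 0, 0, 40, 30), det_row(1:4, 2, 100, 0, 140, 30))
  pred <- rbind(det_row(1:2, 1, 0, 0, 40, 30), det_row(3:4, 2, 0, 0, 40, 30),
                det_row(1:2, 2, 100, 0, 140, 30),
                det_row(3:4, 1, 100, 0, 140, 30))
  scenes$swap <- list(gt = gt, pred = pred)
  # missing detections and a spurious track
  gt2 <- rbind(det_row(1:6, 1, 0, 0, 40, 30), det_row(1:6, 2, 100, 0, 140, 30),
               det_row(3:6, 3, 200, 0, 240, 30))
  pred2 <- rbind(det_row(1:6, 5, 1, 1, 41, 31), det_row(2:6, 6, 99, 0, 139, 30),
                 det_row(1:6, 7, 300, 300, 340, 330))
  scenes$messy <- list(gt = gt2, pred = pred2)
  # fragmented identity
  pred3 <- rbind(det_row(1:3, 4, 0, 0, 40, 30), det_row(4:6, 8, 0, 0, 40, 30),
                 det_row(1:6, 9, 100, 0, 140, 30))
  scenes$frag <- list(gt = gt2[gt2$id != 3, ], pred = pred3)

  for (s in scenes) {
    rep <- evaluate_tracking(s$gt, s$pred, 0.5)
    expect_equal(rep$mota, oracle_mota(s$gt, s$pred, 0.5))
    expect_equal(rep$idf1, oracle_idf1(s$gt, s$pred, 0.5))
    expect_equal(rep$hota, oracle_hota(s$gt, s$pred, 0.5))
  }
  expect_equal(evaluate_tracking(scenes$swap$gt, scenes$swap$pred)$ids, 2L)
  # no predictions at all: zero HOTA by the empty TP sum
  expect_equal(hota_paper(gt, pred[0, ], 0.5), 0)
})

test_that("ratio metrics are invariant to frame shifts and translations", {
  scene <- simulate_scene(sim_preset("day_high", n_pigs = 6, n_frames = 60,
                                     seed = 2))
  res <- run_sequence(scene$dets, n_frames = 60)
  r0 <- evaluate_tracking(scene$gt, res$records)
  shift <- function(x, df, dx) {
    x$frame <- x$frame + df
    for (cc in c("left", "right")) x[[cc]] <- x[[cc]] + dx
    x
  }
  r1 <- evaluate_tracking(shift(scene$gt, 50, 300),
                          shift(res$records, 50, 300))
  expect_equal(r1$hota, r0$hota)
  expect_equal(r1$mota, r0$mota)
  expect_equal(r1$idf1, r0$idf1)
  expect_equal(r1$ids, r0$ids)
})

test_that("standard HOTA variant is the sqrt-threshold-averaged score", {
  gt <- rbind(det_row(1:4, 1, 0, 0, 40, 30), det_row(1:4, 2, 100, 0, 140, 30))
  rep <- evaluate_tracking(gt, gt, hota_standard = TRUE)
  expect_equal(rep$hota_standard, 1)
  pred <- gt; pred$id <- ifelse(gt$frame <= 2, gt$id, gt$id + 10L)
  rep2 <- evaluate_tracking(gt, pred, hota_standard = TRUE)
  expect_equal(rep2$hota_standard, sqrt(rep2$hota), tolerance = 1e-9)
  expect_lt(rep2$hota, 1)
})

test_that("sequences aggregate by pooling counts, ids by summing", {
  make <- function(seed, n) {
    scene <- simulate_scene(sim_preset("day_high", n_pigs = 6, n_frames = n,
                                       seed = seed))
    res <- run_sequence(scene$dets, n_frames = n)
    list(scene = scene, rep = evaluate_tracking(scene$gt, res$records))
  }
  a <- make(21, 50); b <- make(22, 80)
  agg <- aggregate_sequences(list(a$rep, b$rep))
  expect_equal(agg$ids, a$rep$ids + b$rep$ids)
  cA <- a$rep$counts; cB <- b$rep$counts
  expect_equal(agg$mota,
               1 - (cA$FP + cB$FP + cA$FN + cB$FN + cA$IDS + cB$IDS) /
                 (cA$g_t + cB$g_t))
  expect_equal(agg$idf1, 2 * (cA$IDTP + cB$IDTP) /
                 (2 * (cA$IDTP + cB$IDTP) + cA$IDFP + cB$IDFP +
                    cA$IDFN + cB$IDFN))
  expect_equal(agg$hota, (cA$sum_Ac + cB$sum_Ac) /
                 (cA$hota_den + cB$hota_den))
  # single sequence aggregates to itself
  expect_equal(aggregate_sequences(list(a$rep)), a$rep)
  # printed-row reports: only the IDs sum is defined
  rows <- benchmark_results("one_min")
  agg2 <- aggregate_sequences(lapply(seq_len(nrow(rows)), function(i)
    metrics_report(ids = rows$ids[i], name = rows$video[i])))
  expect_equal(agg2$ids, sum(rows$ids))
  expect_true(is.na(agg2$hota))
})
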