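# Independent brute-force oracles used to cross-check the assignment solver
# and the evaluation metrics on small instances. These deliberately share no
# code with the package implementation.

# Exhaustive gated assignment by bitmask DP over columns: maximize the
# number of matched pairs among pairs with cost <= max_cost, then minimize
# total cost. Returns list(n_matched, total_cost).
oracle_assignment <- function(cost, max_cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(list(n_matched = 0L, total_cost = 0))
  stopifnot(m <= 20L)
  n_masks <- bitwShiftL(1L, m)
  best_cnt <- matrix(-1L, n + 1L, n_masks)    # rows processed x used-col mask
  best_cost <- matrix(Inf, n + 1L, n_masks)
  best_cnt[1L, 1L] <- 0L
  best_cost[1L, 1L] <- 0
  for (i in seq_len(n)) {
    for (mask in 0:(n_masks - 1L)) {
      c0 <- best_cnt[i, mask + 1L]
      if (c0 < 0L) next
      v0 <- best_cost[i, mask + 1L]
      # leave row i unmatched
      if (c0 > best_cnt[i + 1L, mask + 1L] ||
          (c0 == best_cnt[i + 1L, mask + 1L] &&
           v0 < best_cost[i + 1L, mask + 1L])) {
        best_cnt[i + 1L, mask + 1L] <- c0
        best_cost[i + 1L, mask + 1L] <- v0
      }
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) == 0L && cost[i, j] <= max_cost) {
          nm <- mask + bit
          if (c0 + 1L > best_cnt[i + 1L, nm + 1L] ||
              (c0 + 1L == best_cnt[i + 1L, nm + 1L] &&
               v0 + cost[i, j] < best_cost[i + 1L, nm + 1L])) {
            best_cnt[i + 1L, nm + 1L] <- c0 + 1L
            best_cost[i + 1L, nm + 1L] <- v0 + cost[i, j]
          }
        }
      }
    }
  }
  cnt <- max(best_cnt[n + 1L, ])
  val <- min(best_cost[n + 1L, best_cnt[n + 1L, ] == cnt])
  list(n_matched = cnt, total_cost = val)
}

# Per-frame maximum-cardinality gated matching by enumeration (no cost
# minimization subtleties needed for the constructed scenes, where matches
# are unambiguous at the gate). Returns the frame-level correspondence list.
oracle_frame_match <- function(gt, pred, iou_min) {
  box_iou <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
    if (un <= 0) 0 else inter / un
  }
  frames <- sort(unique(c(gt$frame, pred$frame)))
  out <- list()
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    ng <- nrow(g); np <- nrow(p)
    if (!ng || !np) next
    iom <- matrix(0, ng, np)
    for (i in seq_len(ng)) for (j in seq_len(np)) {
      iom[i, j] <- box_iou(as.numeric(g[i, c("left", "top", "right", "bottom")]),
                           as.numeric(p[j, c("left", "top", "right", "bottom")]))
    }
    # enumerate all injective partial maps rows -> cols (tiny scenes only)
    stopifnot(ng <= 4L, np <= 4L)
    best <- NULL; best_cnt <- -1L; best_sum <- -Inf
    choices <- c(0L, seq_len(np))
    grid <- do.call(expand.grid, rep(list(choices), ng))
    for (r in seq_len(nrow(grid))) {
      asg <- as.integer(grid[r, ])
      used <- asg[asg > 0L]
      if (anyDuplicated(used)) next
      ok <- all(vapply(seq_len(ng), function(i)
        asg[i] == 0L || iom[i, asg[i]] >= iou_min, TRUE))
      if (!ok) next
      cnt <- length(used)
      s <- sum(vapply(seq_len(ng), function(i)
        if (asg[i] > 0L) iom[i, asg[i]] else 0, 0))
      if (cnt > best_cnt || (cnt == best_cnt && s > best_sum)) {
        best <- asg; best_cnt <- cnt; best_sum <- s
      }
    }
    for (i in seq_len(ng)) {
      if (best[i] > 0L) {
        out[[length(out) + 1L]] <- data.frame(frame = f, gt_id = g$id[i],
                                              pred_id = p$id[best[i]])
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(frame = integer(), gt_id = integer(), pred_id = integer())
}

# MOTA by direct arithmetic from an oracle correspondence.
oracle_mota <- function(gt, pred, iou_min) {
  assoc <- oracle_frame_match(gt, pred, iou_min)
  ids <- 0L
  last <- list()
  for (r in order(assoc$frame)) {
    g <- as.character(assoc$gt_id[r])
    if (!is.null(last[[g]]) && last[[g]] != assoc$pred_id[r]) ids <- ids + 1L
    last[[g]] <- assoc$pred_id[r]
  }
  tp <- nrow(assoc)
  1 - ((nrow(pred) - tp) + (nrow(gt) - tp) + ids) / nrow(gt)
}

# IDF1 by enumerating all identity bijections.
oracle_idf1 <- function(gt, pred, iou_min) {
  assoc <- oracle_frame_match(gt, pred, iou_min)
  gids <- unique(gt$id); pids <- unique(pred$id)
  ov <- matrix(0L, length(gids), length(pids))
  for (r in seq_len(nrow(assoc))) {
    i <- match(assoc$gt_id[r], gids); j <- match(assoc$pred_id[r], pids)
    ov[i, j] <- ov[i, j] + 1L
  }
  k <- max(length(gids), length(pids))
  padded <- matrix(0L, k, k)
  padded[seq_along(gids), seq_along(pids)] <- ov
  perms <- perm_all(k)
  idtp <- max(vapply(seq_len(nrow(perms)), function(r)
    sum(padded[cbind(seq_len(k), perms[r, ])]), 0L))
  2 * idtp / (2 * idtp + (nrow(pred) - idtp) + (nrow(gt) - idtp))
}

perm_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Single-threshold HOTA by direct evaluation of the association-accuracy sum
# over an oracle correspondence.
oracle_hota <- function(gt, pred, iou_min) {
  assoc <- oracle_frame_match(gt, pred, iou_min)
  tp <- nrow(assoc)
  den <- nrow(gt) + nrow(pred) - tp
  if (tp == 0L) return(0)
  s <- 0
  for (r in seq_len(tp)) {
    g <- assoc$gt_id[r]; p <- assoc$pred_id[r]
    tpa <- sum(assoc$gt_id == g & assoc$pred_id == p)
    fna <- sum(gt$id == g) - tpa
    fpa <- sum(pred$id == p) - tpa
    s <- s + tpa / (tpa + fna + fpa)
  }
  s / den
}

# detection-table row builder for constructed scenes
det_row <- function(frame, id, left, top, right, bottom, conf = 1,
                    class = "lie", interp = 0L) {
  data.frame(frame = as.integer(frame), id = as.integer(id), left = left,
             top = top, right = right, bottom = bottom, conf = conf,
             class = class, interp = as.integer(interp),
             stringsAsFactors = FALSE)
}

det_rows <- function(...) do.call(rbind, list(...))

# constant-velocity noiseless detections for n pigs far apart
lanes_dets <- function(n_pigs, n_frames, conf = 0.9, class = "stand",
                       speed = 3, w = 60, h = 40, gap = 200) {
  do.call(rbind, lapply(seq_len(n_pigs), function(i) {
    x <- 10 + speed * (seq_len(n_frames) - 1)
    y <- i * gap
    det_row(seq_len(n_frames), -1L, x, y, x + w, y + h, conf, class)
  }))
}
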