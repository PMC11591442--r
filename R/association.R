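# IoU costs, gated Hungarian assignment, and the two-stage BYTE cascade.
#
# Stage 1 matches predicted track boxes against high-confidence detections;
# stage 2 rescues the tracks left unmatched using low-confidence detections;
# low-confidence detections that match nothing are background and discarded.

#' Intersection over union of two boxes
#'
#' @param a,b Numeric `c(left, top, right, bottom)`.
#' @return IoU in \[0, 1\]: 1 iff identical, 0 iff disjoint.
#' @export
iou <- function(a, b) {
  as.numeric(iou_matrix(matrix(a, 1), matrix(b, 1)))
}

#' IoU matrix between two sets of boxes
#'
#' @param A,B Numeric matrices with one box `(left, top, right, bottom)` per
#'   row.
#' @return `nrow(A)` x `nrow(B)` matrix of IoU values.
#' @export
iou_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(numeric(), n, m))
  ix <- pmax(0, outer(A[, 3], B[, 3], pmin) - outer(A[, 1], B[, 1], pmax))
  iy <- pmax(0, outer(A[, 4], B[, 4], pmin) - outer(A[, 2], B[, 2], pmax))
  inter <- ix * iy
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  union <- outer(areaA, areaB, `+`) - inter
  out <- inter / union
  out[union <= 0] <- 0
  out
}

#' BYTE association thresholds
#'
#' @param tau_high Confidence above which a detection is high-score
#'   (default 0.6).
#' @param tau_low Confidence at or below which a detection is discarded
#'   (default 0.1); detections in `(tau_low, tau_high]` are low-score.
#' @param eta New-track threshold: a stage-1 unmatched detection spawns a
#'   track only if its confidence exceeds `eta` (default 0.75).
#' @param iou_gate_stage1 Minimum IoU for a stage-1 match (default 0.2, i.e.
#'   assignment cost below 0.8).
#' @param iou_gate_stage2 Minimum IoU for a stage-2 match (default 0.5).
#' @return A list of class `byte_thresholds`.
#' @export
byte_thresholds <- function(tau_high = 0.6, tau_low = 0.1, eta = 0.75,
                            iou_gate_stage1 = 0.2, iou_gate_stage2 = 0.5) {
  stopifnot(tau_high > 0, tau_high <= 1, tau_low >= 0,
            iou_gate_stage1 >= 0, iou_gate_stage1 <= 1,
            iou_gate_stage2 >= 0, iou_gate_stage2 <= 1,
            eta > 0, eta <= 1)
  if (tau_low >= tau_high) stop("tau_low must be below tau_high")
  if (eta < tau_high) {
    warning("eta below tau_high: some high-score detections can never ",
            "spawn tracks, which is usually unintended")
  }
  structure(list(tau_high = tau_high, tau_low = tau_low, eta = eta,
                 iou_gate_stage1 = iou_gate_stage1,
                 iou_gate_stage2 = iou_gate_stage2),
            class = "byte_thresholds")
}

#' Split detections into high-score, low-score and discarded sets
#'
#' `conf > tau_high` is high; `tau_low < conf <= tau_high` is low; the rest
#' are discarded. The three index sets partition the input.
#'
#' @param conf Numeric vector of confidences.
#' @param th A [byte_thresholds()] object.
#' @return List of integer index vectors `high`, `low`, `discarded`.
#' @export
split_by_confidence <- function(conf, th) {
  high <- which(conf > th$tau_high)
  low <- which(conf > th$tau_low & conf <= th$tau_high)
  discarded <- which(conf <= th$tau_low)
  list(high = high, low = low, discarded = discarded)
}

new_association_result <- function(matches, unmatched_rows, unmatched_cols) {
  structure(list(matches = matches, unmatched_tracks = unmatched_rows,
                 unmatched_detections = unmatched_cols),
            class = "association_result")
}

#' Gated minimum-cost assignment
#'
#' Solves the rectangular assignment problem on `cost` with the Hungarian
#' algorithm, maximizing the number of matched pairs among pairs with
#' `cost <= max_cost` and, among such assignments, minimizing total cost.
#' Pairs exceeding the gate are never matched. Equal-cost alternatives are
#' broken toward the lowest (row, column) pair.
#'
#' @param cost Numeric matrix (rows: tracks, columns: detections), finite
#'   entries.
#' @param max_cost Gate: pairs with cost above this are rejected.
#' @return An `association_result`: `matches` (two-column matrix of row and
#'   column indices), `unmatched_tracks`, `unmatched_detections`.
#' @export
hungarian_match <- function(cost, max_cost = 1) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) {
    return(new_association_result(
      matrix(integer(), 0, 2, dimnames = list(NULL, c("track", "detection"))),
      seq_len(n), seq_len(m)))
  }
  if (any(!is.finite(cost))) stop("cost matrix has non-finite entries")
  big <- 1e6
  work <- cost
  work[cost > max_cost] <- big
  # deterministic tie-break toward low indices
  eps <- 1e-9
  work <- work + outer(seq_len(n), seq_len(m),
                       function(i, j) ((i - 1) * m + j) * eps)
  k <- max(n, m)
  sq <- matrix(big, k, k)
  sq[seq_len(n), seq_len(m)] <- work
  assign <- lap_square(sq)              # column index per row
  rows <- seq_len(n)
  cols <- assign[seq_len(n)]
  ok <- cols <= m & cost[cbind(rows, pmin(cols, m))] <= max_cost
  matches <- cbind(track = rows[ok], detection = cols[ok])
  new_association_result(matches,
                         setdiff(seq_len(n), matches[, 1]),
                         setdiff(seq_len(m), matches[, 2]))
}

# O(k^3) Hungarian algorithm (potentials / shortest augmenting path) on a
# square cost matrix; returns the assigned column for each row.
lap_square <- function(a) {
  k <- nrow(a)
  INF <- .Machine$double.xmax / 4
  u <- numeric(k + 1)
  v <- numeric(k + 1)
  p <- integer(k + 1)     # p[j]: row assigned to column j (0 = none)
  way <- integer(k + 1)
  for (i in seq_len(k)) {
    p[k + 1] <- i         # virtual column k+1 starts the augmenting path
    j0 <- k + 1L
    minv <- rep(INF, k)
    used <- rep(FALSE, k + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(k)) {
        if (!used[j]) {
          cur <- a[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(k + 1)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == k + 1L) break
    }
  }
  res <- integer(k)
  for (j in seq_len(k)) if (p[j] > 0L) res[p[j]] <- j
  res
}

#' Two-stage BYTE association
#'
#' Splits detections by confidence, matches all candidate tracks against the
#' high-score set (stage 1), then matches the stage-1 unmatched tracks
#' against the low-score set (stage 2). Low-score detections unmatched after
#' stage 2 are background; stage-1 unmatched high-score detections are the
#' candidates for track birth. Behavior classes never gate the association.
#'
#' @param track_boxes Matrix of predicted track boxes, one
#'   `(left, top, right, bottom)` row per track.
#' @param det_boxes Matrix of detection boxes, one row per detection.
#' @param det_conf Detection confidences.
#' @param th A [byte_thresholds()] object.
#' @return List with `stage1` and `stage2` (`association_result`s whose
#'   detection indices refer to the original detection rows), the confidence
#'   partition (`dets_high`, `dets_low`, `dets_discarded`), `unmatched_tracks`
#'   (after both stages) and `birth_candidates` (stage-1 unmatched
#'   high-score detections).
#' @export
byte_associate <- function(track_boxes, det_boxes, det_conf, th) {
  n_trk <- nrow(track_boxes)
  sp <- split_by_confidence(det_conf, th)

  cost1 <- 1 - iou_matrix(track_boxes, det_boxes[sp$high, , drop = FALSE])
  s1 <- hungarian_match(cost1, max_cost = 1 - th$iou_gate_stage1)
  s1$matches[, "detection"] <- sp$high[s1$matches[, "detection"]]
  s1$unmatched_detections <- sp$high[s1$unmatched_detections]

  t_remain <- s1$unmatched_tracks
  cost2 <- 1 - iou_matrix(track_boxes[t_remain, , drop = FALSE],
                          det_boxes[sp$low, , drop = FALSE])
  s2 <- hungarian_match(cost2, max_cost = 1 - th$iou_gate_stage2)
  s2$matches <- cbind(track = t_remain[s2$matches[, "track"]],
                      detection = sp$low[s2$matches[, "detection"]])
  s2$unmatched_tracks <- t_remain[s2$unmatched_tracks]
  s2$unmatched_detections <- sp$low[s2$unmatched_detections]

  list(stage1 = s1, stage2 = s2,
       dets_high = sp$high, dets_low = sp$low, dets_discarded = sp$discarded,
       unmatched_tracks = s2$unmatched_tracks,
       birth_candidates = s1$unmatched_detections)
}
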