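# Seeded pig-pen simulator: ground truth plus degraded detections with the
# statistical structure the tracker assumes. Pigs are axis-aligned boxes of
# class-dependent size whose behavior evolves by a Markov chain and whose
# position follows a class-dependent bounded random walk with persistent
# heading, reflected at the pen walls. Detections drop at random and,
# additionally, when a pig is occluded by a pen mate (pairwise-overlap
# dropout); surviving occluded detections get reduced confidence. All
# randomness comes from per-pig substreams derived from the scenario seed,
# so adding a pig never perturbs the others.

#' Simulation scenario
#'
#' @param n_pigs Number of pigs (pens of 6-15 are typical).
#' @param n_frames Frames to simulate (300 = 1 min at 5 fps).
#' @param fps Frames per second (default 5).
#' @param pen Pen size in pixels, `c(width, height)`.
#' @param behavior_transition 4x4 row-stochastic matrix over
#'   `(lie, stand, eat, other)`; rows must sum to 1.
#' @param speed_by_class Mean per-frame displacement in pixels per class
#'   (lying pigs barely move).
#' @param detect_prob Probability a visible pig is detected in a frame.
#' @param conf_visible,conf_occluded Mean/sd of detection confidence for
#'   visible and occluded pigs.
#' @param occlusion List with `overlap_min` (pairwise IoU above which the
#'   smaller pig of a pair counts as occluded) and `p_occ` (extra drop
#'   probability for occluded pigs). `p_occ = 0` disables occlusion effects.
#' @param box_jitter_sd Gaussian noise sd, pixels, applied to detected box
#'   center and size.
#' @param seed Scenario seed.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_pigs = 10L, n_frames = 300L, fps = 5,
                         pen = c(1280L, 720L),
                         behavior_transition = preset_chain("medium"),
                         speed_by_class = c(lie = 0.3, stand = 1.2,
                                            eat = 0.6, other = 3),
                         detect_prob = 0.97,
                         conf_visible = c(mean = 0.88, sd = 0.04),
                         conf_occluded = c(mean = 0.45, sd = 0.08),
                         occlusion = list(overlap_min = 0.3, p_occ = 0.5),
                         box_jitter_sd = 1.5, seed = 1L) {
  stopifnot(n_pigs >= 1, n_frames >= 1, fps > 0, length(pen) == 2L,
            detect_prob >= 0, detect_prob <= 1,
            occlusion$p_occ >= 0, occlusion$p_occ <= 1,
            box_jitter_sd >= 0)
  if (!all(dim(behavior_transition) == c(4L, 4L)) ||
      any(abs(rowSums(behavior_transition) - 1) > 1e-9) ||
      any(behavior_transition < 0)) {
    stop("behavior_transition must be a 4x4 row-stochastic matrix")
  }
  stopifnot(all(pig_classes() %in% names(speed_by_class)))
  structure(list(n_pigs = as.integer(n_pigs), n_frames = as.integer(n_frames),
                 fps = fps, pen = as.numeric(pen),
                 behavior_transition = behavior_transition,
                 speed_by_class = speed_by_class,
                 detect_prob = detect_prob,
                 conf_visible = conf_visible, conf_occluded = conf_occluded,
                 occlusion = occlusion, box_jitter_sd = box_jitter_sd,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

# Behavior transition matrices for the three activity regimes. "high" moves
# freely between eat/stand/walk-like states; "low" is lie-dominated (its
# stationary distribution puts > 0.9 on lie).
preset_chain <- function(level = c("high", "medium", "low")) {
  level <- match.arg(level)
  m <- switch(level,
    high = rbind(c(0.90, 0.06, 0.02, 0.02),
                 c(0.03, 0.85, 0.06, 0.06),
                 c(0.01, 0.05, 0.92, 0.02),
                 c(0.02, 0.08, 0.02, 0.88)),
    medium = rbind(c(0.970, 0.020, 0.005, 0.005),
                   c(0.050, 0.900, 0.030, 0.020),
                   c(0.030, 0.040, 0.910, 0.020),
                   c(0.050, 0.050, 0.020, 0.880)),
    low = rbind(c(0.9970, 0.0020, 0.0005, 0.0005),
                c(0.1200, 0.8500, 0.0100, 0.0200),
                c(0.1000, 0.0400, 0.8500, 0.0100),
                c(0.1200, 0.0300, 0.0100, 0.8400)))
  dimnames(m) <- list(pig_classes(), pig_classes())
  m
}

# Stationary distribution of a row-stochastic matrix.
chain_stationary <- function(P) {
  e <- eigen(t(P))
  v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
  stats::setNames(v / sum(v), rownames(P))
}

#' Scenario presets for the three day/night activity regimes
#'
#' `day_high`: frequent eating/standing/walking, high detector confidence.
#' `day_medium`: lie-leaning mixed activity, high confidence. `night_low`:
#' mostly lying pigs and a lower-confidence night detector. All presets run
#' at 5 fps.
#'
#' @param name One of `"day_high"`, `"day_medium"`, `"night_low"`.
#' @param n_pigs,n_frames,seed Passed through to [sim_scenario()].
#' @return A [sim_scenario()].
#' @export
sim_preset <- function(name, n_pigs = 10L, n_frames = 300L, seed = 1L) {
  known <- c("day_high", "day_medium", "night_low")
  if (!is.character(name) || length(name) != 1L || !name %in% known) {
    stop("unknown preset: ", paste(name, collapse = ", "),
         " (expected one of ", paste(known, collapse = ", "), ")")
  }
  switch(name,
    day_high = sim_scenario(
      n_pigs = n_pigs, n_frames = n_frames, seed = seed,
      behavior_transition = preset_chain("high"),
      detect_prob = 0.97,
      conf_visible = c(mean = 0.88, sd = 0.04),
      conf_occluded = c(mean = 0.45, sd = 0.08),
      occlusion = list(overlap_min = 0.3, p_occ = 0.5)),
    day_medium = sim_scenario(
      n_pigs = n_pigs, n_frames = n_frames, seed = seed,
      behavior_transition = preset_chain("medium"),
      detect_prob = 0.97,
      conf_visible = c(mean = 0.88, sd = 0.04),
      conf_occluded = c(mean = 0.45, sd = 0.08),
      occlusion = list(overlap_min = 0.3, p_occ = 0.4)),
    night_low = sim_scenario(
      n_pigs = n_pigs, n_frames = n_frames, seed = seed,
      behavior_transition = preset_chain("low"),
      detect_prob = 0.93,
      conf_visible = c(mean = 0.78, sd = 0.06),
      conf_occluded = c(mean = 0.40, sd = 0.08),
      occlusion = list(overlap_min = 0.3, p_occ = 0.5)))
}

# class-dependent box half-sizes (w/2, h/2) in pixels: lying pigs project
# wider and flatter than standing ones
class_half_sizes <- function() {
  rbind(lie = c(60, 36), stand = c(48, 32), eat = c(48, 32),
        other = c(50, 32))
}

# Draw all per-pig randomness from a deterministic substream, restoring the
# caller's RNG state afterwards.
with_substream <- function(seed, i, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
  force(expr)
}

#' Simulate a pen: ground truth and degraded detections
#'
#' @param sc A [sim_scenario()].
#' @return A list of class `scene_pair` with `gt` (identity-labeled truth,
#'   confidence 1) and `dets` (noisy detections, identity -1), both
#'   detection-table data frames, plus `meta` ([seq_meta()]) and the
#'   scenario.
#' @export
simulate_scene <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  classes <- pig_classes()
  half <- class_half_sizes()
  W <- sc$pen[1]; H <- sc$pen[2]
  margin <- max(half) + 5
  # initial non-overlapping placement on a jittered grid
  spacing <- 2.6 * max(half)
  nx <- max(1L, floor((W - 2 * margin) / spacing) + 1L)
  ny <- max(1L, floor((H - 2 * margin) / spacing) + 1L)
  if (nx * ny < sc$n_pigs) {
    stop(sprintf("pen %gx%g cannot fit %d pigs without overlap",
                 W, H, sc$n_pigs))
  }
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  pi0 <- chain_stationary(sc$behavior_transition)

  per_pig <- lapply(seq_len(sc$n_pigs), function(i) {
    with_substream(sc$seed, i, {
      nf <- sc$n_frames
      cell <- cells[i, ]
      x0 <- margin + (cell$ix - 1) * spacing + stats::runif(1, -8, 8)
      y0 <- margin + (cell$iy - 1) * spacing + stats::runif(1, -8, 8)
      state <- integer(nf)
      state[1] <- sample.int(4L, 1L, prob = pi0)
      u_state <- stats::runif(nf)
      for (f in 2:max(nf, 2L)) {
        if (f > nf) break
        p <- sc$behavior_transition[state[f - 1L], ]
        state[f] <- findInterval(u_state[f], cumsum(p),
                                 rightmost.closed = TRUE) + 1L
        if (state[f] > 4L) state[f] <- 4L
      }
      theta <- cumsum(c(stats::runif(1, 0, 2 * pi),
                        stats::rnorm(nf - 1, 0, 0.4)))
      steplen <- sc$speed_by_class[classes[state]] *
        abs(stats::rnorm(nf, 1, 0.3))
      x <- numeric(nf); y <- numeric(nf)
      x[1] <- x0; y[1] <- y0
      for (f in seq_len(nf - 1L)) {
        xn <- x[f] + steplen[f] * cos(theta[f])
        yn <- y[f] + steplen[f] * sin(theta[f])
        # reflect the center off the walls
        if (xn < margin) xn <- 2 * margin - xn
        if (xn > W - margin) xn <- 2 * (W - margin) - xn
        if (yn < margin) yn <- 2 * margin - yn
        if (yn > H - margin) yn <- 2 * (H - margin) - yn
        x[f + 1L] <- min(max(xn, 0), W)
        y[f + 1L] <- min(max(yn, 0), H)
      }
      list(state = state, x = x, y = y,
           u_drop = stats::runif(nf), u_occ = stats::runif(nf),
           conf_z = stats::rnorm(nf),
           jitter = matrix(stats::rnorm(4L * nf, 0, 1), nf, 4L))
    })
  })

  nf <- sc$n_frames
  gt_rows <- vector("list", nf)
  det_rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    st <- vapply(per_pig, function(p) p$state[f], 0L)
    cx <- vapply(per_pig, function(p) p$x[f], 0)
    cy <- vapply(per_pig, function(p) p$y[f], 0)
    hw <- half[st, 1]; hh <- half[st, 2]
    gt <- data.frame(frame = f, id = seq_len(sc$n_pigs),
                     left = cx - hw, top = cy - hh,
                     right = cx + hw, bottom = cy + hh,
                     conf = 1, class = classes[st], interp = 0L,
                     stringsAsFactors = FALSE)
    gt_rows[[f]] <- gt
    # occlusion: in any heavily overlapping pair, the smaller pig is under
    occluded <- rep(FALSE, sc$n_pigs)
    if (sc$occlusion$p_occ > 0 && sc$n_pigs > 1L) {
      boxes <- as.matrix(gt[, c("left", "top", "right", "bottom")])
      iom <- iou_matrix(boxes, boxes)
      area <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
      for (i in seq_len(sc$n_pigs - 1L)) {
        for (j in (i + 1L):sc$n_pigs) {
          if (iom[i, j] > sc$occlusion$overlap_min) {
            under <- if (area[i] < area[j]) i
                     else if (area[j] < area[i]) j
                     else max(i, j)
            occluded[under] <- TRUE
          }
        }
      }
    }
    kept <- vapply(seq_len(sc$n_pigs), function(i) {
      p <- per_pig[[i]]
      if (p$u_drop[f] > sc$detect_prob) return(FALSE)
      if (occluded[i] && p$u_occ[f] < sc$occlusion$p_occ) return(FALSE)
      TRUE
    }, TRUE)
    if (any(kept)) {
      ki <- which(kept)
      cm <- ifelse(occluded[ki], sc$conf_occluded[["mean"]],
                   sc$conf_visible[["mean"]])
      cs <- ifelse(occluded[ki], sc$conf_occluded[["sd"]],
                   sc$conf_visible[["sd"]])
      conf <- pmin(pmax(cm + cs * vapply(per_pig[ki], function(p)
        p$conf_z[f], 0), 0.02), 0.99)
      jit <- t(vapply(per_pig[ki], function(p) p$jitter[f, ], numeric(4)))
      jcx <- cx[ki] + sc$box_jitter_sd * jit[, 1]
      jcy <- cy[ki] + sc$box_jitter_sd * jit[, 2]
      jw <- pmax(2 * hw[ki] + sc$box_jitter_sd * jit[, 3], 4)
      jh <- pmax(2 * hh[ki] + sc$box_jitter_sd * jit[, 4], 4)
      det_rows[[f]] <- data.frame(
        frame = f, id = -1L,
        left = jcx - jw / 2, top = jcy - jh / 2,
        right = jcx + jw / 2, bottom = jcy + jh / 2,
        conf = conf, class = classes[st[ki]], interp = 0L,
        stringsAsFactors = FALSE)
    }
  }
  gt <- do.call(rbind, gt_rows)
  dets <- do.call(rbind, det_rows[!vapply(det_rows, is.null, TRUE)])
  if (is.null(dets)) dets <- empty_detections()
  rownames(gt) <- rownames(dets) <- NULL
  meta <- seq_meta(name = sprintf("sim-seed%d", sc$seed), fps = sc$fps,
                   n_frames = nf, image_width = W, image_height = H)
  structure(list(gt = gt, dets = dets, meta = meta, scenario = sc),
            class = "scene_pair")
}
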