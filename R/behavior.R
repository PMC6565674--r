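# Behavioral phenotyping: synthetic larva silhouettes, skeleton tracking,
# the six locomotor features, and the RMS side-effect score.

BEHAVIOR_FEATURES <- c("FV_mean", "AV_mean", "AV_STD", "HV_pct",
                       "TB_mean", "dTB_mean")

default_motion_program <- function() {
  list(velocity = 40,        # forward speed, px/s
       velocity_mod = 0,     # fractional sinusoidal speed modulation
       velocity_mod_freq = 0.5,
       turn_rate = 0,        # deg/s heading drift
       tail_beat = 0,        # per-segment bend amplitude, deg
       tail_freq = 1.5,      # tail beat frequency, Hz
       lateral_amp = 0,      # whole-body lateral slip amplitude, px
       body_length = 48,     # px
       start = NULL,         # head start position (x, y), px
       heading = 0)          # initial heading, deg
}

truth_points <- function(tsec, prog) {
  n <- length(tsec)
  v <- prog$velocity * (1 + prog$velocity_mod *
                          sin(2 * pi * prog$velocity_mod_freq * tsec))
  psi <- (prog$heading + prog$turn_rate * tsec) * pi / 180
  dt <- c(0, diff(tsec))
  px <- cumsum(v * cos(psi) * dt)
  py <- cumsum(v * sin(psi) * dt)
  lat <- prog$lateral_amp * sin(2 * pi * prog$tail_freq * tsec)
  px <- px - lat * sin(psi)
  py <- py + lat * cos(psi)
  alpha <- prog$tail_beat * sin(2 * pi * prog$tail_freq * tsec) * pi / 180
  seg <- prog$body_length / 4
  P <- array(0, dim = c(n, 5, 2))
  P[, 1, 1] <- px; P[, 1, 2] <- py
  for (k in 2:5) {
    th <- psi + (k - 2) * alpha        # segment k-1 direction + cumulative bend
    P[, k, 1] <- P[, k - 1, 1] - seg * cos(th)
    P[, k, 2] <- P[, k - 1, 2] - seg * sin(th)
  }
  P
}

#' Simulate larva silhouette frames with a known skeleton
#'
#' Renders an elongated larva (wide head, tapering tail) following a motion
#' program: constant or sinusoidally modulated forward speed, heading drift,
#' tail beating (per-segment bend `tail_beat` degrees at `tail_freq` Hz) and
#' the lateral body slip that accompanies it. The exact 5-point skeleton is
#' returned for tracker validation.
#'
#' @param duration seconds.
#' @param rate frame rate (Hz).
#' @param motion_program list overriding any field of the default program
#'   (see Details); speeds in px/s, angles in degrees.
#' @param frame_size `(height, width)` in px. When the program's `start` is
#'   NULL the whole trajectory is centred in the frame.
#' @param seed integer seed, kept for interface symmetry; rendering is fully
#'   deterministic given the program.
#' @return list with `frames` (list of logical matrices), `truth` (data.frame
#'   `frame, t, x1..x5, y1..y5`), `rate`.
#' @export
simulate_behavior <- function(duration, rate = 25, motion_program = list(),
                              frame_size = c(180, 180), seed = 1) {
  stopifnot(duration > 0, rate > 0)
  prog <- utils::modifyList(default_motion_program(), motion_program)
  n <- round(duration * rate)
  tsec <- (seq_len(n) - 1) / rate
  P <- truth_points(tsec, prog)
  if (is.null(prog$start)) {
    # centre the whole trajectory's bounding box in the frame
    P[, , 1] <- P[, , 1] - (min(P[, , 1]) + max(P[, , 1])) / 2 +
      frame_size[2] / 2
    P[, , 2] <- P[, , 2] - (min(P[, , 2]) + max(P[, , 2])) / 2 +
      frame_size[1] / 2
  } else {
    # offset so the initial head sits at `start`
    P[, , 1] <- P[, , 1] - P[1, 1, 1] + prog$start[1]
    P[, , 2] <- P[, , 2] - P[1, 1, 2] + prog$start[2]
  }

  pad <- 5
  if (min(P[, , 1]) < pad || max(P[, , 1]) > frame_size[2] - pad ||
      min(P[, , 2]) < pad || max(P[, , 2]) > frame_size[1] - pad)
    stop_fc("larva leaves the frame; shorten the program or enlarge frame_size")

  radius_at <- function(s) 3.6 - 2.4 * s   # s in [0, 1] head -> tail
  frames <- vector("list", n)
  for (f in seq_len(n)) {
    img <- matrix(FALSE, frame_size[1], frame_size[2])
    # densely sample the polyline
    for (k in 1:4) {
      u <- seq(0, 1, length.out = 16)
      cx <- P[f, k, 1] + u * (P[f, k + 1, 1] - P[f, k, 1])
      cy <- P[f, k, 2] + u * (P[f, k + 1, 2] - P[f, k, 2])
      rr <- radius_at(((k - 1) + u) / 4)
      for (q in seq_along(u)) {
        r <- rr[q]
        xs <- max(1, floor(cx[q] - r)):min(frame_size[2], ceiling(cx[q] + r))
        ys <- max(1, floor(cy[q] - r)):min(frame_size[1], ceiling(cy[q] + r))
        dd <- outer((ys - cy[q])^2, (xs - cx[q])^2, `+`)
        img[ys, xs] <- img[ys, xs] | dd <= r^2
      }
    }
    frames[[f]] <- img
  }
  truth <- data.frame(frame = seq_len(n), t = tsec)
  for (k in 1:5) {
    truth[[paste0("x", k)]] <- P[, k, 1]
    truth[[paste0("y", k)]] <- P[, k, 2]
  }
  list(frames = frames, truth = truth, rate = rate)
}

# ---- Zhang-Suen thinning ---------------------------------------------------

zhang_suen <- function(img) {
  m <- img
  pad <- function(x) {
    out <- matrix(FALSE, nrow(x) + 2, ncol(x) + 2)
    out[2:(nrow(x) + 1), 2:(ncol(x) + 1)] <- x
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- pad(m)
      nr <- nrow(m); nc <- ncol(m)
      ri <- 2:(nr + 1); ci <- 2:(nc + 1)
      P2 <- p[ri - 1, ci];     P3 <- p[ri - 1, ci + 1]
      P4 <- p[ri, ci + 1];     P5 <- p[ri + 1, ci + 1]
      P6 <- p[ri + 1, ci];     P7 <- p[ri + 1, ci - 1]
      P8 <- p[ri, ci - 1];     P9 <- p[ri - 1, ci - 1]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (phase == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# longest path across the skeleton graph (8-connectivity); returns a matrix
# of (row, col) pixel coordinates in path order, or NULL.
skeleton_path <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  if (n < 3L) return(NULL)
  key <- paste(px[, 1], px[, 2])
  idx <- stats::setNames(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nbrs <- lapply(seq_len(n), function(v) {
    h <- idx[paste(px[v, 1] + offs[, 1], px[v, 2] + offs[, 2])]
    unname(h[!is.na(h)])
  })
  deg <- lengths(nbrs)
  ends <- which(deg == 1L)
  if (!length(ends)) return(NULL)
  bfs <- function(s) {
    dist <- rep(NA_integer_, n); par <- rep(NA_integer_, n)
    dist[s] <- 0L; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in nbrs[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; par[w] <- v; q <- c(q, w)
      }
    }
    list(dist = dist, par = par)
  }
  b1 <- bfs(ends[1])
  e1 <- which.max(replace(b1$dist, -ends, NA))
  b2 <- bfs(e1)
  e2 <- which.max(replace(b2$dist, -ends, NA))
  path <- e2
  while (!is.na(b2$par[path[1]])) path <- c(b2$par[path[1]], path)
  px[path, , drop = FALSE]
}

smooth_path <- function(xy, w = 5) {
  if (nrow(xy) <= w) return(xy)
  apply(xy, 2L, function(v) sliding_mean(v, half_width = floor(w / 2)))
}

# re-center a mid-line point in the silhouette cross-section perpendicular
# to the local path direction; removes the lateral attenuation left by
# thinning and path smoothing at body bends
recenter_point <- function(pt, dir, img, half_width = 5) {
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-9) return(pt)
  nx <- -dir[2] / nd; ny <- dir[1] / nd
  offs <- seq(-half_width, half_width, by = 0.5)
  px <- round(pt[1] + offs * nx); py <- round(pt[2] + offs * ny)
  ok <- py >= 1 & py <= nrow(img) & px >= 1 & px <= ncol(img)
  ok[ok] <- img[cbind(py[ok], px[ok])]
  if (!any(ok)) return(pt)
  # use the contiguous run of silhouette pixels containing the centre
  mid <- which.min(abs(offs))
  if (!ok[mid]) return(pt)
  lo <- mid; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- mid; while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
  shift <- mean(offs[lo:hi])
  c(pt[1] + shift * nx, pt[2] + shift * ny)
}

# extend a skeleton path toward the silhouette tips at both ends: thinning
# erodes each tip irregularly, so the end point is re-anchored at the
# mid-line position one local body radius short of the silhouette boundary
# (the mid-line terminus of a tapered body)
extend_to_boundary <- function(xy, img, max_step = 8) {
  inside <- function(p) {
    r <- round(p[2]); c <- round(p[1])
    r >= 1 && r <= nrow(img) && c >= 1 && c <= ncol(img) && img[r, c]
  }
  local_radius <- function(p, rmax = 6L) {
    pr <- round(p[2]); pc <- round(p[1])
    ys <- max(1, pr - rmax):min(nrow(img), pr + rmax)
    xs <- max(1, pc - rmax):min(ncol(img), pc + rmax)
    bg <- !img[ys, xs]
    if (!any(bg)) return(rmax)
    w <- which(bg, arr.ind = TRUE)
    sqrt(min((ys[w[, 1]] - p[2])^2 + (xs[w[, 2]] - p[1])^2))
  }
  ext_end <- function(tip, ref) {
    d <- tip - ref; d <- d / max(sqrt(sum(d^2)), 1e-9)
    reach <- 0
    for (s in seq_len(max_step)) {
      if (!inside(tip + s * d)) break
      reach <- s
    }
    # boundary sits at ~reach + 0.5 beyond the eroded tip; the mid-line
    # terminus is one local body radius (measured at the tip) short of it
    tip + max(0, reach + 0.5 - local_radius(tip)) * d
  }
  k <- min(4L, nrow(xy) - 1L)
  rbind(ext_end(xy[1, ], xy[1 + k, ]), xy,
        ext_end(xy[nrow(xy), ], xy[nrow(xy) - k, ]))
}

#' Track 5-point skeletons in silhouette frames
#'
#' Per frame: Zhang-Suen thinning of the binary silhouette, longest
#' end-to-end path across the skeleton (which prunes side spurs), mild
#' smoothing of the path, and 5 points at arc-length quantiles
#' {0, 1/4, 1/2, 3/4, 1}. The head is the path end with the larger local
#' silhouette mass; near-ties fall back to continuity with the previous
#' frame. Blank or degenerate frames are flagged missing.
#'
#' @param frames list of logical matrices (silhouettes), or the list
#'   returned by [simulate_behavior()].
#' @param rate frame rate in Hz.
#' @return data.frame `frame, t, valid, x1..x5, y1..y5` with attribute
#'   `rate`; class `skeleton_track`.
#' @export
track_skeleton <- function(frames, rate = NULL) {
  if (is.list(frames) && !is.null(frames$frames)) {
    rate <- rate %||% frames$rate
    frames <- frames$frames
  }
  if (is.null(rate)) stop_fc("rate is required")
  n <- length(frames)
  out <- data.frame(frame = seq_len(n), t = (seq_len(n) - 1) / rate,
                    valid = FALSE)
  for (k in 1:5) { out[[paste0("x", k)]] <- NA_real_; out[[paste0("y", k)]] <- NA_real_ }

  # pass 1: per-frame oriented mid-line paths
  paths <- vector("list", n)
  prev_head <- NULL
  for (f in seq_len(n)) {
    img <- frames[[f]]
    if (!any(img)) next
    # thin only the silhouette bounding box
    rr <- range(which(rowSums(img) > 0)); cc <- range(which(colSums(img) > 0))
    r0 <- max(1, rr[1] - 2); c0 <- max(1, cc[1] - 2)
    crop <- img[r0:min(nrow(img), rr[2] + 2), c0:min(ncol(img), cc[2] + 2)]
    path <- skeleton_path(zhang_suen(crop))
    if (is.null(path) || nrow(path) < 5L) next
    path <- cbind(path[, 1] + r0 - 1L, path[, 2] + c0 - 1L)
    xy <- smooth_path(cbind(x = path[, 2], y = path[, 1]))
    xy <- extend_to_boundary(xy, img)
    # local silhouette mass near each end decides the head (wider end)
    mass_near <- function(pt, r = 4) {
      ys <- max(1, round(pt[2] - r)):min(nrow(img), round(pt[2] + r))
      xs <- max(1, round(pt[1] - r)):min(ncol(img), round(pt[1] + r))
      sum(img[ys, xs])
    }
    mA <- mass_near(xy[1, ]); mB <- mass_near(xy[nrow(xy), ])
    flip <- mB > mA
    if (abs(mA - mB) <= 0.1 * max(mA, mB) && !is.null(prev_head)) {
      dA <- sum((xy[1, ] - prev_head)^2); dB <- sum((xy[nrow(xy), ] - prev_head)^2)
      flip <- dB < dA
    }
    if (flip) xy <- xy[rev(seq_len(nrow(xy))), ]
    paths[[f]] <- xy
    prev_head <- xy[1, ]
  }

  # pass 2: the body length is constant, so per-frame arc-length estimates
  # are smoothed over time before quantile placement; this suppresses the
  # along-axis point jitter that pixelation induces
  ok <- !vapply(paths, is.null, logical(1))
  lens <- rep(NA_real_, n)
  lens[ok] <- vapply(paths[ok], function(xy)
    sum(sqrt(rowSums(diff(xy)^2))), numeric(1))
  lsm <- lens
  if (sum(ok) > 3L)
    lsm[ok] <- sliding_mean(lens[ok], half_width = 7L)
  for (f in which(ok)) {
    img <- frames[[f]]
    xy <- paths[[f]]
    arc <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
    targets <- lsm[f] * c(0, 0.25, 0.5, 0.75, 1)
    # centre the smoothed length on the measured path
    targets <- targets + (arc[length(arc)] - lsm[f]) / 2
    targets <- pmin(pmax(targets, 0), arc[length(arc)])
    for (k in 1:5) {
      i <- findInterval(targets[k], arc, all.inside = TRUE)
      w <- (targets[k] - arc[i]) / max(arc[i + 1] - arc[i], 1e-12)
      pt <- xy[i, ] + w * (xy[i + 1, ] - xy[i, ])
      dir <- xy[min(i + 1, nrow(xy)), ] - xy[max(i - 1, 1), ]
      pt <- recenter_point(pt, dir, img)
      out[[paste0("x", k)]][f] <- pt[1]
      out[[paste0("y", k)]][f] <- pt[2]
    }
    out$valid[f] <- TRUE
  }
  attr(out, "rate") <- rate
  class(out) <- c("skeleton_track", "data.frame")
  out
}

#' The six locomotor features of a skeleton track
#'
#' Displacements of the anterior midpoint between consecutive valid frames
#' are decomposed along the body centerline (defined by the two anterior
#' points): the parallel component gives the mean forward velocity
#' (`FV_mean`, signed mean) and the high-velocity time fraction (`HV_pct`,
#' per-frame forward speed above `FV_mean + FV_STD`; defined as 0 when
#' `FV_STD` is 0); the perpendicular component gives the angular velocity
#' metrics (`AV_mean` = mean magnitude, `AV_STD` = SD of the signed
#' series). Tail angles of the three posterior vertex points relative to
#' the body centerline, summed as absolute values, give `TB_mean`
#' (degrees) and their frame-to-frame change `dTB_mean` (degrees/s).
#'
#' @param track a `skeleton_track` (tracked or ground-truth; a truth
#'   data.frame from [simulate_behavior()] is accepted with `rate` given).
#' @param rate frame rate, taken from the track attribute when absent.
#' @return named numeric vector of the six features.
#' @export
compute_behavioral_features <- function(track, rate = NULL) {
  rate <- rate %||% attr(track, "rate")
  if (is.null(rate)) stop_fc("rate is required")
  if (is.null(track$valid)) track$valid <- TRUE
  tr <- track[track$valid, , drop = FALSE]
  if (nrow(tr) < 2L) stop_fc("fewer than 2 valid frames")

  ux <- tr$x1 - tr$x2; uy <- tr$y1 - tr$y2
  nrm <- sqrt(ux^2 + uy^2); ux <- ux / nrm; uy <- uy / nrm
  mx <- (tr$x1 + tr$x2) / 2; my <- (tr$y1 + tr$y2) / 2
  dt <- diff(tr$t)
  i <- seq_len(nrow(tr) - 1L)
  dx <- diff(mx); dy <- diff(my)
  fv <- (dx * ux[i] + dy * uy[i]) / dt
  av <- (-dx * uy[i] + dy * ux[i]) / dt

  fv_mean <- mean(fv)
  # the high-velocity threshold uses a smoothed forward-speed series
  # (7-frame running mean) so the exceedance fraction is robust to
  # single-frame tracking jitter
  fv_s <- if (length(fv) >= 7) sliding_mean(fv, 3L) else fv
  fv_sd <- if (length(fv_s) > 1L) stats::sd(fv_s) else 0
  hv <- if (fv_sd == 0) 0 else 100 * mean(fv_s > mean(fv_s) + fv_sd)

  seg_angle <- function(k) {
    sx <- tr[[paste0("x", k)]] - tr[[paste0("x", k - 1)]]
    sy <- tr[[paste0("y", k)]] - tr[[paste0("y", k - 1)]]
    # signed angle between the segment and the backward body direction
    bx <- -ux; by <- -uy
    atan2(sx * by - sy * bx, sx * bx + sy * by) * 180 / pi
  }
  ang <- vapply(3:5, seg_angle, numeric(nrow(tr)))
  ang <- matrix(ang, nrow = nrow(tr))
  tb <- rowSums(abs(ang))
  dang <- abs(ang[-1L, , drop = FALSE] - ang[-nrow(ang), , drop = FALSE])
  dtb <- rowSums(dang) / dt

  c(FV_mean = fv_mean, AV_mean = mean(abs(av)), AV_STD = stats::sd(av),
    HV_pct = hv, TB_mean = mean(tb), dTB_mean = mean(dtb))
}

#' Combined behavioral side-effect score
#'
#' Each feature's divergence is the absolute fractional deviation of the
#' treated group mean from the untreated baseline mean (absolute difference
#' when a baseline mean is zero, with a message); the combined score is the
#' root mean square of the six divergences. The score's SD comes from
#' per-larva combined scores computed the same way.
#'
#' @param treated matrix or data.frame, one row per larva, columns the six
#'   features.
#' @param baseline same for the untreated group.
#' @return object of class `side_effect_score`: list with `divergences`,
#'   `x_combined`, `sd`, `per_larva`.
#' @examples
#' # divergences (3,4,0,0,0,0) -> sqrt(25/6)
#' @export
side_effect_score <- function(treated, baseline) {
  treated <- as.matrix(treated)[, BEHAVIOR_FEATURES, drop = FALSE]
  baseline <- as.matrix(baseline)[, BEHAVIOR_FEATURES, drop = FALSE]
  if (!nrow(treated) || !nrow(baseline)) stop_fc("both groups must be non-empty")
  mb <- colMeans(baseline)
  zero <- mb == 0
  if (any(zero))
    message(sprintf("baseline mean is 0 for %s; using absolute differences",
                    paste(names(mb)[zero], collapse = ", ")))
  div_of <- function(mt) {
    d <- abs(mt - mb)
    d[!zero] <- d[!zero] / abs(mb[!zero])
    d
  }
  div <- div_of(colMeans(treated))
  per <- apply(treated, 1L, function(r) sqrt(mean(div_of(r)^2)))
  structure(list(divergences = div,
                 x_combined = sqrt(mean(div^2)),
                 sd = if (length(per) > 1) stats::sd(per) else 0,
                 per_larva = per),
            class = "side_effect_score")
}

#' @export
print.side_effect_score <- function(x, ...) {
  cat(sprintf("<side_effect_score> x_combined = %.4f (sd %.4f)\n",
              x$x_combined, x$sd))
  print(round(x$divergences, 4))
  invisible(x)
}
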