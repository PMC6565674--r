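# build a ground-truth style track directly from 5-point geometry
track_from_points <- function(P, rate) {
  n <- dim(P)[1]
  out <- data.frame(frame = seq_len(n), t = (seq_len(n) - 1) / rate,
                    valid = TRUE)
  for (k in 1:5) {
    out[[paste0("x", k)]] <- P[, k, 1]
    out[[paste0("y", k)]] <- P[, k, 2]
  }
  attr(out, "rate") <- rate
  out
}

straight_points <- function(n, v, rate, L = 48) {
  P <- array(0, dim = c(n, 5, 2))
  for (f in seq_len(n)) for (k in 1:5) {
    P[f, k, 1] <- 100 + v * (f - 1) / rate - (k - 1) * L / 4
    P[f, k, 2] <- 60
  }
  P
}

test_that("behavioral features satisfy their geometric anchors", {
  rate <- 25
  # stationary: all velocity features zero, HV defined as 0
  f0 <- compute_behavioral_features(track_from_points(
    straight_points(50, 0, rate), rate))
  expect_equal(unname(f0[c("FV_mean", "AV_mean", "AV_STD", "HV_pct",
                           "TB_mean", "dTB_mean")]),
               c(0, 0, 0, 0, 0, 0))
  # straight swim at constant v: FV = v, AV = 0
  fv <- compute_behavioral_features(track_from_points(
    straight_points(50, 30, rate), rate))
  expect_equal(unname(fv["FV_mean"]), 30, tolerance = 1e-9)
  expect_equal(unname(fv["AV_mean"]), 0, tolerance = 1e-9)
  # rigid translation with a fixed bent tail: TB > 0, dTB = 0
  P <- straight_points(50, 20, rate)
  bend <- 20 * pi / 180
  for (f in 1:50) for (k in 3:5) {
    ang <- (k - 2) * bend
    P[f, k, 1] <- P[f, k - 1, 1] - 12 * cos(ang)
    P[f, k, 2] <- P[f, k - 1, 2] - 12 * sin(ang)
  }
  fb <- compute_behavioral_features(track_from_points(P, rate))
  expect_gt(fb[["TB_mean"]], 100)   # 20 + 40 + 60 degrees
  expect_equal(fb[["dTB_mean"]], 0, tolerance = 1e-9)
  expect_error(compute_behavioral_features(track_from_points(P, rate)[1, ]),
               "2 valid")
})

test_that("the tracker recovers a straight larva as collinear equispaced points", {
  sim <- simulate_behavior(0.2, 25, motion_program = list(velocity = 0),
                           frame_size = c(120, 120), seed = 1)
  trk <- track_skeleton(sim)
  expect_true(all(trk$valid))
  f <- 1
  xs <- sapply(1:5, function(k) trk[[paste0("x", k)]][f])
  ys <- sapply(1:5, function(k) trk[[paste0("y", k)]][f])
  seglen <- sqrt(diff(xs)^2 + diff(ys)^2)
  expect_true(all(abs(seglen - 48 / 4) < 1.5))
  # collinearity: largest perpendicular residual from the head-tail line
  dx <- xs[5] - xs[1]; dy <- ys[5] - ys[1]
  nrm <- sqrt(dx^2 + dy^2)
  res <- abs(dy * (xs - xs[1]) - dx * (ys - ys[1])) / nrm
  expect_lt(max(res), 1)
})

test_that("a bent larva yields nonzero tracked tail angles and blank frames are flagged", {
  sim <- simulate_behavior(0.2, 25,
                           motion_program = list(velocity = 0, tail_beat = 25,
                                                 tail_freq = 0,
                                                 heading = 30),
                           frame_size = c(140, 140), seed = 2)
  # force a static L-bend: tail_freq 0 gives sin(0) = 0, so bend manually
  sim2 <- simulate_behavior(0.8, 25,
                            motion_program = list(velocity = 0, tail_beat = 25,
                                                  tail_freq = 1.25),
                            frame_size = c(140, 140), seed = 2)
  trk <- track_skeleton(sim2)
  idx <- which(trk$valid & abs(sin(2 * pi * 1.25 * trk$t)) > 0.7)
  feats <- compute_behavioral_features(trk[idx, ], rate = 25)
  expect_gt(feats[["TB_mean"]], 10)
  # blank frame handling
  frames <- sim$frames
  frames[[3]] <- frames[[3]] & FALSE
  trk2 <- track_skeleton(frames, rate = 25)
  expect_false(trk2$valid[3])
  expect_true(is.na(trk2$x1[3]))
})

test_that("tracked features match programmed motion within 5%", {
  rel_err <- vapply(1:2, function(s) {
    prog <- list(velocity = 80, velocity_mod = 0.8, velocity_mod_freq = 0.75,
                 turn_rate = 30, tail_beat = 16, tail_freq = 1.5,
                 lateral_amp = 6, body_length = 64, heading = 120 * s)
    sim <- simulate_behavior(12, 25, motion_program = prog,
                             frame_size = c(440, 440), seed = s)
    trk <- track_skeleton(sim)
    truth_tr <- sim$truth; truth_tr$valid <- TRUE
    ft <- compute_behavioral_features(truth_tr, rate = 25)
    fk <- compute_behavioral_features(trk)
    abs(fk - ft) / abs(ft)
  }, numeric(6))
  expect_lt(max(rowMeans(rel_err)), 0.05)
  # programmed forward speed itself is recovered
  sim <- simulate_behavior(4, 25,
                           motion_program = list(velocity = 45,
                                                 start = c(120, 150)),
                           frame_size = c(340, 340), seed = 5)
  fk <- compute_behavioral_features(track_skeleton(sim))
  expect_lt(abs(fk[["FV_mean"]] - 45) / 45, 0.05)
})

test_that("side-effect scores are the RMS of baseline divergences", {
  base <- matrix(rep(c(10, 8, 6, 20, 30, 100), each = 4), nrow = 4)
  colnames(base) <- c("FV_mean", "AV_mean", "AV_STD", "HV_pct",
                      "TB_mean", "dTB_mean")
  s0 <- side_effect_score(base, base)
  expect_equal(unname(s0$x_combined), 0)
  expect_equal(unname(s0$divergences), rep(0, 6))
  # divergences (3, 4, 0, 0, 0, 0) -> sqrt(25/6)
  treated <- base
  treated[, 1] <- base[, 1] * 4   # divergence 3
  treated[, 2] <- base[, 2] * 5   # divergence 4
  s1 <- side_effect_score(treated, base)
  expect_equal(unname(s1$x_combined), sqrt(25 / 6), tolerance = 1e-12)
  # equal divergences d give x_combined = d
  treated2 <- base * 1.35
  s2 <- side_effect_score(treated2, base)
  expect_equal(unname(s2$x_combined), 0.35, tolerance = 1e-12)
  # monotone in each |divergence|
  treated3 <- treated
  treated3[, 3] <- base[, 3] * 2
  expect_gt(side_effect_score(treated3, base)$x_combined, s1$x_combined)
  # zero baseline feature falls back to absolute difference
  base0 <- base; base0[, 4] <- 0
  treated0 <- base0; treated0[, 4] <- 2
  expect_message(s4 <- side_effect_score(treated0, base0), "absolute")
  expect_equal(unname(s4$divergences["HV_pct"]), 2)
})
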