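test_that("state segmentation follows the stimulation protocol", {
  win <- segment_states(stimulus_schedule(600, c(600, 720, 840, 960)), 1080)
  expect_equal(win$pre, c(0, 600))
  expect_equal(win$early, list(c(610, 660), c(730, 780), c(850, 900),
                               c(970, 1020)))
  expect_equal(win$late, list(c(660, 720), c(780, 840), c(900, 960),
                              c(1020, 1080)))
  # disjointness within each state
  for (state in list(win$early, win$late)) {
    iv <- do.call(rbind, state)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2]))
  }
  # no stimuli: the whole recording is resting state
  w0 <- segment_states(stimulus_schedule(300, numeric(0)), 300)
  expect_equal(w0$pre, c(0, 300))
  expect_length(w0$early, 0)
  expect_error(segment_states(stimulus_schedule(10, c(10, 50)), 200),
               "closer than 120")
  expect_message(segment_states(stimulus_schedule(10, 10), 100), "truncated")
})

test_that("inter-area correlation matches its definition and a brute-force oracle", {
  T <- 600
  set.seed(1)
  x <- rnorm(T)
  sv <- make_sv(list(r1 = cbind(x, x), r2 = cbind(x, -x)))
  w <- list(c(0, T / 20))
  expect_equal(inter_area_correlation(sv, c(1, 2), w), 1)
  # independent Gaussian traces: mean |r| near the closed-form chance level
  tr <- latent_traces(1000, 5, rho = 0, seed = 2)
  sv0 <- make_sv(tr, rate = 20)
  got <- inter_area_correlation(sv0, c(1, 2), list(c(0, 50)))
  expect_lt(abs(got - sqrt(2 / (pi * (1000 - 1)))), 0.01)
  # every Pearson r agrees with a two-pass covariance oracle
  brute_r <- function(a, b) {
    ma <- mean(a); mb <- mean(b)
    sum((a - ma) * (b - mb)) /
      sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  }
  cc <- cor(sv0$dff[, 1:5], sv0$dff[, 6:10])
  for (i in 1:5) for (j in 1:5)
    expect_equal(cc[i, j], brute_r(sv0$dff[, i], sv0$dff[, j + 5]),
                 tolerance = 1e-10)
  # an area with no active supervoxel propagates a missing value
  sv0$active[6:10] <- FALSE
  expect_true(is.na(inter_area_correlation(sv0, c(1, 2), list(c(0, 50)))))
  # too few frames is missing as well
  expect_true(is.na(inter_area_correlation(sv0, c(1, 2), list(c(0, 2)))))
})

test_that("fingerprint dimensionality is C(R,2) x S", {
  T <- 3600   # 180 s at 20 Hz
  sch <- stimulus_schedule(60, 60)
  win <- segment_states(sch, 180)
  set.seed(3)
  mk <- function(R) make_sv(lapply(seq_len(R), function(r)
    cbind(rnorm(T), rnorm(T))), pre_duration = 60)
  atl4 <- structure(list(region_names = sprintf("R%d", 1:4)),
                    class = "atlas_labels")
  fp4 <- suppressWarnings(assemble_fingerprint(list(mk(4)), atl4, win))
  expect_equal(nrow(fp4), choose(4, 2) * 3)   # 18
  # a single-state (no stimulus) recording has S = 1
  w1 <- segment_states(stimulus_schedule(120, numeric(0)), 120)
  atl2 <- structure(list(region_names = c("A", "B")), class = "atlas_labels")
  fp1 <- suppressWarnings(assemble_fingerprint(list(mk(2)), atl2, w1))
  expect_equal(nrow(fp1), 1)
})

test_that("missing regions knock out exactly their (R-1) x S metrics", {
  T <- 3600
  sch <- stimulus_schedule(60, 60)
  win <- segment_states(sch, 180)
  set.seed(4)
  sv <- make_sv(lapply(1:4, function(r) cbind(rnorm(T), rnorm(T))),
                pre_duration = 60)
  sv$active[sv$region == 3] <- FALSE
  atl4 <- structure(list(region_names = sprintf("R%d", 1:4)),
                    class = "atlas_labels")
  fp <- suppressWarnings(assemble_fingerprint(list(sv), atl4, win))
  miss <- is.na(fp$value)
  expect_equal(sum(miss), (4 - 1) * 3)
  expect_true(all(fp$i[miss] == 3 | fp$j[miss] == 3))
})

test_that("significant wild-type pairs separate planted from chance connectivity", {
  T <- 2400
  set.seed(5)
  svs <- lapply(1:8, function(l) {
    tr <- latent_traces(T, 3, rho = 0.6, seed = 100 + l)
    tr$r3 <- matrix(rnorm(T * 3), T)   # third region uncorrelated
    make_sv(tr)
  })
  atl <- structure(list(region_names = c("A", "B", "C")),
                   class = "atlas_labels")
  res <- suppressWarnings(
    significant_wt_pairs(svs, atl, resting_window = c(0, 120), seed = 2))
  expect_true(res$significant[res$i == 1 & res$j == 2])
  expect_error(significant_wt_pairs(svs[1:2], atl), ">= 3")
})

test_that("null pairs pass the significance filter at roughly the type-I rate", {
  T <- 1600
  hits <- vapply(1:10, function(s) {
    svs <- lapply(1:6, function(l)
      make_sv(list(a = matrix(rnorm(T * 3), T), b = matrix(rnorm(T * 3), T))))
    atl <- structure(list(region_names = c("A", "B")), class = "atlas_labels")
    res <- suppressWarnings(
      significant_wt_pairs(svs, atl, resting_window = c(0, 80), seed = s))
    res$significant[1]
  }, logical(1))
  expect_lte(sum(hits), 3)   # Binom(10, 0.05): P(>= 4) < 1e-3
})

test_that("divergence maps report direction, magnitude and antisymmetry", {
  T <- 1600
  set.seed(6)
  atl <- structure(list(region_names = c("A", "B")), class = "atlas_labels")
  wt <- lapply(1:6, function(l) make_sv(latent_traces(T, 3, 0.5, seed = 200 + l)))
  lo <- lapply(1:6, function(l) make_sv(latent_traces(T, 3, 0.3, seed = 300 + l)))
  # identical groups: no change anywhere
  d0 <- divergence_map(wt, wt, atl, window = c(0, 80))
  expect_true(all(d0$direction == "no change"))
  expect_true(all(d0$magnitude == 0))
  d1 <- divergence_map(lo, wt, atl, window = c(0, 80))
  expect_equal(d1$direction[1], "decrease")
  expect_lt(abs(d1$magnitude[1] - (0.3 - 0.5)), 0.12)
  d2 <- divergence_map(wt, lo, atl, window = c(0, 80))
  expect_equal(d2$magnitude[1], -d1$magnitude[1])
})
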