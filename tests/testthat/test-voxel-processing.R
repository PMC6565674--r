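test_that("the time-averaged signal equals the sample standard deviation", {
  expect_equal(time_averaged_signal(c(1, 1, 1, 1)), 0)
  expect_equal(time_averaged_signal(c(0, 2)), sqrt(2))
  expect_equal(time_averaged_signal(c(1, 2, 3)), 1)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(sample(2:50, 1), sd = runif(1, 0.1, 10))
    expect_equal(time_averaged_signal(x), sd(x), tolerance = 1e-12)
  }
  expect_error(time_averaged_signal(5), "T >= 2")
})

make_volume <- function(data, rate = 20, pre = NULL) {
  structure(list(data = data, frame_rate = rate,
                 voxel_size = c(40, 10, 10),
                 schedule = list(pre_duration = pre %||% (dim(data)[1] / rate))),
            class = "volume_series")
}

test_that("the time-varying voxel filter removes only clearly quiet voxels", {
  # one slice, 11 voxels: ten with sd 1 traces, one constant
  T <- 40
  set.seed(2)
  base <- sin(seq_len(T)) * sqrt(2)   # sd very close to 1
  data <- array(0, dim = c(T, 1, 1, 11))
  for (v in 1:10) data[, 1, 1, v] <- base / sd(base)
  data[, 1, 1, 11] <- 5
  keep <- select_timevarying_voxels(make_volume(data), window = c(0, 2))
  expect_equal(sum(keep), 10)
  expect_false(keep[1, 1, 11])
  # scale equivariance: rescaling the slice leaves the mask unchanged
  keep2 <- select_timevarying_voxels(make_volume(data * 37), window = c(0, 2))
  expect_identical(keep, keep2)
  # degenerate all-equal slice: everything retained
  flat <- array(rep(base, 4), dim = c(T, 1, 2, 2))
  expect_true(all(select_timevarying_voxels(make_volume(flat),
                                            window = c(0, 2))))
})

test_that("supervoxels recover planted co-varying blocks as a partition", {
  # two disjoint 2x2 blocks in one slice with independent traces
  T <- 300
  set.seed(3)
  tr1 <- rnorm(T); tr2 <- rnorm(T)
  data <- array(rnorm(T * 1 * 2 * 8, sd = 0.01), dim = c(T, 1, 2, 8))
  for (y in 1:2) for (x in 1:2) data[, 1, y, x] <- data[, 1, y, x] + 10 * tr1
  for (y in 1:2) for (x in 6:7) data[, 1, y, x] <- data[, 1, y, x] + 10 * tr2
  mask <- array(FALSE, dim = c(1, 2, 8))
  mask[1, 1:2, c(1:2, 6:7)] <- TRUE
  sv <- build_supervoxels(make_volume(data), mask, seed = 1, k_range = 1:4)
  expect_equal(length(sv$members), 2)
  got <- lapply(sv$members, function(m) sort(paste(m[, 2], m[, 3])))
  expect_setequal(vapply(got, paste, character(1), collapse = ";"),
                  c("1 1;1 2;2 1;2 2", "1 6;1 7;2 6;2 7"))
  # partition contract: union of members equals the retained set, disjoint
  allv <- do.call(rbind, sv$members)
  expect_equal(nrow(allv), sum(mask))
  expect_false(anyDuplicated(paste(allv[, 1], allv[, 2], allv[, 3])) > 0)
})

test_that("an isolated retained voxel becomes a singleton supervoxel", {
  T <- 50
  set.seed(4)
  data <- array(rnorm(T * 1 * 3 * 3), dim = c(T, 1, 3, 3))
  mask <- array(FALSE, dim = c(1, 3, 3)); mask[1, 2, 2] <- TRUE
  sv <- build_supervoxels(make_volume(data), mask, seed = 1)
  expect_equal(length(sv$members), 1)
  expect_equal(sv$traces[, 1], data[, 1, 2, 2])
})

test_that("supervoxel count and traces match planted well-separated neurons", {
  # 6 neurons of 2x2 voxels with distinct sparse-transient traces
  T <- 400; rate <- 20
  set.seed(5)
  kern <- exp(-(0:59) / 30)
  mk_trace <- function() {
    s <- rpois(T, 0.01)
    as.numeric(stats::filter(c(rep(0, 60), s), kern, sides = 1))[-(1:60)]
  }
  data <- array(rnorm(T * 2 * 5 * 8, 100, 0.5), dim = c(T, 2, 5, 8))
  truth_traces <- matrix(0, T, 6)
  n <- 0
  for (z in 1:2) for (x0 in c(1, 4, 7)) {
    n <- n + 1
    truth_traces[, n] <- mk_trace()
    for (y in 1:2) for (x in x0:(x0 + 1))
      data[, z, y, x] <- data[, z, y, x] + 30 * truth_traces[, n]
  }
  mask <- array(FALSE, dim = c(2, 5, 8)); mask[1:2, 1:2, c(1:2, 4:5, 7:8)] <- TRUE
  sv <- build_supervoxels(make_volume(data, rate), mask, seed = 2, k_range = 1:4)
  expect_gte(length(sv$members), 5)   # within 20% of 6 planted
  expect_lte(length(sv$members), 7)
  # mean supervoxel-to-truth correlation
  best <- vapply(seq_along(sv$members), function(k)
    max(cor(sv$traces[, k], truth_traces)), numeric(1))
  expect_gte(mean(best), 0.9)
})

test_that("dF/F matches hand arithmetic and is scale invariant", {
  expect_equal(compute_dff(rep(5, 500), rate = 20), rep(0, 500))
  tr <- rep(10, 800); tr[400] <- 20
  d <- compute_dff(tr, rate = 20)
  f_at_peak <- (399 * 10 + 20) / 400
  expect_equal(d[400], (20 - f_at_peak) / f_at_peak, tolerance = 1e-12)
  set.seed(6)
  x <- runif(900, 50, 150)
  expect_equal(compute_dff(x, 20), compute_dff(7.3 * x, 20), tolerance = 1e-12)
  expect_error(compute_dff(rep(1, 100), rate = 20), "longer")
})

test_that("active-supervoxel detection flags transients and is monotone in c", {
  T <- 2000; rate <- 20
  set.seed(7)
  kern <- exp(-(0:59) / 30)
  quiet <- replicate(6, 100 + rnorm(T, sd = 0.5))
  burst <- replicate(6, {
    s <- rpois(T, 0.005)
    100 + 10 * rnorm(T, sd = 0.05) +
      50 * as.numeric(stats::filter(c(rep(0, 60), s), kern, sides = 1))[-(1:60)]
  })
  sv <- make_sv(list(r1 = quiet / 100 - 1, r2 = burst / 100 - 1), rate = rate)
  sv$traces <- cbind(quiet, burst)
  sv$dff <- NULL
  out <- detect_active_supervoxels(sv)
  expect_true(all(out$active[7:12]))     # 10x-noise transients detected
  expect_false(any(out$active[1:6]))     # pure noise stays inactive
  # flat dF/F is never active
  svf <- make_sv(list(r1 = matrix(0, 600, 2)))
  svf$dff <- NULL; svf$traces <- matrix(100, 600, 2)
  expect_false(any(detect_active_supervoxels(svf)$active))
  # monotone nonincreasing active fraction in c
  fr <- vapply(c(2, 4, 6, 10), function(cc)
    mean(detect_active_supervoxels(sv, c = cc)$active), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("the voxel pipeline is invariant under global intensity rescaling", {
  atl <- tiny_atlas()
  sch <- stimulus_schedule(30, numeric(0))
  tru <- ground_truth(atl, plant_connectivity(4), "wild_type")
  rec <- simulate_condition_recording(atl, tru, sch,
                                      imaging = list(duration = 30,
                                                     n_neurons_per_region = 1),
                                      seed = 9)
  v1 <- rec$volume
  v2 <- v1; v2$data <- v1$data * 4.2
  m1 <- select_timevarying_voxels(v1); m2 <- select_timevarying_voxels(v2)
  expect_identical(m1, m2)
  s1 <- build_supervoxels(v1, m1, seed = 3, k_range = 1:3)
  s2 <- build_supervoxels(v2, m2, seed = 3, k_range = 1:3)
  expect_identical(s1$members, s2$members)
  expect_equal(apply(s1$traces, 2, compute_dff, rate = v1$frame_rate),
               apply(s2$traces, 2, compute_dff, rate = v1$frame_rate),
               tolerance = 1e-10)
})
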