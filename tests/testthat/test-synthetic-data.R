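test_that("atlas generation is a deterministic partition with canonical names", {
  atl <- generate_atlas(c(4, 16, 16), n_regions = 11, seed = 1)
  counts <- tabulate(atl$labels[atl$labels > 0], nbins = 11)
  expect_length(atl$region_names, 11)
  expect_identical(atl$region_names,
                   c("Ce", "HBl", "HBr", "OBl", "OBr", "OTl", "OTr",
                     "Pa", "SPa", "Ha", "Th"))
  expect_true(all(counts >= 1))
  expect_identical(atl$labels,
                   generate_atlas(c(4, 16, 16), n_regions = 11, seed = 1)$labels)
  # different seed, different layout
  expect_false(identical(atl$labels,
                         generate_atlas(c(4, 16, 16), 11, seed = 2)$labels))
  expect_error(generate_atlas(c(1, 2, 2), n_regions = 11),
               "too small")
})

test_that("stimulus schedules validate their invariants", {
  s <- stimulus_schedule(600, c(600, 720, 840, 960))
  expect_equal(s$pulse_pattern$pulse_len, 0.5)
  expect_equal(s$pulse_pattern$n_pulses, 2)
  expect_error(stimulus_schedule(600, c(700, 650)), "increasing")
  expect_error(stimulus_schedule(600, c(500)), "pre_duration")
})

test_that("recordings are bit-identical under a fixed seed and confine neurons to their region", {
  atl <- tiny_atlas()
  sch <- stimulus_schedule(pre_duration = 30, stimulus_times = numeric(0))
  rho <- plant_connectivity(4)
  tru <- ground_truth(atl, rho, "wild_type")
  img <- list(duration = 30, n_neurons_per_region = 2)
  a <- simulate_condition_recording(atl, tru, sch, imaging = img, seed = 7)
  b <- simulate_condition_recording(atl, tru, sch, imaging = img, seed = 7)
  expect_identical(a$volume$data, b$volume$data)
  # label conservation: every neuron voxel carries its assigned region label
  for (n in seq_along(a$truth$neuron_voxels)) {
    vx <- a$truth$neuron_voxels[[n]]
    expect_true(all(atl$labels[vx] == a$truth$neuron_positions$region[n]))
  }
})

test_that("planted correlations are recovered from noiseless neuron traces", {
  atl <- tiny_atlas()
  sch <- stimulus_schedule(pre_duration = 300, stimulus_times = numeric(0))
  for (rho_target in c(0, 0.3, 0.6, 0.9)) {
    rr <- replicate(6, {
      rho <- plant_connectivity(4, data.frame(i = 1, j = 2,
                                              state = c("pre", "early", "late"),
                                              rho = rho_target))
      tru <- ground_truth(atl, rho, "wild_type")
      rec <- simulate_condition_recording(
        atl, tru, sch, imaging = list(duration = 300, n_neurons_per_region = 2),
        seed = sample.int(1e6, 1))
      tr <- rec$truth$neuron_traces
      reg <- rec$truth$neuron_positions$region
      mean(cor(tr[, reg == 1], tr[, reg == 2]))
    })
    expect_lt(abs(mean(rr) - rho_target), 0.05)
  }
})

test_that("unreachable planted connectivity fails with the attainable bound", {
  atl <- tiny_atlas()
  rho <- plant_connectivity(4, data.frame(
    i = c(1, 1), j = c(2, 3), state = "pre", rho = c(0.7, 0.7)))
  tru <- ground_truth(atl, rho, "wild_type")
  expect_error(
    simulate_condition_recording(atl, tru,
                                 stimulus_schedule(10, numeric(0)),
                                 imaging = list(duration = 10), seed = 1),
    "unreachable")
})

test_that("mutant recordings show stimulus-locked bursts", {
  atl <- tiny_atlas()
  sch <- stimulus_schedule(pre_duration = 30, stimulus_times = c(30, 60, 90, 120))
  rho <- plant_connectivity(4)
  tru <- ground_truth(atl, rho, "mutant")
  rec <- simulate_condition_recording(
    atl, tru, sch, imaging = list(duration = 150, n_neurons_per_region = 2),
    seed = 3)
  tr <- rowMeans(rec$truth$neuron_traces)
  rate <- rec$volume$frame_rate
  pre <- mean(tr[1:(30 * rate)])
  post <- mean(unlist(lapply(sch$stimulus_times, function(tk)
    tr[(tk * rate + 1):((tk + 5) * rate)])))
  expect_gt(post, pre)
})

test_that("drug-effect perturbations are clipped into [0, 1]", {
  atl <- tiny_atlas()
  rho <- plant_connectivity(4, data.frame(i = 1, j = 2, state = "pre", rho = 0.9))
  pert <- array(0, dim = c(4, 4, 3), dimnames = dimnames(rho))
  pert[1, 2, "pre"] <- pert[2, 1, "pre"] <- 0.5
  tru <- ground_truth(atl, rho, "mutant", drug_effect = pert)
  expect_equal(unname(tru$planted_connectivity[1, 2, "pre"]), 1)
  expect_equal(unname(tru$planted_connectivity[1, 2, "early"]), 0)
})

test_that("LFP simulation honours fixed and absent events", {
  t0 <- simulate_lfp(60, 100, event_rate = 0, seed = 1)
  expect_equal(nrow(t0$true_events), 0)
  t5 <- simulate_lfp(120, 100, seed = 1, event_times = c(10, 30, 50, 70, 90))
  expect_equal(nrow(t5$true_events), 5)
  expect_identical(simulate_lfp(30, 100, seed = 4)$samples,
                   simulate_lfp(30, 100, seed = 4)$samples)
})

test_that("behavior simulation is deterministic and fails when the larva leaves the frame", {
  s1 <- simulate_behavior(1, 20, motion_program = list(velocity = 0), seed = 2)
  s2 <- simulate_behavior(1, 20, motion_program = list(velocity = 0), seed = 2)
  expect_identical(s1$frames, s2$frames)
  # stationary program: ground-truth forward displacement is zero
  expect_equal(diff(range(s1$truth$x1)), 0)
  expect_error(
    simulate_behavior(10, 20, motion_program = list(velocity = 200),
                      frame_size = c(100, 100), seed = 1),
    "leaves the frame")
})
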