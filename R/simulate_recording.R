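# Synthetic atlas-registered calcium recordings with planted, recoverable
# inter-area correlation structure.
#
# Activity model: each neuron's spike train is a Poisson mixture of shared
# per-area-pair event streams and private events. With shared rate
# rho * lambda and private rate (1 - sum(rho)) * lambda, every neuron fires
# at total rate lambda and the cross-area spike-count correlation for a pair
# equals its planted rho exactly; convolution with one calcium kernel
# preserves those correlations (frame counts are independent across frames).

STATE_NAMES <- c("pre", "early", "late")

#' Plant an inter-area connectivity structure
#'
#' Builds the symmetric `(region x region x state)` array of target Pearson
#' correlations used by [simulate_condition_recording()].
#'
#' @param n_regions number of atlas regions.
#' @param entries data.frame with columns `i`, `j`, `state`
#'   (one of `"pre"`, `"early"`, `"late"`) and `rho` in `[0, 1]`; or `NULL`
#'   for an all-zero structure.
#' @return numeric array `(n_regions, n_regions, 3)`, symmetric in the first
#'   two dimensions with zero diagonal.
#' @export
plant_connectivity <- function(n_regions, entries = NULL) {
  rho <- array(0, dim = c(n_regions, n_regions, length(STATE_NAMES)),
               dimnames = list(NULL, NULL, STATE_NAMES))
  if (!is.null(entries)) {
    stopifnot(all(c("i", "j", "state", "rho") %in% names(entries)))
    for (r in seq_len(nrow(entries))) {
      i <- entries$i[r]; j <- entries$j[r]; s <- as.character(entries$state[r])
      v <- entries$rho[r]
      if (i == j) stop_fc("connectivity entries need i != j")
      if (v < 0 || v > 1) stop_fc("rho must lie in [0, 1], got %g", v)
      rho[i, j, s] <- v; rho[j, i, s] <- v
    }
  }
  rho
}

#' Ground truth for one synthetic condition
#'
#' @param atlas an `atlas_labels` object.
#' @param connectivity planted connectivity array from [plant_connectivity()].
#' @param condition `"wild_type"` or `"mutant"`; mutants additionally show
#'   stimulus-locked global bursts.
#' @param drug_effect optional additive perturbation, same shape as
#'   `connectivity`; the effective structure is `clip(rho + effect, 0, 1)`.
#' @param seizure_times optional numeric vector of spontaneous event times (s).
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(atlas, connectivity, condition = c("wild_type", "mutant"),
                         drug_effect = NULL, seizure_times = numeric(0)) {
  condition <- match.arg(condition)
  R <- length(atlas$region_names)
  stopifnot(all(dim(connectivity) == c(R, R, length(STATE_NAMES))))
  eff <- connectivity
  if (!is.null(drug_effect)) {
    stopifnot(all(dim(drug_effect) == dim(connectivity)))
    eff <- pmin(pmax(connectivity + drug_effect, 0), 1)
    for (s in seq_len(dim(eff)[3])) diag(eff[, , s]) <- 0
  }
  structure(list(planted_connectivity = eff, raw_connectivity = connectivity,
                 drug_effect = drug_effect, condition = condition,
                 seizure_times = seizure_times, neuron_positions = NULL),
            class = "ground_truth")
}

# per-frame state index used during generation: pre before the first stimulus,
# early for [t_k, t_k + 60), late from t_k + 60 until the next stimulus.
generation_states <- function(times, schedule) {
  st <- rep("pre", length(times))
  for (tk in schedule$stimulus_times) {
    st[times >= tk & times < tk + 60] <- "early"
    st[times >= tk + 60] <- "late"   # later stimuli (larger tk) overwrite
  }
  st
}

default_imaging <- function() {
  list(rate = 20, noise_sd = 2, n_neurons_per_region = 5,
       baseline = 100, signal_amp = 20, tau_decay = 1.5,
       spike_rate = 0.15, neuron_extent = c(1, 2, 2),
       burst_gain = 5, burst_decay = 5, duration = NULL)
}

place_neurons <- function(atlas, n_per_region, extent, seed) {
  set.seed(substream_seed(seed, "neurons"))
  lab <- atlas$labels
  dims <- dim(lab)
  out <- list()
  for (r in seq_along(atlas$region_names)) {
    vox <- which(lab == r, arr.ind = TRUE)
    ord <- sample.int(nrow(vox))
    taken <- character(0)
    placed <- 0L
    for (k in ord) {
      z0 <- vox[k, 1]; y0 <- vox[k, 2]; x0 <- vox[k, 3]
      zz <- z0:(z0 + extent[1] - 1); yy <- y0:(y0 + extent[2] - 1)
      xx <- x0:(x0 + extent[3] - 1)
      if (max(zz) > dims[1] || max(yy) > dims[2] || max(xx) > dims[3]) next
      block <- as.matrix(expand.grid(z = zz, y = yy, x = xx))
      if (any(lab[block] != r)) next
      keys <- paste(block[, 1], block[, 2], block[, 3])
      if (any(keys %in% taken)) next
      taken <- c(taken, keys)
      placed <- placed + 1L
      out[[length(out) + 1L]] <- list(region = r, voxels = block)
      if (placed == n_per_region) break
    }
    if (placed < n_per_region)
      stop_fc("could only place %d of %d neurons in region %s; enlarge the atlas",
              placed, n_per_region, atlas$region_names[r])
  }
  out
}

#' Simulate an atlas-registered calcium recording for one larva
#'
#' Renders region-structured correlated activity into a 4D fluorescence
#' volume. Each neuron's spike train mixes shared per-area-pair Poisson
#' event streams (rate `rho * spike_rate`) with private events (rate
#' `(1 - sum(rho)) * spike_rate`), so cross-area spike correlations equal
#' the planted `rho` exactly; mixing rates switch at the stimulus-defined
#' state boundaries. Spikes are convolved with a single-exponential calcium
#' kernel (1-frame rise, decay `tau_decay`) and rendered as small voxel
#' blocks plus additive Gaussian imaging noise. Mutants receive a
#' stimulus-locked multiplicative rate surge (`burst_gain`-fold, decaying
#' over `burst_decay` seconds) on all neurons.
#'
#' @param atlas `atlas_labels`.
#' @param truth `ground_truth`.
#' @param schedule `stimulus_schedule`.
#' @param imaging list overriding any of: `rate` (Hz), `noise_sd`,
#'   `n_neurons_per_region`, `baseline`, `signal_amp`, `tau_decay` (s),
#'   `spike_rate` (Hz, spontaneous events per neuron), `neuron_extent`
#'   `(z, y, x)`, `burst_gain`, `burst_decay`, `duration` (s, default last
#'   stimulus + 120 s).
#' @param seed integer seed; output is deterministic given all inputs.
#' @return list with `volume` (a `volume_series`) and `truth` (the input
#'   `ground_truth` augmented with `neuron_positions`, per-neuron noiseless
#'   `neuron_traces`, and `frame_states`).
#' @export
simulate_condition_recording <- function(atlas, truth, schedule,
                                         imaging = list(), seed = 1) {
  img <- utils::modifyList(default_imaging(), imaging)
  rate <- img$rate
  R <- length(atlas$region_names)
  rho <- truth$planted_connectivity

  # feasibility: per region and state the latent loadings must not exceed
  # unit variance
  for (s in STATE_NAMES) {
    load <- rowSums(rho[, , s])
    if (any(load > 1 + 1e-12))
      stop_fc(paste0("planted connectivity unreachable in state '%s': region %d ",
                     "has total pair loading %.3f > 1 (attainable bound: scale ",
                     "rows to sum <= 1)"), s, which.max(load), max(load))
  }

  dur <- img$duration %||% (if (length(schedule$stimulus_times))
    max(schedule$stimulus_times) + 120 else schedule$pre_duration)
  T <- round(dur * rate)
  times <- (seq_len(T) - 1) / rate
  st <- generation_states(times, schedule)

  neurons <- place_neurons(atlas, img$n_neurons_per_region,
                           img$neuron_extent, seed)
  n_neu <- length(neurons)
  region_of <- vapply(neurons, `[[`, integer(1), "region")

  pairs <- area_pairs(R)
  active_pair <- vapply(seq_len(nrow(pairs)), function(p)
    any(rho[pairs$i[p], pairs$j[p], ] > 0), logical(1))
  pairs <- pairs[active_pair, , drop = FALSE]
  n_pairs <- nrow(pairs)

  # per-frame shared/private Poisson rates (events per frame), with the
  # mutant stimulus-locked multiplicative rate surge applied to all streams
  lam <- img$spike_rate / rate
  surge <- rep(1, T)
  if (truth$condition == "mutant" && length(schedule$stimulus_times)) {
    for (tk in schedule$stimulus_times) {
      idx <- times >= tk
      surge[idx] <- surge[idx] +
        (img$burst_gain - 1) * exp(-(times[idx] - tk) / img$burst_decay)
    }
  }

  rho_t <- matrix(0, T, max(1L, n_pairs))   # per-frame pair mixing fractions
  priv_t <- matrix(1, T, R)                 # per-frame private fraction
  for (s in STATE_NAMES) {
    fr <- which(st == s)
    if (!length(fr)) next
    if (n_pairs) for (p in seq_len(n_pairs))
      rho_t[fr, p] <- rho[pairs$i[p], pairs$j[p], s]
    for (r in seq_len(R)) priv_t[fr, r] <- 1 - rowSums(rho[r, , s, drop = FALSE])
  }

  set.seed(substream_seed(seed, "activity"))
  shared <- if (n_pairs)
    matrix(stats::rpois(T * n_pairs, lam * surge * rho_t), T) else
    matrix(0, T, 0)
  spikes <- matrix(stats::rpois(T * n_neu,
                                lam * surge * priv_t[, region_of]), T)
  if (n_pairs) for (p in seq_len(n_pairs)) {
    on <- region_of == pairs$i[p] | region_of == pairs$j[p]
    spikes[, on] <- spikes[, on] + shared[, p]
  }

  # calcium kernel: 1-frame rise, exponential decay, unit event amplitude
  K <- max(2L, ceiling(5 * img$tau_decay * rate))
  kern <- exp(-(0:(K - 1)) / (img$tau_decay * rate))
  signal <- apply(spikes, 2L, function(z) {
    as.numeric(stats::filter(c(rep(0, K), z), kern,
                             method = "convolution", sides = 1))[-seq_len(K)]
  })

  set.seed(substream_seed(seed, "render"))
  dims <- dim(atlas$labels)
  vol <- array(stats::rnorm(T * prod(dims), mean = img$baseline,
                            sd = img$noise_sd),
               dim = c(T, dims))
  for (n in seq_len(n_neu)) {
    vx <- neurons[[n]]$voxels
    for (v in seq_len(nrow(vx)))
      vol[, vx[v, 1], vx[v, 2], vx[v, 3]] <-
        vol[, vx[v, 1], vx[v, 2], vx[v, 3]] + img$signal_amp * signal[, n]
  }
  vol[vol < 1e-3] <- 1e-3   # intensity floor enforced at load

  truth$neuron_positions <- data.frame(
    neuron = seq_len(n_neu), region = region_of,
    z = vapply(neurons, function(n) n$voxels[1, 1], numeric(1)),
    y = vapply(neurons, function(n) n$voxels[1, 2], numeric(1)),
    x = vapply(neurons, function(n) n$voxels[1, 3], numeric(1)))
  truth$neuron_voxels <- lapply(neurons, `[[`, "voxels")
  truth$neuron_traces <- signal
  truth$frame_states <- st

  vs <- structure(list(data = vol, frame_rate = rate,
                       voxel_size = atlas$voxel_size, schedule = schedule),
                  class = "volume_series")
  list(volume = vs, truth = truth)
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d frames @ %g Hz, %s voxels\n",
              d[1], x$frame_rate, paste(d[-1], collapse = "x")))
  invisible(x)
}
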