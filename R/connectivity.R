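# Inter-area correlation fingerprints: state segmentation, mean absolute
# Pearson correlation per area pair, group fingerprints, significance and
# divergence maps.

#' Segment a recording into the three activity states
#'
#' Pre-stimulus: `[0, first stimulus)`. For each stimulus at `t_k`:
#' early post-stimulus `[t_k + 10, t_k + 60)` (the first 10 s are dropped to
#' improve stationarity) and late post-stimulus `[t_k + 60, t_k + 120)`.
#' All intervals are half-open, in seconds. Trailing windows extending past
#' the recording are truncated with a message.
#'
#' @param schedule a `stimulus_schedule`.
#' @param duration recording length in seconds.
#' @return object of class `state_windows`: list with `pre` (one interval),
#'   `early` and `late` (lists of intervals).
#' @examples
#' segment_states(stimulus_schedule(600, c(600, 720, 840, 960)), 1080)
#' @export
segment_states <- function(schedule, duration) {
  stim <- schedule$stimulus_times
  if (length(stim) > 1 && any(diff(stim) < 120))
    stop_fc("stimuli closer than 120 s produce overlapping state windows")
  pre_end <- if (length(stim)) stim[1] else duration
  clip <- function(iv) {
    if (iv[1] >= duration) return(NULL)
    if (iv[2] > duration) {
      message(sprintf("state window [%g, %g) truncated at %g s",
                      iv[1], iv[2], duration))
      iv[2] <- duration
    }
    iv
  }
  early <- Filter(Negate(is.null), lapply(stim, function(tk)
    clip(c(tk + 10, tk + 60))))
  late <- Filter(Negate(is.null), lapply(stim, function(tk)
    clip(c(tk + 60, tk + 120))))
  structure(list(pre = c(0, min(pre_end, duration)), early = early,
                 late = late),
            class = "state_windows")
}

#' Mean absolute inter-area correlation
#'
#' Pearson correlations between every pair of active supervoxel dF/F traces
#' drawn one from each area, restricted to the concatenated windows; returns
#' the mean of their absolute values. `NA` (a missing metric) when either
#' area has no active supervoxel or the windows hold fewer than `min_frames`
#' frames.
#'
#' @param sv a `supervoxel_set` with `dff` and `active` filled in (see
#'   [detect_active_supervoxels()]).
#' @param pair integer `c(i, j)` region ids.
#' @param windows list of half-open intervals (s), or a single interval.
#' @param min_frames minimum pooled frame count (default 100).
#' @param active_only use only active supervoxels (default TRUE).
#' @return scalar in `[0, 1]`, or `NA_real_`.
#' @export
inter_area_correlation <- function(sv, pair, windows, min_frames = 100,
                                   active_only = TRUE) {
  if (is.numeric(windows)) windows <- list(windows)
  fr <- frames_in_windows(windows, sv$frame_rate, nrow(sv$traces))
  if (length(fr) < min_frames) return(NA_real_)
  use <- if (active_only) which(sv$active %in% TRUE) else
    seq_along(sv$members)
  a <- use[sv$region[use] %in% pair[1]]
  b <- use[sv$region[use] %in% pair[2]]
  if (!length(a) || !length(b)) return(NA_real_)
  cc <- suppressWarnings(
    stats::cor(sv$dff[fr, a, drop = FALSE], sv$dff[fr, b, drop = FALSE]))
  mean(abs(cc), na.rm = TRUE)
}

# states with at least one interval in a state_windows object
states_present <- function(windows) {
  c("pre", if (length(windows$early)) "early",
    if (length(windows$late)) "late")
}

# all (pair, state) metrics for one larva -> data.frame
larva_metrics <- function(sv, n_regions, windows, min_frames = 100,
                          active_only = TRUE) {
  pr <- area_pairs(n_regions)
  out <- do.call(rbind, lapply(states_present(windows), function(s) {
    w <- windows[[s]]
    if (s == "pre") w <- list(w)
    data.frame(i = pr$i, j = pr$j, state = s,
               value = vapply(seq_len(nrow(pr)), function(p)
                 inter_area_correlation(sv, c(pr$i[p], pr$j[p]), w,
                                        min_frames, active_only),
                 numeric(1)))
  }))
  out$state <- factor(out$state, levels = states_present(windows))
  out
}

#' Assemble a group connectivity fingerprint
#'
#' Per-larva (area pair x state) mean absolute correlations averaged over the
#' group, missing values excluded per metric. An 11-region atlas with the
#' three-state protocol yields the canonical 165-metric fingerprint
#' (55 pairs x 3 states).
#'
#' @param sv_list list of `supervoxel_set`s, one per larva, with activity
#'   flags set.
#' @param atlas `atlas_labels`.
#' @param windows `state_windows` from [segment_states()].
#' @param group_label optional condition label stored on the result.
#' @param min_larvae warn when fewer larvae than this contribute (default 5).
#' @param min_frames,active_only passed to [inter_area_correlation()].
#' @return object of class `fc_fingerprint`: data.frame with columns
#'   `i`, `j`, `state`, `value`, `n_larvae`, plus attributes `region_names`
#'   and `per_larva` (metric x larva matrix).
#' @export
assemble_fingerprint <- function(sv_list, atlas, windows, group_label = NULL,
                                 min_larvae = 5, min_frames = 100,
                                 active_only = TRUE) {
  if (!length(sv_list)) stop_fc("assemble_fingerprint needs at least one larva")
  if (length(sv_list) < min_larvae)
    warning(sprintf("fingerprint averaged over only %d larvae (expected >= %d)",
                    length(sv_list), min_larvae))
  R <- length(atlas$region_names)
  per <- lapply(sv_list, larva_metrics, n_regions = R, windows = windows,
                min_frames = min_frames, active_only = active_only)
  vals <- vapply(per, `[[`, numeric(nrow(per[[1]])), "value")
  vals <- matrix(vals, nrow = nrow(per[[1]]))
  out <- per[[1]][, c("i", "j", "state")]
  out$value <- rowMeans(vals, na.rm = TRUE)
  out$value[is.nan(out$value)] <- NA_real_
  out$n_larvae <- rowSums(!is.na(vals))
  if (any(out$n_larvae == 0L))
    message(sprintf("%d fingerprint metrics missing for every larva",
                    sum(out$n_larvae == 0L)))
  structure(out, class = c("fc_fingerprint", "data.frame"),
            region_names = atlas$region_names, per_larva = vals,
            group_label = group_label)
}

#' Fingerprint metric ids ("Pa–Th|pre"-style)
#' @param fp an `fc_fingerprint`.
#' @return character vector, one id per metric.
#' @export
metric_ids <- function(fp) {
  nm <- attr(fp, "region_names")
  paste0(pair_key(fp$i, fp$j, nm), "|", as.character(fp$state))
}

#' Significantly connected area pairs in wild-type larvae
#'
#' For each area pair, per-larva resting-state mean absolute correlations are
#' compared against a chance-level sample obtained by circularly
#' time-shifting each larva's second-area supervoxel traces (which preserves
#' autocorrelation but destroys genuine inter-area synchrony), using an
#' unpaired two-tailed t-test. Approximate normality of both samples is
#' checked with the Jarque-Bera test, with a warning on rejection.
#'
#' @param sv_list list of wild-type `supervoxel_set`s (>= 3) with activity
#'   flags set.
#' @param atlas `atlas_labels`.
#' @param resting_window half-open interval (s); defaults to the pre-stimulus
#'   period.
#' @param alpha significance level (default 0.05).
#' @param seed seed for the circular shifts.
#' @return data.frame of pairs with columns `i`, `j`, `observed`,
#'   `chance`, `p`, `significant`.
#' @export
significant_wt_pairs <- function(sv_list, atlas, resting_window = NULL,
                                 alpha = 0.05, seed = 1) {
  if (length(sv_list) < 3L)
    stop_fc("significant_wt_pairs needs >= 3 wild-type larvae, got %d",
            length(sv_list))
  set.seed(substream_seed(seed, "wt-pairs"))
  R <- length(atlas$region_names)
  pr <- area_pairs(R)
  if (is.null(resting_window))
    resting_window <- c(0, sv_list[[1]]$schedule$pre_duration)

  shifted <- lapply(sv_list, function(sv) {
    T <- nrow(sv$dff)
    off <- sample.int(T - 1L, R, replace = TRUE)  # one offset per region
    sh <- sv
    for (k in seq_along(sv$members)) {
      r <- sv$region[k]
      if (is.na(r)) next
      o <- off[r]
      sh$dff[, k] <- sv$dff[c((o + 1L):T, 1L:o), k]
    }
    sh
  })

  res <- lapply(seq_len(nrow(pr)), function(p) {
    pij <- c(pr$i[p], pr$j[p])
    obs <- vapply(sv_list, inter_area_correlation, numeric(1),
                  pair = pij, windows = list(resting_window))
    # chance level: correlate area i traces with circularly shifted area j
    ch <- vapply(seq_along(sv_list), function(l) {
      sv <- sv_list[[l]]; sh <- shifted[[l]]
      mix <- sv
      bidx <- which(sv$region %in% pij[2])
      mix$dff[, bidx] <- sh$dff[, bidx]
      inter_area_correlation(mix, pij, list(resting_window))
    }, numeric(1))
    obs <- obs[is.finite(obs)]; ch <- ch[is.finite(ch)]
    if (length(obs) < 2L || length(ch) < 2L ||
        stats::sd(obs) == 0 || stats::sd(ch) == 0) {
      message(sprintf("pair %d-%d skipped (degenerate samples)", pij[1], pij[2]))
      return(data.frame(i = pij[1], j = pij[2], observed = mean(obs),
                        chance = mean(ch), p = NA_real_, significant = FALSE))
    }
    for (smp in list(obs, ch)) if (length(smp) >= 4L &&
                                   jarque_bera(smp)$p.value < alpha)
      warning(sprintf("pair %d-%d: Jarque-Bera rejects normality", pij[1], pij[2]))
    p <- stats::t.test(obs, ch, var.equal = FALSE)$p.value
    data.frame(i = pij[1], j = pij[2], observed = mean(obs),
               chance = mean(ch), p = p, significant = p < alpha)
  })
  do.call(rbind, res)
}

#' Connectivity divergence map between a treated group and wild-types
#'
#' Per area pair: `magnitude = mean(treated) - mean(wild-type)` of the
#' per-larva resting mean absolute correlations, direction its sign, and an
#' unpaired two-tailed t-test p-value; pairs with `p >= alpha` are reported
#' as no change.
#'
#' @param treated,wt lists of `supervoxel_set`s with activity flags set.
#' @param pairs data.frame with columns `i`, `j` (e.g. the significant
#'   wild-type pairs); defaults to all pairs.
#' @param atlas `atlas_labels`.
#' @param window half-open interval (s); defaults to the pre-stimulus state.
#' @param alpha significance level.
#' @return data.frame with columns `i`, `j`, `magnitude`, `direction`
#'   (`"increase"`, `"decrease"`, `"no change"`), `p`.
#' @export
divergence_map <- function(treated, wt, atlas, pairs = NULL, window = NULL,
                           alpha = 0.05) {
  if (!length(treated) || !length(wt))
    stop_fc("both groups must be non-empty")
  if (is.null(pairs)) pairs <- area_pairs(length(atlas$region_names))
  if (is.null(window)) window <- c(0, treated[[1]]$schedule$pre_duration)
  res <- lapply(seq_len(nrow(pairs)), function(p) {
    pij <- c(pairs$i[p], pairs$j[p])
    a <- vapply(treated, inter_area_correlation, numeric(1), pair = pij,
                windows = list(window))
    b <- vapply(wt, inter_area_correlation, numeric(1), pair = pij,
                windows = list(window))
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    mag <- mean(a) - mean(b)
    pv <- if (length(a) > 1 && length(b) > 1 &&
              (stats::sd(a) > 0 || stats::sd(b) > 0))
      tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
               error = function(e) 1) else 1
    dir <- if (pv >= alpha || !is.finite(mag) || mag == 0) "no change"
      else if (mag > 0) "increase" else "decrease"
    data.frame(i = pij[1], j = pij[2], magnitude = mag, direction = dir, p = pv)
  })
  do.call(rbind, res)
}
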