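# Local field potential analysis: synthetic seizure-bearing traces,
# empirical mode decomposition, higher-order-moment features, seizure
# classification and the efficacy score.

#' Simulate a local field potential trace with seizure bursts
#'
#' Background is 1/f-like (AR(1), phi = 0.98) noise of unit standard
#' deviation; seizures are multi-peak bursts — an 8-Hz oscillation with
#' superimposed sharp spikes under an asymmetric envelope — of amplitude
#' `snr` times the background, placed at Poisson times (or at `event_times`
#' when given).
#'
#' @param duration trace length in seconds.
#' @param rate sampling rate in Hz (default 100).
#' @param event_rate expected seizures per minute (ignored when
#'   `event_times` given).
#' @param snr burst amplitude relative to background SD (default 6).
#' @param seed integer seed.
#' @param event_times optional fixed burst onset times (s).
#' @param event_duration burst length in seconds (default 3).
#' @return object of class `lfp_trace`: list with `samples` (mV), `rate`,
#'   `true_events` (data.frame start/end in seconds).
#' @export
simulate_lfp <- function(duration, rate = 100, event_rate = 0.5, snr = 6,
                         seed = 1, event_times = NULL, event_duration = 3) {
  stopifnot(duration > 0, rate > 0)
  set.seed(substream_seed(seed, "lfp"))
  T <- round(duration * rate)
  bg <- as.numeric(stats::filter(stats::rnorm(T + 500), 0.98,
                                 method = "recursive"))[-seq_len(500)]
  bg <- bg / stats::sd(bg)

  if (is.null(event_times)) {
    n_ev <- stats::rpois(1, event_rate * duration / 60)
    event_times <- sort(stats::runif(n_ev, 0, max(0, duration - event_duration)))
    # enforce non-overlap
    if (length(event_times) > 1) {
      keep <- c(TRUE, diff(event_times) >= event_duration + 1)
      event_times <- event_times[keep]
    }
  }
  x <- bg
  ev <- data.frame(start = numeric(0), end = numeric(0))
  for (t0 in event_times) {
    i0 <- floor(t0 * rate) + 1L
    len <- min(round(event_duration * rate), T - i0 + 1L)
    if (len < rate / 2) next
    tt <- (seq_len(len) - 1) / rate
    # rapid onset, sustained high amplitude, brief offset ramp
    env <- pmin(tt / 0.2, 1) *
      pmin(1, pmax(0, (event_duration - tt) / 0.5))
    osc <- sin(2 * pi * 8 * tt + stats::runif(1, 0, 2 * pi))
    spikes <- numeric(len)
    sp_at <- seq(1, len, by = round(rate / 8))
    spikes[sp_at] <- stats::runif(length(sp_at), 0.5, 1.5)
    spikes <- as.numeric(stats::filter(spikes, exp(-(0:round(rate / 20)) / (rate / 40)),
                                       method = "convolution", sides = 1))
    spikes[is.na(spikes)] <- 0
    burst <- snr * env * (osc + 2 * spikes)
    x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] + burst
    ev <- rbind(ev, data.frame(start = t0, end = t0 + len / rate))
  }
  structure(list(samples = x, rate = rate, true_events = ev),
            class = "lfp_trace")
}

# ---- empirical mode decomposition -----------------------------------------

local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  s <- sign(d)
  # flats inherit the previous slope so plateau edges count once
  for (i in which(s == 0)) s[i] <- if (i > 1) s[i - 1] else 1
  idx <- which(diff(s) != 0) + 1L
  list(max = idx[s[idx - 1L] > 0], min = idx[s[idx - 1L] < 0])
}

spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  # mirror up to two boundary extrema on each side
  l <- seq_len(min(2L, k)); r <- seq.int(max(1L, k - 1L), k)
  xi <- c(2 - rev(idx[l]), idx, 2 * n - rev(idx[r]))
  yi <- c(rev(val[l]), val, rev(val[r]))
  keep <- !duplicated(xi)
  stats::spline(xi[keep], yi[keep], xout = seq_len(n), method = "fmm")$y
}

sift_imf <- function(h, tol, max_sift) {
  n <- length(h)
  for (i in seq_len(max_sift)) {
    e <- local_extrema(h)
    if (length(e$max) < 2L || length(e$min) < 2L) return(NULL)
    m <- (spline_envelope(e$max, h[e$max], n) +
          spline_envelope(e$min, h[e$min], n)) / 2
    crit <- sum(m^2) / (sum(h^2) + 1e-300)
    h <- h - m
    if (crit < tol) break
  }
  h
}

#' Empirical mode decomposition
#'
#' Standard sifting: cubic-spline envelopes through local maxima and minima
#' (boundary extrema mirrored), mean-envelope subtraction until the
#' normalized envelope energy falls below `sift_tolerance`, repeated on the
#' residual until it is monotone (fewer than two maxima or minima) or
#' `max_imfs` is reached. The decomposition is complete by construction:
#' the IMFs and residual sum exactly to the input.
#'
#' @param signal numeric vector, length >= 16.
#' @param max_imfs maximum number of intrinsic mode functions (default 8).
#' @param sift_tolerance sifting stop criterion (default 0.05).
#' @param max_sift maximum sifting passes per IMF (default 15).
#' @return object of class `imf_decomposition`: list with `imfs` (list of
#'   numeric vectors) and `residual`.
#' @export
emd_decompose <- function(signal, max_imfs = 8, sift_tolerance = 0.05,
                          max_sift = 15) {
  if (length(signal) < 16L)
    stop_fc("emd_decompose needs >= 16 samples, got %d", length(signal))
  imfs <- list(); r <- as.numeric(signal)
  for (k in seq_len(max_imfs)) {
    im <- sift_imf(r, sift_tolerance, max_sift)
    if (is.null(im)) break
    imfs[[k]] <- im
    r <- r - im
    e <- local_extrema(r)
    if (length(e$max) < 2L || length(e$min) < 2L) break
  }
  structure(list(imfs = imfs, residual = r), class = "imf_decomposition")
}

#' Higher-order-moment features from an IMF decomposition
#'
#' Per fixed-length segment and per IMF: variance, skewness and excess
#' kurtosis (moments 2-4). The IMF count is fixed at `n_imfs` by truncation
#' or zero-padding so feature vectors are comparable across segments;
#' zero-variance segments get skewness and kurtosis 0.
#'
#' @param dec an `imf_decomposition` (or a list of them, one per segment).
#' @param n_imfs number of IMFs used (default 4).
#' @return numeric vector of length `n_imfs * 3` (or a matrix with one row
#'   per segment).
#' @export
imf_moment_features <- function(dec, n_imfs = 4) {
  if (is.list(dec) && !inherits(dec, "imf_decomposition"))
    return(t(vapply(dec, imf_moment_features, numeric(n_imfs * 3),
                    n_imfs = n_imfs)))
  n <- length(dec$residual)
  feats <- unlist(lapply(seq_len(n_imfs), function(k) {
    im <- if (k <= length(dec$imfs)) dec$imfs[[k]] else numeric(n)
    v <- stats::var(im)
    if (!is.finite(v) || v <= 0) c(0, 0, 0)
    else c(v, moment_skewness(im), moment_kurtosis(im))
  }))
  names(feats) <- paste0(rep(sprintf("imf%d", seq_len(n_imfs)), each = 3),
                         c("_var", "_skew", "_kurt"))
  feats
}

segment_bounds <- function(T, rate, segment_len, overlap = 0.5) {
  step <- max(1L, round(segment_len * rate * (1 - overlap)))
  wlen <- round(segment_len * rate)
  st <- seq.int(1L, max(1L, T - wlen + 1L), by = step)
  cbind(start = st, end = pmin(st + wlen - 1L, T))
}

#' Train the seizure/non-seizure segment classifier
#'
#' Linear discriminant analysis on standardized IMF moment features of
#' labeled segments. Training segments are cut from simulated mutant traces
#' under light stimuli (here: [simulate_lfp()] with known event times).
#'
#' @param features numeric matrix (segments x features).
#' @param labels logical or 0/1 vector, TRUE = seizure segment.
#' @param seed integer seed (LDA is deterministic; the seed fixes any
#'   upstream standardization order).
#' @return object of class `seizure_classifier`.
#' @export
train_seizure_classifier <- function(features, labels, seed = 1) {
  stopifnot(nrow(features) == length(labels))
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop_fc("training needs both seizure and non-seizure segments")
  # seizure bursts raise IMF variances multiplicatively; log-transform the
  # variance features so the discriminant boundary is linear in them
  var_cols <- grep("_var$", colnames(features))
  if (!length(var_cols)) var_cols <- seq(1L, ncol(features), by = 3L)
  X <- log_var_features(features, var_cols)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sd, `/`)
  fit <- MASS::lda(Z, grouping = factor(labels, levels = c(FALSE, TRUE)))
  structure(list(lda = fit, center = mu, scale = sd, var_cols = var_cols),
            class = "seizure_classifier")
}

log_var_features <- function(features, var_cols) {
  features[, var_cols] <- log(features[, var_cols, drop = FALSE] + 1e-6)
  features
}

classify_segments <- function(model, features) {
  X <- log_var_features(features, model$var_cols)
  Z <- sweep(sweep(X, 2L, model$center), 2L, model$scale, `/`)
  as.logical(stats::predict(model$lda, Z)$class == "TRUE")
}

#' Default training set for the seizure classifier
#'
#' Simulates seizure-bearing and seizure-free traces with known event times
#' and returns labeled segment features.
#'
#' @param rate sampling rate (Hz).
#' @param snr burst amplitude used for the training bursts.
#' @param n_events bursts in the seizure-bearing training trace.
#' @param segment_len,n_imfs as used at detection time.
#' @param seed integer seed.
#' @return list with `features` and `labels`.
#' @export
seizure_training_set <- function(rate = 100, snr = 6, n_events = 20,
                                 segment_len = 2, n_imfs = 4, seed = 1) {
  dur <- n_events * 12 + 30
  tr <- simulate_lfp(dur, rate, snr = snr, seed = substream_seed(seed, "train"),
                     event_times = 10 + (seq_len(n_events) - 1) * 12)
  sb <- segment_bounds(length(tr$samples), rate, segment_len)
  x <- tr$samples / stats::mad(tr$samples)
  feats <- t(apply(sb, 1L, function(b)
    imf_moment_features(emd_decompose(x[b[1]:b[2]]), n_imfs = n_imfs)))
  mid <- (sb[, 1] + sb[, 2]) / 2 / rate
  labels <- vapply(mid, function(m)
    any(m >= tr$true_events$start & m <= tr$true_events$end), logical(1))
  list(features = feats, labels = labels)
}

#' Detect seizures in an LFP trace
#'
#' The trace is robustly variance-normalized (so calls are invariant to
#' amplitude rescaling), cut into overlapping fixed-length segments, each
#' segment is EMD-decomposed and classified on its IMF moment features, and
#' consecutive positive segments are merged into events. Event frequency is
#' reported per 45-minute interval, the screen's counting convention.
#'
#' @param trace an `lfp_trace` (or numeric vector with `rate` given).
#' @param model a trained `seizure_classifier`.
#' @param segment_len segment length in seconds (default 2, 50% overlap).
#' @param rate sampling rate, required when `trace` is a bare vector.
#' @param n_imfs IMFs used for features (must match training).
#' @param min_segments minimum consecutive positive segments per event
#'   (default 2; a genuine burst spans at least two overlapping segments,
#'   so isolated single-segment positives are discarded).
#' @return object of class `seizure_calls`: list with `events` (data.frame
#'   start/end/score), `duration`, `frequency` (events per 45 min).
#' @export
detect_seizures <- function(trace, model, segment_len = 2, rate = NULL,
                            n_imfs = 4, min_segments = 2) {
  if (!inherits(model, "seizure_classifier"))
    stop_fc("detect_seizures requires a trained seizure_classifier")
  if (inherits(trace, "lfp_trace")) {
    x <- trace$samples; rate <- trace$rate
  } else {
    if (is.null(rate)) stop_fc("rate must be given for a bare numeric trace")
    x <- as.numeric(trace)
  }
  dur <- length(x) / rate
  sc <- stats::mad(x)
  if (sc == 0) {
    return(structure(list(events = data.frame(start = numeric(0),
                                              end = numeric(0),
                                              score = numeric(0)),
                          duration = dur, frequency = 0),
                     class = "seizure_calls"))
  }
  x <- x / sc
  sb <- segment_bounds(length(x), rate, segment_len)
  feats <- t(apply(sb, 1L, function(b)
    imf_moment_features(emd_decompose(x[b[1]:b[2]]), n_imfs = n_imfs)))
  pos <- classify_segments(model, feats)
  # merge consecutive (overlapping) positive segments into events
  ev <- data.frame(start = numeric(0), end = numeric(0), score = numeric(0))
  i <- 1L
  while (i <= length(pos)) {
    if (pos[i]) {
      j <- i
      while (j < length(pos) && pos[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_segments)
        ev <- rbind(ev, data.frame(start = (sb[i, 1] - 1) / rate,
                                   end = sb[j, 2] / rate,
                                   score = j - i + 1L))
      i <- j + 1L
    } else i <- i + 1L
  }
  structure(list(events = ev, duration = dur,
                 frequency = nrow(ev) * (45 * 60) / dur),
            class = "seizure_calls")
}

#' @export
print.seizure_calls <- function(x, ...) {
  cat(sprintf("<seizure_calls> %d events in %.1f min (%.2f per 45 min)\n",
              nrow(x$events), x$duration / 60, x$frequency))
  invisible(x)
}

#' Seizure-suppression efficacy score
#'
#' `1 - post_frequency / baseline_frequency`: 0 when the post-exposure
#' seizure frequency equals baseline (no effect), 1.00 for seizure-free
#' larvae. Negative values (worsening) are returned as-is with a
#' `worsened` flag.
#'
#' @param baseline,post `seizure_calls` (or bare frequencies per 45 min).
#' @return object of class `efficacy_score`: list with `baseline_freq`,
#'   `post_freq`, `score`, `worsened`.
#' @examples
#' efficacy_score(10, 0)$score   # 1
#' efficacy_score(10, 10)$score  # 0
#' @export
efficacy_score <- function(baseline, post) {
  bf <- if (inherits(baseline, "seizure_calls")) baseline$frequency else baseline
  pf <- if (inherits(post, "seizure_calls")) post$frequency else post
  if (!is.finite(bf) || bf <= 0)
    stop_fc("baseline seizure frequency must be > 0 (larva excluded from scoring)")
  s <- 1 - pf / bf
  structure(list(baseline_freq = bf, post_freq = pf, score = s,
                 worsened = s < 0),
            class = "efficacy_score")
}
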