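# Stationarity QA for connectivity time series: sliding-window correlation
# variance (kappa) against an autoregressive-surrogate null, and supervoxel
# subgroup-stability testing.

# Vectorized sliding-window Pearson correlation via cumulative sums.
sliding_correlation <- function(a, b, wlen, slen) {
  T <- length(a)
  if (length(b) != T) stop_fc("traces must have equal length")
  if (T < 2 * wlen) stop_fc("need at least 2 windows (T >= %d)", 2 * wlen)
  ca <- cumsum(a); cb <- cumsum(b)
  caa <- cumsum(a * a); cbb <- cumsum(b * b); cab <- cumsum(a * b)
  st <- seq.int(1L, T - wlen + 1L, by = slen); en <- st + wlen - 1L
  S <- function(cs) cs[en] - ifelse(st > 1L, cs[st - 1L], 0)
  num <- S(cab) - S(ca) * S(cb) / wlen
  den <- sqrt(pmax(S(caa) - S(ca)^2 / wlen, 0) *
              pmax(S(cbb) - S(cb)^2 / wlen, 0))
  r <- num / den
  r[!is.finite(r)] <- NA_real_
  pmin(pmax(r, -1), 1)
}

#' The kappa stationarity statistic of a window-correlation series
#'
#' `kappa = 1/(T-1) * sum((SWC(t) - mu)^2)` with `mu` the series mean — the
#' sample variance of the sliding-window correlations. Zero iff the series
#' is constant; missing values are excluded.
#'
#' @param values numeric vector of window correlations.
#' @return nonnegative scalar.
#' @examples
#' kappa_statistic(c(0.2, 0.4))  # 0.02
#' @export
kappa_statistic <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(0)
  mu <- mean(v)
  sum((v - mu)^2) / (length(v) - 1L)
}

#' Sliding-window correlation and its variance statistic kappa
#'
#' Pearson correlation between two traces over sliding windows (default
#' 30 s, stepped by 1 s), and the stationarity statistic
#' `kappa = 1/(T-1) * sum((SWC(t) - mu)^2)` — the sample variance of the
#' window-correlation series. Zero-variance windows yield missing
#' correlations which are excluded from kappa (with a message).
#'
#' @param a_trace,b_trace numeric traces of equal length.
#' @param rate sampling rate (Hz).
#' @param window window length in seconds (default 30).
#' @param step window step in seconds (default 1).
#' @param block_bootstrap optionally reassemble the SWC series from
#'   randomly ordered 30-s windows grouped into 5-min blocks before
#'   computing kappa (off by default).
#' @param seed seed used only when `block_bootstrap = TRUE`.
#' @return object of class `swc_series`: list with `values`, `mu`, `kappa`,
#'   `window`, `step`, `rate`, and the parent `traces` (used by
#'   [arr_surrogate_test()] to build its null).
#' @examples
#' s <- swc_kappa(rnorm(2400), rnorm(2400), rate = 20)
#' s$kappa
#' @export
swc_kappa <- function(a_trace, b_trace, rate, window = 30, step = 1,
                      block_bootstrap = FALSE, seed = 1) {
  wlen <- round(window * rate); slen <- max(1L, round(step * rate))
  vals <- sliding_correlation(a_trace, b_trace, wlen, slen)
  if (anyNA(vals))
    message(sprintf("%d zero-variance windows excluded from kappa", sum(is.na(vals))))
  use <- vals[!is.na(vals)]
  if (block_bootstrap) {
    set.seed(substream_seed(seed, "swc-block"))
    per_block <- max(1L, round(300 / window))
    n_blocks <- max(1L, floor(length(use) / per_block))
    use <- use[sample.int(length(use), n_blocks * per_block)]
  }
  mu <- mean(use)
  kap <- kappa_statistic(use)
  structure(list(values = vals, mu = mu, kappa = kap, window = window,
                 step = step, rate = rate,
                 traces = cbind(a = a_trace, b = b_trace)),
            class = "swc_series")
}

fit_ar2 <- function(x) {
  fit <- tryCatch(stats::ar(x, order.max = 2, aic = FALSE,
                            method = "yule-walker", demean = TRUE),
                  error = function(e) NULL)
  if (is.null(fit) || any(Mod(polyroot(c(1, -fit$ar))) <= 1.001)) {
    # shrink toward white noise to restore stationarity
    warning("AR(2) fit near-nonstationary; applying ridge shrinkage")
    phi <- if (is.null(fit)) c(0, 0) else 0.98 * fit$ar
    v <- stats::var(x) * max(1e-8, 1 - sum(phi^2))
    return(list(ar = phi, var.pred = v, x.mean = mean(x)))
  }
  fit
}

simulate_ar <- function(T, phi, innov_sd, burn = 200L, innov = NULL) {
  z <- innov %||% stats::rnorm(T + burn)
  as.numeric(stats::filter(z * innov_sd, phi, method = "recursive"))[-seq_len(burn)]
}

#' Stationarity verdict from AR(2)-surrogate null data
#'
#' Tests whether the sliding-window correlation of a trace pair varies more
#' than expected under static connectivity. The null is built at the trace
#' level: an AR(2) model is fitted to each parent trace (Yule-Walker) and
#' surrogate trace pairs are simulated with innovations correlated to match
#' the observed overall Pearson correlation, then windowed identically; the
#' surrogate kappas form the null distribution. `p` is the fraction of
#' surrogate kappas at or above the observed kappa, and the series is
#' declared dynamic when `p < alpha` (an excessive kappa relative to the
#' null indicates non-stationary connectivity).
#'
#' Innovations are Gaussian with matched variance by default;
#' `innovations = "resample"` bootstraps the AR residuals instead.
#'
#' @param swc an `swc_series` from [swc_kappa()] (must carry parent traces).
#' @param n_surrogates number of surrogate pairs (default 500).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param innovations `"gaussian"` or `"resample"`.
#' @return list with `verdict` (`"stationary"` or `"dynamic"`), `p`,
#'   `kappa`, `surrogate_kappa`, and the fitted AR coefficients.
#' @export
arr_surrogate_test <- function(swc, n_surrogates = 500, alpha = 0.05,
                               seed = 1, innovations = c("gaussian", "resample")) {
  innovations <- match.arg(innovations)
  if (is.null(swc$traces))
    stop_fc("swc_series carries no parent traces; build it with swc_kappa()")
  a <- swc$traces[, 1]; b <- swc$traces[, 2]
  T <- length(a)
  fa <- fit_ar2(a); fb <- fit_ar2(b)
  r0 <- stats::cor(a, b)
  wlen <- round(swc$window * swc$rate); slen <- max(1L, round(swc$step * swc$rate))

  resid_of <- function(x, f) {
    xc <- x - f$x.mean
    phi <- c(f$ar, 0, 0)[1:2]
    t <- 3:T
    e <- xc[t] - phi[1] * xc[t - 1] - phi[2] * xc[t - 2]
    e / stats::sd(e)
  }
  ra <- if (innovations == "resample") resid_of(a, fa)
  rb <- if (innovations == "resample") resid_of(b, fb)

  set.seed(substream_seed(seed, "arr"))
  burn <- 200L
  ks <- vapply(seq_len(n_surrogates), function(s) {
    if (innovations == "gaussian") {
      z1 <- stats::rnorm(T + burn)
      z2 <- r0 * z1 + sqrt(max(0, 1 - r0^2)) * stats::rnorm(T + burn)
    } else {
      z1 <- ra[sample.int(length(ra), T + burn, replace = TRUE)]
      z2 <- r0 * z1 + sqrt(max(0, 1 - r0^2)) *
        rb[sample.int(length(rb), T + burn, replace = TRUE)]
    }
    sa <- simulate_ar(T, fa$ar, sqrt(fa$var.pred), burn, innov = z1)
    sb <- simulate_ar(T, fb$ar, sqrt(fb$var.pred), burn, innov = z2)
    v <- sliding_correlation(sa, sb, wlen, slen)
    v <- v[!is.na(v)]
    if (length(v) > 1L) stats::var(v) else 0
  }, numeric(1))

  p <- mean(ks >= swc$kappa)
  list(verdict = if (p < alpha) "dynamic" else "stationary", p = p,
       kappa = swc$kappa, surrogate_kappa = ks,
       ar = list(a = fa$ar, b = fb$ar))
}

#' Supervoxel subgroup stability of inter-area correlation
#'
#' Checks that enough supervoxels are sampled per area: each area's active
#' supervoxels are repeatedly split at random into halves, the inter-area
#' mean absolute correlation is recomputed for each half-pairing, and the
#' per-repetition differences are t-tested against zero mean.
#'
#' @param sv a `supervoxel_set` with activity flags set.
#' @param pair integer `c(i, j)` region ids (>= 4 active supervoxels each).
#' @param window half-open resting interval (s); defaults to pre-stimulus.
#' @param n_rep number of random splits (default 50).
#' @param seed integer seed.
#' @return list with `differences` (length `n_rep`) and `p.value`.
#' @export
subgroup_stability <- function(sv, pair, window = NULL, n_rep = 50, seed = 1) {
  if (is.null(window)) window <- c(0, sv$schedule$pre_duration)
  act <- which(sv$active %in% TRUE)
  a <- act[sv$region[act] == pair[1]]
  b <- act[sv$region[act] == pair[2]]
  if (length(a) < 4L || length(b) < 4L)
    stop_fc("subgroup stability needs >= 4 active supervoxels per area (areas %d: %d, %d: %d)",
            pair[1], length(a), pair[2], length(b))
  fr <- frames_in(window, sv$frame_rate, nrow(sv$dff))
  half_corr <- function(ai, bi) {
    cc <- suppressWarnings(stats::cor(sv$dff[fr, ai, drop = FALSE],
                                      sv$dff[fr, bi, drop = FALSE]))
    mean(abs(cc), na.rm = TRUE)
  }
  set.seed(substream_seed(seed, "subgroup"))
  diffs <- vapply(seq_len(n_rep), function(r) {
    sa <- sample(a); sb <- sample(b)
    ha <- seq_len(floor(length(a) / 2))
    hb <- seq_len(floor(length(b) / 2))
    half_corr(sa[ha], sb[hb]) - half_corr(sa[-ha], sb[-hb])
  }, numeric(1))
  p <- if (stats::sd(diffs) == 0) 1 else
    stats::t.test(diffs, mu = 0)$p.value
  list(differences = diffs, p.value = p)
}

#' Per-larva stationarity QA report
#'
#' Runs [swc_kappa()] + [arr_surrogate_test()] on every area pair of a larva
#' and summarizes the stationary-pair fraction.
#'
#' @param sv a `supervoxel_set` with dF/F and activity flags.
#' @param atlas `atlas_labels`.
#' @param window resting interval (s); defaults to pre-stimulus.
#' @param n_surrogates,alpha,seed passed to [arr_surrogate_test()].
#' @return data.frame (pair, kappa, p, verdict) with attributes `median_p`
#'   and `stationary_fraction`.
#' @export
stationarity_report <- function(sv, atlas, window = NULL, n_surrogates = 200,
                                alpha = 0.05, seed = 1) {
  if (is.null(window)) window <- c(0, sv$schedule$pre_duration)
  fr <- frames_in(window, sv$frame_rate, nrow(sv$dff))
  R <- length(atlas$region_names)
  pr <- area_pairs(R)
  rows <- lapply(seq_len(nrow(pr)), function(p) {
    a <- which(sv$active %in% TRUE & sv$region == pr$i[p])
    b <- which(sv$active %in% TRUE & sv$region == pr$j[p])
    if (!length(a) || !length(b))
      return(data.frame(i = pr$i[p], j = pr$j[p], kappa = NA, p = NA,
                        verdict = NA))
    ta <- rowMeans(sv$dff[fr, a, drop = FALSE])
    tb <- rowMeans(sv$dff[fr, b, drop = FALSE])
    s <- swc_kappa(ta, tb, sv$frame_rate)
    tst <- arr_surrogate_test(s, n_surrogates = n_surrogates, alpha = alpha,
                              seed = substream_seed(seed, paste0("qa", p)))
    data.frame(i = pr$i[p], j = pr$j[p], kappa = s$kappa, p = tst$p,
               verdict = tst$verdict)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$verdict)
  attr(out, "median_p") <- stats::median(out$p[ok])
  attr(out, "stationary_fraction") <- mean(out$verdict[ok] == "stationary")
  out
}
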