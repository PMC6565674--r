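# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_fc <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a per-stage substream seed from a global seed
#'
#' All randomness in the package is driven by a single integer seed fanned out
#' into per-stage substreams, so that adding or reordering stages does not
#' perturb unrelated ones. Derived seeds stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 8191) %% 2147483629)
}

# Half-open interval [start, end) in seconds -> frame indices (1-based)
frames_in <- function(interval, rate, n_frames) {
  i0 <- floor(interval[1] * rate) + 1L
  i1 <- ceiling(interval[2] * rate)
  if (i1 < i0) return(integer(0))
  seq.int(max(1L, i0), min(n_frames, i1))
}

frames_in_windows <- function(windows, rate, n_frames) {
  if (length(windows) == 0L) return(integer(0))
  sort(unique(unlist(lapply(windows, frames_in, rate = rate, n_frames = n_frames))))
}

# Centered sliding mean with shrinking edge windows, via cumulative sums.
sliding_mean <- function(x, half_width) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half_width, 1L)
  hi <- pmin(seq_len(n) + half_width, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Sample skewness and excess kurtosis (moment estimators).
moment_skewness <- function(x) {
  n <- length(x); m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

moment_kurtosis <- function(x) {
  n <- length(x); m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

#' Jarque-Bera normality test
#'
#' Chi-square test (2 df) on sample skewness and excess kurtosis. Used to
#' check approximate normality of per-larva correlation samples before
#' t-testing them.
#'
#' @param x numeric vector, length >= 4.
#' @return list with `statistic` and `p.value`.
#' @export
jarque_bera <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stop_fc("jarque_bera needs at least 4 finite values, got %d", n)
  jb <- n / 6 * (moment_skewness(x)^2 + moment_kurtosis(x)^2 / 4)
  list(statistic = jb, p.value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

# Pairwise label utilities: area pairs are always stored with i < j.
area_pairs <- function(n_regions) {
  idx <- utils::combn(n_regions, 2L)
  data.frame(i = idx[1L, ], j = idx[2L, ])
}

pair_key <- function(i, j, names = NULL) {
  if (is.null(names)) sprintf("%d-%d", pmin(i, j), pmax(i, j))
  else paste(names[pmin(i, j)], names[pmax(i, j)], sep = "–")
}
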