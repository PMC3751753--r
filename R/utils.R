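#' @importFrom rlang .data
#' @importFrom stats fft lm cor.test median mad quantile rnorm runif sd var
#'   predict coef setNames
#' @importFrom utils head tail
NULL

# Run code under a local, restored RNG state so simulators never disturb the
# caller's random stream and are bit-reproducible given their seed argument.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), code)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name),
      call. = FALSE
    )
  }
  invisible(x)
}

# Rolling standard deviation over a k-sample window, one value per window
# start (length n - k + 1). Two-pass via cumulative sums; sample (n-1) form.
rolling_sd <- function(x, k) {
  n <- length(x)
  if (k < 2L || k > n) stop("window does not fit the series", call. = FALSE)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - k + 1L)
  s <- cs[i + k] - cs[i]
  s2 <- cs2[i + k] - cs2[i]
  v <- (s2 - s^2 / k) / (k - 1)
  sqrt(pmax(v, 0))
}

# Local-maximum peak picking with an amplitude threshold and a refractory
# spacing: returns indices of samples that exceed `threshold`, are local
# maxima, and are at least `min_gap` samples apart (keeping the larger peak
# when two compete).
find_peaks <- function(x, threshold, min_gap) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(
    x > threshold &
      x >= c(-Inf, x[-n]) &
      x > c(x[-1L], -Inf)
  )
  if (length(cand) == 0L) return(integer(0))
  # greedy by height, then enforce spacing
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  for (i in ord) {
    lo <- max(1L, i - min_gap)
    hi <- min(n, i + min_gap)
    if (!any(keep[lo:hi])) keep[i] <- TRUE
  }
  sort(which(keep))
}

# Moving average with centred window (odd k), edges padded by replication.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2L))[
    (half + 1L):(half + length(x))
  ]
}

# Half-open [start, end) 0-based sample interval helper.
sample_interval <- function(start, end) {
  stopifnot(start < end)
  c(start = as.integer(start), end = as.integer(end))
}
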