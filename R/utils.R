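`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# Deterministic 32-bit mix of a base seed and an id string, for
# parallel-safe per-fly RNG streams. Polynomial string hash mod (2^31 - 1).
mix_seed <- function(seed, id) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (cp in utf8ToInt(as.character(id))) {
    h <- (h * 31 + cp) %% m
  }
  as.integer(h)
}

# Zero-truncated Poisson sampler by inversion; vectorized over n.
# lambda is the underlying (untruncated) Poisson rate.
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  p0 <- stats::dpois(0, lambda)
  u <- stats::runif(n)
  stats::qpois(p0 + u * (1 - p0), lambda)
}

# Underlying Poisson rate whose zero-truncated mean equals `mean_count`.
# mean of ZTP(lambda) = lambda / (1 - exp(-lambda)), a strictly increasing
# map from (0, Inf) onto (1, Inf).
ztpois_lambda <- function(mean_count) {
  if (mean_count <= 1) {
    stop2("wake_activity_rate must exceed 1 count/min (awake minutes always emit at least one count)")
  }
  f <- function(l) l / (1 - exp(-l)) - mean_count
  stats::uniroot(f, c(1e-8, mean_count + 10), tol = 1e-10)$root
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  n <- length(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

is_count_vector <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x == floor(x))
}
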