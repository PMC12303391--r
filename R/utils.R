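#' @include AllClasses.R
NULL

# Otsu threshold on a numeric vector (256-level histogram over its range)
.otsu <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(NA_real_)
  h <- tabulate(pmin(nbins, 1L + as.integer((v - rng[1]) / diff(rng) *
                                              nbins)), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Theil-Sen slope: median of pairwise slopes (subsampled above n = 400)
.theil_sen <- function(x, y, max_n = 400L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n > max_n) {
    idx <- round(seq(1L, n, length.out = max_n))
    o <- order(x)
    x <- x[o][idx]; y <- y[o][idx]
    n <- max_n
  }
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & abs(dx) > 1e-12
  stats::median(dy[keep] / dx[keep])
}

# population standard deviation (divide by n, not n - 1)
.pop_sd <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  sqrt(mean((v - mean(v))^2))
}

# derive a per-task RNG seed below 2^31 from a base seed and a tag
# (double arithmetic: exact below 2^53, immune to integer overflow)
.derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 1009 + sum(utf8ToInt(tag)) * 7) %%
               2147483587)
}

.bin_index <- function(v, breaks) {
  findInterval(v, breaks, rightmost.closed = TRUE, all.inside = FALSE)
}
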