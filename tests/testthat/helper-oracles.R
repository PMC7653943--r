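# Independent brute-force oracles used to cross-check the closed-form and
# inversion code paths.

# smallest gate count whose captured motion reaches m_est - s/2
oracle_smallest_n <- function(c, s) {
  if (c <= s / 2) return(1L)
  target <- c - s / 2
  for (n in 1:10000) {
    if (c * (n - 1) / n >= target - 1e-9) return(n)
  }
  stop("oracle did not terminate")
}

# 1-D grid-search least squares for the single-mode amplitude c
oracle_grid_c <- function(n, y, lo = 0, hi = 60) {
  w <- (n - 1) / n
  sse <- function(c) sum((y - c * w)^2)
  for (level in 1:6) {
    grid <- seq(lo, hi, length.out = 201)
    vals <- vapply(grid, sse, numeric(1))
    best <- grid[which.min(vals)]
    step <- grid[2] - grid[1]
    lo <- best - step
    hi <- best + step
  }
  best
}

# 2-D grid-search least squares for the dual amplitudes (a, b)
oracle_grid_ab <- function(r, p, y, lo = c(0, 0), hi = c(40, 30)) {
  u <- (r - 1) / r
  v <- (p - 1) / p
  sse <- function(a, b) sum((y - a * u - b * v)^2)
  for (level in 1:6) {
    ga <- seq(lo[1], hi[1], length.out = 61)
    gb <- seq(lo[2], hi[2], length.out = 61)
    vals <- outer(ga, gb, Vectorize(sse))
    idx <- arrayInd(which.min(vals), dim(vals))
    best <- c(ga[idx[1]], gb[idx[2]])
    step <- c(ga[2] - ga[1], gb[2] - gb[1])
    lo <- best - step
    hi <- best + step
  }
  best
}

# analytic half-maximum width of a boxcar (width w) convolved with a
# Gaussian of standard deviation sigma, found numerically
oracle_box_gauss_fwhm <- function(w, sigma) {
  prof <- function(x) {
    stats::pnorm((x + w / 2) / sigma) - stats::pnorm((x - w / 2) / sigma)
  }
  half <- prof(0) / 2
  upper <- stats::uniroot(function(x) prof(x) - half, c(0, w / 2 + 6 * sigma))$root
  2 * upper
}
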