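# Internal numerical helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never leak global state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Band-pass a real signal by zeroing FFT coefficients outside [lo, hi) Hz.
# Used by the session generator to build band-limited noise components.
fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)            # fold to [0, fs/2]
  keep <- f >= lo & f < hi
  X[!keep] <- 0+0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Separable 3-D Gaussian smoothing with periodic boundary, via the 3-D FFT.
# fwhm is in voxels; fwhm = 0 returns the input.
gauss_smooth3d <- function(arr, fwhm) {
  if (all(fwhm <= 0)) return(arr)
  d <- dim(arr)
  fwhm <- rep_len(fwhm, 3L)
  sig <- fwhm / sqrt(8 * log(2))
  k <- array(1, d)
  for (ax in 1:3) {
    if (sig[ax] <= 0) next
    # circular distance along this axis
    idx <- seq_len(d[ax]) - 1L
    dist <- pmin(idx, d[ax] - idx)
    k1 <- stats::dnorm(dist, sd = sig[ax])
    shape <- c(1, 1, 1); shape[ax] <- d[ax]
    k <- k * array(rep(k1, each = prod(d[seq_len(ax - 1L)])), d)
  }
  k <- k / sum(k)
  out <- Re(stats::fft(stats::fft(arr) * stats::fft(k), inverse = TRUE)) / prod(d)
  out
}

# FFT of a periodic 3-D Gaussian kernel (normalized to sum 1); reused for
# repeated smoothing at a fixed size.
gauss_kernel_fft <- function(d, fwhm) {
  fwhm <- rep_len(fwhm, 3L)
  sig <- fwhm / sqrt(8 * log(2))
  k <- array(1, d)
  for (ax in 1:3) {
    if (sig[ax] <= 0) next
    idx <- seq_len(d[ax]) - 1L
    dist <- pmin(idx, d[ax] - idx)
    k1 <- stats::dnorm(dist, sd = sig[ax])
    k <- k * array(rep(k1, each = prod(d[seq_len(ax - 1L)])), d)
  }
  stats::fft(k / sum(k))
}

# Lag-1 spatial autocorrelation of a 3-D field along each axis, pooled over
# a list of residual arrays; used to match null-field smoothness.
field_neighbor_rho <- function(arrs) {
  if (is.array(arrs)) arrs <- list(arrs)
  rho <- numeric(3)
  for (ax in 1:3) {
    num <- 0; den <- 0
    for (a in arrs) {
      a <- a - mean(a)
      d <- dim(a)
      i1 <- seq_len(d[ax] - 1L); i2 <- i1 + 1L
      x1 <- switch(ax, a[i1, , , drop = FALSE], a[, i1, , drop = FALSE], a[, , i1, drop = FALSE])
      x2 <- switch(ax, a[i2, , , drop = FALSE], a[, i2, , drop = FALSE], a[, , i2, drop = FALSE])
      num <- num + sum(x1 * x2)
      den <- den + sum(a^2) * (d[ax] - 1L) / d[ax]
    }
    rho[ax] <- num / den
  }
  pmin(pmax(rho, 0), 0.98)
}

# Convert a field's neighbour autocorrelation to the FWHM (voxels) of the
# Gaussian kernel that, applied to white noise, reproduces it. Smoothing
# with kernel sigma_k gives a field ACF rho = exp(-1 / (4 sigma_k^2)).
rho_to_fwhm <- function(rho) {
  out <- numeric(length(rho))
  pos <- rho > 0
  out[pos] <- sqrt(8 * log(2)) * sqrt(-1 / (4 * log(rho[pos])))
  out
}

# Label the 6-connected components of the voxel set `mask_idx` (linear
# indices into an array of dimension `dims`). Returns a list of integer
# vectors of member voxel indices, one per cluster.
label_clusters_6conn <- function(mask_idx, dims) {
  n <- length(mask_idx)
  if (n == 0L) return(list())
  pos <- array(0L, dims)
  pos[mask_idx] <- seq_len(n)
  coords <- arrayInd(mask_idx, dims)
  labels <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (labels[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    labels[i] <- cur
    while (length(stack) > 0L) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cj <- coords[j, ]
      for (ax in 1:3) {
        for (s in c(-1L, 1L)) {
          v <- cj[ax] + s
          if (v < 1L || v > dims[ax]) next
          cc <- cj; cc[ax] <- v
          k <- pos[cc[1L], cc[2L], cc[3L]]
          if (k > 0L && labels[k] == 0L) {
            labels[k] <- cur
            stack <- c(stack, k)
          }
        }
      }
    }
  }
  split(mask_idx, labels)
}

# Welch-averaged one-sided power spectral density.
# `segments` is a list of numeric vectors (epochs); each is cut into
# `nper`-sample Hann windows with 50% overlap. Epochs shorter than `nper`
# (but at least `min_len`) are Hann-windowed whole and zero-padded to `nper`
# so all periodograms share one frequency grid.
welch_psd <- function(segments, fs, nper, min_len = nper %/% 2L) {
  if (is.numeric(segments)) segments <- list(segments)
  acc <- NULL
  nwin <- 0L
  freqs <- (seq_len(nper %/% 2L + 1L) - 1L) * fs / nper
  hann <- function(m) 0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1))
  add_win <- function(xw, w) {
    xw <- (xw - mean(xw)) * w
    if (length(xw) < nper) xw <- c(xw, numeric(nper - length(xw)))
    P <- Mod(stats::fft(xw))^2 / (fs * sum(w^2))
    P <- P[seq_len(nper %/% 2L + 1L)]
    P[c(-1L, -length(P))] <- 2 * P[c(-1L, -length(P))]
    P
  }
  step <- nper %/% 2L
  for (seg in segments) {
    m <- length(seg)
    if (m < min_len) next
    if (m < nper) {
      P <- add_win(seg, hann(m))
      acc <- if (is.null(acc)) P else acc + P
      nwin <- nwin + 1L
    } else {
      starts <- seq(1L, m - nper + 1L, by = step)
      w <- hann(nper)
      for (s in starts) {
        P <- add_win(seg[s:(s + nper - 1L)], w)
        acc <- if (is.null(acc)) P else acc + P
        nwin <- nwin + 1L
      }
    }
  }
  if (nwin == 0L) stop("no epoch long enough for spectral estimation", call. = FALSE)
  list(freq = freqs, psd = acc / nwin, n_windows = nwin)
}

# FFT-based 'valid' cross-correlation of x with a (short) kernel:
# out[i] = sum_j x[i + j - 1] * k[j], i = 1 .. length(x) - length(k) + 1.
xcorr_valid <- function(x, k) {
  n <- length(x); m <- length(k)
  nfft <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  K <- stats::fft(c(rev(k), numeric(nfft - m)))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  full[m:n]
}

# Running (boxcar) sum of window m over x, 'valid' alignment.
running_sum <- function(x, m) {
  cs <- c(0, cumsum(x))
  cs[(m + 1L):length(cs)] - cs[seq_len(length(cs) - m)]
}

# Contiguous runs of TRUE in a logical vector -> two-column matrix (start, end).
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
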