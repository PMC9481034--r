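# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random state. All randomness in the package flows through this helper so
# that every output is a pure function of its inputs and seed.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Reflective (mirror) padding of a matrix by `m` pixels on every side.
pad_reflect <- function(x, m) {
  nr <- nrow(x); nc <- ncol(x)
  if (m >= nr || m >= nc) stop("padding exceeds image size")
  ri <- c(rev(seq_len(m) + 1L), seq_len(nr), nr - seq_len(m))
  ci <- c(rev(seq_len(m) + 1L), seq_len(nc), nc - seq_len(m))
  x[ri, ci, drop = FALSE]
}

# Smallest 7-smooth integer >= n (sizes at which the FFT is fast).
next_fft_size <- function(n) {
  n <- as.integer(max(1L, n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Mirror-extension index: maps any integer offset onto 1..n without
# repeating the border sample (reflect-101 extension).
reflect_index <- function(n, i) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n - 2L)
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}

# Circular cross-correlation via FFT, kernel centre aligned to (1, 1).
fft_xcorr_circular <- function(x, k) {
  s <- dim(k)
  kp <- matrix(0, nrow(x), ncol(x))
  ri <- ((seq_len(s[1]) - (s[1] + 1L) %/% 2L) %% nrow(x)) + 1L
  ci <- ((seq_len(s[2]) - (s[2] + 1L) %/% 2L) %% ncol(x)) + 1L
  kp[ri, ci] <- k
  fx <- fftwtools::fftw2d(x)
  fk <- fftwtools::fftw2d(kp)
  Re(fftwtools::fftw2d(fx * Conj(fk), inverse = 1)) / length(x)
}

# Cross-correlation of an image with a (small, odd-sized) kernel under
# reflective boundary conditions, same spatial extent as the input. The
# image is mirror-padded out to an FFT-friendly size before the circular
# correlation, then cropped back.
xcorr2_reflect <- function(img, kernel) {
  if (any(dim(kernel) > dim(img))) stop("kernel larger than image")
  m <- max(dim(kernel)) %/% 2 + 1L
  tr <- next_fft_size(nrow(img) + 2L * m)
  tc <- next_fft_size(ncol(img) + 2L * m)
  padded <- img[reflect_index(nrow(img), seq_len(tr) - m),
                reflect_index(ncol(img), seq_len(tc) - m), drop = FALSE]
  out <- fft_xcorr_circular(padded, kernel)
  out[(m + 1L):(m + nrow(img)), (m + 1L):(m + ncol(img)), drop = FALSE]
}

# Local box mean with window `win` (odd) under reflective boundary
# conditions, computed with a summed-area table.
box_mean <- function(x, win) {
  stopifnot(win %% 2L == 1L, win >= 1L)
  if (win == 1L) return(x)
  m <- win %/% 2L
  p <- x[reflect_index(nrow(x), seq_len(nrow(x) + 2L * m) - m),
         reflect_index(ncol(x), seq_len(ncol(x) + 2L * m) - m), drop = FALSE]
  I <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  I[-1, -1] <- t(apply(apply(p, 2, cumsum), 1, cumsum))
  nr <- nrow(x); nc <- ncol(x)
  (I[win + seq_len(nr), win + seq_len(nc)] -
     I[seq_len(nr), win + seq_len(nc)] -
     I[win + seq_len(nr), seq_len(nc)] +
     I[seq_len(nr), seq_len(nc)]) / (win * win)
}

# Full 2D convolution of two small kernels (output size dim(a)+dim(b)-1).
conv2_full <- function(a, b) {
  sa <- dim(a); sb <- dim(b)
  out <- matrix(0, sa[1] + sb[1] - 1L, sa[2] + sb[2] - 1L)
  for (i in seq_len(sa[1])) {
    ii <- i:(i + sb[1] - 1L)
    for (j in seq_len(sa[2])) {
      if (a[i, j] != 0)
        out[ii, j:(j + sb[2] - 1L)] <- out[ii, j:(j + sb[2] - 1L)] + a[i, j] * b
    }
  }
  out
}

# Robust per-pixel noise standard deviation of an image, from the median
# absolute horizontal difference of adjacent pixels (signal structure is
# sparse in gradient space, so the median reflects the noise).
robust_noise_sd <- function(img) {
  d <- abs(img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE])
  stats::median(d) / (0.6744898 * sqrt(2))
}

# Odd-sized isotropic 2D Gaussian kernel, unit sum.
gaussian_kernel_2d <- function(sigma_px) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma_px)))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

# Euclidean distance from points (px, py) to the segment p0--p1 (2-vectors).
dist_to_segment <- function(px, py, p0, p1) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx * vx + vy * vy
  if (len2 == 0) return(sqrt((px - p0[1])^2 + (py - p0[2])^2))
  t <- ((px - p0[1]) * vx + (py - p0[2]) * vy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (p0[1] + t * vx))^2 + (py - (p0[2] + t * vy))^2)
}

# Stable checksum of an R object (used for provenance records).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
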