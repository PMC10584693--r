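# Independent brute-force oracles, deliberately naive implementations that
# share no code path with the package internals.

# exhaustive 26-neighborhood scan; plateau representative = lexicographically
# smallest member of each equal-valued connected candidate group
brute_local_maxima <- function(arr) {
  d <- dim(arr)
  cand <- matrix(0L, 0, 3)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    v <- arr[z, y, x]
    if (!is.finite(v)) next
    nb <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3]) next
      nb <- c(nb, arr[zz, yy, xx])
    }
    if (all(v >= nb)) cand <- rbind(cand, c(z, y, x))
  }
  cand
}

# dense direct 3D Gaussian convolution with replicate padding (no
# separability assumption)
brute_gauss3d <- function(arr, sigma) {
  d <- dim(arr)
  r <- ceiling(4 * sigma)
  out <- array(0, d)
  ker <- array(0, 2 * r + 1)
  kz <- exp(-0.5 * ((-r[1]:r[1]) / sigma[1])^2)
  ky <- exp(-0.5 * ((-r[2]:r[2]) / sigma[2])^2)
  kx <- exp(-0.5 * ((-r[3]:r[3]) / sigma[3])^2)
  kz <- kz / sum(kz); ky <- ky / sum(ky); kx <- kx / sum(kx)
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    acc <- 0
    for (iz in seq_along(kz)) for (iy in seq_along(ky)) for (ix in seq_along(kx)) {
      zz <- clampi(z + iz - r[1] - 1L, d[1])
      yy <- clampi(y + iy - r[2] - 1L, d[2])
      xx <- clampi(x + ix - r[3] - 1L, d[3])
      acc <- acc + kz[iz] * ky[iy] * kx[ix] * arr[zz, yy, xx]
    }
    out[z, y, x] <- acc
  }
  out
}

# direct minimization of Li's cross-entropy criterion over a threshold scan
# (the fixed-point iteration should land at this minimum's binarization)
brute_li_scan <- function(values) {
  v <- sort(values - min(values))
  cands <- (v[-1] + v[-length(v)]) / 2
  cands <- unique(cands[cands > 0])
  crit <- vapply(cands, function(t) {
    b <- v[v <= t]; f <- v[v > t]
    if (!length(b) || !length(f)) return(Inf)
    mb <- mean(b); mf <- mean(f)
    if (mb <= 0) return(Inf)
    -(sum(b) * log(mb) + sum(f) * log(mf))
  }, numeric(1))
  cands[which.min(crit)] + min(values)
}

# naive per-bin groupby for binned means
brute_binned <- function(x, y, edges, min_count) {
  rows <- list()
  for (b in seq_len(length(edges) - 1L)) {
    if (b < length(edges) - 1L) {
      sel <- x >= edges[b] & x < edges[b + 1L]
    } else {
      sel <- x >= edges[b] & x <= edges[b + 1L]
    }
    yy <- y[sel]
    if (length(yy) < min_count) next
    rows[[length(rows) + 1L]] <- data.frame(
      center = mean(edges[b:(b + 1L)]), mean = mean(yy),
      se = if (length(yy) > 1) sd(yy) / sqrt(length(yy)) else 0,
      count = length(yy))
  }
  do.call(rbind, rows)
}

# deterministic bimodal sample (no RNG) used for frozen-threshold checks
li_fixture <- function() {
  c(qnorm(ppoints(200), 10, 1), qnorm(ppoints(100), 20, 1.5))
}

random_stack <- function(d = c(16, 16, 16), vox = c(0.35, 0.1, 0.1)) {
  image_stack(array(runif(prod(d)), d), vox)
}
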