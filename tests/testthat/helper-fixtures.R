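## Fixture builders shared across the suite. All geometry is generated in
## code; no binary fixtures are stored.

## digitized vertical cylinder (axis along y) in a (nz, ny, nx) grid
make_cylinder_mask <- function(nz = 11, ny = 60, nx = 11, r_vox = 3,
                               y0 = 6, y1 = NULL, voxel_size = c(1, 1, 1)) {
  if (is.null(y1)) y1 <- ny - 5
  a <- array(FALSE, c(nz, ny, nx))
  cz <- (nz + 1) / 2; cx <- (nx + 1) / 2
  disk <- outer((seq_len(nz) - cz)^2, (seq_len(nx) - cx)^2, `+`) <= r_vox^2
  for (y in y0:y1) a[, y, ] <- disk
  binary_mask(array(as.integer(a), dim = dim(a)), voxel_size)
}

## Y-shaped tube: vertical trunk plus one diagonal arm -> 1 triple point
make_y_mask <- function() {
  b <- array(FALSE, c(9, 40, 30))
  for (y in 3:37) {
    b[, y, 13:17][outer(abs(1:9 - 5), abs(13:17 - 15),
                        function(i, j) i^2 + j^2) <= 4] <- TRUE
  }
  for (k in 0:10) {
    xs <- 15 + k
    b[, 20 + k, (xs - 1):(xs + 1)][abs(1:9 - 5) <= 1] <- TRUE
  }
  binary_mask(array(as.integer(b), dim = dim(b)), c(1, 1, 1))
}

## solid torus in the (y, x) plane -> skeleton is a single closed cycle
make_torus_mask <- function(R0 = 9, rt = 2.5) {
  tor <- array(FALSE, c(9, 30, 30))
  for (z in 1:9) for (y in 1:30) for (x in 1:30) {
    rr <- sqrt((y - 15)^2 + (x - 15)^2)
    tor[z, y, x] <- (rr - R0)^2 + (z - 5)^2 <= rt^2
  }
  binary_mask(array(as.integer(tor), dim = dim(tor)), c(1, 1, 1))
}

## random 8-bit stack with a bimodal-ish histogram
make_random_stack8 <- function(seed, n = 4000) {
  set.seed(seed)
  k <- sample(2:4, 1)
  centers <- sample(10:240, k)
  v <- unlist(lapply(centers, function(ct) {
    pmin(pmax(round(rnorm(ceiling(n / k), ct, sample(3:25, 1))), 0), 255)
  }))[seq_len(n)]
  dims <- c(10, 20, n / 200)
  vol_image(array(v, dim = dims), c(1, 1, 1), "8")
}

## independent brute-force threshold oracles (class-sum formulations,
## deliberately different from the package's cumulative-vector code path)
oracle_best_threshold <- function(counts, criterion, target = 0.5) {
  n <- sum(counts)
  best_t <- NA_integer_
  best_val <- -Inf
  vals <- rep(NA_real_, 255)
  for (t in 0:254) {
    c0 <- counts[1:(t + 1)]; c1 <- counts[(t + 2):256]
    n0 <- sum(c0); n1 <- sum(c1)
    if (n0 == 0 || n1 == 0) next
    lev0 <- 0:t; lev1 <- (t + 1):255
    val <- switch(criterion,
      otsu = {
        m0 <- sum(c0 * lev0) / n0; m1 <- sum(c1 * lev1) / n1
        (n0 / n) * (n1 / n) * (m0 - m1)^2
      },
      max_entropy = {
        p0 <- c0[c0 > 0] / n0; p1 <- c1[c1 > 0] / n1
        -sum(p0 * log(p0)) - sum(p1 * log(p1))
      },
      percentile = -abs(n0 / n - target),
      moments = {
        p <- counts / n; lev <- 0:255
        m1 <- sum(p * lev); m2 <- sum(p * lev^2); m3 <- sum(p * lev^3)
        cd <- m2 - m1^2
        c0m <- (-m2^2 + m1 * m3) / cd
        c1m <- (-m3 + m2 * m1) / cd
        z1 <- 0.5 * (-c1m + sqrt(c1m^2 - 4 * c0m))
        z0 <- 0.5 * (-c1m - sqrt(c1m^2 - 4 * c0m))
        -abs(n0 / n - (z1 - m1) / (z1 - z0))
      })
    vals[t + 1] <- val
    if (val > best_val + 1e-12) { best_val <- val; best_t <- t }
  }
  list(best = best_t, value = best_val, values = vals)
}

## brute-force 26-connected flood fill used as the hysteresis oracle
oracle_hysteresis <- function(a, low, high) {
  d <- dim(a)
  keep <- array(FALSE, d)
  frontier <- which(a > high)
  keep[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- integer(0)
    for (i in frontier) {
      z <- (i - 1) %% d[1] + 1
      y <- ((i - 1) %/% d[1]) %% d[2] + 1
      x <- (i - 1) %/% (d[1] * d[2]) + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        zz <- z + dz; yy <- y + dy; xx <- x + dx
        if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] ||
            xx < 1 || xx > d[3]) next
        if (!keep[zz, yy, xx] && a[zz, yy, xx] > low) {
          keep[zz, yy, xx] <- TRUE
          nxt <- c(nxt, zz + d[1] * (yy - 1) + d[1] * d[2] * (xx - 1))
        }
      }
    }
    frontier <- nxt
  }
  keep
}
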