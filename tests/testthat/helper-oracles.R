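# Independent brute-force oracles used to check the package's
# implementations. These work on raw logical arrays with explicit
# coordinate arithmetic, deliberately avoiding the package's internals.

# Set-based dilation: scatter every element offset from every true voxel.
brute_dilate <- function(arr, element) {
  d <- dim(arr)
  out <- array(FALSE, dim = d)
  tv <- which(arr, arr.ind = TRUE)
  if (nrow(tv) == 0) return(out)
  for (r in seq_len(nrow(element))) {
    p <- sweep(tv, 2, element[r, ], "+")
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] &
          p[, 2] >= 1 & p[, 2] <= d[2] &
          p[, 3] >= 1 & p[, 3] <= d[3]
    if (any(ok)) out[p[ok, , drop = FALSE]] <- TRUE
  }
  out
}

# Set-based erosion: a voxel survives iff every translated offset lands
# on a true voxel (outside the grid counts as false).
brute_erode <- function(arr, element) {
  d <- dim(arr)
  out <- array(TRUE, dim = d)
  for (r in seq_len(nrow(element))) {
    o <- element[r, ]
    shifted <- array(FALSE, dim = d)
    src_i <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    src_j <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    src_k <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    dst_i <- src_i - o[1]; dst_j <- src_j - o[2]; dst_k <- src_k - o[3]
    shifted[dst_i, dst_j, dst_k] <- arr[src_i, src_j, src_k]
    out <- out & shifted
  }
  out
}

# Closing on a background-padded domain (dilate, erode, crop), the
# conservative boundary convention.
brute_close <- function(arr, element) {
  d <- dim(arr)
  ext <- unname(apply(abs(element), 2, max))
  p <- array(FALSE, dim = d + 2 * ext)
  p[(ext[1] + 1):(ext[1] + d[1]), (ext[2] + 1):(ext[2] + d[2]),
    (ext[3] + 1):(ext[3] + d[3])] <- arr
  res <- brute_erode(brute_dilate(p, element), element)
  res[(ext[1] + 1):(ext[1] + d[1]), (ext[2] + 1):(ext[2] + d[2]),
      (ext[3] + 1):(ext[3] + d[3])]
}

# Random blob mask: union of random balls plus sparse noise voxels.
random_blob_array <- function(d, n_balls = 3, noise_frac = 0.002) {
  arr <- array(FALSE, dim = d)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  for (b in seq_len(n_balls)) {
    c0 <- runif(3, 0.2, 0.8) * d
    r0 <- runif(1, 0.08, 0.25) * min(d)
    inside <- rowSums(sweep(idx, 2, c0, "-")^2) <= r0^2
    arr[idx[inside, , drop = FALSE]] <- TRUE
  }
  n_noise <- round(noise_frac * prod(d))
  if (n_noise > 0) arr[sample(prod(d), n_noise)] <- TRUE
  arr
}

# Exact one-sided signed-rank p value by full enumeration of the 2^n
# sign assignments (tie-free absolute differences assumed).
enumerate_signed_rank_p <- function(d, alternative = "less") {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% rk)
  if (alternative == "less") mean(v_all <= v_obs) else mean(v_all >= v_obs)
}

# Weighted kappa straight from the definition, summing weights over
# every cell of observed and chance tables built by explicit loops.
brute_weighted_kappa <- function(a, b, categories = 0:3) {
  K <- length(categories)
  n <- length(a)
  O <- matrix(0, K, K); E <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    O[i, j] <- sum(a == categories[i] & b == categories[j])
    E[i, j] <- sum(a == categories[i]) * sum(b == categories[j]) / n
  }
  num <- 0; den <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    w <- (i - j)^2 / (K - 1)^2
    num <- num + w * O[i, j]
    den <- den + w * E[i, j]
  }
  1 - num / den
}

# Small fully in-memory phantom-like fixture on a coarse grid for fast
# unit tests (not the full generator).
tiny_grid_mask <- function(d = c(16, 12, 6), spacing = c(1, 1, 1)) {
  odacs_mask(array(FALSE, dim = d), spacing = spacing)
}

# Physical coordinates (mm) of a mask's true voxel centres.
voxel_to_physical_for_test <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}
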