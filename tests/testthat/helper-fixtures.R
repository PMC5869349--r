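# Fixture builders and independent brute-force oracles used across tests.

cube_mask <- function(shape, from, to, spacing = c(1, 1, 1)) {
  a <- array(FALSE, shape)
  a[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  binary_mask(a, spacing)
}

ball_mask <- function(radius_mm, shape, spacing = c(1, 1, 1),
                      centre_idx = (shape + 1) / 2) {
  co <- lapply(1:3, function(ax)
    ((seq_len(shape[ax]) - centre_idx[ax]) * spacing[ax])^2)
  d2 <- outer(outer(co[[1]], co[[2]], "+"), co[[3]], "+")
  binary_mask(array(d2 <= radius_mm^2, shape), spacing)
}

random_mask <- function(shape, p = 0.25, spacing = c(1, 1, 1)) {
  a <- array(runif(prod(shape)) < p, shape)
  if (!any(a)) a[ceiling(shape[1] / 2), ceiling(shape[2] / 2),
                 ceiling(shape[3] / 2)] <- TRUE
  binary_mask(a, spacing)
}

# independent surface extraction: triple loop, 6-neighbour complement test
oracle_surface_coords <- function(mask) {
  m <- mask$data
  dm <- dim(m)
  out <- NULL
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!m[i, j, k]) next
    surf <- i == 1 || i == dm[1] || j == 1 || j == dm[2] ||
      k == 1 || k == dm[3] ||
      !m[i - 1, j, k] || !m[i + 1, j, k] ||
      !m[i, j - 1, k] || !m[i, j + 1, k] ||
      !m[i, j, k - 1] || !m[i, j, k + 1]
    if (surf) out <- rbind(out, c(i, j, k))
  }
  sweep(out - 1, 2, mask$spacing, "*")
}

# brute-force O(n^2) directed closest-point distances between surfaces
oracle_directed <- function(a, b) {
  pa <- oracle_surface_coords(a)
  pb <- oracle_surface_coords(b)
  vapply(seq_len(nrow(pa)), function(i)
    sqrt(min(colSums((t(pb) - pa[i, ])^2))), numeric(1))
}

oracle_hd <- function(a, b) max(max(oracle_directed(a, b)),
                                max(oracle_directed(b, a)))

oracle_mda <- function(a, b) mean(c(oracle_directed(a, b),
                                    oracle_directed(b, a)))

# brute-force minimum coverage margin: max over truth voxel centres of the
# distance to the nearest candidate voxel centre (volumes, not surfaces)
oracle_min_margin <- function(truth, candidate) {
  pt <- which(truth$data, arr.ind = TRUE)
  pc <- which(candidate$data, arr.ind = TRUE)
  pt <- sweep(pt - 1, 2, truth$spacing, "*")
  pc <- sweep(pc - 1, 2, candidate$spacing, "*")
  max(vapply(seq_len(nrow(pt)), function(i)
    sqrt(min(colSums((t(pc) - pt[i, ])^2))), numeric(1)))
}

# blurred-sphere PET phantom with analytic ground truth
sphere_phantom <- function(radius_mm, contrast = 10, n = 48,
                           fwhm_mm = 4.1, noise_frac = 0) {
  ctr <- (n - 1) / 2
  co <- ((0:(n - 1)) - ctr)^2
  d2 <- outer(outer(co, co, "+"), co, "+")
  truth <- array(d2 <= radius_mm^2, c(n, n, n))
  act <- array(1, c(n, n, n))
  act[truth] <- contrast
  if (fwhm_mm > 0)
    act <- gaussian_smooth(act, fwhm_mm / (2 * sqrt(2 * log(2))), c(1, 1, 1))
  if (noise_frac > 0)
    act <- act + array(rnorm(length(act), 0, noise_frac * contrast), dim(act))
  list(image = scalar_image(act), truth = binary_mask(truth),
       seed_mm = rep(ctr, 3))
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns,
# applying the same two-sided doubling rule as the reference test
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  if (v_obs > n * (n + 1) / 4) min(1, 2 * p_ge) else min(1, 2 * p_le)
}
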