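# Independent oracles used across the suite. These deliberately use naive
# algorithms (recursive flood fill, full enumeration, triple loops) so they
# share no code with the implementation they check.

# flood-fill connected-component labeling on a 3D logical array
oracle_label3d <- function(mask, connectivity) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nz_off <- rowSums(offs != 0)
  offs <- offs[nz_off > 0 & nz_off <= switch(as.character(connectivity),
                                             "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labels <- array(0L, dims)
  cur <- 0L
  for (i in which(mask)) {
    if (labels[i] != 0L) next
    cur <- cur + 1L
    stack <- list(arrayInd(i, dims)[1, ])
    labels[i] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1L) || any(q > dims)) next
        if (mask[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0L) {
          labels[q[1], q[2], q[3]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  labels
}

# canonical form of a labeling: map labels to first-occurrence order so two
# labelings can be compared regardless of label numbering
canonical_labels <- function(labels) {
  v <- as.vector(labels)
  nz <- v != 0L
  v[nz] <- match(v[nz], unique(v[nz]))
  v
}

# exact voxel-centre membership count for one sphere, by triple loop
oracle_sphere_voxels <- function(center_um, d_um, dims, vs) {
  r2 <- (d_um / 2)^2
  cnt <- 0L
  for (z in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (x in seq_len(dims[3])) {
      p <- (c(z, y, x) - 0.5) * vs
      if (sum((p - center_um)^2) <= r2) cnt <- cnt + 1L
    }
  cnt
}

# brute-force two-sided exact Mann-Whitney p by enumeration over all
# labelings (independent of the package implementation)
oracle_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  mu <- na * nb / 2
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  hits <- 0L
  for (j in seq_len(ncol(combs))) {
    u <- sum(r[combs[, j]]) - na * (na + 1) / 2
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / ncol(combs)
}

# principal-axis elongation from raw voxel coordinates (independent PCA)
oracle_elongation <- function(labels, id, vs) {
  idx <- which(labels == id)
  co <- arrayInd(idx, dim(labels))
  pts <- sweep(co, 2, c(0.5, 0.5, 0.5)) %*% diag(vs)
  ev <- eigen(stats::cov(pts) * (nrow(pts) - 1) / nrow(pts) +
                diag(vs^2 / 12), symmetric = TRUE)$values
  sqrt(max(ev) / max(min(ev), 1e-12))
}

# random small logical mask with tunable fill
random_mask <- function(dims, fill, seed) {
  withr::with_seed(seed, array(stats::runif(prod(dims)) < fill, dims))
}

# small simulation config helper for clean (noise-free) scenes
clean_sim <- function(grid_shape, voxel = 2, amp = 3000, bg = 100) {
  simulation_config(grid_shape = grid_shape, voxel_size_um = voxel,
                    background_level = bg, plaque_amplitude = amp,
                    noise_gaussian_sd = 0, noise_poisson = FALSE)
}
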