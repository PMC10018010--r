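# Analytic gradients of the training losses with respect to network outputs.
# Internal: the training loops consume these; finite-difference tests in
# test-networks.R/test-training.R pin them against numerical derivatives.

dice_loss_grad <- function(y, p, eps = .EPS) {
  n <- batch_size(y)
  g <- array(0, dim(p))
  for (i in seq_len(n)) {
    yi <- y[, , , i]; pi <- p[, , , i]
    I <- sum(yi * pi); U <- sum(yi) + sum(pi)
    g[, , , i] <- -(2 * yi * (U + eps) - (2 * I + eps)) / (U + eps)^2
  }
  g / n
}

entropy_min_loss_grad <- function(p, entropy = "single", eps = .EPS) {
  tot <- length(p)
  g <- -(log(pmax(p, eps)) + 1) / tot
  if (entropy == "full_binary")
    g <- g + (log(pmax(1 - p, eps)) + 1) / tot
  g
}

segmentation_loss_grad <- function(y, p, entropy = "single", eps = .EPS)
  dice_loss_grad(y, p, eps) + entropy_min_loss_grad(p, entropy, eps)

adversarial_generator_loss_grad <- function(d, eps = .EPS)
  -1 / pmax(d, eps) / length(d)

reconstruction_loss_grad <- function(x, x_recon)
  2 * (x_recon - x) / length(x)

discriminator_loss_grad <- function(d, z, eps = .EPS)
  -(z / pmax(d, eps) - (1 - z) / pmax(1 - d, eps)) / length(d)

# gradient of cluster_loss_flat wrt the flat feature matrix (n x d)
cluster_loss_grad_flat <- function(f, l) {
  n <- nrow(f)
  cc <- class_centroids(f, l)
  g <- matrix(0, n, ncol(f))
  both <- all(cc$present)
  if (both)
    rsign <- sign(cc$centroids[1, ] - cc$centroids[2, ]) # d(c0 - c1)
  for (j in 0:1) {
    if (!cc$present[j + 1]) next
    idx <- which(l == j)
    nj <- length(idx)
    sj <- sign(sweep(f[idx, , drop = FALSE], 2, cc$centroids[j + 1, ]))
    # direct tightening term + its path through the class centroid
    g[idx, ] <- sj / n -
      matrix(colSums(sj) / (n * nj), nj, ncol(f), byrow = TRUE)
    if (both) {
      # repulsion -|c0 - c1|: dc_j/df_i = 1/nj for i in class j
      rj <- if (j == 0) -rsign / nj else rsign / nj
      g[idx, ] <- g[idx, ] + matrix(rj, nj, ncol(f), byrow = TRUE)
    }
  }
  g
}

# reshape a flat (n x d) feature gradient back to a (Hf, Wf, d, N) map
unflatten_features <- function(g, fdim) {
  dim(g) <- c(fdim[1], fdim[2], fdim[4], fdim[3])
  aperm(g, c(1, 2, 4, 3))
}
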