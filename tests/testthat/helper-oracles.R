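# Independent per-pixel double-loop reference implementations of every
# training loss. Deliberately naive (explicit scalar loops, no shared code
# with the package internals) so they can serve as oracles.

EPS <- 1e-7

ref_dice <- function(y, p, eps = EPS) {
  d <- dim(y)
  per <- numeric(d[4])
  for (n in seq_len(d[4])) {
    num <- 0; den <- 0
    for (h in seq_len(d[1])) for (w in seq_len(d[2])) {
      num <- num + y[h, w, 1, n] * p[h, w, 1, n]
      den <- den + y[h, w, 1, n] + p[h, w, 1, n]
    }
    per[n] <- 1 - (2 * num + eps) / (den + eps)
  }
  mean(per)
}

ref_entropy <- function(p, mode = "single", eps = EPS) {
  d <- dim(p)
  per <- numeric(d[4])
  for (n in seq_len(d[4])) {
    s <- 0
    for (h in seq_len(d[1])) for (w in seq_len(d[2])) {
      v <- p[h, w, 1, n]
      s <- s - v * log(max(v, eps))
      if (mode == "full_binary") s <- s - (1 - v) * log(max(1 - v, eps))
    }
    per[n] <- s / (d[1] * d[2])
  }
  mean(per)
}

ref_advgen <- function(d, eps = EPS) {
  v <- as.vector(d)
  s <- 0
  for (i in seq_along(v)) s <- s - log(max(v[i], eps))
  s / length(v)
}

ref_mse <- function(x, xr) {
  d <- dim(x)
  per <- numeric(d[4])
  for (n in seq_len(d[4])) {
    s <- 0
    for (h in seq_len(d[1])) for (w in seq_len(d[2]))
      for (c in seq_len(d[3]))
        s <- s + (x[h, w, c, n] - xr[h, w, c, n])^2
    per[n] <- s / (d[1] * d[2] * d[3])
  }
  mean(per)
}

ref_disc <- function(d, z, eps = EPS) {
  v <- as.vector(d)
  s <- 0
  for (i in seq_along(v))
    s <- s - (z * log(max(v[i], eps)) + (1 - z) * log(max(1 - v[i], eps)))
  s / length(v)
}

ref_cluster <- function(f, l) {
  n <- nrow(f); d <- ncol(f)
  cen <- matrix(NA_real_, 2, d); cnt <- c(0, 0)
  for (j in 0:1) {
    s <- numeric(d)
    for (i in seq_len(n)) if (l[i] == j) {
      s <- s + f[i, ]; cnt[j + 1] <- cnt[j + 1] + 1
    }
    if (cnt[j + 1] > 0) cen[j + 1, ] <- s / cnt[j + 1]
  }
  tight <- 0
  for (i in seq_len(n))
    tight <- tight + sum(abs(f[i, ] - cen[l[i] + 1, ]))
  tight <- tight / n
  repel <- if (all(cnt > 0)) sum(abs(cen[1, ] - cen[2, ])) else 0
  tight - repel
}

# random fixtures used by oracle-equivalence loops
rand_mask_batch <- function(h, w, n)
  array(rbinom(h * w * n, 1, 0.4), c(h, w, 1, n))

rand_prob_batch <- function(h, w, n)
  array(runif(h * w * n, 0.001, 0.999), c(h, w, 1, n))

# the shared oracle-equivalence suite (acceptance criterion: every loss
# matches its double-loop reference within 1e-6 on >= 100 random tensors)
run_loss_oracle_suite <- function(n_cases = 100, seed = 42, tol = 1e-6) {
  set.seed(seed)
  worst <- 0
  for (k in seq_len(n_cases)) {
    h <- sample(2:8, 1); w <- sample(2:8, 1); n <- sample(1:3, 1)
    y <- rand_mask_batch(h, w, n)
    p <- rand_prob_batch(h, w, n)
    x <- array(runif(h * w * 3 * n), c(h, w, 3, n))
    xr <- array(runif(h * w * 3 * n), c(h, w, 3, n))
    dmap <- array(runif(h * w * n, 0.01, 0.99), c(h, w, n))
    fm <- matrix(rnorm(h * 2), ncol = 2)
    lb <- rbinom(h, 1, 0.5)
    mode <- if (k %% 2 == 0) "full_binary" else "single"
    worst <- max(worst, abs(dice_loss(y, p) - ref_dice(y, p)),
      abs(entropy_min_loss(p, mode) - ref_entropy(p, mode)),
      abs(segmentation_loss(y, p, mode) -
            (ref_dice(y, p) + ref_entropy(p, mode))),
      abs(adversarial_generator_loss(dmap) - ref_advgen(dmap)),
      abs(reconstruction_loss(x, xr) - ref_mse(x, xr)),
      abs(discriminator_loss(dmap, k %% 2) - ref_disc(dmap, k %% 2)),
      abs(clustering_loss(fm, NULL, lb, NULL) - ref_cluster(fm, lb)))
    if (worst > tol) break
  }
  worst
}

# a small two-domain benchmark for reuse across test files
tiny_benchmark <- function(seed = 11, n_source = 14, n_target = 12,
                           size = 32) {
  make_benchmark(n_source = n_source, n_target = n_target,
                 params = nuclei_geometry(size = size, n_range = c(5, 9),
                                          radius_range = c(3, 6)),
                 seed = seed)
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(epochs = 2, batch_size = 4, seed = 3, depth = 3, base = 8,
         disc_base = 8), list(...))
  do.call(train_config, args)
}
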