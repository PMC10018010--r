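#' @useDynLib nucadapt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- batch/array helpers ----------------------------------------------------

# Coerce an image/mask/feature array to the internal (H, W, C, N) layout.
# Accepts (H,W), (H,W,C) or (H,W,C,N); plain vectors are rejected.
as_batch <- function(x, channels = NULL) {
  if (is.null(dim(x))) stop("expected an array with dim (H,W[,C[,N]])")
  d <- dim(x)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected 2-4 dimensional array")
  if (!is.null(channels) && dim(x)[3] != channels)
    stop(sprintf("expected %d channel(s), got %d", channels, dim(x)[3]))
  x
}

batch_size <- function(x) dim(x)[4]

check_same_shape <- function(a, b, what = "arrays") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch between %s: (%s) vs (%s)", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ---- primitive ops ----------------------------------------------------------

conv2d <- function(x, w, b, stride = 1L, pad = 0L)
  .conv2d_forward_cpp(x, w, b, as.integer(stride), as.integer(pad))

conv2d_grad <- function(x, w, gy, stride = 1L, pad = 0L)
  .conv2d_backward_cpp(x, w, gy, as.integer(stride), as.integer(pad))

relu_fwd <- function(x) x * (x > 0)
relu_bwd <- function(gy, x) gy * (x > 0)

lrelu_fwd <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_bwd <- function(gy, x, slope = 0.2) gy * ifelse(x > 0, 1, slope)

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))

# ---- instance normalization --------------------------------------------------
# Per-sample, per-channel standardization with learned affine (gamma, beta).
# Keeps activations bounded so deep stacks cannot drift into saturated
# sigmoid regions; identical in train and eval mode (no running statistics),
# preserving the pure-function contract of the networks.

instnorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  mu <- colMeans(m)
  s <- sqrt(colMeans(m^2) - mu^2 + eps)
  xhat <- (m - rep(mu, each = d[1] * d[2])) / rep(s, each = d[1] * d[2])
  gc_ <- rep(gamma, d[4]); bc <- rep(beta, d[4])
  y <- xhat * rep(gc_, each = d[1] * d[2]) + rep(bc, each = d[1] * d[2])
  dim(y) <- d
  list(y = y, xhat = xhat, s = s)
}

instnorm_bwd <- function(dy, cache, gamma, xdim) {
  d <- xdim
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3] * d[4])
  dgamma_pc <- colSums(dym * cache$xhat)               # per channel x sample
  dbeta_pc <- colSums(dym)
  # reduce over the batch to per-channel parameter gradients
  dgamma <- rowSums(matrix(dgamma_pc, d[3], d[4]))
  dbeta <- rowSums(matrix(dbeta_pc, d[3], d[4]))
  gc_ <- rep(rep(gamma, d[4]), each = n)
  dxhat <- dym * gc_
  mh <- colMeans(dxhat)
  mxh <- colMeans(dxhat * cache$xhat)
  dx <- (dxhat - rep(mh, each = n) - cache$xhat * rep(mxh, each = n)) /
    rep(cache$s, each = n)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}
# backward expressed in terms of the forward output p
sigmoid_bwd <- function(gy, p) gy * p * (1 - p)

# ---- parameter init ---------------------------------------------------------

# He-style fan-in init for conv weights (kh, kw, Cin, Cout); biases get the
# usual small uniform init (also keeps preactivations off the exact ReLU
# kink, where subgradients are ambiguous).
init_conv <- function(kh, kw, cin, cout, gain = 2) {
  sd <- sqrt(gain / (kh * kw * cin))
  bound <- 1 / sqrt(kh * kw * cin)
  list(w = array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                 dim = c(kh, kw, cin, cout)),
       b = stats::runif(cout, -bound, bound))
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# elementwise sum of two same-shaped gradient lists (NULL-tolerant)
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
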