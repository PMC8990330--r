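# Numerical core of the ConvLSTM classifier: parameter initialization,
# forward pass, and backpropagation through time. Activation layout follows
# src/convops.cpp: feature maps are (B*H*W) x C matrices.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# one ConvLSTM layer: gates i, f, g, o in blocks of `filters` columns;
# forget-gate bias initialized to 1
init_convlstm_layer <- function(c_in, filters, kernel) {
  k2 <- kernel^2
  b <- numeric(4 * filters)
  b[(filters + 1):(2 * filters)] <- 1
  list(
    Wx = glorot(k2 * c_in, 4 * filters, k2 * c_in, filters),
    Wh = glorot(k2 * filters, 4 * filters, k2 * filters, filters),
    b = b, kernel = kernel, filters = filters, c_in = c_in
  )
}

init_dense <- function(n_in, n_out) {
  list(W = glorot(n_in, n_out, n_in, n_out), b = numeric(n_out))
}

# X: list of T (B*HW x C_in) matrices. Returns hidden sequence + cache.
# The cell-step arithmetic (patch extraction, gate GEMMs, nonlinearities)
# lives in src/convops.cpp.
convlstm_fwd <- function(X, layer, H, W, B) {
  f_n <- layer$filters
  HW <- H * W
  h <- matrix(0, B * HW, f_n)
  cc <- matrix(0, B * HW, f_n)
  Tn <- length(X)
  cache <- vector("list", Tn)
  hs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    st <- clstm_step_fwd(X[[t]], h, cc, layer$Wx, layer$Wh, layer$b,
                         H, W, B, layer$kernel)
    st$c_prev <- cc
    h <- st$h
    cc <- st$c
    cache[[t]] <- st
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

# dH: list of T gradients on the hidden sequence (zeros matrices allowed).
convlstm_bwd <- function(X, hs, cache, layer, H, W, B, dH, need_dx = FALSE) {
  f_n <- layer$filters
  HW <- H * W
  Tn <- length(X)
  dWx <- matrix(0, nrow(layer$Wx), ncol(layer$Wx))
  dWh <- matrix(0, nrow(layer$Wh), ncol(layer$Wh))
  db <- numeric(length(layer$b))
  dh_next <- matrix(0, B * HW, f_n)
  dc_next <- matrix(0, B * HW, f_n)
  dX <- if (need_dx) vector("list", Tn) else NULL
  for (t in rev(seq_len(Tn))) {
    st <- cache[[t]]
    dh <- dH[[t]] + dh_next
    h_prev <- if (t > 1L) hs[[t - 1L]] else matrix(0, B * HW, f_n)
    g <- clstm_step_bwd(X[[t]], h_prev, st$c_prev, st$gi, st$gf, st$gg,
                        st$go, st$tc, layer$Wx, layer$Wh, dh, dc_next,
                        H, W, B, layer$kernel, need_dx)
    dWx <- dWx + g$dWx
    dWh <- dWh + g$dWh
    db <- db + drop(g$db)
    dh_next <- g$dh_prev
    dc_next <- g$dc_prev
    if (need_dx) dX[[t]] <- g$dx
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# reshape (B*HW) x C activations to B x (HW*C) sample-major features
to_sample_major <- function(h, HW, B) {
  C <- ncol(h)
  out <- matrix(0, B, HW * C)
  for (c in seq_len(C))
    out[, ((c - 1L) * HW + 1L):(c * HW)] <- t(matrix(h[, c], HW, B))
  out
}

from_sample_major <- function(g, HW, B, C) {
  h <- matrix(0, B * HW, C)
  for (c in seq_len(C))
    h[, c] <- as.vector(t(g[, ((c - 1L) * HW + 1L):(c * HW), drop = FALSE]))
  h
}

adam_init <- function(params) {
  flat <- unlist(params, use.names = FALSE)
  list(m = numeric(length(flat)), v = numeric(length(flat)), t = 0L)
}

# params/grads as flat numeric vectors
adam_update <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-7) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flat, template) {
  out <- template
  pos <- 0L
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    n <- length(x)
    v <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(x)) dim(v) <- dim(x)
    v
  }
  out <- rebuild(template)
  stopifnot(pos == length(flat))
  out
}

# weighted binary cross-entropy; probabilities clipped away from {0,1}
weighted_bce <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
}
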