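# Minimal neural-network internals: dense layers, stacked GRU sequence
# encoder, manual backpropagation and Adam. Parameters live in nested
# lists of numeric arrays; the tree helpers below let the optimizer walk
# any parameter structure generically.

sigmoid <- function(x) 1 / (1 + exp(-x))

rand_mat <- function(nr, nc) {
  # Xavier/Glorot uniform
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(seq_along(a), function(i) tree_map(f, a[[i]]))
           else lapply(seq_along(a), function(i) tree_map(f, a[[i]], b[[i]]))
    names(out) <- names(a)
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

tree_zeros <- function(p) tree_map(function(x) x * 0, p)

tree_add <- function(a, b) tree_map(`+`, a, b)

tree_finite <- function(p) {
  ok <- TRUE
  tree_map(function(x) { if (!all(is.finite(x))) ok <<- FALSE; x }, p)
  ok
}

# ---- Adam ----------------------------------------------------------------

adam_new <- function(params, lr = 1e-3, weight_decay = 1e-4,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L,
       lr = lr, wd = weight_decay, b1 = beta1, b2 = beta2, eps = eps)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$b1; b2 <- opt$b2
  mh <- 1 / (1 - b1^opt$t); vh <- 1 / (1 - b2^opt$t)
  # update moments and parameters in one recursive pass
  step <- function(p, m, v, g) {
    if (is.list(p)) {
      ms <- vector("list", length(p)); vs <- ms; ps <- ms
      for (i in seq_along(p)) {
        r <- step(p[[i]], m[[i]], v[[i]], g[[i]])
        ms[[i]] <- r$m; vs[[i]] <- r$v; ps[[i]] <- r$p
      }
      names(ms) <- names(p); names(vs) <- names(p); names(ps) <- names(p)
      return(list(m = ms, v = vs, p = ps))
    }
    gd <- g + opt$wd * p
    m2 <- b1 * m + (1 - b1) * gd
    v2 <- b2 * v + (1 - b2) * gd^2
    list(m = m2, v = v2,
         p = p - opt$lr * (m2 * mh) / (sqrt(v2 * vh) + opt$eps))
  }
  r <- step(params, opt$m, opt$v, grads)
  opt$m <- r$m; opt$v <- r$v
  list(opt = opt, params = r$p)
}

# ---- MLP -----------------------------------------------------------------

mlp_new <- function(dims) {
  # dims: c(in, hidden..., out); ReLU hidden activations, linear output
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    layers[[i]] <- list(W = rand_mat(dims[i], dims[i + 1L]),
                        b = matrix(0, 1, dims[i + 1L]))
  }
  layers
}

mlp_forward <- function(mlp, X) {
  L <- length(mlp)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (i in seq_len(L)) {
    Z <- acts[[i]] %*% mlp[[i]]$W +
      matrix(mlp[[i]]$b, nrow(acts[[i]]), ncol(mlp[[i]]$b), byrow = TRUE)
    acts[[i + 1L]] <- if (i < L) pmax(Z, 0) else Z
  }
  list(out = acts[[L + 1L]], acts = acts)
}

mlp_backward <- function(mlp, cache, dY) {
  L <- length(mlp)
  grads <- vector("list", L)
  d <- dY
  for (i in rev(seq_len(L))) {
    if (i < L) d <- d * (cache$acts[[i + 1L]] > 0)
    grads[[i]] <- list(W = crossprod(cache$acts[[i]], d),
                       b = matrix(colSums(d), 1))
    d <- d %*% t(mlp[[i]]$W)
  }
  list(grads = grads, dX = d)
}

# ---- GRU -----------------------------------------------------------------
# Gate layout in the combined weight matrices: [reset | update | candidate].

gru_layer_new <- function(input_dim, hidden_dim) {
  list(W = rand_mat(input_dim, 3L * hidden_dim),
       U = rand_mat(hidden_dim, 3L * hidden_dim),
       b = matrix(0, 1, 3L * hidden_dim))
}

gru_new <- function(input_dim, hidden_dim, n_layers = 1L) {
  lapply(seq_len(n_layers), function(l)
    gru_layer_new(if (l == 1L) input_dim else hidden_dim, hidden_dim))
}

gru_cell_forward <- function(layer, X, h) {
  H <- ncol(h)
  A <- X %*% layer$W + matrix(layer$b, nrow(X), 3L * H, byrow = TRUE)
  Uh <- h %*% layer$U
  ir <- 1:H; iz <- (H + 1L):(2L * H); im <- (2L * H + 1L):(3L * H)
  r <- sigmoid(A[, ir, drop = FALSE] + Uh[, ir, drop = FALSE])
  z <- sigmoid(A[, iz, drop = FALSE] + Uh[, iz, drop = FALSE])
  n <- tanh(A[, im, drop = FALSE] + r * Uh[, im, drop = FALSE])
  hn <- (1 - z) * n + z * h
  list(h = hn, cache = list(X = X, h = h, r = r, z = z, n = n, Uh = Uh))
}

gru_cell_backward <- function(layer, cache, dh_next) {
  H <- ncol(cache$h)
  ir <- 1:H; iz <- (H + 1L):(2L * H); im <- (2L * H + 1L):(3L * H)
  r <- cache$r; z <- cache$z; n <- cache$n
  Uhn <- cache$Uh[, im, drop = FALSE]
  dn <- dh_next * (1 - z)
  dz <- dh_next * (cache$h - n)
  dh <- dh_next * z
  dan <- dn * (1 - n^2)
  dr <- dan * Uhn
  daz <- dz * z * (1 - z)
  dar <- dr * r * (1 - r)
  dA <- cbind(dar, daz, dan)
  dUh <- cbind(dar, daz, dan * r)
  dX <- dA %*% t(layer$W)
  dh <- dh + dUh %*% t(layer$U)
  list(dX = dX,
       dh = dh,
       grads = list(W = crossprod(cache$X, dA),
                    U = crossprod(cache$h, dUh),
                    b = matrix(colSums(dA), 1)))
}

# Full-sequence forward over a stacked GRU.
# xs: list over timesteps of (batch x input_dim) matrices.
# Returns top-layer states per step plus all caches for BPTT.
gru_forward <- function(gru, xs, h0 = NULL) {
  L <- length(gru); tau <- length(xs)
  B <- nrow(xs[[1L]]); H <- nrow(gru[[1L]]$U)
  h <- if (is.null(h0)) replicate(L, matrix(0, B, H), simplify = FALSE) else h0
  caches <- vector("list", tau)
  states <- vector("list", tau)
  for (t in seq_len(tau)) {
    x <- xs[[t]]
    caches[[t]] <- vector("list", L)
    for (l in seq_len(L)) {
      fc <- gru_cell_forward(gru[[l]], x, h[[l]])
      h[[l]] <- fc$h
      caches[[t]][[l]] <- fc$cache
      x <- fc$h
    }
    states[[t]] <- h[[L]]
  }
  list(states = states, caches = caches, h_final = h)
}

# BPTT: dstates is a list over timesteps of gradients w.r.t. the top-layer
# state at that step (NULL allowed). Returns parameter gradients.
gru_backward <- function(gru, fwd, dstates) {
  L <- length(gru); tau <- length(fwd$caches)
  H <- nrow(gru[[1L]]$U)
  B <- nrow(fwd$states[[1L]])
  grads <- tree_zeros(gru)
  dh <- replicate(L, matrix(0, B, H), simplify = FALSE)
  for (t in rev(seq_len(tau))) {
    dupper <- NULL  # gradient flowing into layer l's output at step t
    for (l in rev(seq_len(L))) {
      d_out <- dh[[l]]
      if (l == L && !is.null(dstates[[t]])) d_out <- d_out + dstates[[t]]
      if (!is.null(dupper)) d_out <- d_out + dupper
      bk <- gru_cell_backward(gru[[l]], fwd$caches[[t]][[l]], d_out)
      grads[[l]] <- tree_add(grads[[l]], bk$grads)
      dh[[l]] <- bk$dh
      dupper <- if (l > 1L) bk$dX else NULL
    }
  }
  grads
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
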