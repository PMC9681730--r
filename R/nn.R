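# Dense neural-network primitives with manual backpropagation.
# All layers are small (widths 64-320), so plain base-R matrix algebra is
# fast enough for batch-size-1 training on a single CPU.

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)
sigmoid <- function(x) 1 / (1 + exp(-x))

# uniform init in +-1/sqrt(fan_in), deterministic under the caller's RNG
init_mat <- function(nr, nc, fan_in = nr) {
  s <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

gcn_layer_dims <- function(cfg) {
  d0 <- cfg$node_embed_dim; d1 <- cfg$gcn1_dim; d2 <- cfg$gcn2_dim
  nl <- if (is.null(cfg$n_gcn_layers)) 2L else cfg$n_gcn_layers
  stopifnot(nl >= 1L)
  dims <- c(d0, rep(d1, nl - 1L), d2)   # e.g. 2 layers: 64 -> 128 -> 64
  dims
}

init_gcn_params <- function(vocab, cfg) {
  dims <- gcn_layer_dims(cfg)
  layers <- lapply(seq_len(length(dims) - 1L), function(l)
    list(W = init_mat(dims[l], dims[l + 1L]), b = numeric(dims[l + 1L]),
         B = init_mat(5L, dims[l + 1L], dims[l])))
  list(embed = init_mat(vocab, cfg$node_embed_dim, cfg$node_embed_dim),
       layers = layers)
}

init_lstm_params <- function(cfg) {
  de <- cfg$token_embed_dim; dh <- cfg$lstm_hidden
  dir <- function() {
    b <- numeric(4L * dh)
    b[(dh + 1L):(2L * dh)] <- 1   # forget-gate bias
    list(Wx = init_mat(de, 4L * dh, de), Wh = init_mat(dh, 4L * dh, dh), b = b)
  }
  list(embed = init_mat(41L, de, de), fwd = dir(), bwd = dir(),
       Wfc = init_mat(2L * cfg$lstm_hidden, cfg$linker_fc_dim),
       bfc = numeric(cfg$linker_fc_dim))
}

init_mlp_params <- function(input_dim, cfg) {
  list(W1 = init_mat(input_dim, cfg$mlp_hidden), b1 = numeric(cfg$mlp_hidden),
       W2 = init_mat(cfg$mlp_hidden, cfg$output_dim),
       b2 = numeric(cfg$output_dim))
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like)
  else if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
  else numeric(length(p))
}

map2_params <- function(a, b, f) {
  if (is.list(a)) Map(function(x, y) map2_params(x, y, f), a, b)
  else f(a, b)
}

sum_params <- function(p) {
  if (is.list(p)) sum(vapply(p, sum_params, numeric(1))) else sum(p)
}

# ---- graph convolution branch ------------------------------------------

#' Precompute the tensors a graph-convolution branch needs
#'
#' Builds the symmetric-normalized adjacency with self-loops,
#' D^-1/2 (A + I) D^-1/2, and the per-node bond-type aggregation matrix
#' Eb (n x 5) with Eb[i, b] = sum over neighbors j bonded to i by type b of
#' Ahat[i, j], used for the learned bond-type message term.
#' @param g a `molecular_graph`.
#' @return list with `codes1` (1-based node codes), `Ahat`, `Eb`, `n`.
#' @export
graph_tensors <- function(g) {
  n <- g$node_count
  A <- adjacency_matrix(g) + diag(n)
  dmh <- 1 / sqrt(rowSums(A))
  Ahat <- A * (dmh %o% dmh)
  Eb <- matrix(0, n, 5L)
  if (nrow(g$edges) > 0L) {
    for (k in seq_len(nrow(g$edges))) {
      i <- g$edges$i[k]; j <- g$edges$j[k]; b <- g$edges$code[k]
      Eb[i, b] <- Eb[i, b] + Ahat[i, j]
      Eb[j, b] <- Eb[j, b] + Ahat[j, i]
    }
  }
  list(codes1 = g$node_codes + 1L, Ahat = Ahat, Eb = Eb, n = n,
       kind = g$kind)
}

gcn_layer_forward <- function(H, gt, W, b, B, cfg) {
  M <- gt$Ahat %*% H
  Z <- M %*% W + matrix(b, nrow(M), length(b), byrow = TRUE)
  if (cfg$use_bond_encoding) Z <- Z + gt$Eb %*% B
  list(M = M, Z = Z, H = leaky_relu(Z, cfg$leaky_relu_slope))
}

gcn_layer_backward <- function(dH, cache, gt, W, cfg) {
  dZ <- dH * leaky_relu_grad(cache$Z, cfg$leaky_relu_slope)
  g <- list(W = crossprod(cache$M, dZ), b = colSums(dZ))
  g$B <- if (cfg$use_bond_encoding) crossprod(gt$Eb, dZ) else NULL
  dM <- dZ %*% t(W)
  g$dH_in <- gt$Ahat %*% dM   # Ahat symmetric
  g
}

pool_forward <- function(H, pooling) {
  switch(pooling,
    max  = list(h = apply(H, 2, max),
                arg = max.col(t(H), ties.method = "first")),
    mean = list(h = colMeans(H)),
    sum  = list(h = colSums(H)))
}

pool_backward <- function(dh, H, cache, pooling) {
  dH <- matrix(0, nrow(H), ncol(H))
  if (pooling == "max") {
    dH[cbind(cache$arg, seq_along(dh))] <- dh
  } else if (pooling == "mean") {
    dH[] <- rep(dh / nrow(H), each = nrow(H))
  } else {
    dH[] <- rep(dh, each = nrow(H))
  }
  dH
}

gcn_branch_forward <- function(gt, P, cfg) {
  if (any(gt$codes1 < 1L | gt$codes1 > nrow(P$embed)))
    stop("node code out of range for this branch (max ",
         nrow(P$embed) - 1L, ")")
  H <- P$embed[gt$codes1, , drop = FALSE]
  layers <- vector("list", length(P$layers))
  for (l in seq_along(P$layers)) {
    layers[[l]] <- gcn_layer_forward(H, gt, P$layers[[l]]$W,
                                     P$layers[[l]]$b, P$layers[[l]]$B, cfg)
    H <- layers[[l]]$H
  }
  pl <- pool_forward(H, cfg$pooling)
  list(out = pl$h, layers = layers, pool = pl, Hlast = H)
}

gcn_branch_backward <- function(dh, cache, gt, P, cfg, grad) {
  dH <- pool_backward(dh, cache$Hlast, cache$pool, cfg$pooling)
  for (l in rev(seq_along(P$layers))) {
    gl <- gcn_layer_backward(dH, cache$layers[[l]], gt, P$layers[[l]]$W, cfg)
    grad$layers[[l]]$W <- grad$layers[[l]]$W + gl$W
    grad$layers[[l]]$b <- grad$layers[[l]]$b + gl$b
    if (cfg$use_bond_encoding)
      grad$layers[[l]]$B <- grad$layers[[l]]$B + gl$B
    dH <- gl$dH_in
  }
  for (r in seq_along(gt$codes1))
    grad$embed[gt$codes1[r], ] <- grad$embed[gt$codes1[r], ] + dH[r, ]
  grad
}

# ---- bidirectional LSTM branch -----------------------------------------

lstm_dir_forward <- function(X, P, dh) {
  Tn <- nrow(X)
  h <- numeric(dh); c <- numeric(dh)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    a <- drop(X[t, ] %*% P$Wx + h %*% P$Wh) + P$b
    i <- sigmoid(a[1:dh]); f <- sigmoid(a[(dh + 1):(2 * dh)])
    o <- sigmoid(a[(2 * dh + 1):(3 * dh)]); g <- tanh(a[(3 * dh + 1):(4 * dh)])
    c_new <- f * c + i * g
    tc <- tanh(c_new)
    cache[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = c, tc = tc,
                       h_prev = h)
    c <- c_new; h <- o * tc
  }
  list(h = h, cache = cache)
}

lstm_dir_backward <- function(dh_final, X, P, fw, dh) {
  Tn <- nrow(X)
  gWx <- zero_like(P$Wx); gWh <- zero_like(P$Wh); gb <- zero_like(P$b)
  dX <- matrix(0, Tn, nrow(P$Wx))
  dhv <- dh_final; dc <- numeric(dh)
  for (t in rev(seq_len(Tn))) {
    cc <- fw$cache[[t]]
    do <- dhv * cc$tc
    dc <- dc + dhv * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g; df <- dc * cc$c_prev; dg <- dc * cc$i
    dc_prev <- dc * cc$f
    da <- c(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
            do * cc$o * (1 - cc$o), dg * (1 - cc$g^2))
    gWx <- gWx + X[t, ] %o% da
    gWh <- gWh + cc$h_prev %o% da
    gb <- gb + da
    dX[t, ] <- da %*% t(P$Wx)
    dhv <- drop(da %*% t(P$Wh))
    dc <- dc_prev
  }
  list(Wx = gWx, Wh = gWh, b = gb, dX = dX)
}

linker_branch_forward <- function(tokens, P, cfg) {
  dh <- cfg$lstm_hidden
  L <- tokens$true_length
  if (L == 0L) {
    hcat <- numeric(2L * dh)
    Zfc <- drop(hcat %*% P$Wfc) + P$bfc
    return(list(out = leaky_relu(Zfc, cfg$leaky_relu_slope), L = 0L,
                Zfc = Zfc, hcat = hcat))
  }
  codes1 <- tokens$codes[seq_len(L)] + 1L
  X <- P$embed[codes1, , drop = FALSE]
  fw <- lstm_dir_forward(X, P$fwd, dh)
  bw <- lstm_dir_forward(X[rev(seq_len(L)), , drop = FALSE], P$bwd, dh)
  hcat <- c(fw$h, bw$h)
  Zfc <- drop(hcat %*% P$Wfc) + P$bfc
  list(out = leaky_relu(Zfc, cfg$leaky_relu_slope), L = L, codes1 = codes1,
       X = X, fw = fw, bw = bw, hcat = hcat, Zfc = Zfc)
}

linker_branch_backward <- function(dh_out, cache, P, cfg, grad) {
  dZfc <- dh_out * leaky_relu_grad(cache$Zfc, cfg$leaky_relu_slope)
  grad$Wfc <- grad$Wfc + cache$hcat %o% dZfc
  grad$bfc <- grad$bfc + dZfc
  if (cache$L == 0L) return(grad)
  dhcat <- drop(dZfc %*% t(P$Wfc))
  nh <- cfg$lstm_hidden
  gf <- lstm_dir_backward(dhcat[1:nh], cache$X, P$fwd, cache$fw, nh)
  Xr <- cache$X[rev(seq_len(cache$L)), , drop = FALSE]
  gb <- lstm_dir_backward(dhcat[(nh + 1):(2 * nh)], Xr, P$bwd, cache$bw, nh)
  grad$fwd$Wx <- grad$fwd$Wx + gf$Wx; grad$fwd$Wh <- grad$fwd$Wh + gf$Wh
  grad$fwd$b <- grad$fwd$b + gf$b
  grad$bwd$Wx <- grad$bwd$Wx + gb$Wx; grad$bwd$Wh <- grad$bwd$Wh + gb$Wh
  grad$bwd$b <- grad$bwd$b + gb$b
  dX <- gf$dX + gb$dX[rev(seq_len(cache$L)), , drop = FALSE]
  for (r in seq_len(cache$L))
    grad$embed[cache$codes1[r], ] <- grad$embed[cache$codes1[r], ] + dX[r, ]
  grad
}

# ---- MLP head and loss --------------------------------------------------

mlp_forward <- function(x, P, cfg) {
  Z1 <- drop(x %*% P$W1) + P$b1
  H1 <- leaky_relu(Z1, cfg$leaky_relu_slope)
  logits <- drop(H1 %*% P$W2) + P$b2
  list(x = x, Z1 = Z1, H1 = H1, logits = logits)
}

mlp_backward <- function(dlogits, cache, P, cfg, grad) {
  grad$W2 <- grad$W2 + cache$H1 %o% dlogits
  grad$b2 <- grad$b2 + dlogits
  dH1 <- drop(dlogits %*% t(P$W2))
  dZ1 <- dH1 * leaky_relu_grad(cache$Z1, cfg$leaky_relu_slope)
  grad$W1 <- grad$W1 + cache$x %o% dZ1
  grad$b1 <- grad$b1 + dZ1
  list(grad = grad, dx = drop(dZ1 %*% t(P$W1)))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# weighted cross-entropy on 2-class logits; y in {0 (inactive), 1 (active)}
ce_loss_grad <- function(logits, y, weight) {
  p <- softmax(logits)
  onehot <- c(1 - y, y)   # class order: (inactive, active)
  loss <- -weight * log(max(p[y + 1L], 1e-12))
  list(loss = loss, dlogits = weight * (p - onehot), p_active = p[2L])
}

# ---- Adam ---------------------------------------------------------------

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v,
                     function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_params(params, upd, `-`)
  list(params = params, state = state)
}
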