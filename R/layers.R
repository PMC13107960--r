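# Neural-network primitives with hand-derived backward passes. Everything
# operates on plain base-R matrices; activations for a batch are stored
# flattened as (B*L) x d with row (b-1)*L + t holding position t of item b.
# Gradients were verified against central finite differences (see tests).

RMS_EPS <- 1e-6

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
silu <- function(x) x / (1 + exp(-x))
silu_grad <- function(x) { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) }

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- RMS / layer normalization ----

rmsnorm_fwd <- function(x, g) {
  r <- sqrt(rowMeans(x^2) + RMS_EPS)
  y <- sweep(x / r, 2, g, `*`)
  list(y = y, x = x, r = r, g = g)
}

rmsnorm_bwd <- function(cache, dy) {
  x <- cache$x; r <- cache$r; g <- cache$g
  d <- ncol(x)
  gdy <- sweep(dy, 2, g, `*`)
  dx <- gdy / r - x * (rowSums(gdy * x) / (d * r^3))
  dg <- colSums(dy * (x / r))
  list(dx = dx, dg = dg)
}

layernorm_fwd <- function(x, g) {
  mu <- rowMeans(x)
  xc <- x - mu
  r <- sqrt(rowMeans(xc^2) + RMS_EPS)
  y <- sweep(xc / r, 2, g, `*`)
  list(y = y, xc = xc, r = r, g = g)
}

layernorm_bwd <- function(cache, dy) {
  xc <- cache$xc; r <- cache$r; g <- cache$g
  d <- ncol(xc)
  gdy <- sweep(dy, 2, g, `*`)
  gdy_c <- gdy - rowMeans(gdy)
  dx <- gdy_c / r - xc * (rowSums(gdy * xc) / (d * r^3))
  dg <- colSums(dy * (xc / r))
  list(dx = dx, dg = dg)
}

norm_fwd <- function(x, g, kind) {
  if (kind == "rms") rmsnorm_fwd(x, g) else layernorm_fwd(x, g)
}
norm_bwd <- function(cache, dy, kind) {
  if (kind == "rms") rmsnorm_bwd(cache, dy) else layernorm_bwd(cache, dy)
}

## ---- multi-head causal self-attention ----

# x: (B*L) x d. Shared projections; causal mask within each sequence.
mha_fwd <- function(x, Wq, Wk, Wv, Wo, B, L, n_heads) {
  d <- ncol(x); dh <- d %/% n_heads
  Q <- x %*% Wq; K <- x %*% Wk; V <- x %*% Wv
  ctx <- matrix(0, nrow(x), d)
  A_list <- vector("list", B * n_heads)
  neg <- -1e30
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- (Q[rows, cols, drop = FALSE] %*% t(K[rows, cols, drop = FALSE])) / sqrt(dh)
      S[upper.tri(S)] <- neg                      # causal: t attends to <= t
      A <- softmax_rows(S)
      A_list[[(b - 1L) * n_heads + h]] <- A
      ctx[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
    }
  }
  out <- ctx %*% Wo
  list(y = out, x = x, Q = Q, K = K, V = V, ctx = ctx, A = A_list,
       B = B, L = L, n_heads = n_heads, Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo)
}

mha_bwd <- function(cache, dy) {
  x <- cache$x; B <- cache$B; L <- cache$L; nh <- cache$n_heads
  d <- ncol(x); dh <- d %/% nh
  dWo <- t(cache$ctx) %*% dy
  dctx <- dy %*% t(cache$Wo)
  dQ <- matrix(0, nrow(x), d); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[(b - 1L) * nh + h]]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dctx_h <- dctx[rows, cols, drop = FALSE]
      dA <- dctx_h %*% t(Vh)
      dV[rows, cols] <- t(A) %*% dctx_h
      dS <- A * (dA - rowSums(dA * A))            # softmax rows backward
      dQ[rows, cols] <- (dS %*% cache$K[rows, cols, drop = FALSE]) / sqrt(dh)
      dK[rows, cols] <- (t(dS) %*% cache$Q[rows, cols, drop = FALSE]) / sqrt(dh)
    }
  }
  dx <- dQ %*% t(cache$Wq) + dK %*% t(cache$Wk) + dV %*% t(cache$Wv)
  list(dx = dx,
       dWq = t(x) %*% dQ, dWk = t(x) %*% dK, dWv = t(x) %*% dV, dWo = dWo)
}

## ---- cross-attention over a pocket context ----

# x: (B*L) x d queries; ctxs: list of B matrices (L_p x d_p).
cross_attn_fwd <- function(x, ctxs, Wq, Wk, Wv, Wo, B, L, n_heads) {
  d <- ncol(x); dh <- d %/% n_heads
  Q <- x %*% Wq
  Ks <- lapply(ctxs, function(P) P %*% Wk)
  Vs <- lapply(ctxs, function(P) P %*% Wv)
  ctx <- matrix(0, nrow(x), d)
  A_list <- vector("list", B * n_heads)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- (Q[rows, cols, drop = FALSE] %*% t(Ks[[b]][, cols, drop = FALSE])) / sqrt(dh)
      A <- softmax_rows(S)
      A_list[[(b - 1L) * n_heads + h]] <- A
      ctx[rows, cols] <- A %*% Vs[[b]][, cols, drop = FALSE]
    }
  }
  list(y = ctx %*% Wo, x = x, Q = Q, Ks = Ks, Vs = Vs, ctxs = ctxs, ctx = ctx,
       A = A_list, B = B, L = L, n_heads = n_heads,
       Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo)
}

cross_attn_bwd <- function(cache, dy) {
  x <- cache$x; B <- cache$B; L <- cache$L; nh <- cache$n_heads
  d <- ncol(x); dh <- d %/% nh
  dWo <- t(cache$ctx) %*% dy
  dctx <- dy %*% t(cache$Wo)
  dQ <- matrix(0, nrow(x), d)
  dWk <- matrix(0, nrow(cache$Wk), ncol(cache$Wk))
  dWv <- matrix(0, nrow(cache$Wv), ncol(cache$Wv))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    dKb <- matrix(0, nrow(cache$Ks[[b]]), d)
    dVb <- matrix(0, nrow(cache$Vs[[b]]), d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[(b - 1L) * nh + h]]
      dctx_h <- dctx[rows, cols, drop = FALSE]
      Vh <- cache$Vs[[b]][, cols, drop = FALSE]
      dA <- dctx_h %*% t(Vh)
      dVb[, cols] <- t(A) %*% dctx_h
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- (dS %*% cache$Ks[[b]][, cols, drop = FALSE]) / sqrt(dh)
      dKb[, cols] <- (t(dS) %*% cache$Q[rows, cols, drop = FALSE]) / sqrt(dh)
    }
    dWk <- dWk + t(cache$ctxs[[b]]) %*% dKb
    dWv <- dWv + t(cache$ctxs[[b]]) %*% dVb
  }
  list(dx = dQ %*% t(cache$Wq),
       dWq = t(x) %*% dQ, dWk = dWk, dWv = dWv, dWo = dWo)
}

## ---- SwiGLU feed-forward ----

swiglu_fwd <- function(x, Wg, Wu, Wd) {
  u <- x %*% Wg; v <- x %*% Wu
  s <- silu(u)
  z <- s * v
  list(y = z %*% Wd, x = x, u = u, v = v, s = s, z = z,
       Wg = Wg, Wu = Wu, Wd = Wd)
}

swiglu_bwd <- function(cache, dy) {
  dz <- dy %*% t(cache$Wd)
  ds <- dz * cache$v
  dv <- dz * cache$s
  du <- ds * silu_grad(cache$u)
  list(dx = du %*% t(cache$Wg) + dv %*% t(cache$Wu),
       dWg = t(cache$x) %*% du, dWu = t(cache$x) %*% dv,
       dWd = t(cache$z) %*% dy)
}
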