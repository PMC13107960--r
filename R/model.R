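# The generator network: dual-stream decoder with a numerical-embedding
# channel. The fusion stream carries E_text + (raw + sign + magnitude)
# numerical increments; every block runs the shared-weight attention on both
# streams, isolates the differential H_diff = H_fusion - H_text, and updates
# each stream with residual + Norm + SwiGLU + Norm. With the numerical
# channel off the two streams coincide bitwise and the fusion path *is* a
# plain causal decoder (see the methods vignette for why the fusion update
# keeps the common-mode attention term alongside H_diff).

#' Model configuration
#'
#' @param vocab_size token-vocabulary size
#' @param d_model embedding width (divisible by `n_heads`)
#' @param n_layers number of decoder blocks
#' @param n_heads attention heads
#' @param d_ff SwiGLU inner width
#' @param K_bins learnable magnitude bins (soft quantization)
#' @param h_mag hidden width of the two magnitude MLPs
#' @param max_len maximum sequence length
#' @param pocket_dim width of pocket residue embeddings (0 disables
#'   conditioning)
#' @param norm `"rms"` or `"layer"` normalization
#' @return object of class `nmf_config`
#' @export
nmf_config <- function(vocab_size, d_model = 64L, n_layers = 2L, n_heads = 4L,
                       d_ff = 2L * d_model, K_bins = 16L, h_mag = 32L,
                       max_len = 256L, pocket_dim = 0L, norm = "rms") {
  if (d_model %% n_heads != 0)
    nmg_stop("config_error", "d_model must be divisible by n_heads")
  if (K_bins < 2L) nmg_stop("config_error", "K_bins must be >= 2")
  stopifnot(vocab_size > 0, n_layers > 0, max_len > 0, norm %in% c("rms", "layer"))
  structure(list(vocab_size = as.integer(vocab_size), d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d_ff = as.integer(d_ff), K_bins = as.integer(K_bins),
                 h_mag = as.integer(h_mag), max_len = as.integer(max_len),
                 pocket_dim = as.integer(pocket_dim), norm = norm),
            class = "nmf_config")
}

rmat <- function(n, m, sd = 0.02) matrix(stats::rnorm(n * m, sd = sd), n, m)

#' Initialize model parameters
#' @param config an `nmf_config`
#' @param seed integer seed
#' @return named list of parameter arrays
#' @export
nmf_init_params <- function(config, seed = 0L) {
  set.seed(as.integer(seed))
  d <- config$d_model; K <- config$K_bins; h <- config$h_mag
  p <- list(
    tok_emb = rmat(config$vocab_size, d),
    pos_emb = rmat(config$max_len, d),
    sign_emb = rmat(3L, d),            # rows: sign -1, 0, +1
    q_W1 = stats::rnorm(h, sd = 0.5), q_b1 = numeric(h),
    q_W2 = rmat(h, K, sd = 0.2), q_b2 = numeric(K),
    r_W1 = stats::rnorm(h, sd = 0.5), r_b1 = numeric(h),
    r_W2 = rmat(h, K, sd = 0.2), r_b2 = numeric(K),
    v_q = rmat(K, d), v_r = rmat(K, d),
    lambda = 1.0,
    ln_f = rep(1, d),
    head_tok = rmat(d, config$vocab_size), head_tok_b = numeric(config$vocab_size),
    head_num = rmat(d, 1L), head_num_b = 0.0
  )
  for (l in seq_len(config$n_layers)) {
    p[[paste0("L", l, ".Wq")]] <- rmat(d, d)
    p[[paste0("L", l, ".Wk")]] <- rmat(d, d)
    p[[paste0("L", l, ".Wv")]] <- rmat(d, d)
    p[[paste0("L", l, ".Wo")]] <- rmat(d, d)
    p[[paste0("L", l, ".ln1")]] <- rep(1, d)
    p[[paste0("L", l, ".Wg")]] <- rmat(d, config$d_ff)
    p[[paste0("L", l, ".Wu")]] <- rmat(d, config$d_ff)
    p[[paste0("L", l, ".Wd")]] <- rmat(config$d_ff, d)
    p[[paste0("L", l, ".ln2")]] <- rep(1, d)
  }
  if (config$pocket_dim > 0L) {
    p$c_ln <- rep(1, d)
    p$c_Wq <- rmat(d, d)
    p$c_Wk <- rmat(config$pocket_dim, d)
    p$c_Wv <- rmat(config$pocket_dim, d)
    p$c_Wo <- matrix(0, d, d)   # zero-initialized gate: identity at step 0
  }
  p
}

#' Attach pocket-conditioning parameters to an unconditional model
#' @param model a `nummolgen_model`
#' @param pocket_dim residue-embedding width
#' @param seed seed for the new projections
#' @return the extended model
#' @export
nmf_add_pocket_params <- function(model, pocket_dim, seed = 0L) {
  stopifnot(inherits(model, "nummolgen_model"))
  set.seed(as.integer(seed))
  d <- model$config$d_model
  model$config$pocket_dim <- as.integer(pocket_dim)
  model$params$c_ln <- rep(1, d)
  model$params$c_Wq <- rmat(d, d)
  model$params$c_Wk <- rmat(pocket_dim, d)
  model$params$c_Wv <- rmat(pocket_dim, d)
  model$params$c_Wo <- matrix(0, d, d)
  model
}

## ---- numerical embedding (exported op) ----

#' Numerical embedding channel
#'
#' Decomposes per-position scalars into raw injection (the scalar broadcast
#' over all embedding coordinates and added to the token embedding), a
#' discrete sign embedding, and a soft magnitude-quantization embedding
#' (two GELU-MLP softmaxes over K learnable bins, the second table scaled by
#' a learnable lambda).
#'
#' @param E_text L x d token(+position) embeddings
#' @param numeric_values length-L scalars
#' @param params model parameter list (uses sign_emb, q_*/r_* MLPs, v_q, v_r,
#'   lambda)
#' @param cache keep intermediates for the backward pass
#' @return list with `e_raw`, `e_sign`, `e_mag`, `e_num` (each L x d) and,
#'   for inspection, the bin weights `p_q`, `p_r`
#' @export
numerical_embedding <- function(E_text, numeric_values, params, cache = FALSE) {
  if (any(!is.finite(numeric_values)))
    nmg_stop("numeric_domain", "numeric inputs must be finite")
  n <- as.numeric(numeric_values)
  stopifnot(length(n) == nrow(E_text))
  e_raw <- E_text + n                       # column-wise broadcast over d
  sidx <- sign(n) + 2L                      # -1,0,+1 -> rows 1,2,3
  e_sign <- params$sign_emb[sidx, , drop = FALSE]
  a <- abs(n)
  zq <- outer(a, params$q_W1) + matrix(params$q_b1, length(n), length(params$q_b1), byrow = TRUE)
  uq <- gelu(zq)
  lq <- uq %*% params$q_W2 + matrix(params$q_b2, length(n), ncol(params$q_W2), byrow = TRUE)
  p_q <- softmax_rows(lq)
  zr <- outer(a, params$r_W1) + matrix(params$r_b1, length(n), length(params$r_b1), byrow = TRUE)
  ur <- gelu(zr)
  lr <- ur %*% params$r_W2 + matrix(params$r_b2, length(n), ncol(params$r_W2), byrow = TRUE)
  p_r <- softmax_rows(lr)
  mag_q <- p_q %*% params$v_q
  mag_r <- p_r %*% params$v_r
  e_mag <- mag_q + params$lambda * mag_r
  out <- list(e_raw = e_raw, e_sign = e_sign, e_mag = e_mag,
              e_num = e_raw + e_sign + e_mag, p_q = p_q, p_r = p_r)
  if (cache) out <- c(out, list(n = n, a = a, sidx = sidx, zq = zq, uq = uq,
                                zr = zr, ur = ur, mag_r = mag_r))
  out
}

num_embed_bwd <- function(cache, d_incr, params, grads) {
  # d_incr: gradient wrt the numerical increment (n + e_sign + e_mag)
  L <- length(cache$n)
  for (s in 1:3) {
    rows <- which(cache$sidx == s)
    if (length(rows))
      grads$sign_emb[s, ] <- grads$sign_emb[s, ] +
        colSums(d_incr[rows, , drop = FALSE])
  }
  # magnitude: e_mag = p_q v_q + lambda p_r v_r
  grads$v_q <- grads$v_q + t(cache$p_q) %*% d_incr
  grads$v_r <- grads$v_r + params$lambda * (t(cache$p_r) %*% d_incr)
  grads$lambda <- grads$lambda + sum(d_incr * cache$mag_r)
  dp_q <- d_incr %*% t(params$v_q)
  dp_r <- params$lambda * (d_incr %*% t(params$v_r))
  dlq <- cache$p_q * (dp_q - rowSums(dp_q * cache$p_q))
  dlr <- cache$p_r * (dp_r - rowSums(dp_r * cache$p_r))
  grads$q_W2 <- grads$q_W2 + t(cache$uq) %*% dlq
  grads$q_b2 <- grads$q_b2 + colSums(dlq)
  grads$r_W2 <- grads$r_W2 + t(cache$ur) %*% dlr
  grads$r_b2 <- grads$r_b2 + colSums(dlr)
  duq <- dlq %*% t(params$q_W2)
  dur <- dlr %*% t(params$r_W2)
  dzq <- duq * gelu_grad(cache$zq)
  dzr <- dur * gelu_grad(cache$zr)
  grads$q_W1 <- grads$q_W1 + colSums(dzq * cache$a)
  grads$q_b1 <- grads$q_b1 + colSums(dzq)
  grads$r_W1 <- grads$r_W1 + colSums(dzr * cache$a)
  grads$r_b1 <- grads$r_b1 + colSums(dzr)
  grads
}

## ---- full forward ----

#' Forward pass of the dual-stream model
#'
#' @param params parameter list
#' @param config an `nmf_config`
#' @param batch result of [pad_batch()]
#' @param pockets optional list of B pocket matrices (L_p x pocket_dim)
#' @param channel_on if FALSE, the numerical channel is forced off
#'   (E_fusion := E_text); both streams then coincide bitwise
#' @param want_cache keep intermediates for the backward pass
#' @param want_streams keep per-block stream states (H_text/H_fusion/H_diff)
#' @return list with `logits` ((B*L) x V), `numeric_preds` (length B*L),
#'   `hidden`, optionally `cache` and `streams`
#' @export
nmf_forward <- function(params, config, batch, pockets = NULL,
                        channel_on = TRUE, want_cache = FALSE,
                        want_streams = FALSE) {
  B <- nrow(batch$text_ids); L <- ncol(batch$text_ids)
  if (L > config$max_len)
    nmg_stop("contract_violation",
             sprintf("sequence length %d exceeds max_len %d", L, config$max_len))
  d <- config$d_model
  ids <- as.integer(t(batch$text_ids))          # flatten row-major: b-major
  # rows of flattened activations: (b-1)*L + t
  E_text <- params$tok_emb[ids + 1L, , drop = FALSE] +
    params$pos_emb[rep(seq_len(L), B), , drop = FALSE]
  nums <- as.numeric(t(batch$numeric_values))

  ne <- NULL
  if (channel_on) {
    ne <- numerical_embedding(E_text, nums, params, cache = TRUE)
    E_fusion <- E_text + (nums + (ne$e_num - ne$e_raw))  # n*1 + e_sign + e_mag
  } else {
    E_fusion <- E_text
  }

  xattn <- NULL
  if (!is.null(pockets)) {
    if (config$pocket_dim <= 0L)
      nmg_stop("config_error", "model has no pocket-conditioning parameters")
    if (length(pockets) == 1L && B > 1L) pockets <- rep(pockets, B)
    if (length(pockets) != B)
      nmg_stop("contract_violation", "need one pocket context per batch item")
    for (P in pockets) if (ncol(P) != config$pocket_dim)
      nmg_stop("config_error",
               sprintf("pocket embedding dim %d != configured pocket_dim %d",
                       ncol(P), config$pocket_dim))
    cn <- norm_fwd(E_fusion, params$c_ln, config$norm)
    ca <- cross_attn_fwd(cn$y, pockets, params$c_Wq, params$c_Wk, params$c_Wv,
                         params$c_Wo, B, L, config$n_heads)
    E_fusion <- E_fusion + ca$y
    xattn <- list(cn = cn, ca = ca)
  }

  # Both streams share one update rule and one weight set, so the fusion
  # update Norm(E_fusion + H_fusion) decomposes exactly as
  # Norm(E_fusion + H_text + H_diff): the text stream is the common-mode
  # baseline and never alters the fusion path's value. It is therefore only
  # materialized when stream diagnostics are requested (or when the
  # numerical channel is off, in which case the streams coincide bitwise).
  Tcur <- E_text; Fcur <- E_fusion
  run_text <- want_streams
  blocks <- vector("list", config$n_layers)
  streams <- if (want_streams) vector("list", config$n_layers) else NULL
  for (l in seq_len(config$n_layers)) {
    pl <- function(nm) params[[paste0("L", l, ".", nm)]]
    identical_streams <- !channel_on && is.null(pockets)
    af <- mha_fwd(Fcur, pl("Wq"), pl("Wk"), pl("Wv"), pl("Wo"), B, L, config$n_heads)
    nf1 <- norm_fwd(Fcur + af$y, pl("ln1"), config$norm)
    sf <- swiglu_fwd(nf1$y, pl("Wg"), pl("Wu"), pl("Wd"))
    nf2 <- norm_fwd(nf1$y + sf$y, pl("ln2"), config$norm)
    if (run_text) {
      if (identical_streams) {
        at <- af; nt2y <- nf2$y
      } else {
        at <- mha_fwd(Tcur, pl("Wq"), pl("Wk"), pl("Wv"), pl("Wo"), B, L, config$n_heads)
        nt1 <- norm_fwd(Tcur + at$y, pl("ln1"), config$norm)
        st <- swiglu_fwd(nt1$y, pl("Wg"), pl("Wu"), pl("Wd"))
        nt2y <- norm_fwd(nt1$y + st$y, pl("ln2"), config$norm)$y
      }
      streams[[l]] <- list(H_text = at$y, H_fusion = af$y,
                           H_diff = af$y - at$y,
                           E_prime = nf1$y, T_out = nt2y, F_out = nf2$y)
      Tcur <- nt2y
    }
    blocks[[l]] <- list(af = af, nf1 = nf1, sf = sf, nf2 = nf2, Fin = Fcur)
    Fcur <- nf2$y
  }
  fin <- norm_fwd(Fcur, params$ln_f, config$norm)
  logits <- fin$y %*% params$head_tok +
    matrix(params$head_tok_b, nrow(fin$y), config$vocab_size, byrow = TRUE)
  numeric_preds <- as.numeric(fin$y %*% params$head_num) + params$head_num_b
  out <- list(logits = logits, numeric_preds = numeric_preds, hidden = fin$y,
              B = B, L = L)
  if (want_streams) out$streams <- streams
  if (want_cache)
    out$cache <- list(ids = ids, nums = nums, ne = ne, xattn = xattn,
                      blocks = blocks, fin = fin, E_text = E_text,
                      channel_on = channel_on, B = B, L = L,
                      pockets = pockets)
  out
}

## ---- full backward ----

# dlogits: (B*L) x V; dnum: length B*L. Returns gradient list shaped like
# params (entries absent from the graph stay zero).
nmf_backward <- function(params, config, fwd, dlogits, dnum) {
  cache <- fwd$cache
  B <- cache$B; L <- cache$L; d <- config$d_model
  grads <- lapply(params, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x)))

  fin <- cache$fin
  grads$head_tok <- t(fin$y) %*% dlogits
  grads$head_tok_b <- colSums(dlogits)
  grads$head_num <- matrix(as.numeric(t(fin$y) %*% dnum), ncol = 1)
  grads$head_num_b <- sum(dnum)
  dfin <- dlogits %*% t(params$head_tok) + outer(dnum, as.numeric(params$head_num))
  nb <- norm_bwd(fin, dfin, config$norm)
  grads$ln_f <- grads$ln_f + nb$dg
  dF <- nb$dx

  # Only the fusion path carries loss gradient (the text stream is the
  # common-mode baseline; see forward).
  for (l in rev(seq_len(config$n_layers))) {
    bl <- cache$blocks[[l]]
    nm <- function(s) paste0("L", l, ".", s)
    n2f <- norm_bwd(bl$nf2, dF, config$norm)
    grads[[nm("ln2")]] <- grads[[nm("ln2")]] + n2f$dg
    swf <- swiglu_bwd(bl$sf, n2f$dx)
    grads[[nm("Wg")]] <- grads[[nm("Wg")]] + swf$dWg
    grads[[nm("Wu")]] <- grads[[nm("Wu")]] + swf$dWu
    grads[[nm("Wd")]] <- grads[[nm("Wd")]] + swf$dWd
    dnf1 <- n2f$dx + swf$dx
    n1f <- norm_bwd(bl$nf1, dnf1, config$norm)
    grads[[nm("ln1")]] <- grads[[nm("ln1")]] + n1f$dg
    af <- mha_bwd(bl$af, n1f$dx)
    grads[[nm("Wq")]] <- grads[[nm("Wq")]] + af$dWq
    grads[[nm("Wk")]] <- grads[[nm("Wk")]] + af$dWk
    grads[[nm("Wv")]] <- grads[[nm("Wv")]] + af$dWv
    grads[[nm("Wo")]] <- grads[[nm("Wo")]] + af$dWo
    dF <- n1f$dx + af$dx
  }

  # cross-attention (applied to the fusion embedding)
  if (!is.null(cache$xattn)) {
    ca <- cross_attn_bwd(cache$xattn$ca, dF)
    grads$c_Wq <- grads$c_Wq + ca$dWq
    grads$c_Wk <- grads$c_Wk + ca$dWk
    grads$c_Wv <- grads$c_Wv + ca$dWv
    grads$c_Wo <- grads$c_Wo + ca$dWo
    cn <- norm_bwd(cache$xattn$cn, ca$dx, config$norm)
    grads$c_ln <- grads$c_ln + cn$dg
    dF <- dF + cn$dx          # residual: E_fusion + gate(...)
  }

  # embedding layer: E_fusion = E_text + incr (incr = n + e_sign + e_mag)
  dE_text <- dF
  if (cache$channel_on)
    grads <- num_embed_bwd(cache$ne, dF, params, grads)

  # scatter-add into token/position embeddings
  ids1 <- cache$ids + 1L
  agg <- rowsum(dE_text, group = ids1)
  tids <- as.integer(rownames(agg))
  grads$tok_emb[tids, ] <- grads$tok_emb[tids, ] + agg
  aggp <- rowsum(dE_text, group = rep(seq_len(L), B))
  grads$pos_emb[seq_len(L), ] <- grads$pos_emb[seq_len(L), ] + aggp
  grads
}
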