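tiny_config <- function(V = 18L, pocket_dim = 0L)
  nmf_config(vocab_size = V, d_model = 16L, n_layers = 2L, n_heads = 2L,
             d_ff = 24L, K_bins = 4L, h_mag = 6L, max_len = 12L,
             pocket_dim = pocket_dim)

tiny_batch <- function(V = 18L, B = 2L, L = 7L, seed = 3L) {
  set.seed(seed)
  list(text_ids = matrix(sample(0:(V - 1L), B * L, TRUE), B, L),
       numeric_values = matrix(sample(0:3, B * L, TRUE) * 1.0, B, L),
       mask = matrix(TRUE, B, L), lengths = rep(L, B))
}

test_that("numerical embedding decomposes into raw, sign and magnitude channels", {
  config <- tiny_config()
  params <- nmf_init_params(config, seed = 1L)
  set.seed(9)
  E <- matrix(rnorm(8 * 16), 8, 16)
  n <- c(0, 1, 5, 9, 2, 0, 3, 7)
  ne <- numerical_embedding(E, n, params)
  # zero scalar: raw injection leaves the token embedding untouched
  expect_identical(ne$e_raw[1, ], E[1, ])
  expect_identical(ne$e_raw[6, ], E[6, ])
  # raw injection adds the scalar to every coordinate
  expect_equal(ne$e_raw[3, ], E[3, ] + 5)
  # sign embedding depends only on the sign
  pos_rows <- which(n > 0)
  for (r in pos_rows[-1])
    expect_identical(ne$e_sign[r, ], ne$e_sign[pos_rows[1], ])
  expect_false(identical(ne$e_sign[1, ], ne$e_sign[2, ]))
  # composition
  expect_equal(ne$e_num, ne$e_raw + ne$e_sign + ne$e_mag)
  expect_error(numerical_embedding(E, c(n[-1], NaN), params),
               class = "nummolgen_numeric_domain")
})

test_that("soft bin assignments are normalized and sign-consistent over a range", {
  config <- tiny_config()
  params <- nmf_init_params(config, seed = 2L)
  set.seed(11)
  mags <- runif(1000, 0, 12)
  E <- matrix(0, 1000, 16)
  ne <- numerical_embedding(E, mags, params)
  expect_true(all(abs(rowSums(ne$p_q) - 1) < 1e-6))
  expect_true(all(abs(rowSums(ne$p_r) - 1) < 1e-6))
  # e_sign over the integers -9..9 takes exactly three distinct rows
  n <- -9:9
  ne2 <- numerical_embedding(matrix(0, length(n), 16), abs(n) * sign(n), params)
  expect_identical(nrow(unique(ne2$e_sign)), 3L)
  for (i in seq_along(n)) {
    ref <- params$sign_emb[sign(n[i]) + 2L, ]
    expect_identical(ne2$e_sign[i, ], ref)
  }
})

test_that("magnitude embedding is continuous in |n|", {
  config <- tiny_config()
  params <- nmf_init_params(config, seed = 3L)
  eps <- 1e-4
  base <- c(0.5, 2, 5, 8.3)
  n1 <- numerical_embedding(matrix(0, 4, 16), base, params)
  n2 <- numerical_embedding(matrix(0, 4, 16), base + eps, params)
  deltas <- sqrt(rowSums((n2$e_mag - n1$e_mag)^2))
  # smoke bound on the local constant; the map must not jump between bins
  expect_true(all(deltas <= 50 * eps))
})

test_that("analytic gradients match central finite differences", {
  V <- 18L
  config <- tiny_config(V, pocket_dim = 5L)
  params <- nmf_init_params(config, seed = 7L)
  set.seed(21)
  params$c_Wo <- matrix(rnorm(256, sd = 0.05), 16, 16)  # open the gate
  batch <- tiny_batch(V)
  batch$mask[2, 6:7] <- FALSE
  pockets <- lapply(1:2, function(b) matrix(rnorm(20), 4, 5))
  num_id <- 3L
  lossfn <- function(p) {
    fwd <- nmf_forward(p, config, batch, pockets = pockets)
    composite_loss(fwd$logits, fwd$numeric_preds, batch, num_id)$total
  }
  fwd <- nmf_forward(params, config, batch, pockets = pockets, want_cache = TRUE)
  cl <- composite_loss(fwd$logits, fwd$numeric_preds, batch, num_id,
                       want_grads = TRUE)
  grads <- nummolgen:::nmf_backward(params, config, fwd, cl$dlogits, cl$dnum)
  eps <- 1e-5
  set.seed(31)
  for (k in names(params)) {
    x <- params[[k]]
    idx <- if (length(x) > 3) sample(length(x), 3) else seq_along(x)
    for (i in idx) {
      p2 <- params; p2[[k]][i] <- p2[[k]][i] + eps
      p3 <- params; p3[[k]][i] <- p3[[k]][i] - eps
      fd <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      an <- grads[[k]][i]
      expect_lt(abs(fd - an) / max(1e-4, abs(fd) + abs(an)), 1e-3,
                label = sprintf("grad %s[%d]", k, i))
    }
  }
})

test_that("with the numerical channel off the model is exactly a plain decoder", {
  V <- 18L
  config <- tiny_config(V)
  params <- nmf_init_params(config, seed = 13L)
  batch <- tiny_batch(V)
  fwd <- nmf_forward(params, config, batch, channel_on = FALSE,
                     want_streams = TRUE)
  for (bl in fwd$streams) {
    expect_identical(bl$H_diff, matrix(0, nrow(bl$H_diff), ncol(bl$H_diff)))
    expect_identical(bl$T_out, bl$F_out)
  }
  plain <- reference_plain_decoder(params, config, batch)
  expect_equal(fwd$logits, plain, tolerance = 1e-12)
})

test_that("attention is causal: later tokens never affect earlier outputs", {
  V <- 18L
  config <- tiny_config(V)
  params <- nmf_init_params(config, seed = 17L)
  batch <- tiny_batch(V)
  base <- nmf_forward(params, config, batch)
  for (t_perturb in c(4L, 6L)) {
    b2 <- batch
    b2$text_ids[1, t_perturb] <- (b2$text_ids[1, t_perturb] + 5L) %% V
    b2$numeric_values[1, t_perturb] <- b2$numeric_values[1, t_perturb] + 2
    alt <- nmf_forward(params, config, b2)
    rows <- 1:(t_perturb - 1L)             # positions strictly before the edit
    expect_equal(base$logits[rows, ], alt$logits[rows, ], tolerance = 1e-12)
    expect_equal(base$numeric_preds[rows], alt$numeric_preds[rows],
                 tolerance = 1e-12)
    expect_gt(max(abs(base$logits[t_perturb, ] - alt$logits[t_perturb, ])), 0)
  }
})

test_that("forward is deterministic with normalized token distributions", {
  V <- 18L
  config <- tiny_config(V)
  params <- nmf_init_params(config, seed = 19L)
  batch <- tiny_batch(V)
  f1 <- nmf_forward(params, config, batch)
  f2 <- nmf_forward(params, config, batch)
  expect_identical(f1$logits, f2$logits)
  expect_identical(f1$numeric_preds, f2$numeric_preds)
  expect_true(all(is.finite(f1$logits)))
  P <- nummolgen:::softmax_rows(f1$logits)
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  # over-length contract
  long <- tiny_batch(V, B = 1L, L = 13L)
  expect_error(nmf_forward(params, config, long),
               class = "nummolgen_contract_violation")
})

test_that("incremental decoding reproduces the full forward pass", {
  V <- 18L
  config <- tiny_config(V)
  params <- nmf_init_params(config, seed = 23L)
  batch <- tiny_batch(V, B = 2L, L = 7L)
  full <- nmf_forward(params, config, batch)
  st <- nummolgen:::decode_init(params, config, 2L)
  inc <- matrix(NA_real_, 2L * 7L, config$vocab_size)
  for (t in 1:7) {
    stepped <- nummolgen:::decode_step(st, batch$text_ids[, t],
                                       batch$numeric_values[, t])
    st <- stepped$state
    inc[c(t, 7 + t), ] <- stepped$logits
  }
  expect_equal(full$logits, inc, tolerance = 1e-10)
})

test_that("gated pocket cross-attention is an exact identity at initialization", {
  V <- 18L
  config <- tiny_config(V, pocket_dim = 5L)
  params <- nmf_init_params(config, seed = 29L)   # c_Wo is zero here
  batch <- tiny_batch(V)
  set.seed(5)
  pockets <- lapply(1:2, function(b) matrix(rnorm(20), 4, 5))
  with_p <- nmf_forward(params, config, batch, pockets = pockets)
  without <- nmf_forward(params, config, batch)
  expect_identical(with_p$logits, without$logits)
  # open the gate: the context must actually be consumed
  set.seed(6)
  params$c_Wo <- matrix(rnorm(256, sd = 0.1), 16, 16)
  open1 <- nmf_forward(params, config, batch, pockets = pockets)
  other <- lapply(pockets, function(P) P + 0.5)
  open2 <- nmf_forward(params, config, batch, pockets = other)
  expect_gt(max(abs(open1$logits - open2$logits)), 1e-8)
  # residues form a set: attention is invariant to row permutation
  perm <- lapply(pockets, function(P) P[c(2, 1, 4, 3), ])
  open3 <- nmf_forward(params, config, batch, pockets = perm)
  expect_equal(open1$logits, open3$logits, tolerance = 1e-12)
  # single-residue context: attention collapses onto that residue
  one_res <- lapply(1:2, function(b) matrix(rnorm(5), 1, 5))
  f1 <- nmf_forward(params, config, batch, pockets = one_res)
  expect_true(all(is.finite(f1$logits)))
  # dimension mismatch is a configuration error
  bad <- lapply(1:2, function(b) matrix(rnorm(12), 4, 3))
  expect_error(nmf_forward(params, config, batch, pockets = bad),
               class = "nummolgen_config_error")
})
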