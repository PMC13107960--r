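test_that("composite loss obeys its algebra", {
  V <- 10L; B <- 2L; L <- 6L
  set.seed(4)
  batch <- list(text_ids = matrix(sample(0:(V - 1L), B * L, TRUE), B, L),
                numeric_values = matrix(0, B, L),
                mask = matrix(TRUE, B, L), lengths = rep(L, B))
  num_id <- 3L
  batch$text_ids[1, 4] <- num_id
  batch$numeric_values[1, 4] <- 2
  # uniform logits: CE is exactly log V
  logits <- matrix(0, B * L, V)
  preds <- numeric(B * L)
  preds[3] <- 2                       # exact numeric prediction at t=3 (next is [NUM])
  cl <- composite_loss(logits, preds, batch, num_id)
  expect_equal(cl$ce_token, log(V), tolerance = 1e-6)
  expect_identical(cl$mse_numeric, 0)
  expect_identical(cl$total, cl$ce_token + cl$mse_numeric)
  # wrong numeric prediction contributes its squared error
  preds[3] <- 0
  cl2 <- composite_loss(logits, preds, batch, num_id)
  expect_equal(cl2$mse_numeric, 4)
  expect_equal(cl2$total, cl2$ce_token + cl2$mse_numeric)
  # random case: additivity and non-negativity
  set.seed(8)
  logits <- matrix(rnorm(B * L * V), B * L, V)
  cl3 <- composite_loss(logits, rnorm(B * L), batch, num_id)
  expect_gte(cl3$ce_token, 0)
  expect_gte(cl3$mse_numeric, 0)
  expect_equal(cl3$total, cl3$ce_token + cl3$mse_numeric)
  # degenerate mask
  batch$mask[] <- FALSE
  expect_error(composite_loss(logits, preds, batch, num_id),
               class = "nummolgen_degenerate_batch")
})

test_that("pretraining is seed-deterministic and lr=0 is a no-op", {
  fx <- fx_encoded(12L, seed = 2L)
  config <- nmf_config(vocab_size = length(fx$tv$tokens), d_model = 16L,
                       n_layers = 1L, n_heads = 2L, max_len = 160L)
  m1 <- nmf_pretrain(fx$seqs, fx$tv, fx_vocab(), config = config,
                     epochs = 3L, lr = 3e-3, seed = 7L)
  m2 <- nmf_pretrain(fx$seqs, fx$tv, fx_vocab(), config = config,
                     epochs = 3L, lr = 3e-3, seed = 7L)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  m0 <- nmf_pretrain(fx$seqs, fx$tv, fx_vocab(), config = config,
                     epochs = 3L, lr = 0, seed = 7L)
  expect_equal(diff(m0$history$total), rep(0, 2), tolerance = 1e-12)
})

test_that("a tiny model memorizes a small corpus", {
  sm <- fx_small_model()
  # cross-entropy driven to a memorization regime
  expect_lt(utils::tail(sm$model$history$ce, 1), 0.2)
  gen <- nmf_generate(sm$model, sm$anns, mode = "greedy", seed = 0L)
  truth <- vapply(sm$anns, `[[`, character(1), "canonical_smiles")
  expect_gte(mean(gen$smiles == truth), 0.75)
})

test_that("checkpoints round-trip and refuse vocabulary mismatches", {
  sm <- fx_small_model()
  path <- tempfile(fileext = ".rds")
  nmf_save(sm$model, path)
  back <- nmf_load(path, fx_vocab())
  expect_identical(back$params, sm$model$params)
  # a different vocabulary must be refused
  one <- tempfile(fileext = ".tsv")
  writeLines("hydroxyl\t[OX2H]", one)
  other <- build_vocabulary(one)
  expect_error(nmf_load(path, other), class = "nummolgen_config_error")
})

test_that("zero-initialized cross-attention leaves the step-0 loss unchanged", {
  sm <- fx_small_model()
  model <- nmf_add_pocket_params(sm$model, 8L, seed = 1L)
  pockets <- generate_pocket_fixtures(n_pockets = 4L, L_p = 6L, d_p = 8L,
                                      seed = 2L)
  batch <- pad_batch(sm$seqs[1:8])
  pk <- lapply(rep(1:4, 2), function(k) pockets[[k]]$embeddings)
  num_id <- unname(model$tok_vocab$id[["[NUM]"]])
  f_cond <- nmf_forward(model$params, model$config, batch, pockets = pk)
  f_unc <- nmf_forward(sm$model$params, sm$model$config, batch)
  cl_cond <- composite_loss(f_cond$logits, f_cond$numeric_preds, batch, num_id)
  cl_unc <- composite_loss(f_unc$logits, f_unc$numeric_preds, batch, num_id)
  expect_identical(cl_cond$total, cl_unc$total)
})

test_that("fine-tuning makes matched pockets more likely than mismatched ones", {
  sm <- fx_small_model()
  # four pockets, each paired with one molecule family (scaffold class)
  pockets <- generate_pocket_fixtures(n_pockets = 4L, L_p = 6L, d_p = 8L,
                                      seed = 3L)
  fam <- rep(1:4, length.out = length(sm$seqs))
  pairs <- lapply(seq_along(sm$seqs), function(i)
    list(pocket = pockets[[fam[i]]]$embeddings, seq = sm$seqs[[i]]))
  ft <- nmf_finetune(pairs, sm$model, epochs = 25L, batch_size = 24L,
                     lr = 2e-3, seed = 0L)
  num_id <- unname(ft$tok_vocab$id[["[NUM]"]])
  batch <- pad_batch(sm$seqs)
  ce_with <- function(pk) {
    f <- nmf_forward(ft$params, ft$config, batch, pockets = pk)
    composite_loss(f$logits, f$numeric_preds, batch, num_id)$ce_token
  }
  matched <- ce_with(lapply(fam, function(k) pockets[[k]]$embeddings))
  mismatched <- ce_with(lapply(fam, function(k) pockets[[(k %% 4) + 1L]]$embeddings))
  expect_lt(matched, mismatched)
  # determinism of the fine-tuning stage
  ft2 <- nmf_finetune(pairs, sm$model, epochs = 2L, batch_size = 24L,
                      lr = 2e-3, seed = 9L)
  ft3 <- nmf_finetune(pairs, sm$model, epochs = 2L, batch_size = 24L,
                      lr = 2e-3, seed = 9L)
  expect_identical(ft2$params, ft3$params)
})

test_that("non-finite losses abort training with diagnostics", {
  fx <- fx_encoded(12L, seed = 2L)
  config <- nmf_config(vocab_size = length(fx$tv$tokens), d_model = 16L,
                       n_layers = 1L, n_heads = 2L, max_len = 160L)
  broken <- nmf_init_params(config, seed = 1L)
  broken$head_tok[1, ] <- Inf                      # poisoned warm start
  expect_error(nmf_pretrain(fx$seqs, fx$tv, fx_vocab(), config = config,
                            epochs = 2L, lr = 1e-3, seed = 1L,
                            init_params = broken),
               class = "nummolgen_divergence")
})
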