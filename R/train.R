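# Training: composite next-token cross-entropy + numeric MSE, Adam, and the
# pretraining / pocket-conditional fine-tuning stages. The fitted model is a
# classed S3 object ("nummolgen_model") with the usual accessor methods.

#' Composite loss: next-token cross-entropy + numeric mean squared error
#'
#' The numeric term is evaluated only at positions whose *next* token is
#' [NUM] — elsewhere the target is identically zero and would swamp the
#' count-regression signal. Both terms are means over their own position
#' sets; the total is their sum.
#'
#' @param logits (B*L) x V prediction matrix (row (b-1)*L+t predicts t+1)
#' @param numeric_preds length B*L numeric-head outputs
#' @param batch result of [pad_batch()] (targets + mask)
#' @param num_id 0-based token id of [NUM]
#' @param want_grads also return d(loss)/d(logits) and d(loss)/d(numeric)
#' @return list with `ce_token`, `mse_numeric`, `total` (and gradients)
#' @export
composite_loss <- function(logits, numeric_preds, batch, num_id,
                           want_grads = FALSE) {
  B <- nrow(batch$text_ids); L <- ncol(batch$text_ids)
  # predicting position t+1 from t: valid where both are real tokens
  valid <- batch$mask[, -L, drop = FALSE] & batch$mask[, -1L, drop = FALSE]
  if (!any(valid))
    nmg_stop("degenerate_batch", "mask leaves no next-token positions")
  idx <- which(valid, arr.ind = TRUE)                 # (b, t)
  rows <- (idx[, 1] - 1L) * L + idx[, 2]              # flattened row of t
  tgt <- batch$text_ids[cbind(idx[, 1], idx[, 2] + 1L)]  # 0-based ids

  Z <- logits[rows, , drop = FALSE]
  zmax <- apply(Z, 1, max)
  lse <- log(rowSums(exp(Z - zmax))) + zmax
  logp <- Z[cbind(seq_along(rows), tgt + 1L)] - lse
  ce <- -mean(logp)

  num_next <- tgt == num_id
  mrows <- rows[num_next]
  if (length(mrows)) {
    mtgt <- batch$numeric_values[cbind(idx[num_next, 1], idx[num_next, 2] + 1L)]
    err <- numeric_preds[mrows] - mtgt
    mse <- mean(err^2)
  } else {
    mse <- 0
  }
  out <- list(ce_token = ce, mse_numeric = mse, total = ce + mse)
  if (want_grads) {
    P <- exp(Z - lse)                                  # softmax rows
    P[cbind(seq_along(rows), tgt + 1L)] <-
      P[cbind(seq_along(rows), tgt + 1L)] - 1
    dlogits <- matrix(0, nrow(logits), ncol(logits))
    dl <- rowsum(P / length(rows), group = rows)       # duplicate rows impossible, but safe
    dlogits[as.integer(rownames(dl)), ] <- dl
    dnum <- numeric(length(numeric_preds))
    if (length(mrows)) dnum[mrows] <- 2 * err / length(mrows)
    out$dlogits <- dlogits
    out$dnum <- dnum
  }
  out
}

## ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## ---- the fitted-model class ----

new_nummolgen_model <- function(config, params, tok_vocab, fg_vocab, stage,
                             history = NULL, seed = NA_integer_) {
  structure(list(config = config, params = params, tok_vocab = tok_vocab,
                 fg_vocab = fg_vocab, fg_hash = fg_vocab_hash(fg_vocab),
                 stage = stage, history = history, seed = seed),
            class = "nummolgen_model")
}

#' @export
print.nummolgen_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<nummolgen_model> stage=%s  d=%d layers=%d heads=%d K=%d  V=%d  %s parameters\n",
              x$stage, x$config$d_model, x$config$n_layers, x$config$n_heads,
              x$config$K_bins, x$config$vocab_size, format(np, big.mark = ",")))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  final training loss: total=%.4f (ce=%.4f, mse=%.4f)\n",
                utils::tail(x$history$total, 1), utils::tail(x$history$ce, 1),
                utils::tail(x$history$mse, 1)))
  invisible(x)
}

#' @export
summary.nummolgen_model <- function(object, ...) {
  print(object)
  cat(sprintf("  fg vocabulary: %d groups (hash %s)\n",
              object$fg_vocab$size, object$fg_hash))
  cat(sprintf("  pocket conditioning: %s\n",
              if (object$config$pocket_dim > 0) sprintf("on (d_p=%d)", object$config$pocket_dim) else "off"))
  if (!is.null(object$history)) {
    cat("  loss trace (head/tail):\n")
    print(utils::head(object$history, 3))
    print(utils::tail(object$history, 3))
  }
  invisible(object)
}

#' @export
coef.nummolgen_model <- function(object, ...) {
  c(lambda = object$params$lambda,
    n_parameters = sum(vapply(object$params, length, numeric(1))))
}

#' @export
plot.nummolgen_model <- function(x, ...) {
  if (is.null(x$history) || !nrow(x$history)) {
    graphics::plot.new(); graphics::title("no training history"); return(invisible(x))
  }
  graphics::plot(x$history$epoch, x$history$total, type = "l",
                 xlab = "epoch", ylab = "loss", main = "composite training loss", ...)
  graphics::lines(x$history$epoch, x$history$ce, lty = 2)
  graphics::legend("topright", c("total", "cross-entropy"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Log-likelihood of encoded sequences under the model
#'
#' Token-level log-likelihood (the cross-entropy part of the training
#' objective, negated and summed).
#' @param object a `nummolgen_model`
#' @param seqs list of `dual_sequence` (defaults: error — supply data)
#' @param ... unused
#' @export
logLik.nummolgen_model <- function(object, seqs, ...) {
  batch <- pad_batch(seqs)
  fwd <- nmf_forward(object$params, object$config, batch)
  num_id <- unname(object$tok_vocab$id[["[NUM]"]])
  cl <- composite_loss(fwd$logits, fwd$numeric_preds, batch, num_id)
  n_pos <- sum(batch$mask[, -1, drop = FALSE] & batch$mask[, -ncol(batch$mask), drop = FALSE])
  structure(-cl$ce_token * n_pos, df = sum(vapply(object$params, length, numeric(1))),
            nobs = n_pos, class = "logLik")
}

#' Next-token predictive distribution
#'
#' @param object a `nummolgen_model`
#' @param seq a `dual_sequence` prefix
#' @param ... unused
#' @return list: `token_probs` (named probabilities for the next token) and
#'   `numeric_pred` (next numeric value)
#' @export
predict.nummolgen_model <- function(object, seq, ...) {
  batch <- pad_batch(list(seq))
  fwd <- nmf_forward(object$params, object$config, batch)
  r <- length(seq$text_ids)
  p <- softmax_rows(fwd$logits[r, , drop = FALSE])[1, ]
  list(token_probs = stats::setNames(p, object$tok_vocab$tokens),
       numeric_pred = fwd$numeric_preds[r])
}

## ---- checkpoints ----

#' Save / load a model checkpoint
#'
#' Single-file archive holding config, weights, both vocabularies and the
#' functional-group vocabulary hash. Loading verifies the hash when a
#' vocabulary is supplied and refuses mismatches.
#' @param model a `nummolgen_model`
#' @param path file path
#' @export
nmf_save <- function(model, path) {
  stopifnot(inherits(model, "nummolgen_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname nmf_save
#' @param fg_vocab optional `fg_vocabulary` to validate against
#' @export
nmf_load <- function(path, fg_vocab = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "nummolgen_model"))
    nmg_stop("format_error", "file is not a nummolgen_model checkpoint")
  if (!is.null(fg_vocab) && !identical(fg_vocab_hash(fg_vocab), model$fg_hash))
    nmg_stop("config_error",
             "functional-group vocabulary hash mismatch: checkpoint was built with a different vocabulary")
  model
}

## ---- stage 1: unconditional pretraining ----

#' Pretrain the generator on encoded dual sequences
#'
#' @param seqs list of `dual_sequence`
#' @param tok_vocab token vocabulary used to encode them
#' @param fg_vocab functional-group vocabulary
#' @param config an `nmf_config` (vocab_size/max_len are filled in if missing)
#' @param epochs training epochs (full passes)
#' @param batch_size minibatch size
#' @param lr Adam learning rate
#' @param seed master seed (init + shuffling)
#' @param target_loss optional early stop once total loss falls below
#' @param init_params optional warm-start parameter list (defaults to a
#'   seeded fresh initialization)
#' @param verbose print per-epoch losses
#' @return a fitted `nummolgen_model`
#' @export
nmf_pretrain <- function(seqs, tok_vocab, fg_vocab, config = NULL,
                         epochs = 60L, batch_size = 32L, lr = 3e-3,
                         seed = 0L, target_loss = NULL, init_params = NULL,
                         verbose = FALSE) {
  if (!length(seqs)) nmg_stop("config_error", "empty training corpus")
  maxlen <- max(vapply(seqs, function(s) length(s$text_ids), integer(1)))
  if (is.null(config))
    config <- nmf_config(vocab_size = length(tok_vocab$tokens), max_len = maxlen)
  params <- init_params %||% nmf_init_params(config, derive_seed(seed, "init"))
  state <- adam_init(params)
  num_id <- unname(tok_vocab$id[["[NUM]"]])
  hist <- list()
  set.seed(derive_seed(seed, "shuffle"))
  n <- length(seqs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_ce <- 0; ep_mse <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      take <- ord[start:min(start + batch_size - 1L, n)]
      batch <- pad_batch(seqs[take])
      fwd <- nmf_forward(params, config, batch, want_cache = TRUE)
      cl <- composite_loss(fwd$logits, fwd$numeric_preds, batch, num_id,
                           want_grads = TRUE)
      if (!is.finite(cl$total))
        nmg_stop("divergence",
                 sprintf("non-finite loss at epoch %d (ce=%g mse=%g); lower the learning rate",
                         ep, cl$ce_token, cl$mse_numeric))
      grads <- nmf_backward(params, config, fwd, cl$dlogits, cl$dnum)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params; state <- upd$state
      ep_ce <- ep_ce + cl$ce_token; ep_mse <- ep_mse + cl$mse_numeric; nb <- nb + 1
    }
    hist[[ep]] <- data.frame(epoch = ep, ce = ep_ce / nb, mse = ep_mse / nb,
                             total = (ep_ce + ep_mse) / nb)
    if (verbose) message(sprintf("epoch %3d  ce=%.4f mse=%.4f", ep,
                                 ep_ce / nb, ep_mse / nb))
    if (!is.null(target_loss) && (ep_ce + ep_mse) / nb < target_loss) break
  }
  new_nummolgen_model(config, params, tok_vocab, fg_vocab, "pretrained",
                   do.call(rbind, hist), seed)
}

## ---- stage 2: pocket-conditional fine-tuning ----

#' Fine-tune with pocket contexts through gated cross-attention
#'
#' The cross-attention output projection starts at zero, so the step-0
#' conditional loss equals the unconditional model's loss on the same batch
#' exactly; training then opens the gate.
#'
#' @param pairs list of list(pocket = L_p x d_p matrix, seq = `dual_sequence`)
#' @param model a pretrained `nummolgen_model`
#' @param epochs,batch_size,lr,seed,verbose as in [nmf_pretrain()]
#' @return fine-tuned `nummolgen_model` (stage "conditional")
#' @export
nmf_finetune <- function(pairs, model, epochs = 30L, batch_size = 16L,
                         lr = 1e-3, seed = 0L, verbose = FALSE) {
  stopifnot(inherits(model, "nummolgen_model"), length(pairs) > 0)
  d_p <- unique(vapply(pairs, function(p) ncol(p$pocket), integer(1)))
  if (length(d_p) != 1L)
    nmg_stop("config_error", "pocket embeddings have inconsistent widths")
  if (model$config$pocket_dim == 0L)
    model <- nmf_add_pocket_params(model, d_p, derive_seed(seed, "xattn"))
  else if (model$config$pocket_dim != d_p)
    nmg_stop("config_error",
             sprintf("pocket dim %d != model pocket_dim %d", d_p,
                     model$config$pocket_dim))
  params <- model$params; config <- model$config
  state <- adam_init(params)
  num_id <- unname(model$tok_vocab$id[["[NUM]"]])
  hist <- list()
  set.seed(derive_seed(seed, "shuffle"))
  n <- length(pairs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_ce <- 0; ep_mse <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      take <- ord[start:min(start + batch_size - 1L, n)]
      batch <- pad_batch(lapply(pairs[take], `[[`, "seq"))
      pockets <- lapply(pairs[take], `[[`, "pocket")
      fwd <- nmf_forward(params, config, batch, pockets = pockets,
                         want_cache = TRUE)
      cl <- composite_loss(fwd$logits, fwd$numeric_preds, batch, num_id,
                           want_grads = TRUE)
      if (!is.finite(cl$total))
        nmg_stop("divergence", sprintf("non-finite loss at epoch %d", ep))
      grads <- nmf_backward(params, config, fwd, cl$dlogits, cl$dnum)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params; state <- upd$state
      ep_ce <- ep_ce + cl$ce_token; ep_mse <- ep_mse + cl$mse_numeric; nb <- nb + 1
    }
    hist[[ep]] <- data.frame(epoch = ep, ce = ep_ce / nb, mse = ep_mse / nb,
                             total = (ep_ce + ep_mse) / nb)
    if (verbose) message(sprintf("ft epoch %3d  ce=%.4f mse=%.4f", ep,
                                 ep_ce / nb, ep_mse / nb))
  }
  out <- new_nummolgen_model(config, params, model$tok_vocab, model$fg_vocab,
                          "conditional", rbind(model$history, do.call(rbind, hist)),
                          seed)
  out
}
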