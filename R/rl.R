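# Reinforcement-learning alignment: augmented-likelihood policy optimization
# against a frozen prior, with a multi-objective reward combining docking
# affinity, drug-likeness (QED) and synthetic accessibility (SA).

#' Numerically stable sigmoid normalization
#'
#' f(x, b) = 1 / (1 + exp(-k (x - b))): maps a raw property score onto (0,1)
#' around threshold b; strictly increasing in x, saturating at the tails.
#'
#' @param x raw score
#' @param b threshold (midpoint: f(b, b) = 0.5)
#' @param k scale (steepness)
#' @return value in (0,1)
#' @export
sigmoid_normalize <- function(x, b, k = 10) {
  if (any(!is.finite(b)) || any(!is.finite(k)))
    nmg_stop("numeric_domain", "threshold and scale must be finite")
  z <- k * (x - b)
  ifelse(z >= 0, 1 / (1 + exp(-z)), exp(z) / (1 + exp(z)))
}

#' Reward specification
#'
#' Weights (dock 0.4, QED 0.3, SA 0.3), thresholds (dock -3.0 on the
#' negated-affinity scale, QED 0.2, SA 0.5 on the normalized 0-1 scale) and
#' sigmoid scale k = 10. `dock_transform` maps the raw docking affinity
#' (kcal/mol, lower = stronger binding) onto the increasing scale fed to the
#' sigmoid; the default negates it so stronger binders score higher.
#'
#' @param w_dock,w_qed,w_sa component weights (must be non-negative, sum 1)
#' @param b_dock,b_qed,b_sa sigmoid thresholds
#' @param k sigmoid scale
#' @param dock_transform function applied to the raw docking score
#' @return object of class `reward_spec`
#' @export
reward_spec <- function(w_dock = 0.4, w_qed = 0.3, w_sa = 0.3,
                        b_dock = -3.0, b_qed = 0.2, b_sa = 0.5, k = 10,
                        dock_transform = function(x) -x) {
  w <- c(w_dock, w_qed, w_sa)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    nmg_stop("config_error", "reward weights must be non-negative and sum to 1")
  if (k <= 0) nmg_stop("config_error", "sigmoid scale k must be positive")
  structure(list(w_dock = w_dock, w_qed = w_qed, w_sa = w_sa,
                 b_dock = b_dock, b_qed = b_qed, b_sa = b_sa, k = k,
                 dock_transform = dock_transform),
            class = "reward_spec")
}

#' Multi-objective generation reward
#'
#' R = w_dock f(T(dock), b_dock) + w_qed f(QED, b_qed) + w_sa f(SA, b_sa),
#' with f the sigmoid of [sigmoid_normalize()] and T the spec's docking
#' transform. All three components must be present; there is no silent
#' default.
#'
#' @param dock_score raw docking affinity (kcal/mol)
#' @param qed drug-likeness in [0,1]
#' @param sa normalized synthetic accessibility in [0,1] (higher = easier)
#' @param spec a `reward_spec`
#' @return reward in (0,1)
#' @export
reward <- function(dock_score, qed, sa, spec = reward_spec()) {
  stopifnot(inherits(spec, "reward_spec"))
  if (any(is.na(dock_score)) || any(is.na(qed)) || any(is.na(sa)))
    nmg_stop("scoring_error", "missing reward component (dock/qed/sa)")
  spec$w_dock * sigmoid_normalize(spec$dock_transform(dock_score), spec$b_dock, spec$k) +
    spec$w_qed * sigmoid_normalize(qed, spec$b_qed, spec$k) +
    spec$w_sa * sigmoid_normalize(sa, spec$b_sa, spec$k)
}

#' Augmented-likelihood RL loss
#'
#' Per-sample squared residual (log pi_prior(S) + sigma R(S) - log pi_theta(S))^2,
#' averaged over the batch. Log-probabilities are summed over the generated
#' (sampled) token positions of each sequence.
#'
#' @param logp_prior,logp_theta summed sequence log-probabilities
#' @param R rewards in [0,1]
#' @param sigma reward scale
#' @return non-negative mean loss
#' @export
rl_loss <- function(logp_prior, logp_theta, R, sigma) {
  if (any(!is.finite(logp_prior)) || any(!is.finite(logp_theta)))
    nmg_stop("numeric_domain", "non-finite log-probability in RL loss")
  mean((logp_prior + sigma * R - logp_theta)^2)
}

# summed log-probability of the sampled positions of each generated sequence
# under `params`; optionally returns what the taped backward needs.
seq_logprob <- function(params, config, seqs, sampled, want_cache = FALSE) {
  batch <- pad_batch(seqs)
  fwd <- nmf_forward(params, config, batch, want_cache = want_cache)
  L <- ncol(batch$text_ids)
  lp <- numeric(length(seqs))
  rows_all <- list()
  for (b in seq_along(seqs)) {
    pos <- which(sampled[[b]])
    pos <- pos[pos >= 2L]                 # a sampled first token has no context
    if (!length(pos)) { rows_all[[b]] <- integer(0); next }
    rows <- (b - 1L) * L + (pos - 1L)     # predictions come from t-1
    Z <- fwd$logits[rows, , drop = FALSE]
    zmax <- apply(Z, 1, max)
    lse <- log(rowSums(exp(Z - zmax))) + zmax
    tgt <- seqs[[b]]$text_ids[pos]
    lp[b] <- sum(Z[cbind(seq_along(rows), tgt + 1L)] - lse)
    rows_all[[b]] <- rows
  }
  list(logp = lp, fwd = fwd, batch = batch, rows = rows_all)
}

#' Probe-set KL divergence between policy and prior
#'
#' Mean over probe sequences of the summed per-position
#' KL(pi_theta(.|prefix) || pi_prior(.|prefix)) over real (non-pad)
#' positions.
#' @param model,prior `nummolgen_model` objects sharing a vocabulary
#' @param probe_seqs list of `dual_sequence`
#' @return non-negative scalar
#' @export
kl_policy_prior <- function(model, prior, probe_seqs) {
  batch <- pad_batch(probe_seqs)
  ftheta <- nmf_forward(model$params, model$config, batch)
  fprior <- nmf_forward(prior$params, prior$config, batch)
  L <- ncol(batch$text_ids)
  kl <- numeric(length(probe_seqs))
  for (b in seq_along(probe_seqs)) {
    len <- batch$lengths[b]
    rows <- (b - 1L) * L + seq_len(len - 1L)
    Pt <- softmax_rows(ftheta$logits[rows, , drop = FALSE])
    Pp <- softmax_rows(fprior$logits[rows, , drop = FALSE])
    kl[b] <- sum(Pt * (log(Pt + 1e-12) - log(Pp + 1e-12)))
  }
  mean(kl)
}

#' Reinforcement-learning fine-tuning
#'
#' Policy-gradient alignment: each step samples a constraint batch, generates
#' molecules at temperature 1, scores them with the (deterministic) scorer,
#' and takes one Adam step on the augmented-likelihood loss against the
#' frozen prior. Invalid SMILES receive reward 0 and stay in the loss.
#'
#' @param model starting policy (`nummolgen_model`); the frozen prior is a deep
#'   copy taken before any update
#' @param scorer function(smiles_vector) -> data.frame with columns
#'   dock, qed, sa (NA rows for invalid molecules are an error: score
#'   invalid molecules upstream or let `invalid_reward` handle them)
#' @param constraint_pool list of count vectors to sample prompts from
#' @param steps,batch_size RL schedule
#' @param sigma reward scale of the augmented likelihood
#' @param lr Adam learning rate
#' @param seed master seed
#' @param rspec a `reward_spec`
#' @param invalid_reward reward assigned to chemically invalid outputs
#' @param verbose print per-step mean rewards
#' @return list: `model` (updated policy), `prior`, `trace` (data.frame
#'   step/mean_reward/loss/n_valid)
#' @export
nmf_rl_finetune <- function(model, scorer, constraint_pool, steps = 40L,
                            batch_size = 8L, sigma = 120, lr = 5e-4,
                            seed = 0L, rspec = reward_spec(),
                            invalid_reward = 0, verbose = FALSE) {
  stopifnot(inherits(model, "nummolgen_model"), length(constraint_pool) > 0)
  prior <- model                      # R copy semantics: frozen deep copy
  params <- model$params; config <- model$config
  state <- adam_init(params)
  trace <- list()
  set.seed(derive_seed(seed, "rl"))
  consecutive_skipped <- 0L
  for (step in seq_len(steps)) {
    take <- sample.int(length(constraint_pool), batch_size, replace = TRUE)
    gen_model <- new_nummolgen_model(config, params, model$tok_vocab,
                                  model$fg_vocab, "rl")
    gen <- nmf_generate(gen_model, constraint_pool[take], mode = "temperature",
                        temperature = 1.0,
                        seed = derive_seed(seed, paste0("rl_gen", step)))
    valid <- is_valid_smiles(gen$smiles)
    if (!any(valid)) {
      consecutive_skipped <- consecutive_skipped + 1L
      nmg_warn(sprintf("RL step %d: all generated molecules invalid; step skipped", step))
      if (consecutive_skipped > max(5L, steps %/% 2L))
        nmg_stop("divergence", "too many consecutive all-invalid RL batches")
      next
    }
    consecutive_skipped <- 0L
    R <- rep(invalid_reward, batch_size)
    if (any(valid)) {
      sc <- scorer(gen$smiles[valid])
      R[valid] <- reward(sc$dock, sc$qed, sc$sa, rspec)
    }
    lp_prior <- seq_logprob(prior$params, config, gen$sequences, gen$sampled)$logp
    pol <- seq_logprob(params, config, gen$sequences, gen$sampled,
                       want_cache = TRUE)
    e <- lp_prior + sigma * R - pol$logp
    loss <- mean(e^2)
    # d loss / d logits: -2 e_b / B at each sampled position's (onehot - p)
    dlogits <- matrix(0, nrow(pol$fwd$logits), ncol(pol$fwd$logits))
    Lpad <- ncol(pol$batch$text_ids)
    for (b in seq_len(batch_size)) {
      rows <- pol$rows[[b]]
      if (!length(rows)) next
      coef <- -2 * e[b] / batch_size
      Z <- pol$fwd$logits[rows, , drop = FALSE]
      P <- softmax_rows(Z)
      pos <- which(gen$sampled[[b]]); pos <- pos[pos >= 2L]
      tgt <- gen$sequences[[b]]$text_ids[pos]
      G <- -P
      G[cbind(seq_along(rows), tgt + 1L)] <- G[cbind(seq_along(rows), tgt + 1L)] + 1
      dlogits[rows, ] <- dlogits[rows, ] + coef * G
    }
    grads <- nmf_backward(params, config, pol$fwd, dlogits,
                          numeric(length(pol$fwd$numeric_preds)))
    upd <- adam_step(params, grads, state, lr)
    params <- upd$params; state <- upd$state
    trace[[length(trace) + 1L]] <-
      data.frame(step = step, mean_reward = mean(R), loss = loss,
                 n_valid = sum(valid))
    if (verbose) message(sprintf("rl step %3d  reward=%.4f loss=%.2f valid=%d/%d",
                                 step, mean(R), loss, sum(valid), batch_size))
  }
  out <- new_nummolgen_model(config, params, model$tok_vocab, model$fg_vocab,
                          "rl", model$history, seed)
  list(model = out, prior = prior, trace = do.call(rbind, trace))
}

#' Mean reward of a policy on a constraint pool
#'
#' Generates `n` molecules from the policy (temperature sampling) and scores
#' them; the summary used to compare prior and RL-tuned policies.
#' @param model a `nummolgen_model`
#' @param scorer as in [nmf_rl_finetune()]
#' @param constraint_pool list of count vectors
#' @param n molecules to draw
#' @param seed RNG seed
#' @param rspec a `reward_spec`
#' @param invalid_reward reward for invalid outputs
#' @return list: `mean_reward`, `rewards`, `smiles`, `validity`
#' @export
nmf_policy_reward <- function(model, scorer, constraint_pool, n = 32L,
                              seed = 0L, rspec = reward_spec(),
                              invalid_reward = 0) {
  set.seed(derive_seed(seed, "policy_eval"))
  take <- sample.int(length(constraint_pool), n, replace = TRUE)
  gen <- nmf_generate(model, constraint_pool[take], mode = "temperature",
                      temperature = 1.0, seed = derive_seed(seed, "policy_gen"))
  valid <- is_valid_smiles(gen$smiles)
  R <- rep(invalid_reward, n)
  if (any(valid)) {
    sc <- scorer(gen$smiles[valid])
    R[valid] <- reward(sc$dock, sc$qed, sc$sa, rspec)
  }
  list(mean_reward = mean(R), rewards = R, smiles = gen$smiles,
       validity = mean(valid))
}
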