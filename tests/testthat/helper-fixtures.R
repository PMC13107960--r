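# Shared fixtures, built lazily once per test run.

.fx <- new.env(parent = emptyenv())

fx_vocab <- function() {
  if (is.null(.fx$vocab)) .fx$vocab <- build_vocabulary("default")
  .fx$vocab
}

fx_fixture100 <- function() {
  if (is.null(.fx$f100)) .fx$f100 <- fixture_smiles_100()
  .fx$f100
}

# small encoded corpus shared by codec/model tests
fx_encoded <- function(n = 30L, seed = 1L) {
  key <- paste0("enc_", n, "_", seed)
  if (is.null(.fx[[key]])) {
    vocab <- fx_vocab()
    corpus <- generate_corpus(corpus_spec(n_molecules = n, seed = seed))
    anns <- annotate_molecules(corpus, vocab)
    tv <- build_token_vocabulary(anns, vocab)
    seqs <- lapply(anns, encode_dual, tok_vocab = tv)
    .fx[[key]] <- list(corpus = corpus, anns = anns, tv = tv, seqs = seqs)
  }
  .fx[[key]]
}

# a quickly pretrained small model for generation / RL mechanics tests
fx_small_model <- function() {
  if (is.null(.fx$small_model)) {
    vocab <- fx_vocab()
    corpus <- generate_corpus(corpus_spec(n_molecules = 24L, seed = 5L))
    anns <- annotate_molecules(corpus, vocab)
    tv <- build_token_vocabulary(anns, vocab)
    seqs <- lapply(anns, encode_dual, tok_vocab = tv)
    config <- nmf_config(vocab_size = length(tv$tokens), d_model = 48L,
                         n_layers = 2L, n_heads = 4L, max_len = 160L)
    model <- nmf_pretrain(seqs, tv, vocab, config = config, epochs = 160L,
                          batch_size = 24L, lr = 8e-3, seed = 0L)
    .fx$small_model <- list(model = model, anns = anns, tv = tv, seqs = seqs,
                            corpus = corpus)
  }
  .fx$small_model
}

# a moderately trained policy for RL-alignment tests: alignment needs
# headroom, so this prior is deliberately stopped early (imperfect validity)
fx_rl_model <- function() {
  if (is.null(.fx$rl_model)) {
    vocab <- fx_vocab()
    corpus <- generate_corpus(corpus_spec(n_molecules = 24L, seed = 5L))
    anns <- annotate_molecules(corpus, vocab)
    tv <- build_token_vocabulary(anns, vocab)
    seqs <- lapply(anns, encode_dual, tok_vocab = tv)
    config <- nmf_config(vocab_size = length(tv$tokens), d_model = 32L,
                         n_layers = 1L, n_heads = 2L, max_len = 160L)
    model <- nmf_pretrain(seqs, tv, vocab, config = config, epochs = 60L,
                          batch_size = 24L, lr = 8e-3, seed = 0L)
    .fx$rl_model <- list(model = model, anns = anns, seqs = seqs)
  }
  .fx$rl_model
}

# independent naive substructure enumerator: recursion in raw pattern-atom
# order over all molecule atoms, bond constraints checked on the complete
# assignment only. Deliberately different from the package matcher.
brute_force_matches <- function(mol, pattern) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  feat <- nummolgen:::mol_features(mol)
  np <- length(pattern$atoms)
  nm <- nrow(mol$atoms)
  bond_lookup <- new.env(parent = emptyenv())
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    key <- paste(sort(c(mol$bonds$i[k], mol$bonds$j[k])), collapse = "_")
    assign(key, c(mol$bonds$order[k], mol$bonds$aromatic[k]), envir = bond_lookup)
  }
  cand <- lapply(seq_len(np), function(p)
    Filter(function(a) nummolgen:::atom_ok(pattern$atoms[[p]], feat, a + 1L),
           0:(nm - 1L)))
  found <- list()
  rec <- function(step, assigned) {
    if (step > np) {
      for (e in pattern$bonds) {
        key <- paste(sort(c(assigned[e$a], assigned[e$b])), collapse = "_")
        kb <- get0(key, envir = bond_lookup)
        if (is.null(kb) ||
            !nummolgen:::bond_ok(e$type, kb[1], as.logical(kb[2]))) return()
      }
      found[[length(found) + 1L]] <<- assigned
      return()
    }
    for (a in cand[[step]]) {
      if (a %in% assigned) next
      rec(step + 1L, c(assigned, a))
    }
  }
  rec(1L, integer(0))
  if (!length(found)) return(list())
  keys <- vapply(found, function(m) paste(sort(m), collapse = ","), character(1))
  found[!duplicated(keys)]
}

# Independent single-stream causal decoder, written longhand: the reference
# implementation that the dual-stream model must reduce to when the
# numerical channel is off.
reference_plain_decoder <- function(params, config, batch) {
  B <- nrow(batch$text_ids); L <- ncol(batch$text_ids)
  d <- config$d_model; nh <- config$n_heads; dh <- d / nh
  out <- matrix(0, B * L, config$vocab_size)
  for (b in seq_len(B)) {
    X <- params$tok_emb[batch$text_ids[b, ] + 1L, , drop = FALSE] +
      params$pos_emb[seq_len(L), , drop = FALSE]
    for (l in seq_len(config$n_layers)) {
      pl <- function(s) params[[paste0("L", l, ".", s)]]
      Q <- X %*% pl("Wq"); K <- X %*% pl("Wk"); Vv <- X %*% pl("Wv")
      ctx <- matrix(0, L, d)
      for (h in seq_len(nh)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        for (t in seq_len(L)) {
          sc <- as.numeric(Q[t, cols] %*% t(K[1:t, cols, drop = FALSE])) / sqrt(dh)
          a <- exp(sc - max(sc)); a <- a / sum(a)
          ctx[t, cols] <- a %*% Vv[1:t, cols, drop = FALSE]
        }
      }
      H <- ctx %*% pl("Wo")
      x1 <- X + H
      r1 <- sqrt(rowMeans(x1^2) + 1e-6)
      n1 <- sweep(x1 / r1, 2, pl("ln1"), `*`)
      u <- n1 %*% pl("Wg"); v <- n1 %*% pl("Wu")
      ff <- ((u / (1 + exp(-u))) * v) %*% pl("Wd")
      x2 <- n1 + ff
      r2 <- sqrt(rowMeans(x2^2) + 1e-6)
      X <- sweep(x2 / r2, 2, pl("ln2"), `*`)
    }
    rf <- sqrt(rowMeans(X^2) + 1e-6)
    Xf <- sweep(X / rf, 2, params$ln_f, `*`)
    out[((b - 1) * L + 1):(b * L), ] <-
      Xf %*% params$head_tok + matrix(params$head_tok_b, L, config$vocab_size,
                                      byrow = TRUE)
  }
  out
}
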