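# Autoregressive generation. Decoding is grammar-constrained by the dual
# sequence template: constraint-header anchors ([FG:*], [NUM] with its count,
# [NONE], [BOS]) are teacher-forced from the requested count vector; position
# tokens inside present groups are sampled under the template grammar (one
# pos-run + [SEP] per instance); after [BOS] only SMILES tokens and [EOS] are
# reachable. Passing a full annotation instead of a count vector forces the
# entire header, including the true positions.
#
# Decoding keeps per-layer key/value caches, so each new token costs
# O(t * d) instead of a fresh full forward.

MAX_INSTANCE_ATOMS <- 12L

## ---- incremental decoder state ----

decode_init <- function(params, config, B, pockets = NULL) {
  d <- config$d_model
  st <- list(params = params, config = config, B = B, t = 0L,
             K = lapply(seq_len(config$n_layers), function(l)
               lapply(seq_len(B), function(b) matrix(0, config$max_len, d))),
             V = lapply(seq_len(config$n_layers), function(l)
               lapply(seq_len(B), function(b) matrix(0, config$max_len, d))))
  if (!is.null(pockets)) {
    if (length(pockets) == 1L && B > 1L) pockets <- rep(pockets, B)
    st$Kp <- lapply(pockets, function(P) P %*% params$c_Wk)
    st$Vp <- lapply(pockets, function(P) P %*% params$c_Wv)
  }
  st
}

# append one token per sequence; returns logits (B x V) for the next position
decode_step <- function(st, ids, nums) {
  params <- st$params; config <- st$config
  B <- st$B; d <- config$d_model
  nh <- config$n_heads; dh <- d %/% nh
  t <- st$t + 1L
  if (t > config$max_len)
    nmg_stop("contract_violation", "decode exceeded max_len")
  E <- params$tok_emb[ids + 1L, , drop = FALSE] +
    matrix(params$pos_emb[t, ], B, d, byrow = TRUE)
  ne <- numerical_embedding(E, nums, params)
  x <- E + (nums + (ne$e_num - ne$e_raw))
  if (!is.null(st$Kp)) {
    cn <- norm_fwd(x, params$c_ln, config$norm)
    q <- cn$y %*% params$c_Wq
    ca <- matrix(0, B, d)
    for (b in seq_len(B)) {
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- (q[b, cols, drop = FALSE] %*% t(st$Kp[[b]][, cols, drop = FALSE])) / sqrt(dh)
        A <- softmax_rows(S)
        ca[b, cols] <- A %*% st$Vp[[b]][, cols, drop = FALSE]
      }
    }
    x <- x + ca %*% params$c_Wo
  }
  for (l in seq_len(config$n_layers)) {
    pl <- function(nmx) params[[paste0("L", l, ".", nmx)]]
    qm <- x %*% pl("Wq"); km <- x %*% pl("Wk"); vm <- x %*% pl("Wv")
    ctx <- matrix(0, B, d)
    for (b in seq_len(B)) {
      st$K[[l]][[b]][t, ] <- km[b, ]
      st$V[[l]][[b]][t, ] <- vm[b, ]
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- (qm[b, cols, drop = FALSE] %*%
                t(st$K[[l]][[b]][seq_len(t), cols, drop = FALSE])) / sqrt(dh)
        A <- softmax_rows(S)
        ctx[b, cols] <- A %*% st$V[[l]][[b]][seq_len(t), cols, drop = FALSE]
      }
    }
    H <- ctx %*% pl("Wo")
    n1 <- norm_fwd(x + H, pl("ln1"), config$norm)
    sw <- swiglu_fwd(n1$y, pl("Wg"), pl("Wu"), pl("Wd"))
    x <- norm_fwd(n1$y + sw$y, pl("ln2"), config$norm)$y
  }
  fin <- norm_fwd(x, params$ln_f, config$norm)
  st$t <- t
  list(state = st,
       logits = fin$y %*% params$head_tok +
         matrix(params$head_tok_b, B, config$vocab_size, byrow = TRUE))
}

## ---- grammar state machines ----

# plan for one sequence: environment advanced token by token
new_gen_plan <- function(constraints, tok_vocab, fg_vocab) {
  e <- new.env(parent = emptyenv())
  if (inherits(constraints, "molecule_annotation")) {
    seq <- encode_dual(constraints, tok_vocab)
    bos <- which(seq_tokens(seq, tok_vocab) == "[BOS]")
    e$forced <- seq$text_ids[seq_len(bos)]
    e$forced_num <- seq$numeric_values[seq_len(bos)]
    e$counts <- unname(count_vector(constraints))
    e$full_header <- TRUE
  } else {
    counts <- as.integer(constraints)
    if (length(counts) != fg_vocab$size)
      nmg_stop("contract_violation",
               sprintf("constraint vector length %d != vocabulary size %d",
                       length(counts), fg_vocab$size))
    e$forced <- integer(0); e$forced_num <- numeric(0)
    e$counts <- counts
    e$full_header <- FALSE
  }
  e$mode <- "header"       # header | group_pos | smiles | done
  e$fptr <- 0L             # consumed forced tokens
  e$group <- 0L            # groups fully emitted so far
  e$inst_left <- 0L
  e$inst_atoms <- 0L
  e$tokens <- integer(0)   # emitted ids
  e$nums <- numeric(0)
  e$sampled <- logical(0)
  e$tok_vocab <- tok_vocab
  e$fg_vocab <- fg_vocab
  e
}

# token-id sets, memoized on the vocabulary
gen_token_sets <- function(tok_vocab) {
  toks <- tok_vocab$tokens
  list(pos = unname(tok_vocab$id[grepl("^pos[0-9]+$", toks)]),
       smiles = unname(tok_vocab$id[!grepl("^pos[0-9]+$", toks) &
                                      !grepl("^\\[", toks)]),
       sep = unname(tok_vocab$id[["[SEP]"]]),
       none = unname(tok_vocab$id[["[NONE]"]]),
       bos = unname(tok_vocab$id[["[BOS]"]]),
       eos = unname(tok_vocab$id[["[EOS]"]]),
       num = unname(tok_vocab$id[["[NUM]"]]),
       pad = unname(tok_vocab$id[["[PAD]"]]))
}

# what does this sequence want next? list(kind = "forced"/"sample"/"done",
# id (forced), numeric, allowed (sample))
plan_next <- function(e, sets) {
  if (e$mode == "done") return(list(kind = "done"))
  if (e$fptr < length(e$forced)) {
    id <- e$forced[e$fptr + 1L]
    return(list(kind = "forced", id = id, numeric = e$forced_num[e$fptr + 1L]))
  }
  if (e$mode == "header") {
    # forced queue exhausted: either full-annotation prompt (ends at [BOS]) or
    # count-vector prompt built group by group
    if (e$full_header) { e$mode <- "smiles"; return(plan_next(e, sets)) }
    if (e$group < length(e$counts)) {
      g <- e$group + 1L
      fg_id <- unname(e$tok_vocab$id[[fg_token(e$fg_vocab$types[[g]]$name)]])
      cnt <- e$counts[g]
      tail_ids <- if (cnt == 0L) sets$none else integer(0)
      e$forced <- c(e$tokens, fg_id, sets$num, tail_ids)  # re-anchor pointer
      e$fptr <- length(e$tokens)
      e$forced_num <- c(e$nums, 0, cnt, if (cnt == 0L) 0)
      if (cnt > 0L) { e$pending_group <- g }
      return(plan_next(e, sets))
    }
    e$forced <- c(e$tokens, sets$bos)
    e$fptr <- length(e$tokens)
    e$forced_num <- c(e$nums, 0)
    e$mode <- "pre_smiles"
    return(plan_next(e, sets))
  }
  if (e$mode == "group_pos") {
    allowed <- if (e$inst_atoms == 0L) sets$pos
    else if (e$inst_atoms >= MAX_INSTANCE_ATOMS) sets$sep
    else c(sets$pos, sets$sep)
    return(list(kind = "sample", allowed = allowed))
  }
  if (e$mode == "smiles") {
    return(list(kind = "sample", allowed = c(sets$smiles, sets$eos)))
  }
  nmg_stop("contract_violation", sprintf("unexpected generation mode %s", e$mode))
}

# record an emitted token and advance the state machine
plan_advance <- function(e, sets, id, numeric, sampled) {
  e$tokens <- c(e$tokens, id)
  e$nums <- c(e$nums, numeric)
  e$sampled <- c(e$sampled, sampled)
  if (e$fptr < length(e$forced) && !sampled) {
    e$fptr <- e$fptr + 1L
    if (e$fptr == length(e$forced)) {
      if (e$mode == "pre_smiles") {
        e$mode <- "smiles"
      } else if (!is.null(e$pending_group)) {
        g <- e$pending_group
        e$pending_group <- NULL
        e$group <- g
        e$inst_left <- e$counts[g]
        e$inst_atoms <- 0L
        e$mode <- "group_pos"
      } else if (e$mode == "header" && !e$full_header) {
        e$group <- e$group + 1L     # count-0 group completed by [NONE]
      }
    }
    return(invisible(e))
  }
  # sampled token
  if (e$mode == "group_pos") {
    if (id == sets$sep) {
      e$inst_left <- e$inst_left - 1L
      e$inst_atoms <- 0L
      if (e$inst_left == 0L) { e$mode <- "header" }
    } else {
      e$inst_atoms <- e$inst_atoms + 1L
    }
  } else if (e$mode == "smiles") {
    if (id == sets$eos) e$mode <- "done"
  }
  invisible(e)
}

## ---- the generation driver ----

#' Generate molecules under functional-group count constraints
#'
#' @param model a fitted `nummolgen_model`
#' @param constraints one constraint, or a list of them; each either an
#'   integer count vector (length = FG-vocabulary size) or a
#'   `molecule_annotation` (its full header, including positions, is
#'   teacher-forced)
#' @param mode `"greedy"`, `"temperature"` or `"top_k"`
#' @param temperature softmax temperature for the sampling modes
#' @param top_k candidate-set size for `"top_k"`
#' @param seed RNG seed
#' @param pockets optional pocket context(s), one per constraint (or one
#'   shared)
#' @return list with `smiles` (character, raw model output: validity is the
#'   evaluator's business), `sequences` (emitted `dual_sequence`s) and
#'   `sampled` (per-sequence logical mask of sampled positions)
#' @export
nmf_generate <- function(model, constraints, mode = c("greedy", "temperature", "top_k"),
                         temperature = 1.0, top_k = 10L, seed = 0L,
                         pockets = NULL) {
  stopifnot(inherits(model, "nummolgen_model"))
  mode <- match.arg(mode)
  if (inherits(constraints, "molecule_annotation") || !is.list(constraints))
    constraints <- list(constraints)
  B <- length(constraints)
  set.seed(as.integer(seed))
  sets <- gen_token_sets(model$tok_vocab)
  plans <- lapply(constraints, new_gen_plan, tok_vocab = model$tok_vocab,
                  fg_vocab = model$fg_vocab)
  st <- decode_init(model$params, model$config, B, pockets)
  logits <- NULL
  repeat {
    nexts <- lapply(plans, plan_next, sets = sets)
    kinds <- vapply(nexts, `[[`, character(1), "kind")
    if (all(kinds == "done")) break
    if (st$t >= model$config$max_len - 1L) {
      # out of room: close every open sequence with [EOS]
      for (b in which(kinds != "done"))
        plan_advance(plans[[b]], sets, sets$eos, 0, kinds[b] == "sample")
      break
    }
    ids <- integer(B); nums <- numeric(B); samp <- logical(B)
    for (b in seq_len(B)) {
      nx <- nexts[[b]]
      if (nx$kind == "done") {
        ids[b] <- sets$pad; nums[b] <- 0
      } else if (nx$kind == "forced") {
        ids[b] <- nx$id; nums[b] <- nx$numeric
      } else {
        z <- logits[b, ] / max(temperature, 1e-8)
        keep <- nx$allowed + 1L
        if (mode == "top_k" && length(keep) > top_k)
          keep <- keep[order(z[keep], decreasing = TRUE)[seq_len(top_k)]]
        zk <- z[keep]
        pick <- if (mode == "greedy") {
          keep[which.max(zk)]
        } else {
          p <- exp(zk - max(zk)); p <- p / sum(p)
          keep[sample.int(length(keep), 1L, prob = p)]
        }
        ids[b] <- pick - 1L; nums[b] <- 0; samp[b] <- TRUE
      }
    }
    stepped <- decode_step(st, ids, nums)
    st <- stepped$state; logits <- stepped$logits
    for (b in seq_len(B))
      if (nexts[[b]]$kind != "done")
        plan_advance(plans[[b]], sets, ids[b], nums[b], samp[b])
  }
  seqs <- lapply(plans, function(e)
    structure(list(text_ids = e$tokens, numeric_values = e$nums),
              class = "dual_sequence"))
  smiles <- vapply(seqs, function(s)
    tryCatch(decode_smiles(s, model$tok_vocab), error = function(err) ""),
    character(1))
  list(smiles = smiles, sequences = seqs,
       sampled = lapply(plans, function(e) e$sampled))
}

#' Simulate molecules from a fitted generator
#'
#' `simulate()` draws `nsim` molecules per constraint with temperature
#' sampling (the model's stochastic output distribution).
#' @param object a `nummolgen_model`
#' @param nsim molecules per constraint
#' @param seed RNG seed
#' @param constraints as in [nmf_generate()]
#' @param ... passed to [nmf_generate()]
#' @export
simulate.nummolgen_model <- function(object, nsim = 1, seed = 0L,
                                  constraints, ...) {
  if (inherits(constraints, "molecule_annotation") || !is.list(constraints))
    constraints <- list(constraints)
  reps <- rep(constraints, each = nsim)
  nmf_generate(object, reps, mode = "temperature", seed = seed, ...)$smiles
}
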