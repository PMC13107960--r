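# Dual-sequence codec: serialize annotations into aligned text-token and
# numeric-value streams and back.
#
# Template (fixed, versioned):
#   for each group, in vocabulary order:
#     present: [FG:name] [NUM] pos... [SEP] pos... [SEP]   (one pos-run +
#              trailing [SEP] per instance, k_i instances)
#     absent : [FG:name] [NUM] [NONE]
#   then [BOS] <smiles tokens> [EOS].
# The numeric stream holds the group count at each [NUM] position, 0
# elsewhere, so both streams always have equal length.

SPECIAL_TOKENS <- c("[PAD]", "[BOS]", "[EOS]", "[NUM]", "[SEP]", "[NONE]")
SMILES_TOKEN_RE <- "\\[[^]]*\\]|Cl|Br|%[0-9][0-9]|."

#' Tokenize a SMILES string at atom level
#' @param smiles SMILES string
#' @return character vector of tokens
#' @export
tokenize_smiles <- function(smiles) {
  regmatches(smiles, gregexpr(SMILES_TOKEN_RE, smiles))[[1]]
}

fg_token <- function(name) paste0("[FG:", name, "]")
pos_token <- function(i) paste0("pos", i)

#' Build the token vocabulary for a corpus
#'
#' Deterministic layout: special tokens first ([PAD] always id 0), then one
#' [FG:name] token per functional-group type in vocabulary order, then
#' position tokens pos0..pos(max_atoms-1), then the SMILES tokens observed in
#' the corpus, sorted lexicographically (C locale).
#'
#' @param annotations list of `molecule_annotation`
#' @param fg_vocab the `fg_vocabulary` used to annotate
#' @param max_atoms position-token cap; defaults to the corpus maximum
#' @return object of class `token_vocabulary`
#' @export
build_token_vocabulary <- function(annotations, fg_vocab, max_atoms = NULL) {
  if (!length(annotations))
    nmg_stop("config_error", "cannot build a token vocabulary from an empty corpus")
  stopifnot(inherits(fg_vocab, "fg_vocabulary"))
  if (is.null(max_atoms))
    max_atoms <- max(vapply(annotations, `[[`, integer(1), "n_atoms"))
  smi_tok <- sort(unique(unlist(lapply(annotations, function(a)
    tokenize_smiles(a$canonical_smiles)))), method = "radix")
  tokens <- c(SPECIAL_TOKENS,
              vapply(fg_vocab$types, function(t) fg_token(t$name), character(1)),
              pos_token(seq_len(max_atoms) - 1L),
              smi_tok)
  if (anyDuplicated(tokens))
    nmg_stop("config_error", "token collision while building vocabulary")
  structure(list(tokens = tokens, id = stats::setNames(seq_along(tokens) - 1L, tokens),
                 max_atoms = as.integer(max_atoms),
                 n_fg = fg_vocab$size),
            class = "token_vocabulary")
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat(sprintf("<token_vocabulary> %d tokens (%d FG, %d position, %d SMILES)\n",
              length(x$tokens), x$n_fg, x$max_atoms,
              length(x$tokens) - length(SPECIAL_TOKENS) - x$n_fg - x$max_atoms))
  invisible(x)
}

tok_id <- function(tok_vocab, tokens) {
  ids <- tok_vocab$id[tokens]
  if (anyNA(ids))
    nmg_stop("encoding_error",
             sprintf("token(s) not in vocabulary: %s",
                     paste(unique(tokens[is.na(ids)]), collapse = " ")),
             tokens = tokens[is.na(ids)])
  unname(ids)
}

#' Encode an annotation into a dual sequence
#'
#' @param annotation a `molecule_annotation`
#' @param tok_vocab a `token_vocabulary`
#' @return object of class `dual_sequence`: `text_ids` (0-based token ids)
#'   and `numeric_values` (reals, aligned)
#' @export
encode_dual <- function(annotation, tok_vocab) {
  stopifnot(inherits(annotation, "molecule_annotation"),
            inherits(tok_vocab, "token_vocabulary"))
  if (annotation$n_atoms > tok_vocab$max_atoms)
    nmg_stop("encoding_error",
             sprintf("molecule has %d atoms, position tokens cap at %d",
                     annotation$n_atoms, tok_vocab$max_atoms))
  text <- character(0); num <- numeric(0)
  for (t in annotation$triplets) {
    text <- c(text, fg_token(t$fg_type), "[NUM]")
    num <- c(num, 0, t$count)
    if (t$count == 0L) {
      text <- c(text, "[NONE]"); num <- c(num, 0)
    } else {
      for (inst in t$instances) {
        ptoks <- vapply(inst, function(at) pos_token(at$index), character(1))
        text <- c(text, ptoks, "[SEP]")
        num <- c(num, rep(0, length(ptoks) + 1L))
      }
    }
  }
  stoks <- tokenize_smiles(annotation$canonical_smiles)
  text <- c(text, "[BOS]", stoks, "[EOS]")
  num <- c(num, rep(0, length(stoks) + 2L))
  structure(list(text_ids = tok_id(tok_vocab, text), numeric_values = num),
            class = "dual_sequence")
}

#' @export
print.dual_sequence <- function(x, ...) {
  cat(sprintf("<dual_sequence> length %d, %d [NUM] slots, total count %g\n",
              length(x$text_ids), sum(x$numeric_values != 0),
              sum(x$numeric_values)))
  invisible(x)
}

seq_tokens <- function(seq, tok_vocab) tok_vocab$tokens[seq$text_ids + 1L]

#' Decode the SMILES region of a dual sequence
#'
#' @param seq a `dual_sequence`
#' @param tok_vocab the `token_vocabulary`
#' @return the SMILES string between [BOS] and [EOS]
#' @export
decode_smiles <- function(seq, tok_vocab) {
  toks <- seq_tokens(seq, tok_vocab)
  b <- match("[BOS]", toks); e <- match("[EOS]", toks)
  if (is.na(b) || is.na(e) || e <= b)
    nmg_stop("malformed_sequence", "sequence has no [BOS]...[EOS] span")
  if (e == b + 1L) return("")
  paste(toks[(b + 1L):(e - 1L)], collapse = "")
}

#' Decode the constraint count vector of a dual sequence
#'
#' @param seq a `dual_sequence`
#' @param fg_vocab the `fg_vocabulary`
#' @param tok_vocab the `token_vocabulary`
#' @return named integer count vector (one entry per group)
#' @export
decode_constraints <- function(seq, fg_vocab, tok_vocab) {
  stopifnot(inherits(fg_vocab, "fg_vocabulary"))
  toks <- seq_tokens(seq, tok_vocab)
  b <- match("[BOS]", toks)
  header_end <- if (is.na(b)) length(toks) else b - 1L
  slots <- which(toks[seq_len(header_end)] == "[NUM]")
  if (length(slots) != fg_vocab$size)
    nmg_stop("malformed_sequence",
             sprintf("header has %d [NUM] slots, vocabulary has %d",
                     length(slots), fg_vocab$size))
  stats::setNames(as.integer(round(seq$numeric_values[slots])),
                  vapply(fg_vocab$types, `[[`, character(1), "name"))
}

#' Pad a batch of dual sequences to a common length
#'
#' @param seqs list of `dual_sequence`
#' @param max_len target length; over-length sequences are an error, never
#'   silently truncated
#' @return list with `text_ids` (B x L integer matrix, [PAD]=0),
#'   `numeric_values` (B x L), `mask` (B x L logical, TRUE = real token)
#' @export
pad_batch <- function(seqs, max_len = NULL) {
  stopifnot(length(seqs) > 0)
  lens <- vapply(seqs, function(s) length(s$text_ids), integer(1))
  if (is.null(max_len)) max_len <- max(lens)
  over <- lens > max_len
  if (any(over))
    nmg_stop("truncation_error",
             sprintf("%d sequence(s) exceed max_len=%d (max observed %d)",
                     sum(over), max_len, max(lens)))
  B <- length(seqs)
  text <- matrix(0L, B, max_len)       # [PAD] id is 0
  num <- matrix(0, B, max_len)
  mask <- matrix(FALSE, B, max_len)
  for (b in seq_len(B)) {
    l <- lens[b]
    text[b, seq_len(l)] <- seqs[[b]]$text_ids
    num[b, seq_len(l)] <- seqs[[b]]$numeric_values
    mask[b, seq_len(l)] <- TRUE
  }
  list(text_ids = text, numeric_values = num, mask = mask, lengths = lens)
}

#' Unpad a batch back into dual sequences
#' @param batch result of [pad_batch()]
#' @return list of `dual_sequence`
#' @export
unpad_batch <- function(batch) {
  lapply(seq_len(nrow(batch$text_ids)), function(b) {
    l <- batch$lengths[b]
    structure(list(text_ids = batch$text_ids[b, seq_len(l)],
                   numeric_values = batch$numeric_values[b, seq_len(l)]),
              class = "dual_sequence")
  })
}

#' Serialize encoded sequences to JSONL
#' @param seqs list of `dual_sequence`
#' @param tok_vocab the `token_vocabulary`
#' @param path output file
#' @export
write_dual_sequences <- function(seqs, tok_vocab, path) {
  write_jsonl(lapply(seqs, function(s) list(
    text_tokens = seq_tokens(s, tok_vocab),
    numeric_values = s$numeric_values)), path)
}
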