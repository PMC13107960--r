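test_that("token vocabulary is deterministic with the mandated layout", {
  fx <- fx_encoded()
  tv <- fx$tv
  expect_identical(unname(tv$id[["[PAD]"]]), 0L)
  expect_true(all(c("[BOS]", "[EOS]", "[NUM]", "[SEP]", "[NONE]") %in% tv$tokens))
  expect_identical(unname(tv$id[tv$tokens]), seq_along(tv$tokens) - 1L)
  expect_identical(sum(grepl("^\\[FG:", tv$tokens)), 27L)
  # position tokens cover the corpus maximum
  max_atoms <- max(vapply(fx$anns, `[[`, integer(1), "n_atoms"))
  expect_true(paste0("pos", max_atoms - 1L) %in% tv$tokens)
  tv2 <- build_token_vocabulary(fx$anns, fx_vocab())
  expect_identical(tv, tv2)
  expect_error(build_token_vocabulary(list(), fx_vocab()),
               class = "nummolgen_config_error")
})

test_that("encoding follows the template and keeps both streams aligned", {
  fx <- fx_encoded()
  tv <- fx$tv
  for (i in seq_along(fx$seqs)) {
    s <- fx$seqs[[i]]
    expect_identical(length(s$text_ids), length(s$numeric_values))
    toks <- tv$tokens[s$text_ids + 1L]
    # numeric sparsity: nonzero only at [NUM]
    expect_true(all(toks[s$numeric_values != 0] == "[NUM]"))
    # one [NUM] per group, in vocabulary order
    fg_pos <- which(grepl("^\\[FG:", toks))
    expect_length(fg_pos, 27L)
    expect_identical(toks[fg_pos],
                     vapply(fx_vocab()$types, function(t)
                       paste0("[FG:", t$name, "]"), character(1)))
    expect_identical(toks[fg_pos + 1L], rep("[NUM]", 27L))
    # absent groups carry [NONE]; the numeric at [NUM] equals the count
    cv <- unname(count_vector(fx$anns[[i]]))
    expect_identical(as.integer(s$numeric_values[fg_pos + 1L]), cv)
    expect_identical(toks[fg_pos[cv == 0] + 2L],
                     rep("[NONE]", sum(cv == 0)))
  }
})

test_that("all-absent annotations produce an all-zero numeric stream", {
  vocab <- fx_vocab()
  ann <- annotate_molecule("C", vocab)   # methane: no groups at all
  tv <- build_token_vocabulary(list(ann), vocab)
  s <- encode_dual(ann, tv)
  expect_true(all(s$numeric_values == 0))
  toks <- tv$tokens[s$text_ids + 1L]
  expect_identical(sum(toks == "[NONE]"), 27L)
})

test_that("decode round-trips SMILES and count vectors exactly", {
  fx <- fx_encoded()
  for (i in seq_along(fx$seqs)) {
    expect_identical(decode_smiles(fx$seqs[[i]], fx$tv),
                     fx$anns[[i]]$canonical_smiles)
    expect_identical(decode_constraints(fx$seqs[[i]], fx_vocab(), fx$tv),
                     count_vector(fx$anns[[i]]))
  }
  # malformed sequences are refused
  s <- fx$seqs[[1]]
  toks <- fx$tv$tokens[s$text_ids + 1L]
  cut <- structure(list(text_ids = s$text_ids[seq_len(which(toks == "[BOS]"))],
                        numeric_values = s$numeric_values[seq_len(which(toks == "[BOS]"))]),
                   class = "dual_sequence")
  expect_error(decode_smiles(cut, fx$tv), class = "nummolgen_malformed_sequence")
  short <- structure(list(text_ids = s$text_ids[1:5],
                          numeric_values = s$numeric_values[1:5]),
                     class = "dual_sequence")
  expect_error(decode_constraints(short, fx_vocab(), fx$tv),
               class = "nummolgen_malformed_sequence")
})

test_that("encoding rejects out-of-vocabulary tokens", {
  vocab <- fx_vocab()
  ann_small <- annotate_molecule("CCO", vocab)
  tv_small <- build_token_vocabulary(list(ann_small), vocab)
  ann_br <- annotate_molecule("BrCCBr", vocab)   # Br token unseen
  expect_error(encode_dual(ann_br, tv_small), class = "nummolgen_encoding_error")
})

test_that("pad_batch pads, masks, refuses over-length, and unpads", {
  fx <- fx_encoded()
  seqs <- fx$seqs[1:4]
  lens <- vapply(seqs, function(s) length(s$text_ids), integer(1))
  batch <- pad_batch(seqs, max_len = max(lens))
  expect_identical(dim(batch$text_ids), c(4L, max(lens)))
  expect_identical(unname(rowSums(batch$mask)), as.numeric(lens))
  expect_true(all(batch$text_ids[!batch$mask] == 0L))
  expect_true(all(batch$numeric_values[!batch$mask] == 0))
  back <- unpad_batch(batch)
  expect_identical(back, seqs)
  expect_error(pad_batch(seqs, max_len = max(lens) - 1L),
               class = "nummolgen_truncation_error")
  # exact-length sequence gets no padding
  one <- pad_batch(seqs[1], max_len = lens[1])
  expect_true(all(one$mask))
})
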