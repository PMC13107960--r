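test_that("canonicalization normalizes, is idempotent, and rejects bad input", {
  expect_identical(canonicalize_smiles("OCC"), "CCO")
  expect_identical(canonicalize_smiles("CCO"), "CCO")
  expect_error(canonicalize_smiles("C1CC"), class = "nummolgen_parse_error")
  expect_error(canonicalize_smiles(""), class = "nummolgen_parse_error")

  smi <- c(fx_fixture100(), fx_encoded(40L, seed = 3L)$corpus)
  can1 <- vapply(smi, canonicalize_smiles, character(1), USE.NAMES = FALSE)
  can2 <- vapply(can1, canonicalize_smiles, character(1), USE.NAMES = FALSE)
  expect_identical(can1, can2)
})

test_that("vocabulary building is deterministic with 27 default types", {
  vocab <- fx_vocab()
  expect_s3_class(vocab, "fg_vocabulary")
  expect_identical(vocab$size, 27L)
  expect_identical(vocab$size, length(vocab$types))
  idx <- vapply(vocab$types, `[[`, integer(1), "vocab_index")
  expect_identical(idx, 0:26)
  nm <- vapply(vocab$types, `[[`, character(1), "name")
  expect_false(anyDuplicated(nm) > 0)
  # determinism
  expect_identical(fg_vocab_hash(vocab), fg_vocab_hash(build_vocabulary("default")))

  one <- tempfile(fileext = ".tsv")
  writeLines("hydroxyl\t[OX2H]", one)
  expect_identical(build_vocabulary(one)$size, 1L)
  empty <- tempfile(fileext = ".tsv")
  writeLines("# nothing", empty)
  expect_error(build_vocabulary(empty), class = "nummolgen_config_error")
  bad <- tempfile(fileext = ".tsv")
  writeLines("broken_pattern\t[QQ5]", bad)
  expect_error(build_vocabulary(bad), class = "nummolgen_format_error")
})

test_that("annotation recovers expected groups with positional instances", {
  vocab <- fx_vocab()
  benz <- annotate_molecule("c1ccccc1", vocab)
  cv <- count_vector(benz)
  expect_identical(unname(cv[["aromatic_ring6"]]), 1L)
  inst <- benz$triplets[[which(names(cv) == "aromatic_ring6")]]$instances[[1]]
  expect_length(inst, 6)
  expect_true(all(vapply(inst, `[[`, character(1), "element") == "C"))
  expect_setequal(vapply(inst, `[[`, integer(1), "index"), 0:5)

  methane <- annotate_molecule("C", vocab)
  expect_true(all(count_vector(methane) == 0L))

  glycol <- annotate_molecule("OCCO", vocab)
  expect_identical(unname(count_vector(glycol)[["hydroxyl"]]), 2L)

  expect_error(annotate_molecule("C1CC", vocab), class = "nummolgen_parse_error")
})

test_that("annotation is deterministic and internally consistent", {
  vocab <- fx_vocab()
  a1 <- annotate_molecule("CC(=O)Oc1ccccc1C(=O)O", vocab)
  a2 <- annotate_molecule("CC(=O)Oc1ccccc1C(=O)O", vocab)
  expect_identical(a1, a2)
  for (ann in fx_encoded()$anns) {
    expect_length(ann$triplets, vocab$size)
    for (t in ann$triplets) {
      expect_identical(t$count, length(t$instances))
      for (inst in t$instances) {
        idx <- vapply(inst, `[[`, integer(1), "index")
        expect_false(anyDuplicated(idx) > 0)
        expect_true(all(idx >= 0 & idx < ann$n_atoms))
      }
    }
  }
})

test_that("count vectors project the annotation exactly", {
  vocab <- fx_vocab()
  ann <- annotate_molecule("OCCO", vocab)
  cv <- count_vector(ann)
  expect_length(cv, vocab$size)
  expect_identical(unname(cv),
                   vapply(ann$triplets, `[[`, integer(1), "count"))
  expect_true(all(cv >= 0))
})

test_that("counts agree with the OpenBabel SMARTS oracle on drug-like molecules", {
  vocab <- fx_vocab()
  subset <- fx_fixture100()[seq(1, 100, by = 4)]   # 25 molecules x 27 patterns
  for (s in subset) {
    can <- canonicalize_smiles(s)
    obm <- ChemmineOB::forEachMol("SMILES", can, identity)
    cv <- count_vector(annotate_molecule(can, vocab))
    ob <- vapply(vocab$types, function(t)
      as.integer(ChemmineOB::smartsSearch_OB(obm, t$pattern,
                                             uniqueMatches = TRUE)),
      integer(1))
    expect_identical(unname(cv), ob, info = can)
  }
})

test_that("annotations serialize to JSONL", {
  vocab <- fx_vocab()
  anns <- annotate_molecules(c("CCO", "c1ccccc1"), vocab)
  path <- tempfile(fileext = ".jsonl")
  write_annotations(anns, path)
  recs <- nummolgen:::read_jsonl(path)
  expect_length(recs, 2)
  expect_identical(recs[[1]]$canonical_smiles, "CCO")
  expect_length(recs[[2]]$triplets$type, vocab$size)
})
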