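test_that("validity, uniqueness and novelty behave on edge cases", {
  expect_equal(validity(c("CCO", "C1CC")), 0.5)
  expect_equal(uniqueness(c("CCO", "OCC")), 0.5)   # same canonical molecule
  expect_equal(novelty(c("CCO"), reference = "CCO"), 0)
  expect_equal(novelty(c("CCO"), reference = character(0)), 1)
  expect_error(validity(character(0)), class = "nummolgen_metric_undefined")
  expect_error(uniqueness(character(0)), class = "nummolgen_metric_undefined")
})

test_that("Lipinski metrics separate drug-like from rule-breaking molecules", {
  lip <- lipinski_metrics("CC(=O)Oc1ccccc1C(=O)O")      # aspirin
  expect_identical(lip$all5_fraction, 1)
  expect_identical(lip$mean_rules, 5)
  giant <- paste0(paste(rep("CCCCCCCNC", 11), collapse = ""), "CCCCCCCCCCCC")
  lip2 <- lipinski_metrics(giant)
  expect_identical(lip2$all5_fraction, 0)
  expect_identical(lip2$mean_rules, 0)
  both <- lipinski_metrics(c("CC(=O)Oc1ccccc1C(=O)O", giant))
  expect_equal(both$all5_fraction, 0.5)
  expect_true(both$mean_rules >= 0 && both$mean_rules <= 5)
})

test_that("QED is in [0,1] and SA normalization maps the raw scale correctly", {
  smiles <- c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "c1ccc2ccccc2c1")
  q <- qed_score(smiles)
  expect_true(all(q >= 0 & q <= 1))
  raw <- sa_score(smiles)
  norm <- sa_score(smiles, normalized = TRUE)
  expect_true(all(raw >= 1 & raw <= 10))
  expect_equal(norm, (10 - raw) / 9)
  # endpoints of the stated map
  expect_identical((10 - 1) / 9, 1)
  expect_identical((10 - 10) / 9, 0)
  qs <- qed_and_sa(smiles)
  expect_identical(attr(qs, "n_failed"), 0L)
})

test_that("diversity handles duplicates, disjoint sets and permutations", {
  expect_identical(diversity(c("CCO", "CCO")), 0)
  expect_identical(diversity(c("CCCC", "O=S(=O)(O)O")), 1)  # no shared bits
  set3 <- c("CCO", "c1ccccc1", "CC(=O)O")
  d1 <- diversity(set3)
  d2 <- diversity(rev(set3))
  expect_identical(d1, d2)
  expect_true(d1 >= 0 && d1 <= 1)
  expect_error(diversity("CCO"), class = "nummolgen_metric_undefined")
})

test_that("success rate applies the strict thresholds with boundaries excluded", {
  recs <- data.frame(vina_dock = c(-8.5, -8.18, -9.0, -7.0),
                     qed = c(0.30, 0.30, 0.25, 0.80),
                     sa = c(0.60, 0.60, 0.70, 0.59))
  # row1: success; row2: dock at boundary; row3: qed at boundary; row4: sa at
  # boundary and weak dock
  expect_equal(success_rate(recs), 0.25)
  expect_error(success_rate(recs[0, ]), class = "nummolgen_metric_undefined")
  recs$qed[2] <- NA
  expect_error(success_rate(recs), class = "nummolgen_scoring_error")
})

test_that("constraint compliance measures MSE / EMR / FMR as defined", {
  vocab <- fx_vocab()
  smiles <- c("OCCO", "CC(=O)Oc1ccccc1C(=O)O", "c1ccccc1")
  targets <- lapply(smiles, function(s)
    unname(count_vector(annotate_molecule(s, vocab))))
  cr <- constraint_compliance(targets, smiles, vocab)
  expect_identical(cr$mse, 0)
  expect_identical(cr$emr, 1)
  expect_identical(cr$fmr, 1)
  # perturb one group of one molecule by exactly 3: fuzzy holds, exact fails
  t2 <- targets
  t2[[1]][1] <- t2[[1]][1] + 3L
  cr2 <- constraint_compliance(t2, smiles, vocab)
  expect_equal(cr2$emr, 2 / 3)
  expect_identical(cr2$fmr, 1)
  # by 4: fuzzy fails too
  t3 <- targets
  t3[[1]][1] <- t3[[1]][1] + 4L
  cr3 <- constraint_compliance(t3, smiles, vocab)
  expect_equal(cr3$fmr, 2 / 3)
  # invalid molecules fail EMR/FMR and leave the MSE
  cr4 <- constraint_compliance(targets, c("C1CC", smiles[2:3]), vocab)
  expect_identical(cr4$n_invalid, 1L)
  expect_equal(cr4$emr, 2 / 3)
  expect_identical(cr4$mse, 0)
  expect_error(constraint_compliance(targets[1:2], smiles, vocab),
               class = "nummolgen_contract_violation")
})

test_that("per-molecule MSE follows the stated formula on a two-group vocabulary", {
  two <- tempfile(fileext = ".tsv")
  writeLines(c("hydroxyl\t[OX2H]", "amine\t[NX3H2]"), two)
  vocab2 <- build_vocabulary(two)
  # target (2,0) vs observed (1,1): mean((1)^2,(−1)^2) = 1
  cr <- constraint_compliance(list(c(2L, 0L)), "NCCO", vocab2)
  expect_identical(cr$mse, 1)
  expect_identical(cr$emr, 0)
  expect_identical(cr$fmr, 1)
})

test_that("exact matching is never easier than fuzzy matching", {
  vocab <- fx_vocab()
  smiles <- fx_encoded()$corpus[1:12]
  set.seed(33)
  targets <- lapply(smiles, function(s) {
    tv <- unname(count_vector(annotate_molecule(s, vocab)))
    tweak <- sample(length(tv), 3)
    tv[tweak] <- pmax(0L, tv[tweak] + sample(-3:3, 3, TRUE))
    tv
  })
  cr <- constraint_compliance(targets, smiles, vocab)
  expect_lte(cr$emr, cr$fmr)
  expect_gte(cr$mse, 0)
  expect_true(all(cr$per_group_frequency_ratio >= 0 &
                    cr$per_group_frequency_ratio <= 1))
})

test_that("functional-group profiles report frequencies and averages", {
  vocab <- fx_vocab()
  prof <- fg_profiles(list(a = "c1ccccc1", b = "c1ccccc1"), vocab,
                      groups = "aromatic_ring6")
  expect_identical(unname(prof$frequency_ratio["aromatic_ring6", "a"]), 1)
  expect_identical(unname(prof$average_count["aromatic_ring6", "a"]), 1)
  expect_identical(profile_mse(prof, "a", "b"), 0)
  expect_identical(profile_mse(prof, "a", "b", "average_count"), 0)
  mixed <- fg_profiles(list(ref = c("c1ccccc1", "CCO"),
                            gen = c("c1ccccc1", "c1ccc2ccccc2c1")), vocab)
  expect_true(all(mixed$frequency_ratio >= 0 & mixed$frequency_ratio <= 1))
  expect_gte(profile_mse(mixed, "ref", "gen"), 0)
  expect_error(fg_profiles(list(a = "CCO"), vocab, groups = "no_such_group"),
               class = "nummolgen_lookup_error")
  expect_error(fg_profiles(list(a = character(0)), vocab),
               class = "nummolgen_metric_undefined")
})

test_that("the quality report aggregates all metrics coherently", {
  smiles <- c("CCO", "OCC", "c1ccccc1", "CC(=O)O", "C1CC")
  qr <- quality_report(smiles, reference = "CCO")
  expect_equal(qr$validity, 0.8)
  expect_true(qr$uniqueness > 0 && qr$uniqueness <= 1)
  expect_true(qr$novelty >= 0 && qr$novelty <= 1)
  expect_true(qr$lipinski_mean_rules >= 0 && qr$lipinski_mean_rules <= 5)
  expect_true(qr$diversity >= 0 && qr$diversity <= 1)
  expect_output(print(qr), "validity")
})
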