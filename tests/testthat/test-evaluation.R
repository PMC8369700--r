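test_that("tanimoto follows the set formula on hand-built bitsets", {
  a <- c(TRUE, TRUE, TRUE, FALSE)
  b <- c(FALSE, TRUE, TRUE, TRUE)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, !a), 0)
  expect_equal(tanimoto(a, b), 0.5)      # {1,2,3} vs {2,3,4}
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_error(tanimoto(logical(4), logical(4)), "undefined")
})

test_that("tanimoto stays within [0, 1] on random fingerprints", {
  set.seed(31)
  for (i in 1:50) {
    a <- runif(64) > 0.5; b <- runif(64) > 0.5
    if (!any(a | b)) next
    t <- tanimoto(a, b)
    expect_gte(t, 0); expect_lte(t, 1)
    expect_equal(t, tanimoto(b, a))
  }
})

test_that("isomorphism is InChI string equality", {
  expect_true(is_isomorphic("CCO", "OCC"))
  expect_true(is_isomorphic("CCO", "CCO"))
  expect_false(is_isomorphic("C[C@H](N)O", "C[C@@H](N)O"))  # enantiomers
  expect_false(is_isomorphic("CCO", "CCN"))
  expect_error(is_isomorphic("C1CC", "CCO"), "first side")
  expect_error(is_isomorphic("CCO", "C1CC"), "second side")
})

test_that("isomorphism behaves as an equivalence relation", {
  smi <- toy_smiles_100()[1:10]
  spell <- canonical_smiles(smi, kekule = TRUE)  # different spelling
  expect_true(all(is_isomorphic(smi, smi)))           # reflexive
  expect_true(all(is_isomorphic(smi, spell)))         # same molecule
  expect_true(all(is_isomorphic(spell, smi)))         # symmetric
})

test_that("isomorphic pairs always score Tanimoto 1 under a structural
          fingerprint", {
  smi <- toy_smiles_100()[1:60]
  respelled <- canonical_smiles(smi, kekule = TRUE)
  fp1 <- mol_fingerprints(smi)
  fp2 <- mol_fingerprints(respelled)
  for (i in seq_along(smi)) {
    expect_equal(tanimoto(fp1[i, ], fp2[i, ]), 1)
  }
})

test_that("evaluate_pairs reproduces hand-computed summaries", {
  smi <- toy_smiles_100()[1:10]
  rep1 <- evaluate_pairs(data.frame(reference = smi, predicted = smi))
  expect_equal(rep1$avg_tanimoto, 1)
  expect_equal(rep1$pct_tanimoto_1, 100)
  expect_equal(rep1$pct_isomorphic_of_t1, 100)
  # half right: avg = (1 + t)/2 with one exact and one near miss
  pair <- evaluate_pairs(data.frame(
    reference = c("CCCCO", "CCCCO"),
    predicted = c("CCCCO", "CCCCN")))
  t2 <- pair$per_pair$tanimoto[2]
  expect_lt(t2, 1)
  expect_equal(pair$avg_tanimoto, (1 + t2) / 2)
  expect_equal(pair$pct_tanimoto_1, 50)
  expect_equal(pair$n_tanimoto_1, 1L)
})

test_that("enantiomer predictions are Tanimoto-1.0 but not isomorphic", {
  # the path fingerprint is constitution-only, so mirror images collide at
  # similarity 1.0 and only the InChI layer separates them
  rep <- evaluate_pairs(data.frame(reference = "C[C@H](N)C(C)O",
                                   predicted = "C[C@@H](N)C(C)O"))
  expect_equal(rep$pct_tanimoto_1, 100)
  expect_equal(rep$pct_isomorphic_of_t1, 0)
})

test_that("unparseable molecules are segregated, not silently scored", {
  expect_warning(
    rep <- evaluate_pairs(data.frame(
      reference = c("CCCO", "C1CC", "CCCN"),
      predicted = c("CCCO", "CCCO", "C1CC"))),
    "unparseable")
  expect_equal(rep$n_pairs, 2L)
  expect_equal(rep$n_excluded, 1L)
  expect_equal(rep$n_unparseable_pred, 1L)
  # the bad prediction scores zero
  expect_equal(rep$per_pair$tanimoto[3], 0)
  expect_error(evaluate_pairs(data.frame(reference = character(),
                                         predicted = character())))
})

test_that("tidy and glance expose the report tables", {
  smi <- toy_smiles_100()[1:5]
  rep <- evaluate_pairs(data.frame(reference = smi, predicted = smi))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5L)
  gl <- glance(rep)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$avg_tanimoto, 1)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
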