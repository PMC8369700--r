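test_that("descriptors match hand-derived values on elementary molecules", {
  d <- compute_descriptors(c("C", "CCO", "[Na+].[Cl-]"))
  # single atom: no bonds, one fragment
  expect_equal(d$n_bonds[1], 0L)
  expect_equal(d$element_set[[1]], "C")
  expect_equal(d$n_fragments[1], 1L)
  # ethanol: 2 heavy-atom bonds, average MW ~46.07 Da
  expect_equal(d$n_bonds[2], 2L)
  expect_equal(d$mol_weight[2], 46.07, tolerance = 1e-3)
  # dot-disconnected salt: two fragments, formally charged
  expect_equal(d$n_fragments[3], 2L)
  expect_true(d$has_formal_charge[3])
  expect_false(d$has_stereo[3])
})

test_that("descriptors flag stereo and isotopes", {
  d <- compute_descriptors(c("C[C@H](N)O", "[2H]OC(C)C"))
  expect_true(d$has_stereo[1])
  expect_false(d$has_isotope[1])
  expect_true(d$has_isotope[2])
  expect_equal(d$smiles_length, nchar(d$canonical_smiles))
})

test_that("unparseable SMILES yield an unparseable decision", {
  d <- check_molecule(c("CCCO", "C1CC"), rule_set("dataset1"))
  expect_true(d$passed[1])
  expect_false(d$passed[2])
  expect_equal(d$failed_rules[[2]], "unparseable")
})

test_that("rule decisions follow the documented boundaries and order", {
  r1 <- rule_set("dataset1")
  d <- check_molecule(c("CCO", "CCCO", "C[Si](C)C", "C[C@H](N)O"), r1)
  # 2 bonds < min 3
  expect_false(d$passed[1])
  expect_equal(d$failed_rules[[1]], "bonds")
  # 3 bonds, MW 60.1, neutral, achiral: passes
  expect_true(d$passed[2])
  expect_length(d$failed_rules[[2]], 0L)
  # silicon not in the element set
  expect_false(d$passed[3])
  expect_true("elements" %in% d$failed_rules[[3]])
  # stereo rejected by the strict preset only
  expect_true("stereo" %in% d$failed_rules[[4]])
  d2 <- check_molecule("C[C@H](N)O", rule_set("dataset2"))
  expect_false("stereo" %in% d2$failed_rules[[1]])
})

test_that("charge rule is skipped by the permissive preset", {
  r2 <- rule_set("dataset2")
  d <- check_molecule("C[N+](C)(C)CCC", r2)
  expect_false("charge" %in% d$failed_rules[[1]])
  d1 <- check_molecule("C[N+](C)(C)CCC", rule_set("dataset1"))
  expect_true("charge" %in% d1$failed_rules[[1]])
})

test_that("filter_corpus preserves order, canonicalizes, and attributes
          rejections to the first failed rule", {
  res <- filter_corpus(c("C", "CCCO"), rule_set("dataset1"))
  expect_equal(nrow(res$survivors), 1L)
  expect_equal(res$survivors$input_smiles, "CCCO")
  expect_equal(res$stats$n_rejected[res$stats$rule == "bonds"], 1L)
  expect_equal(sum(res$stats$n_rejected), 1L)
  # empty corpus: zero stats with a warning
  expect_warning(res0 <- filter_corpus(character(), rule_set("dataset1")))
  expect_equal(nrow(res0$survivors), 0L)
  expect_true(all(res0$stats$n_rejected == 0L))
})

test_that("generated rule-passing corpus survives filtering unchanged", {
  smi <- toy_smiles_100()
  res <- filter_corpus(smi, rule_set("dataset1"))
  expect_equal(res$n_passed, 100L)
})

test_that("filtering is idempotent on survivors", {
  smi <- toy_smiles_100()
  res <- filter_corpus(smi, rule_set("dataset1"))
  res2 <- filter_corpus(res$survivors$smiles, rule_set("dataset1"))
  expect_equal(res2$n_passed, res$n_passed)
  expect_true(all(res2$stats$n_rejected == 0L))
})

test_that("loosening one threshold never decreases survivors; the strict
          preset is nested in the permissive one", {
  mixed <- c(toy_smiles_100()[1:40], toy_smiles_stereo_60()[1:30],
             "C", "CC", "[Na+].[Cl-]", "C[Si](C)C")
  base <- rule_set("dataset1")
  n_base <- filter_corpus(mixed, base)$n_passed
  for (loose in list(rule_set("dataset1", max_bonds = 50),
                     rule_set("dataset1", min_bonds = 1),
                     rule_set("dataset1", max_smiles_chars = 80),
                     rule_set("dataset1", max_mw = 3000))) {
    expect_gte(filter_corpus(mixed, loose)$n_passed, n_base)
  }
  # mode nesting: every dataset1 pass also passes dataset2
  d1 <- check_molecule(mixed, rule_set("dataset1"))
  d2 <- check_molecule(mixed, rule_set("dataset2"))
  expect_true(all(d2$passed[d1$passed]))
})

test_that("descriptors agree with an independent cheminformatics oracle", {
  smi <- c(toy_smiles_100(), toy_smiles_stereo_60(),
           "[Na+].[Cl-]", "C[N+](C)(C)C", "CCO")
  oracle <- rdkit_descriptors(smi)
  # the oracle toolchain is part of the reference image; if it ever goes
  # missing the comparison is vacuous rather than wrong
  expect_false(is.null(oracle))
  d <- compute_descriptors(smi)
  for (i in seq_along(smi)) {
    o <- oracle[[i]]
    expect_false(is.null(o))
    expect_equal(d$n_bonds[i], o$n_bonds,
                 label = sprintf("n_bonds for %s", smi[i]))
    expect_equal(d$n_fragments[i], o$n_frags)
    expect_equal(d$has_formal_charge[i], o$charged)
    expect_equal(d$mol_weight[i], o$mw, tolerance = 0.01)
    expect_setequal(setdiff(d$element_set[[i]], "H"),
                    setdiff(unlist(o$elements), "H"))
  }
})

test_that("rule set invariants are enforced at construction", {
  expect_error(rule_set("dataset1", min_bonds = 10, max_bonds = 5))
  expect_error(rule_set("dataset1", max_mw = 0))
  expect_error(rule_set("dataset1", allowed_elements = character()))
  r1 <- rule_set("dataset1"); r2 <- rule_set("dataset2")
  expect_false(r1$allow_charges); expect_false(r1$allow_stereo)
  expect_true(r2$allow_charges); expect_true(r2$allow_stereo)
})
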