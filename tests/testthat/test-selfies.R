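test_that("tokenization splits at bracket boundaries and reassembles", {
  expect_equal(tokenize_selfies("[C]"), "[C]")
  toks <- tokenize_selfies("[C][=C][Branch1][C][O]")
  expect_equal(toks, c("[C]", "[=C]", "[Branch1]", "[C]", "[O]"))
  expect_equal(paste(toks, collapse = ""), "[C][=C][Branch1][C][O]")
  # tokenization is lexical: legacy grammar spellings split identically
  legacy <- "[C][=C][Branch1_1][Ring2][C@Hexpl][Expl=Ring1]"
  toks2 <- tokenize_selfies(legacy)
  expect_length(toks2, 6L)
  expect_true(all(startsWith(toks2, "[") & endsWith(toks2, "]")))
  expect_equal(paste(toks2, collapse = ""), legacy)
})

test_that("malformed bracket strings are rejected", {
  expect_error(tokenize_selfies("[C]x[O]"), "well-formed")
  expect_error(tokenize_selfies("[C][O"), "well-formed")
  expect_error(tokenize_selfies("C"), "well-formed")
})

test_that("elementary derivations match the grammar by hand", {
  expect_equal(selfies_to_smiles("[C][C]"), "CC")
  expect_equal(selfies_to_smiles("[C][=C][C]"), "C=CC")
  # a bare ring token realizes no atom: identity molecule
  expect_equal(selfies_to_smiles("[Ring1]"), "C")
})

test_that("SMILES -> tokens -> SMILES preserves canonical identity", {
  smi <- toy_smiles_100()
  sf <- smiles_to_selfies(smi)
  expect_false(anyNA(sf))
  back <- selfies_to_smiles(sf)
  expect_equal(canonical_smiles(back), canonical_smiles(smi))
})

test_that("stereo descriptors survive the round trip", {
  smi <- c("C[C@H](N)O", "C[C@@H](N)O", "C/C=C/C", "C/C=C\\C",
           toy_smiles_stereo_60()[1:20])
  back <- selfies_to_smiles(smiles_to_selfies(smi))
  expect_equal(canonical_smiles(back), canonical_smiles(smi))
  # enantiomers stay distinct after the round trip
  expect_false(canonical_smiles(back[1]) == canonical_smiles(back[2]))
})

test_that("charged molecules round-trip under the permissive rule set", {
  smi <- c("C[N+](C)(C)CCC", "CCC(=O)[O-]", "CC[NH3+]")
  back <- selfies_to_smiles(smiles_to_selfies(smi))
  expect_equal(canonical_smiles(back), canonical_smiles(smi))
})

test_that("any in-vocabulary token sequence decodes to a parseable
          molecule", {
  sf <- smiles_to_selfies(toy_smiles_100())
  vocab <- build_vocab(lapply(sf, tokenize_selfies))
  toks <- vocab$chemical_tokens
  set.seed(99)
  n_seq <- 300L
  seqs <- replicate(n_seq, paste(sample(toks, sample(1:20, 1),
                                        replace = TRUE), collapse = ""))
  smi <- selfies_to_smiles(seqs)
  expect_false(anyNA(smi))
  expect_true(all(nzchar(smi)))
  can <- canonical_smiles(smi)
  expect_false(anyNA(can))   # every derivation parses
})

test_that("vocabulary ordering is frequency-descending with lexicographic
          ties and deterministic", {
  corpus <- list(c("[C]", "[C]", "[O]"), c("[C]", "[N]"), c("[O]"))
  v <- build_vocab(corpus)
  expect_equal(v$chemical_tokens, c("[C]", "[O]", "[N]"))
  expect_equal(unname(v$token_to_id[c("<pad>", "<start>", "<end>")]),
               c(0L, 1L, 2L))
  expect_equal(unname(v$token_to_id["[C]"]), 3L)
  expect_equal(v$max_len, 3L + 2L)
  expect_identical(v, build_vocab(corpus))
  # singleton corpus
  v1 <- build_vocab(list("[C]"))
  expect_length(v1$chemical_tokens, 1L)
  expect_equal(v1$max_len, 3L)
  expect_error(build_vocab(list()), "empty")
})

test_that("rare-token handling prunes molecules before freezing", {
  corpus <- list(c("[C]"), c("[C]", "[=B]"))
  v <- build_vocab(corpus, rare_tokens = c("[=B]", "[=B]"))
  expect_equal(v$chemical_tokens, "[C]")
  expect_equal(v$n_dropped, 1L)
  kept <- drop_rare_token_molecules(corpus, c("[=B]"))
  expect_length(kept, 1L)
  expect_identical(drop_rare_token_molecules(corpus, character()), corpus)
  # min_count derivation
  v2 <- build_vocab(list(c("[C]", "[C]"), c("[C]", "[N]"), c("[C]")),
                    min_count = 2)
  expect_false("[N]" %in% v2$chemical_tokens)
})

test_that("encode pads to max_len and decode inverts it", {
  sf <- smiles_to_selfies(toy_smiles_100()[1:30])
  toks <- lapply(sf, tokenize_selfies)
  v <- build_vocab(toks)
  for (t in toks) {
    ids <- encode_sequence(t, v)
    expect_length(ids, v$max_len)
    expect_equal(ids[1], v$start_id)
    expect_equal(decode_sequence(ids, v), t)
  }
  expect_error(encode_sequence("[Xx]", v), "\\[Xx\\]")
  long <- rep("[C]", v$max_len - 1L)
  expect_error(encode_sequence(long, v), "exceeds")
})

test_that("vocabulary JSON serialization round-trips", {
  v <- build_vocab(lapply(smiles_to_selfies(toy_smiles_100()[1:20]),
                          tokenize_selfies))
  path <- withr::local_tempfile(fileext = ".json")
  write_vocab(v, path)
  v2 <- read_vocab(path)
  expect_equal(v2$token_to_id, v$token_to_id)
  expect_equal(v2$max_len, v$max_len)
})
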