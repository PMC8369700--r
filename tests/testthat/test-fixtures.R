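test_that("the toy generator yields unique, rule-passing, seed-stable
          corpora", {
  cfg <- toy_corpus_config(n_molecules = 100L, seed = 101L)
  smi <- toy_smiles_100()
  expect_length(smi, 100L)
  expect_equal(anyDuplicated(smi), 0L)
  expect_identical(smi, generate_toy_smiles(cfg))
  d <- check_molecule(smi, rule_set("dataset1"))
  expect_true(all(d$passed))
})

test_that("stereo corpora carry stereo descriptors and pass the permissive
          preset", {
  smi <- toy_smiles_stereo_60()
  d <- check_molecule(smi, rule_set("dataset2"))
  expect_true(all(d$passed))
  expect_gt(sum(d$has_stereo), 0L)
})

test_that("toy corpora span several molecule sizes", {
  d <- compute_descriptors(toy_smiles_100())
  # heavy-atom count = bonds + 1 for trees; recount via bonds and rings
  sizes <- vapply(seq_len(nrow(d)), function(i) {
    length(setdiff(d$element_set[[i]], "H")) * 0 + d$n_bonds[i]
  }, numeric(1))
  expect_gte(length(unique(sizes)), 5L)
})

test_that("an impossible request reports the achievable maximum", {
  expect_error(
    generate_toy_smiles(toy_corpus_config(
      n_molecules = 5000L, max_heavy_atoms = 4L,
      element_pool = c("C", "O"), allow_rings = FALSE, seed = 1L)),
    "could only generate")
})

test_that("the fixture dataset is end-to-end coherent", {
  smi <- toy_smiles_100()[1:30]
  dir <- withr::local_tempdir()
  bb <- backbone_spec("toy", input_px = 96L, grid = c(4L, 4L),
                      channels = 16L)
  ds <- build_fixture_dataset(smi, dir, seed = 3L, size_px = 96L,
                              backbone = bb, shard_size = 128L)
  expect_equal(ds$manifest$total_datapoints, 30L)
  expect_length(ds$manifest$shard_paths, 1L)   # one partial shard
  expect_equal(nrow(ds$table), 30L)
  expect_true(file.exists(file.path(dir, "dataset.csv")))
  back <- read_shards(ds$manifest)
  for (i in c(1L, 15L, 30L)) {
    toks <- decode_sequence(back[[i]]$ids, ds$vocab)
    smi_back <- selfies_to_smiles(paste(toks, collapse = ""))
    expect_equal(canonical_smiles(smi_back), canonical_smiles(smi[i]))
  }
  expect_error(build_fixture_dataset(character(), dir), "empty")
})

test_that("augmentation changes pixels but not token ids", {
  smi <- toy_smiles_100()[1:6]
  bb <- backbone_spec("toy", input_px = 96L, grid = c(4L, 4L),
                      channels = 16L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  plain <- build_fixture_dataset(smi, d1, augment = FALSE, seed = 5L,
                                 size_px = 96L, backbone = bb,
                                 write_images = TRUE)
  aug <- build_fixture_dataset(smi, d2, augment = TRUE, seed = 5L,
                               size_px = 96L, backbone = bb,
                               write_images = TRUE)
  ids_equal <- mapply(function(a, b) identical(a$ids, b$ids),
                      read_shards(plain$manifest), read_shards(aug$manifest))
  expect_true(all(ids_equal))
  img_a <- read_depiction(plain$table$image_path[1])
  img_b <- read_depiction(aug$table$image_path[1])
  expect_false(identical(img_a, img_b))
})
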