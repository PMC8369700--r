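test_that("rendering honors the configured size and is never blank", {
  img <- render_structure("C1=CC=CC=C1", depiction_config(seed = 7))
  expect_equal(dim(img), c(299L, 299L))
  expect_gt(mean(img < 128), 0.001)   # > 0.1% ink
  small <- render_structure("CCO", depiction_config(size_px = 150L,
                                                    seed = 2L))
  expect_equal(dim(small), c(150L, 150L))
})

test_that("rendering is bit-reproducible under a fixed config and seed", {
  cfg <- depiction_config(seed = 42L)
  a <- render_structure("CC(=O)OC1=CC=CC=C1C(=O)O", cfg)
  b <- render_structure("CC(=O)OC1=CC=CC=C1C(=O)O", cfg)
  expect_identical(a, b)
  # a different rotation seed moves ink
  c2 <- render_structure("CC(=O)OC1=CC=CC=C1C(=O)O",
                         depiction_config(seed = 43L))
  expect_false(identical(a, c2))
})

test_that("render rejects unparseable and multi-fragment input", {
  expect_error(render_structure("C1CC", depiction_config()))
  expect_error(render_structure("[Na+].[Cl-]", depiction_config()),
               "multi-fragment")
})

test_that("no toy molecule renders blank", {
  smi <- toy_smiles_100()[1:40]
  imgs <- ocsr:::render_structures(smi, depiction_config(size_px = 128L,
                                                         seed = 3L))
  ink <- vapply(imgs, function(im) mean(im < 128), numeric(1))
  expect_true(all(ink > 0.001))
})

test_that("augmentation preserves shape and 8-bit range, deterministically", {
  img <- render_structure("CCCO", depiction_config(size_px = 96L,
                                                   seed = 1L))
  for (s in 1:12) {
    a <- augment_image(img, seed = s)
    expect_equal(dim(a), dim(img))
    expect_true(all(a >= 0 & a <= 255 & a == round(a)))
    expect_identical(a, augment_image(img, seed = s))
  }
  expect_error(augment_image(img - 0.5, seed = 1), "8-bit")
})

test_that("the augmentation selector is uniform over the ten operations", {
  img <- matrix(255L, 16, 16)
  draws <- vapply(1:2000, function(s) {
    attr(augment_image(img, seed = s), "augmentation")
  }, character(1))
  tab <- table(factor(draws, levels = augmentation_specs()$name))
  expect_length(tab, 10L)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-4)
  expect_true(all(abs(as.vector(tab) / 2000 - 0.1) < 0.03))
})

test_that("pepper at its maximal rate darkens at most ~6% of a white
          image", {
  img <- matrix(255L, 128, 128)
  dark <- vapply(1:200, function(s) {
    a <- augment_image(img, seed = s)
    if (attr(a, "augmentation") %in% c("pepper", "salt_and_pepper")) {
      mean(a < 255)
    } else NA_real_
  }, numeric(1))
  dark <- dark[!is.na(dark)]
  expect_gt(length(dark), 5L)
  expect_true(all(dark <= 0.06))
})

test_that("normalization maps 8-bit values onto [-1, 1] exactly", {
  expect_equal(normalize_image(matrix(0L, 1, 1))[1], -1)
  expect_equal(normalize_image(matrix(255L, 1, 1))[1], 1)
  expect_equal(normalize_image(matrix(128L, 1, 1))[1], 128 / 127.5 - 1)
  img <- render_structure("CCCO", depiction_config(size_px = 64L))
  n <- normalize_image(img)
  expect_true(all(n >= -1 & n <= 1))
})

test_that("PNG write/read round-trips the 8-bit image exactly", {
  img <- render_structure("CCCN", depiction_config(size_px = 80L,
                                                   seed = 9L))
  path <- withr::local_tempfile(fileext = ".png")
  write_depiction(img, path)
  expect_identical(unname(read_depiction(path)), unname(img))
})

test_that("augmentation parameter ranges match the published table", {
  spec <- augmentation_specs()
  expect_equal(nrow(spec), 10L)
  expect_equal(spec$upper[spec$name == "gaussian_blur"], 1.8)
  expect_equal(spec$upper[spec$name == "additive_gaussian_noise"],
               0.1 * 255)
  expect_equal(spec$upper[spec$name == "salt_and_pepper"], 0.05)
  expect_equal(spec$upper[spec$name == "coarse_dropout"], 0.01)
  expect_equal(spec$lower[spec$name == "gamma_contrast"], 0.5)
  expect_equal(spec$upper[spec$name == "gamma_contrast"], 2.0)
  expect_equal(spec$lower[spec$name == "enhance_brightness"], 0.95)
  expect_equal(spec$upper[spec$name == "enhance_brightness"], 1.5)
})
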