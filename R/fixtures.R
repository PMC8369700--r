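# Deterministic synthetic toy-molecule and dataset generation, so every
# stage of the pipeline (curation -> depiction -> tokenization -> packing ->
# training -> evaluation) can be exercised without downloading any corpus.
# Molecules are assembled by seeded random growth (chains, branches, small
# rings) over a weighted element pool, then validated through the real
# curation rules; rejection sampling guarantees rule compliance by
# construction *and* by check.

#' Toy corpus configuration
#'
#' @param n_molecules Number of unique molecules to generate.
#' @param max_heavy_atoms Maximum heavy-atom count per molecule.
#' @param element_pool Elements to draw from (subset of the curation rule
#'   set's allowed elements).
#' @param allow_rings Permit ring closures.
#' @param allow_stereo Inject tetrahedral stereocenters (implies the
#'   `dataset2` preset is the validity reference).
#' @param seed Integer seed; the corpus is a pure function of this
#'   configuration.
#' @return An object of class `ocsr_toy_config`.
#' @export
toy_corpus_config <- function(n_molecules = 100L, max_heavy_atoms = 10L,
                              element_pool = c("C", "N", "O", "F", "S", "Cl"),
                              allow_rings = TRUE, allow_stereo = FALSE,
                              seed = 1L) {
  stopifnot(n_molecules >= 1L, max_heavy_atoms >= 4L,
            all(element_pool %in% DEFAULT_ELEMENTS))
  structure(list(n_molecules = as.integer(n_molecules),
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 element_pool = element_pool,
                 allow_rings = isTRUE(allow_rings),
                 allow_stereo = isTRUE(allow_stereo),
                 seed = as.integer(seed)),
            class = "ocsr_toy_config")
}

# Element draw weights: carbon-dominated, heteroatoms sprinkled in, roughly
# like small organic molecules.
TOY_ELEMENT_WEIGHTS <- c(C = 0.66, N = 0.10, O = 0.12, F = 0.04, S = 0.03,
                         Cl = 0.03, Br = 0.01, B = 0.002, P = 0.005,
                         I = 0.002, Se = 0.001)

# Grow one random molecule; returns a SMILES string (written with the
# package's own graph writer). Assumes an active RNG stream.
grow_toy_molecule <- function(cfg) {
  pool <- cfg$element_pool
  wts <- TOY_ELEMENT_WEIGHTS[pool]
  wts <- wts / sum(wts)
  n_target <- sample(4:cfg$max_heavy_atoms, 1L)
  st <- sf_new_state()
  stereo_center <- NA_integer_
  if (cfg$allow_stereo && stats::runif(1) < 0.5) {
    # explicit stereocenter: H + three distinct substituents (F, Cl, R)
    stereo_center <- sf_add_atom(st, list(element = "C",
                                          stereo = sample(c("@", "@@"), 1L),
                                          n_h = 1L, charge = 0L,
                                          bracket = TRUE))
    st$avail[stereo_center] <- 3L
    for (el in c("F", "Cl")) {
      a <- sf_add_atom(st, list(element = el, stereo = "", n_h = 0L,
                                charge = 0L, bracket = FALSE))
      sf_add_bond(st, stereo_center, a, 1L, "", tree = TRUE)
    }
  } else {
    sf_add_atom(st, list(element = "C", stereo = "", n_h = 0L, charge = 0L,
                         bracket = FALSE))
  }
  while (length(st$element) < n_target) {
    open <- which(st$avail > 0L)
    if (!length(open)) break
    anchor <- if (length(open) == 1L) open else sample(open, 1L)
    el <- sample(pool, 1L, prob = wts)
    cap <- sf_capacity(el)
    order <- 1L
    if (st$avail[anchor] >= 2L && cap >= 2L && el %in% c("C", "N", "O", "S")) {
      r <- stats::runif(1)
      if (r < 0.03 && st$avail[anchor] >= 3L && cap >= 3L &&
          el %in% c("C", "N")) {
        order <- 3L
      } else if (r < 0.18) {
        order <- 2L
      }
    }
    new <- sf_add_atom(st, list(element = el, stereo = "", n_h = 0L,
                                charge = 0L, bracket = el == "Se"))
    sf_add_bond(st, anchor, new, order, "", tree = TRUE)
  }
  if (cfg$allow_rings && stats::runif(1) < 0.45) {
    n_at <- length(st$element)
    cand <- which(st$avail > 0L & st$element == "C")
    if (length(cand) >= 2L) {
      pairs <- expand.grid(a = cand, b = cand)
      pairs <- pairs[pairs$b - pairs$a >= 2L & pairs$b - pairs$a <= 6L, ]
      if (nrow(pairs)) {
        pick <- pairs[sample.int(nrow(pairs), 1L), ]
        dup <- any((st$bond_from == pick$a & st$bond_to == pick$b) |
                     (st$bond_from == pick$b & st$bond_to == pick$a))
        if (!dup) sf_add_bond(st, pick$a, pick$b, 1L, "", tree = FALSE)
      }
    }
  }
  sf_write_smiles(st)
}

#' Generate a deterministic toy SMILES corpus
#'
#' Draws random molecules until `n_molecules` unique, rule-passing
#' structures (under the preset implied by `allow_stereo`) have been
#' collected. Outputs are canonical SMILES, unique, and a pure function of
#' the configuration.
#'
#' @param config A [toy_corpus_config()] (or its arguments via `...`).
#' @param ... Passed to [toy_corpus_config()] when `config` is missing.
#' @return Character vector of `n_molecules` canonical SMILES.
#' @examples
#' \dontrun{
#' smi <- generate_toy_smiles(toy_corpus_config(n_molecules = 20, seed = 7))
#' }
#' @export
generate_toy_smiles <- function(config = NULL, ...) {
  cfg <- config %||% toy_corpus_config(...)
  stopifnot(inherits(cfg, "ocsr_toy_config"))
  preset <- if (cfg$allow_stereo) "dataset2" else "dataset1"
  rules <- rule_set(preset)
  found <- character()
  max_rounds <- 60L
  stale <- 0L
  with_rng(cfg$seed, {
    for (round in seq_len(max_rounds)) {
      batch_n <- min(4096L, max(64L, 2L * (cfg$n_molecules - length(found))))
      raw <- vapply(seq_len(batch_n), function(i) grow_toy_molecule(cfg),
                    character(1))
      res <- suppressWarnings(filter_corpus(raw, rules))
      n_before <- length(found)
      found <- unique(c(found, res$survivors$smiles))
      if (length(found) >= cfg$n_molecules) break
      # the reachable space is exhausted when fresh rounds stop yielding
      stale <- if (length(found) == n_before) stale + 1L else 0L
      if (stale >= 2L) break
    }
  })
  if (length(found) < cfg$n_molecules) {
    stop("could only generate ", length(found), " unique rule-passing ",
         "molecules under this configuration (requested ",
         cfg$n_molecules, ")", call. = FALSE)
  }
  found[seq_len(cfg$n_molecules)]
}

#' Build a complete fixture dataset
#'
#' Full pipeline over a curated SMILES list: render depictions, convert to
#' grammar tokens and padded ids, extract backbone features, and pack
#' everything into binary shards. Mirrors the construction of the three
#' training corpora (plain; with stereo/charges; with augmentation).
#'
#' @param smiles Character vector of curated SMILES.
#' @param out_dir Output directory for shards and the manifest.
#' @param augment Apply one random photometric augmentation per image.
#' @param seed Seed for rotation and augmentation streams.
#' @param size_px Depiction edge length in pixels.
#' @param rotate Randomly rotate each depiction.
#' @param backbone A [backbone_spec()] for feature extraction.
#' @param vocab Optional frozen vocabulary; built from this corpus when
#'   `NULL`.
#' @param shard_size Datapoints per shard.
#' @param write_images Also write each depiction as a PNG under
#'   `out_dir/images`.
#' @return A list: `manifest` (shard manifest), `vocab`, `table` (tibble:
#'   id, smiles, selfies, image_path).
#' @export
build_fixture_dataset <- function(smiles, out_dir, augment = FALSE,
                                  seed = 1L, size_px = 299L, rotate = TRUE,
                                  backbone = backbone_spec("toy"),
                                  vocab = NULL, shard_size = 128L,
                                  write_images = FALSE) {
  smiles <- as_smiles_vector(smiles)
  if (length(smiles) == 0L) stop("empty SMILES list", call. = FALSE)
  selfies <- smiles_to_selfies(smiles)
  if (anyNA(selfies)) stop("unparseable SMILES in fixture input",
                           call. = FALSE)
  tokens <- lapply(selfies, tokenize_selfies)
  if (is.null(vocab)) vocab <- build_vocab(tokens)
  ids <- lapply(tokens, encode_sequence, vocab = vocab)
  cfg <- depiction_config(size_px = size_px, rotate = rotate, seed = seed,
                          augment = augment)
  imgs <- render_structures(smiles, cfg)
  if (augment) {
    imgs <- lapply(seq_along(imgs), function(i) {
      augment_image(imgs[[i]], seed = seed + 7919L * i)
    })
  }
  img_paths <- rep(NA_character_, length(smiles))
  if (write_images) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
    img_paths <- file.path(img_dir, sprintf("mol-%05d.png",
                                            seq_along(smiles)))
    for (i in seq_along(imgs)) write_depiction(imgs[[i]], img_paths[i])
  }
  feats <- extract_features(lapply(imgs, normalize_image), backbone)
  samples <- lapply(seq_along(smiles), function(i) {
    list(features = feats[[i]], ids = ids[[i]])
  })
  manifest <- write_shards(samples, out_dir, shard_size = shard_size)
  tab <- tibble::tibble(id = seq_along(smiles), smiles = smiles,
                        selfies = selfies, image_path = img_paths)
  utils::write.csv(tab, file.path(out_dir, "dataset.csv"),
                   row.names = FALSE)
  list(manifest = manifest, vocab = vocab, table = tab)
}
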