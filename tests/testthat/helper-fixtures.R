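# Shared fixtures, built once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_smiles_100 <- function() {
  cached("toy100", generate_toy_smiles(
    toy_corpus_config(n_molecules = 100L, seed = 101L)))
}

toy_smiles_stereo_60 <- function() {
  cached("toy60s", generate_toy_smiles(
    toy_corpus_config(n_molecules = 60L, allow_stereo = TRUE, seed = 202L)))
}

# A tiny trained model memorizing a handful of molecules; reused by decode
# and evaluation tests.
tiny_trained_model <- function() {
  cached("tiny_model", {
    smi <- generate_toy_smiles(toy_corpus_config(n_molecules = 8L,
                                                 seed = 5L))
    sf <- smiles_to_selfies(smi)
    toks <- lapply(sf, tokenize_selfies)
    vocab <- build_vocab(toks)
    bb <- backbone_spec("toy", input_px = 128L, grid = c(5L, 5L),
                        channels = 32L)
    imgs <- ocsr:::render_structures(
      smi, depiction_config(size_px = 128L, rotate = FALSE, seed = 1L))
    feats <- extract_features(lapply(imgs, normalize_image), bb)
    samples <- lapply(seq_along(smi), function(i) {
      list(features = feats[[i]], ids = encode_sequence(toks[[i]], vocab))
    })
    cfg <- transformer_config(vocab, n_layers = 2L, n_heads = 4L,
                              d_model = 64L, d_ff = 128L, dropout = 0,
                              warmup_steps = 200L, seed = 11L)
    model <- train_model(samples, cfg, epochs = 150L, batch_size = 8L)
    list(model = model, smiles = smi, tokens = toks, vocab = vocab,
         feats = feats, backbone = bb, samples = samples)
  })
}

# Independent descriptor oracle via the RDKit python library, when python
# is available (it is part of the reference toolchain image).
rdkit_descriptors <- function(smiles) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  script <- '
import sys, json
try:
    from rdkit import Chem
    from rdkit.Chem import Descriptors
except Exception:
    print("null"); sys.exit(0)
out = []
for smi in json.load(open(sys.argv[1])):
    m = Chem.MolFromSmiles(smi)
    if m is None:
        out.append(None); continue
    out.append({
        "mw": Descriptors.MolWt(m),
        "n_bonds": m.GetNumBonds(),
        "n_frags": len(Chem.GetMolFrags(m)),
        "charged": any(a.GetFormalCharge() != 0 for a in m.GetAtoms()),
        "elements": sorted(set(a.GetSymbol() for a in m.GetAtoms())),
    })
print(json.dumps(out))
'
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  inf <- tempfile(fileext = ".json")
  jsonlite::write_json(smiles, inf)
  res <- suppressWarnings(system2(py, c(sf, inf), stdout = TRUE,
                                  stderr = FALSE))
  unlink(c(sf, inf))
  out <- tryCatch(jsonlite::fromJSON(paste(res, collapse = ""),
                                     simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(out) || length(out) != length(smiles)) return(NULL)
  out
}
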