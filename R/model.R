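# Backbone feature extraction and the image-to-sequence transformer.
#
# The transformer consumes a flattened spatial feature grid (positions x
# channels) from a CNN backbone and emits token ids autoregressively. The
# two literature backbones are represented by seeded randomly-initialized
# patch-projection networks that reproduce their exact feature-grid
# geometry (pretrained weights are an optional user-supplied hook, never a
# build dependency); the `toy` backbone is fully configurable and is what
# the desk-scale experiments use.

#' Backbone specification
#'
#' @param name `"inception_v3"`, `"efficientnet_b3"` or `"toy"`.
#' @param input_px Expected input edge length (fixed at 299 for the two
#'   literature backbones).
#' @param grid `(h, w)` feature grid; configurable for `toy` only.
#' @param channels Feature channels; configurable for `toy` only.
#' @param pretrained Reserved hook for user-supplied pretrained weights;
#'   only `FALSE` (seeded random initialization, shape contract) is
#'   supported offline.
#' @param seed Seed for the random projection weights.
#' @param patch_px Side of the mean-pooled patch each grid cell is reduced
#'   to before projection.
#' @param projection `"random"` (seeded random linear map + tanh, the
#'   generic CNN-feature stand-in) or, for the `toy` backbone,
#'   `"identity"` (the pooled patch pixels themselves are the channels;
#'   `channels` is then forced to `patch_px^2`).
#' @return An object of class `ocsr_backbone`.
#' @examples
#' backbone_spec("efficientnet_b3")           # 10 x 10 x 1536 at 299 px
#' backbone_spec("toy", grid = c(5, 5), channels = 64)
#' @export
backbone_spec <- function(name = c("toy", "inception_v3", "efficientnet_b3"),
                          input_px = 299L, grid = c(10L, 10L),
                          channels = 64L, pretrained = FALSE, seed = 1L,
                          patch_px = 8L,
                          projection = c("random", "identity")) {
  name <- match.arg(name)
  projection <- match.arg(projection)
  if (name == "inception_v3") {
    grid <- c(8L, 8L); channels <- 2048L; input_px <- 299L
    projection <- "random"
  } else if (name == "efficientnet_b3") {
    grid <- c(10L, 10L); channels <- 1536L; input_px <- 299L
    projection <- "random"
  }
  if (projection == "identity") channels <- as.integer(patch_px)^2
  if (isTRUE(pretrained)) {
    stop("pretrained backbone weights are not bundled; ",
         "use pretrained = FALSE (seeded random initialization)",
         call. = FALSE)
  }
  structure(list(name = name, input_px = as.integer(input_px),
                 grid = as.integer(grid), channels = as.integer(channels),
                 pretrained = FALSE, seed = as.integer(seed),
                 patch_px = as.integer(patch_px), projection = projection),
            class = "ocsr_backbone")
}

#' @export
print.ocsr_backbone <- function(x, ...) {
  cat("<ocsr_backbone: ", x$name, "> ", x$input_px, "px -> ",
      x$grid[1], "x", x$grid[2], " x ", x$channels, " channels\n", sep = "")
  invisible(x)
}

#' Extract image features as a flattened spatial grid
#'
#' Splits each normalized image into the backbone's spatial grid, resamples
#' every cell to a fixed patch, and applies a seeded random linear
#' projection with tanh nonlinearity to the backbone's channel count. The
#' output shape contract is `(h*w positions) x channels`.
#'
#' @param images A normalized matrix in `[-1, 1]` (see [normalize_image()]),
#'   or a list of them.
#' @param backbone A [backbone_spec()].
#' @return A feature matrix (positions x channels) or a list of them, with
#'   attribute `backbone`.
#' @examples
#' \dontrun{
#' img <- normalize_image(render_structure("CCCO"))
#' f <- extract_features(img, backbone_spec("efficientnet_b3"))
#' dim(f)   # 100 x 1536
#' }
#' @export
extract_features <- function(images, backbone = backbone_spec("toy")) {
  stopifnot(inherits(backbone, "ocsr_backbone"))
  single <- is.matrix(images)
  if (single) images <- list(images)
  px <- backbone$input_px
  for (im in images) {
    if (!is.matrix(im) || any(dim(im) != px)) {
      stop("backbone '", backbone$name, "' expects ", px, "x", px,
           " input images", call. = FALSE)
    }
  }
  p <- backbone$patch_px %||% 8L  # pooled patch size per grid cell
  identity_proj <- identical(backbone$projection, "identity")
  W <- if (identity_proj) NULL else with_rng(backbone$seed, {
    matrix(stats::rnorm(p * p * backbone$channels, sd = 1 / p),
           p * p, backbone$channels)
  })
  h <- backbone$grid[1]; w <- backbone$grid[2]
  # per-cell mean-pooling operators (p x px), computed once: cell extraction
  # and antialiased downsampling in one matrix product A %*% img %*% t(B)
  pool_op <- function(n_cells, cell) {
    lo <- (cell - 1) * px / n_cells
    hi <- cell * px / n_cells
    edges <- seq(lo, hi, length.out = p + 1L)
    A <- matrix(0, p, px)
    for (r in seq_len(p)) {
      cols_r <- max(1L, floor(edges[r]) + 1L):min(px, ceiling(edges[r + 1L]))
      A[r, cols_r] <- 1 / length(cols_r)
    }
    A
  }
  row_ops <- lapply(seq_len(h), pool_op, n_cells = h)
  col_ops <- lapply(seq_len(w), pool_op, n_cells = w)
  out <- lapply(images, function(im) {
    patches <- matrix(0, h * w, p * p)
    k <- 0L
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        k <- k + 1L
        patches[k, ] <- as.vector(row_ops[[i]] %*% im %*% t(col_ops[[j]]))
      }
    }
    f <- if (identity_proj) patches else tanh(patches %*% W)
    attr(f, "backbone") <- backbone$name
    f
  })
  if (single) out[[1]] else out
}

#' Warmup learning-rate schedule
#'
#' The inverse-square-root schedule with linear warmup:
#' `rate = d_model^-0.5 * min(step^-0.5, step * warmup^-1.5)`. The rate
#' grows linearly for `step <= warmup` and decays as `step^-0.5` after; the
#' two branches meet at `step == warmup`.
#'
#' @param step Training step (>= 1, vectorized).
#' @param d_model Model dimension.
#' @param warmup Warmup step count.
#' @return Learning rate(s).
#' @examples
#' noam_rate(4000, 512, 4000)   # schedule peak for the default model
#' @export
noam_rate <- function(step, d_model = 512, warmup = 4000) {
  if (any(step < 1)) stop("step must be >= 1", call. = FALSE)
  d_model^(-0.5) * pmin(step^(-0.5), step * warmup^(-1.5))
}

#' Transformer configuration
#'
#' Defaults follow the standard image-captioning transformer: 4
#' encoder-decoder layers, 8 heads, attention dimension 512, feed-forward
#' dimension 2048, dropout 0.1, Adam with the warmup schedule
#' ([noam_rate()], warmup 4000).
#'
#' @param vocab An `ocsr_vocab` (see [build_vocab()]).
#' @param n_layers,n_heads,d_model,d_ff,dropout,warmup_steps Architecture
#'   and optimization hyperparameters.
#' @param positional `"sinusoidal"` (fixed encodings added after the dense
#'   feature projection) or `"learned"` (trainable position embeddings).
#' @param seed Seed for weight initialization and dropout.
#' @return An object of class `ocsr_transformer_config`.
#' @export
transformer_config <- function(vocab, n_layers = 4L, n_heads = 8L,
                               d_model = 512L, d_ff = 2048L, dropout = 0.1,
                               warmup_steps = 4000L,
                               positional = c("sinusoidal", "learned"),
                               seed = 1L) {
  stopifnot(inherits(vocab, "ocsr_vocab"))
  positional <- match.arg(positional)
  if (d_model %% n_heads != 0) {
    stop("d_model must be divisible by n_heads", call. = FALSE)
  }
  stopifnot(dropout >= 0, dropout < 1)
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model), d_ff = as.integer(d_ff),
                 dropout = dropout, warmup_steps = as.integer(warmup_steps),
                 positional = positional, vocab = vocab,
                 seed = as.integer(seed)),
            class = "ocsr_transformer_config")
}

# Hyperparameter list handed to the C++ core.
tf_cfg_list <- function(config, n_positions, max_len) {
  list(n_layers = config$n_layers, n_heads = config$n_heads,
       d_model = config$d_model, d_ff = config$d_ff,
       dropout = config$dropout,
       vocab_size = length(config$vocab$token_to_id),
       pad_id = config$vocab$pad_id, start_id = config$vocab$start_id,
       end_id = config$vocab$end_id,
       positional = config$positional,
       n_positions = as.integer(n_positions), max_len = as.integer(max_len))
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Seeded parameter initialization for a given feature shape.
tf_init_params <- function(config, channels, n_positions) {
  d <- config$d_model; dff <- config$d_ff
  V <- length(config$vocab$token_to_id)
  L <- config$n_layers
  with_rng(config$seed, {
    p <- list(
      enc_proj_W = glorot(channels, d),
      enc_proj_b = matrix(0, 1, d),
      dec_emb = matrix(stats::rnorm(V * d, sd = d^-0.5), V, d),
      out_W = glorot(d, V),
      out_b = matrix(0, 1, V)
    )
    if (config$positional == "learned") {
      p$enc_pos <- matrix(stats::rnorm(n_positions * d, sd = 0.02),
                          n_positions, d)
      p$dec_pos <- matrix(stats::rnorm(config$vocab$max_len * d, sd = 0.02),
                          config$vocab$max_len, d)
    }
    for (l in seq_len(L) - 1L) {
      for (w in c("Wq", "Wk", "Wv", "Wo")) {
        p[[paste0("enc", l, "_", w)]] <- glorot(d, d)
      }
      p[[paste0("enc", l, "_W1")]] <- glorot(d, dff)
      p[[paste0("enc", l, "_b1")]] <- matrix(0, 1, dff)
      p[[paste0("enc", l, "_W2")]] <- glorot(dff, d)
      p[[paste0("enc", l, "_b2")]] <- matrix(0, 1, d)
      for (g in c("ln1", "ln2")) {
        p[[paste0("enc", l, "_", g, "_g")]] <- matrix(1, 1, d)
        p[[paste0("enc", l, "_", g, "_b")]] <- matrix(0, 1, d)
      }
      for (w in c("sWq", "sWk", "sWv", "sWo", "cWq", "cWk", "cWv", "cWo")) {
        p[[paste0("dec", l, "_", w)]] <- glorot(d, d)
      }
      p[[paste0("dec", l, "_W1")]] <- glorot(d, dff)
      p[[paste0("dec", l, "_b1")]] <- matrix(0, 1, dff)
      p[[paste0("dec", l, "_W2")]] <- glorot(dff, d)
      p[[paste0("dec", l, "_b2")]] <- matrix(0, 1, d)
      for (g in c("ln1", "ln2", "ln3")) {
        p[[paste0("dec", l, "_", g, "_g")]] <- matrix(1, 1, d)
        p[[paste0("dec", l, "_", g, "_b")]] <- matrix(0, 1, d)
      }
    }
    p
  })
}

#' Number of trainable parameters
#'
#' @param model An `ocsr_model` (or a raw parameter list).
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  params <- if (inherits(model, "ocsr_model")) model$params else model
  sum(vapply(params, length, integer(1)))
}

#' Train the image-to-sequence transformer
#'
#' Teacher-forced training with Adam under the warmup schedule. The loss is
#' sparse categorical cross-entropy over non-pad target positions. Training
#' is reproducible under `config$seed` on a single-threaded CPU.
#'
#' @param shards An `ocsr_manifest` (see [write_shards()]) or a directory
#'   containing one; alternatively a list of samples (`features`, `ids`).
#' @param config A [transformer_config()]; its vocabulary must match the
#'   shard ids.
#' @param epochs Number of passes over the data.
#' @param batch_size Gradient batch size.
#' @param verbose Print per-epoch loss.
#' @return An object of class `ocsr_model`: `params`, `config`, `history`
#'   (tibble: epoch, loss, lr), `feature_shape`, `steps`.
#' @export
train_model <- function(shards, config, epochs = 10L, batch_size = 32L,
                        verbose = FALSE) {
  stopifnot(inherits(config, "ocsr_transformer_config"))
  samples <- if (is.list(shards) && !inherits(shards, "ocsr_manifest")) {
    shards
  } else {
    read_shards(shards)
  }
  n <- length(samples)
  if (n == 0L) stop("no training samples", call. = FALSE)
  shp <- dim(samples[[1L]]$features)
  max_len <- length(samples[[1L]]$ids)
  vocab_n <- length(config$vocab$token_to_id)
  ids_range <- range(vapply(samples, function(s) max(s$ids), numeric(1)))
  if (ids_range[2] >= vocab_n) {
    stop("shard ids exceed vocabulary size: vocab/shard mismatch",
         call. = FALSE)
  }
  cfg <- tf_cfg_list(config, shp[1], max_len)
  params <- tf_init_params(config, shp[2], shp[1])
  adam_m <- lapply(params, function(x) x * 0)
  adam_v <- lapply(params, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.98; eps <- 1e-9   # Adam per the warmup-schedule paper
  tok_mat <- do.call(rbind, lapply(samples, `[[`, "ids"))
  step <- 0L
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_rng(config$seed + ep, sample.int(n))
    ep_loss <- 0; ep_tok <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(n, start + batch_size - 1L)]
      step <- step + 1L
      lr <- noam_rate(step, config$d_model, config$warmup_steps)
      res <- tf_batch_grad(params, cfg,
                           lapply(samples[idx], `[[`, "features"),
                           tok_mat[idx, , drop = FALSE],
                           config$dropout,
                           seed = config$seed * 1000L + step,
                           want_grads = TRUE)
      g <- res$grads
      for (nm in names(g)) {
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1^step)
        vhat <- adam_v[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + res$loss * res$n_tokens
      ep_tok <- ep_tok + res$n_tokens
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, loss = ep_loss / ep_tok,
                                 lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  lr %.2e", ep,
                      ep_loss / ep_tok, lr))
    }
  }
  structure(
    list(params = params, config = config,
         history = dplyr::bind_rows(hist),
         feature_shape = shp, steps = step),
    class = "ocsr_model"
  )
}

#' @export
print.ocsr_model <- function(x, ...) {
  cat("<ocsr_model> ", x$config$n_layers, " layers, ", x$config$n_heads,
      " heads, d_model ", x$config$d_model, "; ",
      format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  if (nrow(x$history)) {
    cat(sprintf("  trained %d epochs; final loss %.4f\n",
                max(x$history$epoch), utils::tail(x$history$loss, 1)))
  }
  invisible(x)
}

#' Greedy decoding of feature grids to token sequences
#'
#' Starts from the start marker and emits argmax tokens until the end
#' marker or the vocabulary's maximum length.
#'
#' @param model A trained `ocsr_model` (or a list with `params` and
#'   `config`).
#' @param features A feature matrix (positions x channels) or list of them.
#' @param vocab Vocabulary (defaults to the model's).
#' @return A list of token character vectors (one per input).
#' @export
greedy_decode <- function(model, features, vocab = NULL) {
  if (is.null(vocab)) vocab <- model$config$vocab
  single <- is.matrix(features)
  if (single) features <- list(features)
  shp <- dim(features[[1L]])
  cfg <- tf_cfg_list(model$config, shp[1], vocab$max_len)
  ids <- tf_greedy_decode(model$params, cfg, features,
                          vocab$max_len - 1L)
  out <- lapply(seq_len(nrow(ids)), function(b) {
    decode_sequence(ids[b, ], vocab)
  })
  out
}

#' Predict SMILES from depictions
#'
#' Convenience wrapper: normalize, extract features, greedy-decode, and
#' convert the token sequences to SMILES through the grammar decoder (which
#' guarantees a parseable result for any token sequence).
#'
#' @param model A trained `ocsr_model`.
#' @param images An 8-bit image matrix or list of them.
#' @param backbone The [backbone_spec()] used at training time.
#' @return A tibble: `selfies`, `smiles`.
#' @export
predict_structures <- function(model, images, backbone) {
  single <- is.matrix(images)
  if (single) images <- list(images)
  feats <- extract_features(lapply(images, normalize_image), backbone)
  toks <- greedy_decode(model, feats)
  sf <- vapply(toks, paste, character(1), collapse = "")
  tibble::tibble(selfies = sf, smiles = selfies_to_smiles(sf))
}

#' Training history of a fitted model
#'
#' @param x An `ocsr_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `lr`.
#' @export
tidy.ocsr_model <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x An `ocsr_model`.
#' @param ... Unused.
#' @return Tibble with architecture, parameter count and final loss.
#' @export
glance.ocsr_model <- function(x, ...) {
  tibble::tibble(
    n_layers = x$config$n_layers, n_heads = x$config$n_heads,
    d_model = x$config$d_model, d_ff = x$config$d_ff,
    n_parameters = n_parameters(x),
    epochs = if (nrow(x$history)) max(x$history$epoch) else 0L,
    final_loss = if (nrow(x$history)) utils::tail(x$history$loss, 1)
    else NA_real_
  )
}

#' Loss-curve plot
#'
#' @param object An `ocsr_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocsr_model <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' Save a model checkpoint
#'
#' Writes a JSON header (config, shapes) plus raw little-endian doubles for
#' every parameter matrix.
#'
#' @param model An `ocsr_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  hdr <- list(
    config = list(n_layers = model$config$n_layers,
                  n_heads = model$config$n_heads,
                  d_model = model$config$d_model,
                  d_ff = model$config$d_ff,
                  dropout = model$config$dropout,
                  warmup_steps = model$config$warmup_steps,
                  positional = model$config$positional,
                  seed = model$config$seed),
    vocab = list(tokens = names(model$config$vocab$token_to_id),
                 ids = unname(model$config$vocab$token_to_id),
                 max_len = model$config$vocab$max_len),
    feature_shape = model$feature_shape,
    steps = model$steps,
    params = lapply(model$params, dim),
    history = model$history
  )
  hjson <- jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(nchar(hjson, type = "bytes"), con, size = 4L, endian = "little")
  writeBin(charToRaw(hjson), con)
  for (nm in names(model$params)) {
    writeBin(as.numeric(model$params[[nm]]), con, size = 8L,
             endian = "little")
  }
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return An `ocsr_model`.
#' @export
load_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nh <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", nh)),
                            simplifyVector = TRUE)
  vocab <- structure(
    list(token_to_id = stats::setNames(as.integer(hdr$vocab$ids),
                                       hdr$vocab$tokens),
         chemical_tokens = setdiff(hdr$vocab$tokens,
                                   c(SF_PAD, SF_START, SF_END)),
         counts = NULL, max_len = as.integer(hdr$vocab$max_len),
         pad_id = 0L, start_id = 1L, end_id = 2L,
         n_dropped = NA_integer_, rare_tokens = character()),
    class = "ocsr_vocab")
  config <- transformer_config(
    vocab, n_layers = hdr$config$n_layers, n_heads = hdr$config$n_heads,
    d_model = hdr$config$d_model, d_ff = hdr$config$d_ff,
    dropout = hdr$config$dropout, warmup_steps = hdr$config$warmup_steps,
    positional = hdr$config$positional, seed = hdr$config$seed)
  params <- list()
  for (nm in names(hdr$params)) {
    d <- hdr$params[[nm]]
    params[[nm]] <- matrix(readBin(con, "numeric", prod(d), size = 8L,
                                   endian = "little"), d[1], d[2])
  }
  structure(
    list(params = params, config = config,
         history = tibble::as_tibble(hdr$history),
         feature_shape = as.integer(hdr$feature_shape),
         steps = hdr$steps),
    class = "ocsr_model"
  )
}
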