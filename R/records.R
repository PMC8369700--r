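# Sharded on-disk dataset container pairing image feature grids with
# token-id sequences. Each shard is a flat binary file:
#
#   bytes 0-3   magic "OCSR"
#   int32       layout version (1)
#   int32       n datapoints in this shard
#   int32       positions (feature grid rows)
#   int32       channels  (feature grid cols)
#   int32       max_len   (token sequence length)
#   then per datapoint: positions*channels float32 (row-major) features,
#   followed by max_len int32 token ids. Little-endian throughout.
#
# The default shard size is 128 datapoints; a JSON manifest written next to
# the shards records paths, counts and shapes.

SHARD_MAGIC <- charToRaw("OCSR")
SHARD_VERSION <- 1L

#' Write a dataset as fixed-size binary shards
#'
#' @param samples List of datapoints, each a list with `features` (numeric
#'   matrix, positions x channels; identical shape across samples) and `ids`
#'   (integer vector of identical length `max_len`).
#' @param out_dir Output directory (created if needed).
#' @param shard_size Datapoints per shard; every shard except possibly the
#'   last holds exactly this many.
#' @param prefix Shard file name prefix.
#' @return A shard manifest (class `ocsr_manifest`): `shard_paths`,
#'   `shard_counts`, `datapoints_per_shard`, `total_datapoints`,
#'   `feature_shape`, `max_len`. Also serialized as `manifest.json` in
#'   `out_dir`.
#' @examples
#' \dontrun{
#' smp <- replicate(10, list(features = matrix(rnorm(6), 2),
#'                           ids = 1:4), simplify = FALSE)
#' man <- write_shards(smp, tempfile(), shard_size = 4)
#' man$shard_counts   # 4 4 2
#' }
#' @export
write_shards <- function(samples, out_dir, shard_size = 128L,
                         prefix = "shard") {
  stopifnot(is.list(samples), shard_size >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(samples)
  if (n > 0L) {
    shp <- dim(samples[[1L]]$features)
    len <- length(samples[[1L]]$ids)
    ok <- vapply(samples, function(s) {
      identical(dim(s$features), shp) && length(s$ids) == len
    }, logical(1))
    if (!all(ok)) {
      stop("inhomogeneous sample shapes (first offender: datapoint ",
           which(!ok)[1L], ")", call. = FALSE)
    }
  } else {
    shp <- c(0L, 0L); len <- 0L
  }
  n_shards <- if (n == 0L) 0L else ceiling(n / shard_size)
  paths <- character(n_shards)
  counts <- integer(n_shards)
  for (s in seq_len(n_shards)) {
    lo <- (s - 1L) * shard_size + 1L
    hi <- min(n, s * shard_size)
    paths[s] <- sprintf("%s-%05d.bin", prefix, s)
    counts[s] <- hi - lo + 1L
    con <- file(file.path(out_dir, paths[s]), "wb")
    writeBin(SHARD_MAGIC, con)
    writeBin(c(SHARD_VERSION, counts[s], as.integer(shp), as.integer(len)),
             con, size = 4L, endian = "little")
    for (i in lo:hi) {
      writeBin(as.numeric(t(samples[[i]]$features)), con, size = 4L,
               endian = "little")
      writeBin(as.integer(samples[[i]]$ids), con, size = 4L,
               endian = "little")
    }
    close(con)
  }
  manifest <- structure(
    list(dir = normalizePath(out_dir),
         shard_paths = paths,
         shard_counts = counts,
         datapoints_per_shard = as.integer(shard_size),
         total_datapoints = n,
         feature_shape = as.integer(shp),
         max_len = as.integer(len)),
    class = "ocsr_manifest"
  )
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read a shard manifest from disk
#'
#' @param dir Directory containing `manifest.json`.
#' @return An `ocsr_manifest`.
#' @export
read_manifest <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  js$dir <- normalizePath(dir)
  js$shard_paths <- as.character(js$shard_paths)
  js$shard_counts <- as.integer(js$shard_counts)
  js$feature_shape <- as.integer(js$feature_shape)
  structure(js, class = "ocsr_manifest")
}

#' @export
print.ocsr_manifest <- function(x, ...) {
  cat("<ocsr_manifest> ", x$total_datapoints, " datapoints in ",
      length(x$shard_paths), " shard(s) of ", x$datapoints_per_shard,
      "; features ", paste(x$feature_shape, collapse = "x"),
      ", max_len ", x$max_len, "\n", sep = "")
  invisible(x)
}

# Read one shard file; validates header and exact byte length.
read_shard <- function(path, manifest) {
  if (!file.exists(path)) stop("missing shard: ", path, call. = FALSE)
  expect_hdr <- 4L + 5L * 4L
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, SHARD_MAGIC)) {
    stop("corrupt shard (bad magic): ", path, call. = FALSE)
  }
  hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
  ver <- hdr[1L]; n <- hdr[2L]; pos <- hdr[3L]; ch <- hdr[4L]; len <- hdr[5L]
  if (ver != SHARD_VERSION) stop("unknown shard version in ", path,
                                 call. = FALSE)
  rec_bytes <- pos * ch * 4L + len * 4L
  if (sz != expect_hdr + n * rec_bytes) {
    stop("corrupt shard (truncated or padded): ", path, call. = FALSE)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    feats <- readBin(con, "numeric", pos * ch, size = 4L, endian = "little")
    ids <- readBin(con, "integer", len, size = 4L, endian = "little")
    out[[i]] <- list(features = matrix(feats, pos, ch, byrow = TRUE),
                     ids = ids)
  }
  out
}

#' Read all datapoints from a shard manifest
#'
#' Shards are read one at a time (memory is bounded by one shard plus the
#' accumulated output when `callback` is `NULL`).
#'
#' @param manifest An `ocsr_manifest` (or directory path).
#' @param callback Optional `function(samples, shard_index)` invoked per
#'   shard for streaming consumption; when given, returns `NULL` and keeps
#'   only one shard in memory at a time.
#' @return List of datapoints in written order (unless `callback` is used).
#' @export
read_shards <- function(manifest, callback = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "ocsr_manifest"))
  out <- if (is.null(callback)) vector("list", manifest$total_datapoints)
  at <- 0L
  for (s in seq_along(manifest$shard_paths)) {
    smp <- read_shard(file.path(manifest$dir, manifest$shard_paths[s]),
                      manifest)
    if (length(smp) != manifest$shard_counts[s]) {
      stop("shard count mismatch in ", manifest$shard_paths[s],
           call. = FALSE)
    }
    if (is.null(callback)) {
      if (length(smp)) out[at + seq_along(smp)] <- smp
      at <- at + length(smp)
    } else {
      callback(smp, s)
    }
  }
  if (is.null(callback)) out else invisible(NULL)
}
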