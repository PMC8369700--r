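# Random samples whose feature values are exactly representable in the
# shard container's 32-bit float storage.
float32 <- function(x) {
  wcon <- rawConnection(raw(0), "wb")
  writeBin(as.numeric(x), wcon, size = 4L)
  bytes <- rawConnectionValue(wcon)
  close(wcon)
  rcon <- rawConnection(bytes)
  out <- readBin(rcon, "numeric", length(x), size = 4L)
  close(rcon)
  matrix(out, nrow(x), ncol(x))
}

make_samples <- function(n, pos = 3L, ch = 4L, len = 6L) {
  lapply(seq_len(n), function(i) {
    list(features = float32(matrix(rnorm(pos * ch), pos, ch)),
         ids = sample.int(20L, len, replace = TRUE) - 1L)
  })
}

test_that("shard sizes follow the fixed-count contract", {
  set.seed(1)
  dir <- withr::local_tempdir()
  man <- write_shards(make_samples(1000L), dir, shard_size = 128L)
  expect_equal(man$shard_counts, c(rep(128L, 7L), 104L))
  expect_equal(man$total_datapoints, 1000L)
  # exact single full shard
  man1 <- write_shards(make_samples(128L), withr::local_tempdir(),
                       shard_size = 128L)
  expect_equal(man1$shard_counts, 128L)
  # empty input: zero shards, valid manifest
  man0 <- write_shards(list(), withr::local_tempdir(), shard_size = 128L)
  expect_equal(length(man0$shard_paths), 0L)
  expect_equal(man0$total_datapoints, 0L)
  expect_equal(length(read_shards(man0)), 0L)
})

test_that("write-then-read round-trips features and ids bit-exactly", {
  set.seed(2)
  dir <- withr::local_tempdir()
  samples <- make_samples(300L, pos = 5L, ch = 7L, len = 9L)
  man <- write_shards(samples, dir, shard_size = 64L)
  back <- read_shards(man)
  expect_length(back, 300L)
  for (i in c(1L, 64L, 65L, 300L, sample(300L, 20L))) {
    expect_identical(back[[i]]$features, samples[[i]]$features)
    expect_identical(back[[i]]$ids, samples[[i]]$ids)
  }
  # the manifest reloads from its JSON and reads identically
  man2 <- read_manifest(dir)
  back2 <- read_shards(man2)
  expect_identical(back2[[300L]], back[[300L]])
})

test_that("streaming reads visit shards in order with bounded memory", {
  dir <- withr::local_tempdir()
  samples <- make_samples(10L)
  write_shards(samples, dir, shard_size = 4L)
  seen <- list()
  read_shards(dir, callback = function(smp, s) {
    expect_lte(length(smp), 4L)
    seen[[s]] <<- smp
  })
  expect_length(seen, 3L)
  expect_identical(seen[[3L]][[2L]]$ids, samples[[10L]]$ids)
})

test_that("shape mismatches and corrupt shards are reported by name", {
  dir <- withr::local_tempdir()
  bad <- make_samples(3L)
  bad[[2L]]$features <- matrix(0, 2, 2)
  expect_error(write_shards(bad, dir), "inhomogeneous")
  samples <- make_samples(5L)
  man <- write_shards(samples, dir, shard_size = 5L)
  path <- file.path(dir, man$shard_paths[1])
  sz <- file.size(path)
  con <- file(path, "r+b"); truncate_at <- sz - 10L
  seek(con, truncate_at); truncate(con); close(con)
  expect_error(read_shards(man), "truncated|corrupt")
  unlink(path)
  expect_error(read_shards(man), "missing shard")
})
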