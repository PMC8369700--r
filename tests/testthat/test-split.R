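# Brute-force oracle: re-evaluate the greedy farthest-point criterion from
# scratch at every step (O(N^2) per pick).
maxmin_oracle <- function(fp, n_pick, first) {
  n <- nrow(fp)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      uni <- sum(fp[i, ] | fp[j, ])
      sim <- if (uni == 0) 1 else sum(fp[i, ] & fp[j, ]) / uni
      d[i, j] <- 1 - sim
    }
  }
  picked <- first
  while (length(picked) < n_pick) {
    cand <- setdiff(seq_len(n), picked)
    mind <- vapply(cand, function(i) min(d[i, picked]), numeric(1))
    best <- cand[mind == max(mind)]
    picked <- c(picked, min(best))   # lowest-index tie-break
  }
  picked
}

test_that("a hand-checkable three-point instance picks the far point", {
  # A = {1}, B = {1}, C = {2}: after A, the farthest point is C
  fp <- rbind(A = c(TRUE, FALSE), B = c(TRUE, FALSE), C = c(FALSE, TRUE))
  # find a seed whose first (random) pick is row 1
  seed <- which(vapply(1:50, function(s) {
    ocsr:::with_rng(s, sample.int(3, 1)) == 1L
  }, logical(1)))[1]
  picks <- maxmin_pick(fp, 2L, seed = seed)
  expect_equal(picks[1], 1L)
  expect_equal(picks[2], 3L)
})

test_that("picking everything returns all indices", {
  fp <- matrix(runif(40) > 0.5, nrow = 8)
  expect_setequal(maxmin_pick(fp, 8L, seed = 3), 1:8)
  expect_error(maxmin_pick(fp, 9L, seed = 3), "exceeds")
})

test_that("the lazy picker matches the brute-force greedy oracle", {
  set.seed(17)
  for (trial in 1:6) {
    n <- sample(10:50, 1)
    fp <- matrix(runif(n * 32) > 0.6, nrow = n)
    n_pick <- sample(2:min(10, n), 1)
    seed <- sample(1e4, 1)
    mine <- maxmin_pick(fp, n_pick, seed = seed)
    oracle <- maxmin_oracle(fp, n_pick, first = mine[1])
    expect_equal(mine, oracle)
  }
})

test_that("train_test_split partitions the corpus deterministically", {
  smi <- toy_smiles_100()
  sp <- train_test_split(smi, fraction = 0.1, seed = 5)
  expect_length(sp$test_ids, 10L)
  expect_length(sp$train_ids, 90L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$test_ids), seq_along(smi))
  sp2 <- train_test_split(smi, fraction = 0.1, seed = 5)
  expect_identical(sp[c("train_ids", "test_ids")],
                   sp2[c("train_ids", "test_ids")])
  expect_error(train_test_split("CCO", 0.5, 1), "at least 2")
})

test_that("MaxMin test sets are more spread out than random ones", {
  smi <- toy_smiles_100()
  fp <- mol_fingerprints(smi)
  mean_nn_dist <- function(ids) {
    m <- fp[ids, ] * 1
    ones <- rowSums(m)
    inter <- m %*% t(m)
    uni <- outer(ones, ones, "+") - inter
    sim <- ifelse(uni > 0, inter / uni, 1)
    d <- 1 - sim
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  wins <- 0L
  for (s in 1:10) {
    mm <- maxmin_pick(fp, 15L, seed = s)
    rnd <- ocsr:::with_rng(1000L + s, sample.int(nrow(fp), 15L))
    if (mean_nn_dist(mm) >= mean_nn_dist(rnd)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
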