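# MaxMin (farthest-point) diversity selection over fingerprint Tanimoto
# distance. Used to carve test sets that span the corpus's chemical space.

#' Greedy MaxMin diversity picking
#'
#' Selects `n_pick` items by farthest-point sampling under Tanimoto distance
#' (1 - Tanimoto). The first pick is drawn uniformly at random from the
#' seeded stream; each subsequent pick maximizes the minimum distance to all
#' previously picked items, with ties broken by lowest index. The cached
#' minimum distances are updated incrementally, which is behaviorally
#' identical to re-evaluating the greedy criterion from scratch.
#'
#' @param fingerprints Logical matrix, one fingerprint per row, or a list of
#'   logical vectors.
#' @param n_pick Number of items to select.
#' @param seed Integer seed (controls the first pick only).
#' @return Integer vector of `n_pick` row indices, in pick order.
#' @examples
#' fp <- matrix(runif(60) > 0.5, nrow = 6)
#' maxmin_pick(fp, 3, seed = 1)
#' @export
maxmin_pick <- function(fingerprints, n_pick, seed = 1L) {
  fp <- as_fp_matrix(fingerprints)
  n <- nrow(fp)
  stopifnot(n >= 1L)
  n_pick <- as.integer(n_pick)
  if (n_pick > n) stop("n_pick (", n_pick, ") exceeds corpus size (", n, ")",
                       call. = FALSE)
  if (n_pick < 1L) return(integer())
  m <- fp * 1         # numeric for fast cross products
  ones <- rowSums(m)
  first <- with_rng(seed, sample.int(n, 1L))
  picked <- integer(n_pick)
  picked[1L] <- first
  if (n_pick == 1L) return(picked)
  mind <- tanimoto_dist_to(m, ones, first)
  mind[first] <- -Inf
  for (k in 2L:n_pick) {
    nxt <- which.max(mind)        # ties: lowest index
    picked[k] <- nxt
    mind <- pmin(mind, tanimoto_dist_to(m, ones, nxt))
    mind[nxt] <- -Inf
  }
  picked
}

# Distance (1 - Tanimoto) of every row of m to row i. Two all-zero
# fingerprints are treated as identical (distance 0).
tanimoto_dist_to <- function(m, ones, i) {
  inter <- as.vector(m %*% m[i, ])
  uni <- ones + ones[i] - inter
  sim <- ifelse(uni > 0, inter / uni, 1)
  1 - sim
}

as_fp_matrix <- function(fingerprints) {
  if (is.list(fingerprints)) {
    fingerprints <- do.call(rbind, lapply(fingerprints, as.logical))
  }
  stopifnot(is.matrix(fingerprints))
  if (anyNA(fingerprints)) stop("fingerprints contain NA", call. = FALSE)
  fingerprints
}

#' Diversity-aware train/test split
#'
#' Computes fingerprints for the corpus and selects `round(fraction * N)`
#' molecules as a MaxMin-diverse test set; the remainder is the training
#' set. Deterministic under `seed`.
#'
#' @param smiles Character vector of SMILES (or data frame with a `smiles`
#'   column).
#' @param fraction Test fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @param fingerprint Fingerprint backend passed to [mol_fingerprints()].
#' @return An object of class `ocsr_split`: `train_ids`, `test_ids`
#'   (disjoint, covering), `seed`, `fraction`.
#' @examples
#' \dontrun{
#' sp <- train_test_split(c("CCCO", "CCCN", "CCCC", "c1ccccc1"), 0.25, 1)
#' sp$test_ids
#' }
#' @export
train_test_split <- function(smiles, fraction = 0.1, seed = 1L,
                             fingerprint = "FP2") {
  smiles <- as_smiles_vector(smiles)
  n <- length(smiles)
  if (n < 2L) stop("corpus must contain at least 2 molecules", call. = FALSE)
  stopifnot(fraction > 0, fraction < 1)
  fp <- mol_fingerprints(smiles, backend = fingerprint)
  if (anyNA(fp)) {
    stop("unparseable SMILES in corpus: ",
         paste(utils::head(smiles[apply(is.na(fp), 1L, any)], 3L),
               collapse = ", "), call. = FALSE)
  }
  n_test <- max(1L, round(fraction * n))
  test_ids <- sort(maxmin_pick(fp, n_test, seed = seed))
  structure(
    list(train_ids = setdiff(seq_len(n), test_ids),
         test_ids = test_ids,
         seed = as.integer(seed), fraction = fraction, n = n),
    class = "ocsr_split"
  )
}

#' @export
print.ocsr_split <- function(x, ...) {
  cat("<ocsr_split> ", length(x$train_ids), " train / ", length(x$test_ids),
      " test (fraction ", x$fraction, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
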