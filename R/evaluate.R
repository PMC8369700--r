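# Scoring predicted structures against references: fingerprint Tanimoto,
# the Tanimoto-1.0 rate, and isomorphism (standard InChI string equality)
# among the Tanimoto-1.0 pairs. A Tanimoto of 1.0 means identical
# fingerprints, not necessarily identical molecules - enantiomer pairs under
# a constitution-only fingerprint are the canonical example - which is why
# the isomorphism check is layered on top.

#' Tanimoto similarity of two bitsets
#'
#' @param a,b Logical vectors of equal length (fingerprint bitsets), or
#'   integer vectors of set-bit positions.
#' @return `|a & b| / |a | b|`.
#' @examples
#' tanimoto(c(TRUE, TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE, TRUE))  # 0.5
#' @export
tanimoto <- function(a, b) {
  if (!is.logical(a)) a <- seq_bits(a)
  if (!is.logical(b)) b <- seq_bits(b)
  stopifnot(length(a) == length(b))
  uni <- sum(a | b)
  if (uni == 0L) {
    stop("Tanimoto similarity is undefined for two empty bitsets",
         call. = FALSE)
  }
  sum(a & b) / uni
}

seq_bits <- function(pos) {
  stopifnot(is.numeric(pos), all(pos >= 1))
  out <- rep(FALSE, max(pos, 1))
  out[pos] <- TRUE
  out
}

#' Structure isomorphism by InChI string matching
#'
#' Two SMILES are isomorphic iff their standard InChI strings (stereo layers
#' included) are byte-identical.
#'
#' @param smiles_a,smiles_b SMILES strings (vectorized, recycled pairwise).
#' @return Logical vector.
#' @examples
#' \dontrun{
#' is_isomorphic("CCO", "OCC")                    # TRUE
#' is_isomorphic("C[C@H](N)O", "C[C@@H](N)O")     # FALSE (enantiomers)
#' }
#' @export
is_isomorphic <- function(smiles_a, smiles_b) {
  n <- max(length(smiles_a), length(smiles_b))
  a <- rep_len(smiles_a, n); b <- rep_len(smiles_b, n)
  ia <- mol_inchi(a); ib <- mol_inchi(b)
  if (anyNA(ia)) {
    stop("unparseable SMILES on the first side: ",
         paste(utils::head(a[is.na(ia)], 3L), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(ib)) {
    stop("unparseable SMILES on the second side: ",
         paste(utils::head(b[is.na(ib)], 3L), collapse = ", "),
         call. = FALSE)
  }
  ia == ib
}

#' Evaluate predicted structures against references
#'
#' For each (reference, prediction) pair the fingerprint Tanimoto similarity
#' is computed; isomorphism (InChI equality) is then checked only for pairs
#' with Tanimoto exactly 1.0. Unparseable references are excluded with a
#' warning and counted separately; unparseable predictions score Tanimoto 0.
#'
#' @param pairs A data frame with columns `reference` and `predicted`
#'   (SMILES), or a character vector of references.
#' @param predicted When `pairs` is a character vector: the predictions.
#' @param fingerprint Fingerprint backend name (see [mol_fingerprints()]).
#' @return An object of class `ocsr_eval_report`; see [glance.ocsr_eval_report()]
#'   for the summary fields and [tidy.ocsr_eval_report()] for the per-pair
#'   table.
#' @examples
#' \dontrun{
#' rep <- evaluate_pairs(data.frame(reference = c("CCCO", "CCCN"),
#'                                  predicted = c("CCCO", "CCCC")))
#' glance(rep)
#' }
#' @export
evaluate_pairs <- function(pairs, predicted = NULL, fingerprint = "FP2") {
  if (is.character(pairs)) {
    pairs <- tibble::tibble(reference = pairs, predicted = predicted)
  }
  stopifnot(is.data.frame(pairs),
            all(c("reference", "predicted") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("no pairs to evaluate", call. = FALSE)
  ref <- as.character(pairs$reference)
  prd <- as.character(pairs$predicted)
  fp_ref <- mol_fingerprints(ref, backend = fingerprint)
  fp_prd <- mol_fingerprints(prd, backend = fingerprint)
  bad_ref <- apply(is.na(fp_ref), 1L, any)
  bad_prd <- !bad_ref & apply(is.na(fp_prd), 1L, any)
  if (any(bad_ref)) {
    warning(sum(bad_ref), " unparseable reference(s) excluded")
  }
  tani <- rep(NA_real_, length(ref))
  for (i in which(!bad_ref)) {
    if (bad_prd[i]) {
      tani[i] <- 0
      next
    }
    a <- fp_ref[i, ]; b <- fp_prd[i, ]
    tani[i] <- if (sum(a | b) == 0L) {
      # two empty fingerprints: fall back to identity of the molecules
      as.numeric(isTRUE(mol_inchi(ref[i]) == mol_inchi(prd[i])))
    } else {
      sum(a & b) / sum(a | b)
    }
  }
  is_t1 <- !is.na(tani) & tani == 1
  iso <- rep(NA, length(ref))
  if (any(is_t1)) {
    iso[is_t1] <- is_isomorphic(ref[is_t1], prd[is_t1])
  }
  per_pair <- tibble::tibble(
    reference = ref, predicted = prd, tanimoto = tani,
    tanimoto_1 = is_t1, isomorphic = iso,
    reference_parseable = !bad_ref, predicted_parseable = !bad_prd & !bad_ref
  )
  scored <- per_pair[!bad_ref, ]
  n_t1 <- sum(scored$tanimoto_1)
  structure(
    list(per_pair = per_pair,
         n_pairs = nrow(scored),
         n_excluded = sum(bad_ref),
         n_unparseable_pred = sum(bad_prd),
         avg_tanimoto = mean(scored$tanimoto),
         n_tanimoto_1 = n_t1,
         pct_tanimoto_1 = 100 * n_t1 / nrow(scored),
         pct_isomorphic_of_t1 =
           if (n_t1 > 0L) 100 * mean(scored$isomorphic[scored$tanimoto_1])
           else NA_real_,
         fingerprint = fingerprint),
    class = "ocsr_eval_report"
  )
}

#' @export
print.ocsr_eval_report <- function(x, ...) {
  cat("<ocsr_eval_report> ", x$n_pairs, " pairs (", x$fingerprint, ")\n",
      sep = "")
  cat(sprintf("  average Tanimoto      %.4f\n", x$avg_tanimoto))
  cat(sprintf("  Tanimoto 1.0          %.2f%% (%d)\n", x$pct_tanimoto_1,
              x$n_tanimoto_1))
  if (!is.na(x$pct_isomorphic_of_t1)) {
    cat(sprintf("  isomorphic among T1.0 %.2f%%\n", x$pct_isomorphic_of_t1))
  }
  if (x$n_excluded) cat("  excluded references:", x$n_excluded, "\n")
  invisible(x)
}

#' Per-pair evaluation table
#'
#' @param x An `ocsr_eval_report`.
#' @param ... Unused.
#' @return The per-pair tibble (reference, predicted, tanimoto, isomorphic).
#' @export
tidy.ocsr_eval_report <- function(x, ...) x$per_pair

#' One-row evaluation summary
#'
#' @param x An `ocsr_eval_report`.
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `avg_tanimoto`, `n_tanimoto_1`,
#'   `pct_tanimoto_1`, `pct_isomorphic_of_t1`, `n_excluded`,
#'   `n_unparseable_pred`.
#' @export
glance.ocsr_eval_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs, avg_tanimoto = x$avg_tanimoto,
    n_tanimoto_1 = x$n_tanimoto_1, pct_tanimoto_1 = x$pct_tanimoto_1,
    pct_isomorphic_of_t1 = x$pct_isomorphic_of_t1,
    n_excluded = x$n_excluded, n_unparseable_pred = x$n_unparseable_pred
  )
}

#' Histogram of per-pair Tanimoto similarities
#'
#' @param object An `ocsr_eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocsr_eval_report <- function(object, ...) {
  df <- object$per_pair[object$per_pair$reference_parseable, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tanimoto)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "grey30") +
    ggplot2::labs(x = "Tanimoto similarity", y = "pairs",
                  title = sprintf("avg %.3f, %.1f%% at 1.0",
                                  object$avg_tanimoto,
                                  object$pct_tanimoto_1)) +
    ggplot2::theme_minimal()
}
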