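# Dataset curation: rule-based filtering of SMILES corpora.
#
# The rule set mirrors the curation used to build the training corpora:
# molecules must be light (< 1500 Da), single-fragment, drawn from a fixed
# element set, isotope-free, of moderate size (3-40 bonds, < 40 SMILES
# characters), and - in the strict preset - free of charges and stereo.

RULE_ORDER <- c("mw", "fragments", "elements", "isotopes", "bonds",
                "charge", "hydrogens", "length", "stereo")

DEFAULT_ELEMENTS <- c("C", "H", "O", "N", "P", "S", "F", "Cl", "Br", "I",
                      "Se", "B")

#' Curation rule set
#'
#' Builds the named filter configuration applied to SMILES corpora before
#' depiction and training. Two presets are provided: `"dataset1"` (strict:
#' charged groups - including zwitterions - and stereocenters are rejected)
#' and `"dataset2"` (charges and stereochemistry are retained). All
#' thresholds can be overridden individually.
#'
#' @param preset `"dataset1"` or `"dataset2"`.
#' @param max_mw Maximum average molecular weight in Daltons (exclusive).
#' @param allowed_elements Character vector of allowed element symbols.
#' @param min_bonds,max_bonds Inclusive bounds on the number of heavy-atom
#'   bonds (edges of the hydrogen-suppressed molecular graph).
#' @param max_smiles_chars Canonical SMILES must be strictly shorter than
#'   this many characters.
#' @param allow_charges,allow_stereo Skip the charge / stereo rules.
#' @param forbid_multifragment Reject dot-disconnected SMILES (counter ions).
#' @param forbid_isotopes Reject isotopically labelled molecules (D, T, ...).
#' @return An object of class `ocsr_rule_set`.
#' @examples
#' rule_set("dataset1")
#' rule_set("dataset2", max_bonds = 50)
#' @export
rule_set <- function(preset = c("dataset1", "dataset2"),
                     max_mw = 1500,
                     allowed_elements = DEFAULT_ELEMENTS,
                     min_bonds = 3L,
                     max_bonds = 40L,
                     max_smiles_chars = 40L,
                     allow_charges = NULL,
                     allow_stereo = NULL,
                     forbid_multifragment = TRUE,
                     forbid_isotopes = TRUE) {
  preset <- match.arg(preset)
  if (is.null(allow_charges)) allow_charges <- preset == "dataset2"
  if (is.null(allow_stereo)) allow_stereo <- preset == "dataset2"
  stopifnot(max_mw > 0, min_bonds <= max_bonds, length(allowed_elements) > 0)
  structure(
    list(preset = preset, max_mw = max_mw,
         allowed_elements = allowed_elements,
         min_bonds = as.integer(min_bonds), max_bonds = as.integer(max_bonds),
         max_smiles_chars = as.integer(max_smiles_chars),
         allow_charges = isTRUE(allow_charges),
         allow_stereo = isTRUE(allow_stereo),
         forbid_multifragment = isTRUE(forbid_multifragment),
         forbid_isotopes = isTRUE(forbid_isotopes)),
    class = "ocsr_rule_set"
  )
}

#' @export
print.ocsr_rule_set <- function(x, ...) {
  cat("<ocsr_rule_set: ", x$preset, ">\n", sep = "")
  cat("  MW < ", x$max_mw, " Da; bonds ", x$min_bonds, "-", x$max_bonds,
      "; SMILES < ", x$max_smiles_chars, " chars\n", sep = "")
  cat("  elements: {", paste(x$allowed_elements, collapse = ","), "}\n",
      sep = "")
  cat("  charges ", if (x$allow_charges) "allowed" else "rejected",
      "; stereo ", if (x$allow_stereo) "allowed" else "rejected", "\n",
      sep = "")
  invisible(x)
}

#' Molecular descriptors used by the curation rules
#'
#' Computes, for each SMILES, every quantity the rule set inspects. The
#' molecular graph is hydrogen-suppressed: `n_bonds` counts each
#' heavy-atom--heavy-atom connection once, and `mol_weight` is the average
#' molecular weight including implicit hydrogens.
#'
#' @param smiles Character vector (or data frame with a `smiles` column).
#' @return A tibble with one row per input: `smiles`, `canonical_smiles`,
#'   `smiles_length`, `mol_weight`, `n_bonds`, `element_set` (list column),
#'   `n_fragments`, `has_formal_charge`, `has_isotope`, `has_stereo`,
#'   `parsed`.
#' @examples
#' \dontrun{
#' compute_descriptors(c("CCO", "[Na+].[Cl-]"))
#' }
#' @export
compute_descriptors <- function(smiles) {
  smiles <- as_smiles_vector(smiles)
  n <- length(smiles)
  can <- canonical_smiles(smiles)
  mw <- mol_weight(smiles)
  graphs <- mol_graphs(smiles)
  parsed <- !is.na(can) & !vapply(graphs, is.null, logical(1))
  n_bonds <- rep(NA_integer_, n)
  element_set <- vector("list", n)
  n_fragments <- rep(NA_integer_, n)
  has_charge <- rep(NA, n)
  has_isotope <- rep(NA, n)
  has_stereo <- rep(NA, n)
  for (i in seq_len(n)) {
    g <- graphs[[i]]
    if (is.null(g) || !parsed[i]) next
    heavy <- g$atoms$symbol != "H"
    n_bonds[i] <- sum(heavy[g$bonds$from] & heavy[g$bonds$to])
    element_set[[i]] <- sort(unique(g$atoms$symbol))
    n_fragments[i] <- n_components(g$n_atoms, g$bonds)
    has_charge[i] <- any(g$atoms$charge != 0L)
    has_isotope[i] <- any(g$atoms$isotope != 0L)
    has_stereo[i] <- grepl("[@/\\\\]", can[i])
  }
  tibble::tibble(
    smiles = smiles,
    canonical_smiles = can,
    smiles_length = ifelse(is.na(can), NA_integer_, nchar(can)),
    mol_weight = mw,
    n_bonds = n_bonds,
    element_set = element_set,
    n_fragments = n_fragments,
    has_formal_charge = has_charge,
    has_isotope = has_isotope,
    has_stereo = has_stereo,
    parsed = parsed
  )
}

# Connected components of the molecular graph (union-find).
n_components <- function(n_atoms, bonds) {
  if (n_atoms == 0L) return(0L)
  parent <- seq_len(n_atoms)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(bonds$from)) {
    a <- find(bonds$from[k]); b <- find(bonds$to[k])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n_atoms), find, integer(1))))
}

# Bracket atoms in the canonical SMILES that are neither charged, stereo,
# isotopic nor the standard aromatic [nH]/[sH] indicate explicit-hydrogen /
# nonstandard-valence notation; such molecules fail the "hydrogens" rule.
has_weird_explicit_h <- function(can_smiles) {
  vapply(can_smiles, function(s) {
    if (is.na(s)) return(NA)
    brs <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    if (length(brs) == 0L) return(FALSE)
    ok <- grepl("[@+-]", brs) | grepl("^\\[[0-9]", brs) |
      brs %in% c("[nH]", "[sH]", "[pH]") |
      grepl("^\\[(Se|se)H?[0-9]?\\]$", brs)
    any(!ok)
  }, logical(1), USE.NAMES = FALSE)
}

#' Check molecules against a rule set
#'
#' Applies every curation rule and reports each violation. The rules are
#' evaluated in a fixed documented order: `mw`, `fragments`, `elements`,
#' `isotopes`, `bonds`, `charge`, `hydrogens`, `length`, `stereo`. The
#' `charge` and `stereo` rules are skipped when the rule set allows them.
#' Unparseable SMILES yield a decision with `failed_rules = "unparseable"`.
#'
#' @param smiles Character vector (or data frame with a `smiles` column).
#' @param rules An [rule_set()].
#' @return A tibble with one row per molecule: `smiles`, `passed`,
#'   `failed_rules` (list column, empty iff passed), `first_failed` and all
#'   descriptor columns.
#' @examples
#' \dontrun{
#' check_molecule(c("CCCO", "CCO"), rule_set("dataset1"))
#' }
#' @export
check_molecule <- function(smiles, rules = rule_set("dataset1")) {
  stopifnot(inherits(rules, "ocsr_rule_set"))
  desc <- compute_descriptors(smiles)
  weird_h <- has_weird_explicit_h(desc$canonical_smiles)
  failed <- vector("list", nrow(desc))
  for (i in seq_len(nrow(desc))) {
    if (!desc$parsed[i]) {
      failed[[i]] <- "unparseable"
      next
    }
    f <- character()
    if (!(desc$mol_weight[i] < rules$max_mw)) f <- c(f, "mw")
    if (rules$forbid_multifragment && desc$n_fragments[i] > 1L)
      f <- c(f, "fragments")
    if (!all(desc$element_set[[i]] %in% rules$allowed_elements))
      f <- c(f, "elements")
    if (rules$forbid_isotopes && isTRUE(desc$has_isotope[i]))
      f <- c(f, "isotopes")
    if (desc$n_bonds[i] < rules$min_bonds || desc$n_bonds[i] > rules$max_bonds)
      f <- c(f, "bonds")
    if (!rules$allow_charges && isTRUE(desc$has_formal_charge[i]))
      f <- c(f, "charge")
    if (isTRUE(weird_h[i])) f <- c(f, "hydrogens")
    if (!(desc$smiles_length[i] < rules$max_smiles_chars)) f <- c(f, "length")
    if (!rules$allow_stereo && isTRUE(desc$has_stereo[i])) f <- c(f, "stereo")
    failed[[i]] <- f
  }
  dplyr::mutate(
    desc,
    passed = lengths(failed) == 0L,
    failed_rules = failed,
    first_failed = vapply(failed, function(f) {
      if (length(f)) f[[1]] else NA_character_
    }, character(1)),
    .after = "smiles"
  )
}

#' Filter a SMILES corpus
#'
#' Applies [check_molecule()] to a corpus and splits it into canonicalized
#' survivors (input order preserved) and per-rule rejection statistics. Each
#' rejected molecule is counted once, under the first rule it failed.
#'
#' @inheritParams check_molecule
#' @return A list of class `ocsr_filter_result` with elements `survivors`
#'   (tibble: `smiles` = canonical SMILES, `input_smiles`), `stats` (tibble:
#'   `rule`, `n_rejected`), `n_input`, `n_passed` and `rules`.
#' @examples
#' \dontrun{
#' res <- filter_corpus(c("C", "CCCO"), rule_set("dataset1"))
#' res$survivors
#' res$stats
#' }
#' @export
filter_corpus <- function(smiles, rules = rule_set("dataset1")) {
  smiles <- as_smiles_vector(smiles)
  if (length(smiles) == 0L) {
    warning("empty corpus: nothing to filter")
    decisions <- tibble::tibble()
    survivors <- tibble::tibble(smiles = character(),
                                input_smiles = character())
  } else {
    decisions <- check_molecule(smiles, rules)
    survivors <- tibble::tibble(
      smiles = decisions$canonical_smiles[decisions$passed],
      input_smiles = decisions$smiles[decisions$passed]
    )
  }
  rule_levels <- c(RULE_ORDER, "unparseable")
  counts <- if (nrow(decisions)) {
    table(factor(decisions$first_failed, levels = rule_levels))
  } else {
    table(factor(character(), levels = rule_levels))
  }
  structure(
    list(survivors = survivors,
         stats = tibble::tibble(rule = rule_levels,
                                n_rejected = as.integer(counts)),
         n_input = length(smiles),
         n_passed = nrow(survivors),
         rules = rules,
         decisions = decisions),
    class = "ocsr_filter_result"
  )
}

#' @export
print.ocsr_filter_result <- function(x, ...) {
  cat("<ocsr_filter_result> ", x$n_passed, "/", x$n_input,
      " molecules passed (", x$rules$preset, ")\n", sep = "")
  rej <- x$stats[x$stats$n_rejected > 0L, ]
  if (nrow(rej)) {
    cat("  rejections: ",
        paste0(rej$rule, "=", rej$n_rejected, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

# Accept either a character vector or a data frame with a `smiles` column.
as_smiles_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!"smiles" %in% names(x)) {
      stop("data frame input must have a `smiles` column", call. = FALSE)
    }
    x <- x$smiles
  }
  as.character(x)
}
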