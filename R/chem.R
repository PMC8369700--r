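#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib ocsr, .registration = TRUE
NULL

# ---- Open Babel batch backend -----------------------------------------------
#
# All standard chemistry (canonicalization, Kekule SMILES, InChI, 2D layout,
# FP2 path fingerprints, molecular weight) is delegated to the `obabel`
# executable, run once per batch over a temporary file.  Each input line
# carries a numeric title (`m<i>`) so results can be realigned with their
# inputs even when Open Babel silently drops unparseable records.

ob_available <- function() nzchar(Sys.which("obabel"))

assert_obabel <- function() {
  if (!ob_available()) {
    stop("The 'obabel' executable (Open Babel) was not found on the PATH.",
         call. = FALSE)
  }
}

# Run obabel over `smiles`, returning raw output lines plus the temp paths.
ob_batch <- function(smiles, out_format, extra_args = character()) {
  assert_obabel()
  stopifnot(is.character(smiles))
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile()
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste0(smiles, " m", seq_along(smiles)), infile)
  # -e: keep converting after an unparseable record
  args <- c(infile, paste0("-o", out_format), "-O", outfile, "-e",
            extra_args)
  status <- suppressWarnings(
    system2("obabel", shQuote(args), stdout = FALSE, stderr = FALSE)
  )
  if (!identical(status, 0L) || !file.exists(outfile)) {
    stop("obabel failed (status ", status, ")", call. = FALSE)
  }
  readLines(outfile, warn = FALSE)
}

# Align `values` named by "m<i>" titles back onto the input index; NA = failed.
ob_align <- function(values, titles, n) {
  idx <- suppressWarnings(as.integer(sub("^m", "", titles)))
  out <- rep(NA_character_, n)
  keep <- !is.na(idx) & idx >= 1 & idx <= n
  out[idx[keep]] <- values[keep]
  out
}

#' Canonical SMILES via Open Babel
#'
#' Canonicalizes SMILES strings in one batch call. Unparseable inputs yield
#' `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param kekule If `TRUE`, emit Kekule SMILES (localized double bonds, no
#'   aromatic lowercase atoms) instead of canonical aromatic SMILES.
#' @return Character vector the same length as `smiles`.
#' @export
canonical_smiles <- function(smiles, kekule = FALSE) {
  if (length(smiles) == 0L) return(character())
  lines <- if (kekule) {
    ob_batch(smiles, "smi", c("-xk"))
  } else {
    ob_batch(smiles, "can")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vals <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  titles <- vapply(parts, function(p) if (length(p) > 1L) trimws(p[[2]]) else "",
                   character(1))
  ob_align(vals, titles, length(smiles))
}

#' Standard InChI strings via Open Babel
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of standard InChI strings (stereo layers
#'   included); `NA` where the SMILES does not parse.
#' @export
mol_inchi <- function(smiles) {
  if (length(smiles) == 0L) return(character())
  lines <- ob_batch(smiles, "inchi", c("-xt"))
  lines <- lines[startsWith(lines, "InChI=")]
  m <- regmatches(lines, regexec("^(InChI=\\S+) (m[0-9]+)\\s*$", lines))
  vals <- vapply(m, function(x) if (length(x) == 3L) x[[2]] else NA_character_,
                 character(1))
  titles <- vapply(m, function(x) if (length(x) == 3L) x[[3]] else "",
                   character(1))
  ob_align(vals, titles, length(smiles))
}

#' Path-based structural fingerprints
#'
#' Computes Open Babel FP2 fingerprints (1024-bit linear-fragment/path
#' fingerprint) for a batch of SMILES. FP2 is the package's default
#' fingerprint backend for Tanimoto similarity and MaxMin splitting; the
#' backend is pluggable wherever a fingerprint is consumed.
#'
#' @param smiles Character vector of SMILES strings.
#' @param backend Fingerprint name understood by Open Babel (default `"FP2"`;
#'   `"MACCS"` and `"FP3"`/`"FP4"` are also available).
#' @return Logical matrix with one row per input molecule. Rows for
#'   unparseable SMILES are `NA`.
#' @export
mol_fingerprints <- function(smiles, backend = "FP2") {
  if (length(smiles) == 0L) {
    return(matrix(logical(), nrow = 0L, ncol = 0L))
  }
  lines <- ob_batch(smiles, "fpt", c(paste0("-xf", backend), "-xh"))
  # Output: ">m<i> ..." header lines followed by hex dump lines.
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no fingerprints produced", call. = FALSE)
  titles <- sub("^>\\s*(m[0-9]+).*$", "\\1", lines[starts])
  ends <- c(starts[-1L] - 1L, length(lines))
  hex_per_mol <- mapply(function(s, e) {
    blk <- lines[seq(s + 1L, length.out = max(0L, e - s))]
    blk <- blk[grepl("^[0-9a-fA-F ]+$", blk)]   # drop commentary lines
    gsub("\\s", "", paste(blk, collapse = ""))
  }, starts, ends)
  nbits <- max(nchar(hex_per_mol)) * 4L
  rows <- lapply(hex_per_mol, hex_to_bits, nbits = nbits)
  mat <- matrix(NA, nrow = length(smiles), ncol = nbits)
  idx <- suppressWarnings(as.integer(sub("^m", "", titles)))
  keep <- !is.na(idx) & idx >= 1 & idx <= length(smiles)
  for (k in which(keep)) mat[idx[k], ] <- rows[[k]]
  mat
}

# Hex string -> logical bit vector (bit order is backend-internal; Tanimoto
# only needs consistency within a backend).
hex_to_bits <- function(hx, nbits) {
  if (!nzchar(hx)) return(rep(NA, nbits))
  nib <- strtoi(strsplit(hx, "")[[1]], base = 16L)
  bits <- as.logical(t(vapply(nib, function(v) {
    as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L)
  }, integer(4))))
  length(bits) <- nbits
  bits[is.na(bits)] <- FALSE
  bits
}

# ---- molblock parsing -------------------------------------------------------

# Convert SMILES to V2000 molblocks (optionally with 2D coordinates) and
# parse the atom and bond blocks. Returns a list (one per input; NULL where
# parsing failed) of lists with `atoms` and `bonds` tibbles.
mol_graphs <- function(smiles, gen2d = FALSE) {
  if (length(smiles) == 0L) return(list())
  args <- if (gen2d) c("--gen2d") else character()
  lines <- ob_batch(smiles, "sdf", args)
  recs <- split_molblocks(lines)
  out <- vector("list", length(smiles))
  for (r in recs) {
    ttl <- trimws(r[[1]])
    idx <- suppressWarnings(as.integer(sub("^m", "", ttl)))
    if (is.na(idx) || idx < 1L || idx > length(smiles)) next
    out[[idx]] <- parse_molblock(r)
  }
  out
}

split_molblocks <- function(lines) {
  ends <- which(lines == "$$$$")
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) lines[s:(e - 1L)], starts, ends, SIMPLIFY = FALSE)
}

# Plain-vector molecular graph: atoms (x, y, symbol, charge, isotope),
# bonds (from, to, order, wedge), n_atoms, n_bonds.
parse_molblock <- function(rec) {
  counts <- rec[[4]]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atoms <- list(x = numeric(na), y = numeric(na),
                symbol = character(na), charge = integer(na),
                isotope = integer(na))
  if (na > 0L) {
    al <- rec[4L + seq_len(na)]
    atoms$x <- as.numeric(substr(al, 1, 10))
    atoms$y <- as.numeric(substr(al, 11, 20))
    atoms$symbol <- trimws(substr(al, 32, 34))
  }
  bonds <- list(from = integer(nb), to = integer(nb),
                order = integer(nb), wedge = integer(nb))
  if (nb > 0L) {
    bl <- rec[4L + na + seq_len(nb)]
    bonds$from <- as.integer(substr(bl, 1, 3))
    bonds$to <- as.integer(substr(bl, 4, 6))
    bonds$order <- as.integer(substr(bl, 7, 9))
    bonds$wedge <- as.integer(substr(bl, 10, 12))
  }
  # Properties block: charges and isotopes override atom-block columns.
  for (ln in rec[grepl("^M  (CHG|ISO)", rec)]) {
    typ <- substr(ln, 4, 6)
    n <- as.integer(substr(ln, 7, 9))
    for (k in seq_len(n)) {
      off <- 10L + (k - 1L) * 8L
      ai <- as.integer(substr(ln, off, off + 3L))
      vv <- as.integer(substr(ln, off + 4L, off + 7L))
      if (typ == "CHG") atoms$charge[ai] <- vv else atoms$isotope[ai] <- vv
    }
  }
  list(atoms = atoms, bonds = bonds, n_atoms = na, n_bonds = nb)
}

#' Average molecular weights via Open Babel
#'
#' @param smiles Character vector of SMILES strings.
#' @return Numeric vector of average molecular weights in Daltons (implicit
#'   hydrogens included); `NA` where parsing fails.
#' @export
mol_weight <- function(smiles) {
  if (length(smiles) == 0L) return(numeric())
  lines <- ob_batch(smiles, "txt", c("--append", "MW"))
  parts <- strsplit(lines, "\\s+")
  titles <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  vals <- vapply(parts, function(p) if (length(p) > 1L) trimws(p[[2]]) else NA_character_,
                 character(1))
  as.numeric(ob_align(vals, titles, length(smiles)))
}
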