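# A SELFIES-style robust molecular string grammar.
#
# Every token is a bracketed symbol. Atom tokens ([C], [=O], [N+], [C@H],
# [/C], ...) add an atom bonded to the current attachment point; branch
# tokens ([Branch1] ... [#Branch3]) open a side chain whose length (in
# tokens) is spelled out by following index tokens; ring tokens ([Ring1],
# [=Ring2], ...) bond the current atom to an earlier one. Derivation is
# valence-constrained: a requested bond order is reduced to what both
# partners can still accept, and tokens that cannot be realized are skipped,
# so *any* sequence of grammar tokens derives a chemically valid structure.
# This robustness is the reason a sequence model can emit token streams
# without ever producing an unparseable prediction.
#
# Numbers (branch lengths, ring distances) are encoded in base 16 by the
# ordered index alphabet below; a branch/ring token's trailing digit says
# how many index tokens follow.

SF_INDEX_ALPHABET <- c("[C]", "[Ring1]", "[Ring2]",
                       "[Branch1]", "[=Branch1]", "[#Branch1]",
                       "[Branch2]", "[=Branch2]", "[#Branch2]",
                       "[O]", "[N]", "[=N]", "[=C]", "[#C]", "[S]", "[P]")

SF_BASE_CAPACITY <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 5L, S = 6L,
                      F = 1L, Cl = 1L, Br = 1L, I = 1L, Se = 2L)

# Heavy-bond capacity of charged atoms (common organochemical valences).
SF_CHARGED_CAPACITY <- c("B+1" = 2L, "B-1" = 4L, "C+1" = 3L, "C-1" = 3L,
                         "N+1" = 4L, "N-1" = 2L, "O+1" = 3L, "O-1" = 1L,
                         "P+1" = 4L, "P-1" = 6L, "S+1" = 3L, "S-1" = 1L,
                         "Se+1" = 3L)

sf_capacity <- function(element, charge = 0L, n_h = 0L) {
  base <- SF_BASE_CAPACITY[[element]]
  if (is.null(base)) stop("unsupported element: ", element, call. = FALSE)
  cap <- if (charge == 0L) {
    base
  } else {
    key <- sprintf("%s%+d", element, charge)
    if (!is.na(SF_CHARGED_CAPACITY[key])) {
      SF_CHARGED_CAPACITY[[key]]
    } else {
      max(base - abs(charge), 0L)
    }
  }
  max(cap - n_h, 0L)
}

SF_BOND_ORDER <- c("-" = 1L, "=" = 2L, "#" = 3L, "/" = 1L, "\\" = 1L)

# ---- token parsing ----------------------------------------------------------

# Parse one grammar token into its components. Returns a list with
# kind = "atom" | "branch" | "ring", or NULL if the token is not parseable
# as a grammar symbol (such tokens are skipped during derivation).
sf_parse_token <- function(tok) {
  inner <- substr(tok, 2L, nchar(tok) - 1L)
  m <- regmatches(inner, regexec(
    "^([=#/\\\\]?)(Branch|Ring)([123])$", inner))[[1]]
  if (length(m)) {
    return(list(kind = if (m[[3]] == "Branch") "branch" else "ring",
                bond = if (nzchar(m[[2]])) m[[2]] else "-",
                n_index = as.integer(m[[4]])))
  }
  m <- regmatches(inner, regexec(
    "^([=#/\\\\]?)(B|C|N|O|P|S|F|Cl|Br|I|Se)(@@|@)?(?:H([0-9]?))?([+-][0-9]?)?$",
    inner))[[1]]
  if (length(m)) {
    has_h <- grepl("H", inner, fixed = TRUE)
    n_h <- if (!has_h) 0L else if (nzchar(m[[5]])) as.integer(m[[5]]) else 1L
    chg <- 0L
    if (nzchar(m[[6]])) {
      sgn <- if (substr(m[[6]], 1L, 1L) == "+") 1L else -1L
      mag <- if (nchar(m[[6]]) > 1L) as.integer(substr(m[[6]], 2L, 2L)) else 1L
      chg <- sgn * mag
    }
    return(list(kind = "atom",
                bond = if (nzchar(m[[2]])) m[[2]] else "-",
                element = m[[3]],
                stereo = m[[4]],
                n_h = n_h,
                charge = chg,
                bracket = has_h || nzchar(m[[4]]) || chg != 0L ||
                  m[[3]] == "Se"))
  }
  NULL
}

sf_index_value <- function(tokens) {
  vals <- match(tokens, SF_INDEX_ALPHABET) - 1L
  vals[is.na(vals)] <- 0L
  v <- 0L
  for (x in vals) v <- v * 16L + x
  v
}

sf_index_tokens <- function(q) {
  stopifnot(q >= 0L)
  digs <- integer()
  repeat {
    digs <- c(q %% 16L, digs)
    q <- q %/% 16L
    if (q == 0L) break
  }
  SF_INDEX_ALPHABET[digs + 1L]
}

# ---- tokenization -----------------------------------------------------------

#' Split a SELFIES-style string into bracket tokens
#'
#' Tokenization is purely lexical: the string is split at `][` boundaries,
#' so it applies to any bracket-token molecular string regardless of grammar
#' version. Concatenating the returned tokens reproduces the input exactly.
#'
#' @param selfies A single string of the form `[tok][tok]...`.
#' @return Character vector of tokens, each starting with `[` and ending
#'   with `]`.
#' @examples
#' tokenize_selfies("[C][=C][Branch1][C][O]")
#' @export
tokenize_selfies <- function(selfies) {
  stopifnot(is.character(selfies), length(selfies) == 1L)
  if (is.na(selfies)) stop("cannot tokenize NA", call. = FALSE)
  toks <- regmatches(selfies, gregexpr("\\[[^][]*\\]", selfies))[[1]]
  if (paste(toks, collapse = "") != selfies) {
    stop("not a well-formed bracket-token string: ", selfies, call. = FALSE)
  }
  toks
}

# ---- decoder: tokens -> molecular graph -> SMILES ---------------------------

#' Decode a SELFIES-style string to SMILES
#'
#' Derives a molecular graph from the token sequence under valence
#' constraints and writes it out as SMILES. The derivation never fails on a
#' sequence of grammar tokens: bonds are capped by the remaining valence of
#' both partners, unrealizable tokens are skipped, and out-of-range ring
#' indices are clamped. A derivation that realizes no atom at all (for
#' example a bare ring token) decodes to `"C"`, the grammar's identity
#' molecule, so every vocabulary sequence maps to a parseable structure.
#'
#' @param selfies A SELFIES-style string, or a character vector of them.
#' @return Character vector of SMILES strings.
#' @examples
#' selfies_to_smiles("[C][C]")            # "CC"
#' selfies_to_smiles("[C][=C][C]")        # "C=CC"
#' @export
selfies_to_smiles <- function(selfies) {
  vapply(selfies, function(s) {
    st <- sf_new_state()
    sf_derive(tokenize_selfies(s), st)
    sf_write_smiles(st)
  }, character(1), USE.NAMES = FALSE)
}

# Shared mutable derivation state, held in an environment.
sf_new_state <- function() {
  st <- new.env(parent = emptyenv())
  st$element <- character()
  st$stereo <- character()
  st$n_h <- integer()
  st$charge <- integer()
  st$bracket <- logical()
  st$avail <- integer()
  st$bond_from <- integer()
  st$bond_to <- integer()
  st$bond_order <- integer()
  st$bond_dir <- character()
  st$tree <- logical()      # TRUE for chain/branch bonds, FALSE for rings
  st
}

sf_add_atom <- function(st, tk) {
  st$element <- c(st$element, tk$element)
  st$stereo <- c(st$stereo, tk$stereo)
  st$n_h <- c(st$n_h, tk$n_h)
  st$charge <- c(st$charge, tk$charge)
  st$bracket <- c(st$bracket, tk$bracket)
  st$avail <- c(st$avail, sf_capacity(tk$element, tk$charge, tk$n_h))
  length(st$element)
}

sf_add_bond <- function(st, a, b, order, dir, tree) {
  st$bond_from <- c(st$bond_from, a)
  st$bond_to <- c(st$bond_to, b)
  st$bond_order <- c(st$bond_order, order)
  st$bond_dir <- c(st$bond_dir, dir)
  st$tree <- c(st$tree, tree)
  st$avail[a] <- st$avail[a] - order
  st$avail[b] <- st$avail[b] - order
}

# Derive `tokens` attached to atom `cur` (0 = fresh chain). Mutates `st`.
sf_derive <- function(tokens, st = sf_new_state(), cur = 0L) {
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    tk <- sf_parse_token(tokens[[i]])
    i <- i + 1L
    if (is.null(tk)) next
    if (tk$kind == "atom") {
      cap <- sf_capacity(tk$element, tk$charge, tk$n_h)
      if (cur == 0L) {
        cur <- sf_add_atom(st, tk)
        next
      }
      b <- min(SF_BOND_ORDER[[tk$bond]], st$avail[cur], cap)
      if (b <= 0L) {
        if (st$avail[cur] <= 0L) break  # attachment saturated: stop here
        next                            # zero-capacity atom: skip it
      }
      new <- sf_add_atom(st, tk)
      dir <- if (tk$bond %in% c("/", "\\") && b == 1L) tk$bond else ""
      sf_add_bond(st, cur, new, b, dir, tree = TRUE)
      cur <- new
    } else if (tk$kind == "branch") {
      n_idx <- min(tk$n_index, n - i + 1L)
      q <- if (n_idx > 0L) sf_index_value(tokens[i:(i + n_idx - 1L)]) else 0L
      i <- i + n_idx
      take <- min(q + 1L, n - i + 1L)
      if (take > 0L) {
        branch <- tokens[i:(i + take - 1L)]
        i <- i + take
        if (cur != 0L && st$avail[cur] > 0L) {
          sf_derive(branch, st, cur)
        }
      }
    } else { # ring
      n_idx <- min(tk$n_index, n - i + 1L)
      q <- if (n_idx > 0L) sf_index_value(tokens[i:(i + n_idx - 1L)]) else 0L
      i <- i + n_idx
      if (cur == 0L) next
      target <- max(cur - (q + 1L), 1L)
      if (target == cur) next
      dup <- any((st$bond_from == target & st$bond_to == cur) |
                   (st$bond_from == cur & st$bond_to == target))
      if (dup) next
      b <- min(SF_BOND_ORDER[[tk$bond]], st$avail[cur], st$avail[target])
      if (b <= 0L) next
      dir <- if (tk$bond %in% c("/", "\\") && b == 1L) tk$bond else ""
      sf_add_bond(st, target, cur, b, dir, tree = FALSE)
    }
  }
  cur
}

# Note on sf_derive/branches: a branch derivation shares `st` and attaches
# its first atom to `cur`; ring distances are global atom-creation ranks, so
# rings may reach across branch boundaries exactly as in the source grammar.

sf_atom_smiles <- function(st, i) {
  el <- st$element[i]
  if (!st$bracket[i]) return(el)
  h <- if (st$n_h[i] == 0L) "" else if (st$n_h[i] == 1L) "H" else
    paste0("H", st$n_h[i])
  chg <- st$charge[i]
  c_str <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
  else sprintf("%+d", chg)
  paste0("[", el, st$stereo[i], h, c_str, "]")
}

sf_bond_smiles <- function(order, dir) {
  if (order == 2L) "=" else if (order == 3L) "#" else dir
}

# Write SMILES by walking the derivation tree in creation order. Ring-bond
# digits are emitted immediately after their atom (before any branch), which
# together with creation-order traversal preserves neighbour ordering - and
# hence tetrahedral parity markers - from encode to decode.
sf_write_smiles <- function(st) {
  n <- length(st$element)
  if (n == 0L) return("C")
  kids <- vector("list", n)       # tree children, creation order
  parent_bond <- integer(n)
  ring_at <- vector("list", n)    # ring bond ids touching atom, open first
  nb <- length(st$bond_from)
  ring_ids <- which(!st$tree)
  ring_digit <- integer(nb)
  if (length(ring_ids)) {
    ring_digit[ring_ids] <- seq_along(ring_ids)
  }
  for (k in seq_len(nb)) {
    a <- st$bond_from[k]; b <- st$bond_to[k]
    if (st$tree[k]) {
      kids[[a]] <- c(kids[[a]], b)
      parent_bond[b] <- k
    } else {
      ring_at[[a]] <- c(ring_at[[a]], k)
      ring_at[[b]] <- c(ring_at[[b]], k)
    }
  }
  digit_str <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)
  emit <- function(i) {
    out <- sf_atom_smiles(st, i)
    for (k in ring_at[[i]]) {
      d <- digit_str(ring_digit[k])
      # bond symbol on the opening occurrence only
      sym <- if (st$bond_from[k] == i) {
        sf_bond_smiles(st$bond_order[k], st$bond_dir[k])
      } else ""
      out <- paste0(out, sym, d)
    }
    ch <- kids[[i]]
    if (length(ch)) {
      for (j in seq_along(ch)) {
        k <- parent_bond[ch[j]]
        sub <- paste0(sf_bond_smiles(st$bond_order[k], st$bond_dir[k]),
                      emit(ch[j]))
        out <- if (j < length(ch)) {
          paste0(out, "(", sub, ")")
        } else {
          paste0(out, sub)
        }
      }
    }
    out
  }
  roots <- setdiff(seq_len(n), st$bond_to[st$tree])
  paste(vapply(roots, emit, character(1)), collapse = ".")
}

# ---- encoder: SMILES -> tokens ----------------------------------------------

#' Encode SMILES as SELFIES-style strings
#'
#' Input SMILES are first rewritten by Open Babel as Kekule isomeric SMILES
#' (aromatic systems localized), then transcribed token by token. The
#' returned string decodes back to a molecule canonically identical to the
#' input for any molecule passing the curation rules.
#'
#' @param smiles Character vector of SMILES strings.
#' @param kekulize Rewrite via Open Babel first (default). Set to `FALSE`
#'   only for already-Kekule, non-aromatic input.
#' @return Character vector of SELFIES-style strings (`NA` with a warning
#'   for unparseable input).
#' @examples
#' \dontrun{
#' smiles_to_selfies("CCO")
#' selfies_to_smiles(smiles_to_selfies("c1ccccc1"))
#' }
#' @export
smiles_to_selfies <- function(smiles, kekulize = TRUE) {
  if (length(smiles) == 0L) return(character())
  kek <- if (kekulize) canonical_smiles(smiles, kekule = TRUE) else smiles
  bad <- is.na(kek)
  if (any(bad)) {
    warning("unparseable SMILES: ",
            paste(utils::head(smiles[bad], 5L), collapse = ", "))
  }
  out <- rep(NA_character_, length(smiles))
  for (i in which(!bad)) {
    out[i] <- paste(sf_encode_one(kek[i]), collapse = "")
  }
  out
}

# Tokenize a Kekule SMILES string into lexical events.
sf_lex_smiles <- function(s) {
  toks <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("-", "=", "#", "/", "\\")) {
      toks[[length(toks) + 1L]] <- list(type = "bond", sym = ch)
      i <- i + 1L
    } else if (ch == "(") {
      toks[[length(toks) + 1L]] <- list(type = "open"); i <- i + 1L
    } else if (ch == ")") {
      toks[[length(toks) + 1L]] <- list(type = "close"); i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      toks[[length(toks) + 1L]] <- list(type = "ring", id = as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      toks[[length(toks) + 1L]] <-
        list(type = "ring", id = as.integer(substr(s, i + 1L, i + 2L)))
      i <- i + 3L
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0L) stop("unbalanced bracket in SMILES: ", s, call. = FALSE)
      toks[[length(toks) + 1L]] <-
        list(type = "atom", spec = substr(s, i, i + j - 1L))
      i <- i + j
    } else if (ch == ".") {
      stop("multi-fragment SMILES cannot be encoded: ", s, call. = FALSE)
    } else {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br", "Se")) {
        toks[[length(toks) + 1L]] <- list(type = "atom", spec = two)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        toks[[length(toks) + 1L]] <- list(type = "atom", spec = ch)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        stop("aromatic SMILES atom '", ch, "' cannot be encoded; ",
             "kekulize first: ", s, call. = FALSE)
      } else {
        stop("unexpected character '", ch, "' in SMILES: ", s, call. = FALSE)
      }
    }
  }
  toks
}

sf_parse_bracket_atom <- function(spec, smiles) {
  m <- regmatches(spec, regexec(
    "^\\[([0-9]*)([A-Z][a-z]?)(@@|@)?(?:H([0-9]*))?([+-][0-9]*|\\+\\+|--)?\\]$",
    spec))[[1]]
  if (!length(m)) {
    stop("unsupported bracket atom ", spec, " in ", smiles, call. = FALSE)
  }
  if (nzchar(m[[2]])) {
    stop("isotopes cannot be encoded (", spec, ")", call. = FALSE)
  }
  el <- m[[3]]
  if (!el %in% names(SF_BASE_CAPACITY)) {
    stop("unsupported element ", el, " in ", smiles, call. = FALSE)
  }
  n_h <- if (!grepl("H", spec)) 0L else if (nzchar(m[[5]])) as.integer(m[[5]])
  else 1L
  chg <- 0L
  cs <- m[[6]]
  if (nzchar(cs)) {
    if (cs == "++") cs <- "+2"
    if (cs == "--") cs <- "-2"
    sgn <- if (substr(cs, 1L, 1L) == "+") 1L else -1L
    mag <- if (nchar(cs) > 1L) as.integer(substr(cs, 2L, nchar(cs))) else 1L
    chg <- sgn * mag
  }
  list(element = el, stereo = m[[4]], n_h = n_h, charge = chg)
}

# Transcribe one Kekule SMILES into grammar tokens. Returns a character
# vector of tokens. Branch lengths are computed by recursive transcription.
sf_encode_one <- function(smiles) {
  lex <- sf_lex_smiles(smiles)
  rank <- 0L                      # atoms emitted so far (creation rank)
  open_rings <- list()            # id -> list(rank, bond)
  pos <- 1L

  atom_token <- function(ev, bond) {
    if (startsWith(ev$spec, "[")) {
      at <- sf_parse_bracket_atom(ev$spec, smiles)
    } else {
      at <- list(element = ev$spec, stereo = "", n_h = 0L, charge = 0L)
    }
    h <- if (at$n_h == 0L) "" else if (at$n_h == 1L) "H" else
      paste0("H", at$n_h)
    chg <- at$charge
    c_str <- if (chg == 0L) "" else if (chg == 1L) "+" else
      if (chg == -1L) "-" else sprintf("%+d", chg)
    bond_str <- if (bond %in% c("-", "")) "" else bond
    paste0("[", bond_str, at$element, at$stereo, h, c_str, "]")
  }

  # Transcribe events until the matching ")" or end of input.
  walk <- function() {
    out <- character()
    bond <- ""
    repeat {
      if (pos > length(lex)) return(out)
      ev <- lex[[pos]]
      if (ev$type == "close") {
        pos <<- pos + 1L
        return(out)
      }
      pos <<- pos + 1L
      if (ev$type == "bond") {
        bond <- ev$sym
      } else if (ev$type == "atom") {
        rank <<- rank + 1L
        out <- c(out, atom_token(ev, bond))
        bond <- ""
      } else if (ev$type == "ring") {
        key <- as.character(ev$id)
        if (is.null(open_rings[[key]])) {
          open_rings[[key]] <<- list(rank = rank, bond = bond)
        } else {
          op <- open_rings[[key]]
          open_rings[[key]] <<- NULL
          rbond <- if (nzchar(bond) && bond != "-") bond else op$bond
          q <- rank - op$rank - 1L
          idx <- sf_index_tokens(q)
          pre <- if (rbond %in% c("", "-")) "" else rbond
          out <- c(out,
                   paste0("[", pre, "Ring", length(idx), "]"), idx)
        }
        bond <- ""
      } else if (ev$type == "open") {
        inner <- walk()
        q <- length(inner) - 1L
        idx <- sf_index_tokens(q)
        out <- c(out, paste0("[Branch", length(idx), "]"), idx, inner)
      }
    }
  }

  toks <- walk()
  if (length(open_rings)) {
    stop("unclosed ring bond in SMILES: ", smiles, call. = FALSE)
  }
  toks
}

# ---- vocabulary -------------------------------------------------------------

SF_PAD <- "<pad>"
SF_START <- "<start>"
SF_END <- "<end>"

#' Build a token vocabulary from a corpus
#'
#' Molecules containing any of `rare_tokens` are removed before counting
#' (rare-token pruning precedes vocabulary freezing). Chemical tokens are
#' ordered by descending corpus frequency with lexicographic tie-break;
#' the specials `<pad>`, `<start>`, `<end>` take ids 0, 1, 2. `max_len` is
#' the longest surviving sequence plus two (start and end markers).
#'
#' @param corpus A list of token character vectors (as returned by
#'   [tokenize_selfies()]), or a data frame with a `tokens` list column.
#' @param rare_tokens Optional character vector of tokens whose molecules
#'   are dropped before the vocabulary is frozen (duplicates ignored).
#' @param min_count Alternatively, derive `rare_tokens` as all tokens seen
#'   fewer than `min_count` times in the corpus.
#' @return An object of class `ocsr_vocab`: `token_to_id` (named integer
#'   vector over chemical tokens and specials), `chemical_tokens`, `counts`,
#'   `max_len`, `pad_id`, `start_id`, `end_id`.
#' @examples
#' v <- build_vocab(list(c("[C]", "[C]"), c("[C]", "[O]")))
#' v$max_len   # longest sequence + start/end
#' @export
build_vocab <- function(corpus, rare_tokens = NULL, min_count = NULL) {
  corpus <- as_token_corpus(corpus)
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  if (!is.null(min_count)) {
    tab <- table(unlist(corpus))
    rare_tokens <- union(rare_tokens, names(tab)[tab < min_count])
  }
  rare_tokens <- unique(rare_tokens)
  if (length(rare_tokens)) {
    keep <- !vapply(corpus, function(t) any(t %in% rare_tokens), logical(1))
    corpus <- corpus[keep]
    if (length(corpus) == 0L) {
      stop("rare-token pruning removed the whole corpus", call. = FALSE)
    }
  }
  counts <- table(unlist(corpus))
  ord <- order(-as.integer(counts), names(counts), method = "radix")
  chem <- names(counts)[ord]
  ids <- c(0L, 1L, 2L, seq_along(chem) + 2L)
  names(ids) <- c(SF_PAD, SF_START, SF_END, chem)
  structure(
    list(token_to_id = ids,
         chemical_tokens = chem,
         counts = as.integer(counts)[ord],
         max_len = max(lengths(corpus)) + 2L,
         pad_id = 0L, start_id = 1L, end_id = 2L,
         n_dropped = if (length(rare_tokens)) sum(!keep) else 0L,
         rare_tokens = rare_tokens),
    class = "ocsr_vocab"
  )
}

#' @export
print.ocsr_vocab <- function(x, ...) {
  cat("<ocsr_vocab> ", length(x$chemical_tokens),
      " chemical tokens + 3 specials; max_len ", x$max_len, "\n", sep = "")
  invisible(x)
}

as_token_corpus <- function(corpus) {
  if (is.data.frame(corpus)) {
    stopifnot("tokens" %in% names(corpus))
    corpus <- corpus$tokens
  }
  if (is.character(corpus)) corpus <- lapply(corpus, tokenize_selfies)
  stopifnot(is.list(corpus))
  corpus
}

#' Encode a token sequence as padded integer ids
#'
#' Produces `[start] ids... [end]` padded with the pad id to exactly
#' `vocab$max_len`.
#'
#' @param tokens Character vector of tokens (one sequence).
#' @param vocab An [build_vocab()] result.
#' @return Integer vector of length `vocab$max_len`.
#' @export
encode_sequence <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "ocsr_vocab"))
  ids <- vocab$token_to_id[tokens]
  if (anyNA(ids)) {
    stop("out-of-vocabulary token(s): ",
         paste(unique(tokens[is.na(ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(ids) + 2L > vocab$max_len) {
    stop("sequence of ", length(ids), " tokens exceeds max_len ",
         vocab$max_len, call. = FALSE)
  }
  out <- c(vocab$start_id, unname(ids), vocab$end_id)
  c(out, rep(vocab$pad_id, vocab$max_len - length(out)))
}

#' Decode integer ids back to tokens
#'
#' Inverse of [encode_sequence()]: strips the start marker, stops at the
#' first end or pad id, and maps remaining ids to tokens.
#'
#' @param ids Integer vector.
#' @param vocab An [build_vocab()] result.
#' @return Character vector of chemical tokens.
#' @export
decode_sequence <- function(ids, vocab) {
  stopifnot(inherits(vocab, "ocsr_vocab"))
  id_to_token <- names(vocab$token_to_id)[order(vocab$token_to_id)]
  ids <- ids[ids != vocab$start_id]
  stop_at <- which(ids == vocab$end_id | ids == vocab$pad_id)
  if (length(stop_at)) ids <- ids[seq_len(stop_at[1L] - 1L)]
  if (any(ids < 0L | ids >= length(id_to_token))) {
    stop("id out of range for vocabulary", call. = FALSE)
  }
  id_to_token[ids + 1L]
}

#' Drop molecules containing rare tokens
#'
#' @param corpus A list of token sequences or a data frame with a `tokens`
#'   list column.
#' @param rare_tokens Character vector of tokens (treated as a set).
#' @return The corpus with every sequence containing a rare token removed
#'   (same container type as the input).
#' @export
drop_rare_token_molecules <- function(corpus, rare_tokens) {
  rare_tokens <- unique(rare_tokens)
  seqs <- as_token_corpus(corpus)
  keep <- !vapply(seqs, function(t) any(t %in% rare_tokens), logical(1))
  if (is.data.frame(corpus)) corpus[keep, , drop = FALSE] else corpus[keep]
}

#' Serialize a vocabulary to JSON
#'
#' @param vocab An [build_vocab()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "ocsr_vocab"))
  jsonlite::write_json(
    list(tokens = tibble::tibble(token = names(vocab$token_to_id),
                                 id = unname(vocab$token_to_id)),
         counts = tibble::tibble(token = vocab$chemical_tokens,
                                 count = vocab$counts),
         max_len = vocab$max_len,
         rare_tokens = vocab$rare_tokens),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vocabulary from JSON
#'
#' @param path File written by [write_vocab()].
#' @return An `ocsr_vocab` object.
#' @export
read_vocab <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- stats::setNames(as.integer(js$tokens$id), js$tokens$token)
  structure(
    list(token_to_id = ids,
         chemical_tokens = js$counts$token,
         counts = as.integer(js$counts$count),
         max_len = as.integer(js$max_len),
         pad_id = 0L, start_id = 1L, end_id = 2L,
         n_dropped = NA_integer_,
         rare_tokens = as.character(js$rare_tokens %||% character())),
    class = "ocsr_vocab"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
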