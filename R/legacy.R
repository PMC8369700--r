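# Reference token inventories in the legacy (2020-era) SELFIES spellings
# ([Branch1_1], [C@Hexpl], [Expl=Ring1], ...). These are the token sets
# observed on the large public-compound corpora curated with the two rule
# presets; they are bundled so that vocabulary construction and bracket
# tokenization can be exercised against historically printed strings.
# Tokenization is purely lexical, so the grammar generation used here does
# not need to match these spellings.

#' Legacy corpus token inventories
#'
#' The unique chemical-token inventories of the two historical curation
#' presets, in legacy grammar spellings: 27 tokens for the strict preset
#' (no charges, no stereo) and 61 for the permissive one (charges and
#' stereo retained).
#'
#' @param preset `"dataset1"` or `"dataset2"`.
#' @return Character vector of bracket tokens.
#' @examples
#' length(legacy_token_inventory("dataset1"))   # 27
#' length(legacy_token_inventory("dataset2"))   # 61
#' @export
legacy_token_inventory <- function(preset = c("dataset1", "dataset2")) {
  preset <- match.arg(preset)
  if (preset == "dataset1") {
    c("[C]", "[=C]", "[Branch1_1]", "[N]", "[Ring1]", "[O]", "[Branch1_2]",
      "[Expl=Ring1]", "[=N]", "[Branch2_1]", "[Branch1_3]", "[Ring2]",
      "[S]", "[F]", "[=O]", "[Branch2_2]", "[Cl]", "[Branch2_3]", "[#C]",
      "[Br]", "[P]", "[=S]", "[I]", "[=P]", "[Expl=Ring2]", "[B]", "[#N]")
  } else {
    c("[C]", "[=C]", "[Branch1_1]", "[Branch1_2]", "[Ring1]", "[N]", "[O]",
      "[=O]", "[=N]", "[Ring2]", "[Branch2_1]", "[S]", "[Branch1_3]",
      "[F]", "[Branch2_2]", "[Cl]", "[Branch2_3]", "[Br]", "[#C]", "[/C]",
      "[#N]", "[P]", "[C@Hexpl]", "[C@@Hexpl]", "[=N+expl]", "[=S]",
      "[=N-expl]", "[I]", "[O-expl]", "[N+expl]", "[\\C]", "[/N]", "[/O]",
      "[C@expl]", "[B]", "[C@@expl]", "[\\N]", "[Expl/Ring1]", "[\\O]",
      "[NH+expl]", "[I-expl]", "[Expl\\Ring1]", "[P+expl]", "[NH2+expl]",
      "[/Cl]", "[/S]", "[NH3+expl]", "[Cl-expl]", "[/F]", "[#N+expl]",
      "[C-expl]", "[\\S]", "[N-expl]", "[=NH+expl]", "[=I]", "[S-expl]",
      "[\\Cl]", "[S+expl]", "[#C-expl]", "[B-expl]", "[/Br]")
  }
}

#' Legacy rare-token removal list
#'
#' The printed removal list for the permissive corpus (11 entries, one a
#' duplicate, hence 10 distinct tokens); treated as a set wherever it is
#' applied.
#'
#' @return Character vector of bracket tokens (with the duplicate kept, as
#'   printed).
#' @export
legacy_rare_tokens <- function() {
  c("[=B]", "[=Cl]", "[=Br]", "[#I]", "[=I]", "[#S]", "[Expl#Ring1]",
    "[#B]", "[#P]", "[=Br]", "[Expl#Ring2]")
}

#' Legacy worked tokenization examples
#'
#' Two molecules, each in a constitution-only and a stereo-annotated
#' variant, written as legacy-grammar SELFIES strings. Used to exercise
#' bracket tokenization and unique-token counting on historically printed
#' material.
#'
#' @return A tibble: `molecule`, `variant`, `smiles`, `selfies`.
#' @export
legacy_selfies_examples <- function() {
  tibble::tribble(
    ~molecule, ~variant, ~smiles, ~selfies,
    "01", "plain",
    "C1=CC2=C(C=C1C=O)C(C(O2)Br)Br",
    paste0("[C][=C][C][=C][Branch1_1][Branch1_3][C][=C][Ring1]",
           "[Branch1_2][C][=O][C][Branch1_1][Branch2_1][C][Branch1_1]",
           "[Ring2][O][Ring1][Branch2_2][Br][Br]"),
    "01", "stereo",
    "C1=CC2=C(C=C1C=O)[C@@H]([C@H](O2)Br)Br",
    paste0("[C][=C][C][=C][Branch1_1][Branch1_3][C][=C][Ring1]",
           "[Branch1_2][C][=O][C@@Hexpl][Branch1_1][Branch2_1][C@Hexpl]",
           "[Branch1_1][Ring2][O][Ring1][Branch2_2][Br][Br]"),
    "02", "plain",
    "CC1C(=C(N(N1)C)OC2CCC=CC2)C=NO",
    paste0("[C][C][C][Branch2_2][Ring1][Ring2][=C][Branch1_1][Branch2_1]",
           "[N][Branch1_1][Ring2][N][Ring1][Branch1_1][C][O][C][C][C]",
           "[C][=C][C][Ring1][Branch1_2][C][=N][O]"),
    "02", "stereo",
    "CC1C(=C(N(N1)C)OC2CCC=CC2)/C=N/O",
    paste0("[C][C][C][Branch2_2][Ring1][Ring2][=C][Branch1_1][Branch2_1]",
           "[N][Branch1_1][Ring2][N][Ring1][Branch1_1][C][O][C][C][C]",
           "[C][=C][C][Ring1][Branch1_2][/C][=N][/O]")
  )
}
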