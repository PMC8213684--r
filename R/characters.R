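#' Canonical character dictionary for the Tetrix bipunctata complex
#'
#' The morphometric scheme measures 20 linear distances (in mm) spread over
#' the whole body of adult females.  Three characters are flagged as not
#' retained for multivariate analysis -- pronotum height (`prn.h`, strong
#' individual variation) and the lengths of the 2nd and 3rd pulvillus
#' (`pu2.l`, `pu3.l`, affected by wear) -- which leaves 17 characters for
#' the ratio analyses.
#'
#' @return A data frame with one row per character and columns `code`,
#'   `name`, `definition` and `retained` (logical).
#' @seealso [retained_characters()]
#' @examples
#' cs <- character_set()
#' sum(cs$retained)   # 17
#' @export
character_set <- function() {
  out <- data.frame(
    code = c("bt3.l", "eye.b", "eye.h", "fl5.b", "fl5.l", "fm2.b", "fm2.l",
             "fm3.b", "fm3.l", "fro.h", "hea.b", "hwi.l", "prn.b", "prn.h",
             "prn.l", "pu2.l", "pu3.l", "teg.b", "teg.l", "vrt.b"),
    name = c(
      "Basitarsus length", "Eye breadth", "Eye height",
      "5th flagellomere breadth", "5th flagellomere length",
      "Mid-femur breadth", "Mid-femur length", "Hind femur breadth",
      "Hind femur length", "Frons height", "Head breadth",
      "Hind wing length", "Pronotum breadth", "Pronotum height",
      "Pronotum length", "2nd pulvillus length", "3rd pulvillus length",
      "Tegmen breadth", "Tegmen length", "Vertex breadth"),
    definition = c(
      "hind basitarsus, proximal expansion to apex, outer aspect",
      "greatest eye breadth, lateral view",
      "greatest eye height, lateral view",
      "greatest breadth of 5th flagellomere, dorsal aspect",
      "greatest length of 5th flagellomere, dorsal aspect",
      "greatest mid-femur breadth, lateral view",
      "mid-femur, trochanter emargination to knee emargination",
      "greatest hind femur breadth, lateral view",
      "hind femur, proximal edge to knee disc tip",
      "frons, clypeus margin to eye orbit margin, frontal view",
      "greatest head breadth, dorsal view",
      "hind wing, proximal tegmen edge to wing tip, in situ",
      "greatest pronotum breadth, dorsal view",
      "pronotum, humeral to medial carina, lateral view",
      "pronotum, anterior margin to posterior process tip",
      "2nd pulvillus of hind basitarsus, notch to notch",
      "3rd pulvillus of hind basitarsus, notch to notch",
      "greatest breadth of sclerotised tegmen, outer aspect",
      "fore wing, proximal tegmen edge to fore wing tip",
      "shortest vertex breadth, dorsal view"),
    stringsAsFactors = FALSE
  )
  out$retained <- !(out$code %in% c("prn.h", "pu2.l", "pu3.l"))
  out
}

#' Codes of the characters retained for multivariate analysis
#'
#' @return Character vector of the 17 retained character codes.
#' @export
retained_characters <- function() {
  cs <- character_set()
  cs$code[cs$retained]
}

#' Morph label vocabulary
#'
#' `intermediate` marks specimens historically labelled as in-between forms;
#' no procedure in this package assigns it, it is carried as input metadata.
#'
#' @return Character vector of admissible morph labels.
#' @export
morph_levels <- function() {
  c("bipunctata", "kraussi", "intermediate", "unassigned")
}

# Case-insensitive canonicalisation of character codes (dots preserved).
canonical_codes <- function(codes) {
  canon <- character_set()$code
  idx <- match(tolower(codes), tolower(canon))
  out <- canon[idx]
  names(out) <- codes
  out
}
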