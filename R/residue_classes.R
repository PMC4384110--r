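#' Standard amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes used throughout the package.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Built-in residue classes
#'
#' The residue classes over which all count-constraint rules are expressed.
#' `HYDROPHOBIC` is the broad hydrophobic class (including Ala, Cys and the
#' partially hydrophobic Tyr); `STRONG_HYDROPHOBIC` restricts to the six
#' residues with strong hydrophobic side chains; `HYDROPHILIC` is the
#' surface-preferring class; `DISRUPTOR5` groups the five residues most
#' disruptive to strand geometry.
#'
#' @return Named list of character vectors (sets of one-letter codes).
#' @export
#'
#' @examples
#' residue_classes()$AROMATIC
residue_classes <- function() {
  list(
    HYDROPHOBIC        = c("W", "I", "F", "L", "C", "V", "M", "A", "Y"),
    STRONG_HYDROPHOBIC = c("W", "I", "F", "L", "V", "M"),
    AROMATIC           = c("F", "W", "Y"),
    CHARGED            = c("D", "E", "R", "K", "H"),
    HYDROPHILIC        = c("Q", "E", "R", "T", "S", "Y", "D", "H", "K", "N"),
    ALA                = "A",
    CYS                = "C",
    TYR                = "Y",
    PRO                = "P",
    GLY                = "G",
    PRO_GLY            = c("P", "G"),
    PRO_GLY_ALA        = c("P", "G", "A"),
    DISRUPTOR5         = c("P", "G", "N", "D", "E")
  )
}

#' Split a sequence string into residue characters
#'
#' Uppercases the input and optionally validates it against the standard
#' alphabet. Non-standard letters (X, B, Z, U, *, ...) are members of no
#' residue class; by default they trigger a warning, with `strict = TRUE`
#' they are an error.
#'
#' @param sequence Character scalar of one-letter codes.
#' @param strict Error (rather than warn) on non-standard letters.
#' @param warn Emit a warning on non-standard letters (default `TRUE`).
#' @return Character vector of single residues.
#' @export
split_residues <- function(sequence, strict = FALSE, warn = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(toupper(gsub("[[:space:]]", "", sequence)), "")[[1]]
  bad <- setdiff(unique(res), amino_acids())
  if (length(bad)) {
    msg <- sprintf("non-standard residue letter(s): %s",
                   paste(bad, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    if (warn) warning(msg, call. = FALSE)
  }
  res
}

# membership indicator of each residue of `res` in class `members`
class_indicator <- function(res, members) {
  res %in% members
}
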