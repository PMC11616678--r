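# Alphabet constants shared across the package.
#
# Amino acids are upper-case, 3Di structure states lower-case; the casing is
# what disambiguates the two 20-letter alphabets in one vocabulary.

#' The 20 standard amino-acid letters (upper case)
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The 20 3Di structural-alphabet letters (lower case)
#'
#' Same letter set as the amino acids, cast to lower case so that amino-acid
#' and structure tokens never collide inside the bilingual vocabulary.
#' @export
TDI_LETTERS <- c("a", "c", "d", "e", "f", "g", "h", "i", "k", "l",
                 "m", "n", "p", "q", "r", "s", "t", "v", "w", "y")

# Ambiguous / rare amino-acid codes folded into X on read.
AA_AMBIGUOUS <- c("B", "Z", "U", "O")

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Validate a sequence against one of the two alphabets
#'
#' @param seq single string.
#' @param alphabet `"AA"` (upper-case amino acids, X allowed) or `"3Di"`
#'   (lower-case structure states, x allowed as masked placeholder).
#' @param id record id used in error messages.
#' @return `seq`, invisibly, if valid; otherwise an error naming the first
#'   offending position.
#' @keywords internal
validate_seq <- function(seq, alphabet = c("AA", "3Di"), id = "?") {
  alphabet <- match.arg(alphabet)
  chars <- split_chars(seq)
  allowed <- if (alphabet == "AA") c(AA_LETTERS, "X") else c(TDI_LETTERS, "x")
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0) {
    stop(sprintf(
      "record '%s': character '%s' at position %d is not a valid %s letter",
      id, chars[bad[1]], bad[1], alphabet), call. = FALSE)
  }
  invisible(seq)
}

# Infer which alphabet a sequence belongs to from its casing; mixed case errors.
infer_alphabet <- function(seq) {
  if (identical(seq, "")) return("AA")
  has_upper <- grepl("[A-Z]", seq)
  has_lower <- grepl("[a-z]", seq)
  if (has_upper && has_lower) {
    stop("mixed-case sequence: cannot infer alphabet", call. = FALSE)
  }
  if (has_lower) "3Di" else "AA"
}
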