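# Shared alphabet handling. Both the amino-acid and the 3Di alphabet use the
# same 20 uppercase letters (Foldseek convention), with 'X' as the unknown
# residue that scores 0 against everything.

RESIDUE_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
X_CODE <- 20L # 0-based code for 'X' passed to the C++ kernels

# lookup table: utf8 code point -> 0-based residue code (X and unknown -> 20)
.code_lut <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A"):utf8ToInt("Z") + 1L] <- X_CODE
  lut[vapply(RESIDUE_LETTERS, utf8ToInt, 1L) + 1L] <-
    seq_along(RESIDUE_LETTERS) - 1L
  lut
})

#' Encode a residue string as 0-based integer codes
#'
#' Letters outside the 20-letter alphabet (including 'X') map to the unknown
#' code, which scores zero in all alignments.
#' @param s character scalar (already uppercased, no gaps)
#' @return integer vector of codes in 0..20
#' @keywords internal
#' @noRd
encode_residues <- function(s) {
  cp <- utf8ToInt(s)
  if (any(cp > 127L | cp < 1L)) {
    stop("non-ASCII character in sequence", call. = FALSE)
  }
  code <- .code_lut[cp + 1L]
  code[is.na(code)] <- X_CODE
  code
}

# validate a sequence string: non-empty, uppercase letters only, no gaps
check_seq <- function(s, what, id) {
  if (is.na(s) || nchar(s) < 1L) {
    stop(sprintf("empty %s sequence for '%s'", what, id), call. = FALSE)
  }
  if (grepl("[-.]", s)) {
    stop(sprintf("gap character in %s sequence for '%s'", what, id),
         call. = FALSE)
  }
  invisible(s)
}

# split an alignment row into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
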