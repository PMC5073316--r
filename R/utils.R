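# Shared low-level helpers: DNA string manipulation and report rounding.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. `N` is preserved; case is preserved base-by-base.
#'
#' @param x Character vector of DNA strings over `A,C,G,T,N`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("AAACCC")
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Round half away from zero
#'
#' Report-time rounding convention: 0.5 rounds up in magnitude
#' (`round_half_up(0.0135, 3)` is 0.014), unlike base [round()]'s
#' round-half-to-even. Used wherever table-precision values are printed.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Split a DNA string into a character vector of single bases.
str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Validate a DNA string over an allowed alphabet; errors name the first
# offending offset so malformed input is locatable.
check_dna <- function(seq, allow_n = TRUE, arg = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  alphabet <- c(DNA_BASES, if (allow_n) "N")
  ch <- str_chars(toupper(seq))
  bad <- which(!ch %in% alphabet)
  if (length(bad) > 0) {
    abort(sprintf("`%s` contains a non-IUPAC character '%s' at offset %d",
                  arg, ch[bad[1]], bad[1]))
  }
  invisible(toupper(seq))
}

# Circular substring of a linearised circle `seq`, 1-based inclusive, with
# end < start meaning a wrap through the origin.
circular_substr <- function(seq, start, end) {
  n <- nchar(seq)
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, n), substr(seq, 1, end))
  }
}
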