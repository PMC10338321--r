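# Alphabet: the 20 standard amino acids plus the gap character, in a fixed
# order used for all integer encodings in the package. The gap is a
# first-class character (index 21).

#' Amino acid alphabet used throughout the package
#'
#' The 20 standard amino acids followed by the gap character \code{"-"}.
#' All scoring operates on this 21-letter alphabet; the gap is an ordinary
#' character, not missing data.
#'
#' @return Character vector of length 21.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "-")
}

GAP_CHAR <- "-"

# Encode a character vector over the alphabet as integers 1..21.
# Unknown characters yield NA (callers validate earlier).
aa_encode <- function(x) {
  match(x, aa_alphabet())
}

#' Substitution threshold rule for ET sequence distances
#'
#' Builds the binary match rule f(x, y) used by the Evolutionary Trace
#' sequence distance: two aligned characters "match" when their BLOSUM62
#' log-odds score is at least \code{threshold}. The log-odds between the gap
#' character and anything (including itself) is fixed at 0, so a gap never
#' matches at the default threshold of 2.
#'
#' @param threshold Integer log-odds cutoff; the ET convention is 2.
#' @return An object of class \code{"subst_rule"}: a list with the 21x21
#'   log-odds matrix (\code{$logodds}), the threshold, and the 21x21 logical
#'   match matrix (\code{$match}).
#' @export
substitution_rule <- function(threshold = 2) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  blosum <- get_blosum62()
  ab <- aa_alphabet()
  lo <- matrix(0, 21, 21, dimnames = list(ab, ab))
  lo[1:20, 1:20] <- blosum[ab[1:20], ab[1:20]]
  structure(
    list(logodds = lo, threshold = threshold, match = lo >= threshold),
    class = "subst_rule"
  )
}

# BLOSUM62 over the 20 standard amino acids, from Biostrings' shipped table.
get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <- env$BLOSUM62
      aas <- aa_alphabet()[1:20]
      cache <<- m[aas, aas]
    }
    cache
  }
})
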