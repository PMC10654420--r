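#' Canonical amino-acid alphabet
#'
#' All matrices and token arrays in this package are indexed by the 20
#' standard amino acids in alphabetical one-letter order, with `"X"` as the
#' distinguished unknown token (integer code 21).
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_ALPHABET
#' @export
AA_UNKNOWN <- "X"

# integer code of the unknown token
TOK_UNKNOWN <- 21L

# three-letter -> one-letter map, plus common non-standard parents
AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y",
  # non-standard residues mapped to their 20-letter parent
  MSE = "M", SEC = "C", PYL = "K", SEP = "S", TPO = "T", PTR = "Y",
  HYP = "P", MLY = "K", CSO = "C", KCX = "K", CME = "C", FME = "M"
)

#' Convert between sequence strings and integer tokens
#'
#' Tokens are integers in `1:21`: positions `1:20` index [AA_ALPHABET],
#' `21` is the unknown token `"X"`.
#'
#' @param x A single character string over `AA_ALPHABET` plus `"X"`
#'   (lowercase accepted), or a character vector of single letters.
#' @return `tokenize()` returns an integer vector; `untokenize()` the
#'   corresponding character string.
#' @examples
#' tokenize("ACDX")
#' untokenize(c(1L, 2L, 21L))
#' @export
tokenize <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) x <- strsplit(x, "")[[1L]]
  x <- toupper(x)
  idx <- match(x, c(AA_ALPHABET, AA_UNKNOWN))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("sequence contains characters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "))
  }
  idx
}

#' @rdname tokenize
#' @param tokens Integer vector in `1:21`.
#' @export
untokenize <- function(tokens) {
  stopifnot(all(tokens >= 1L & tokens <= 21L))
  paste(c(AA_ALPHABET, AA_UNKNOWN)[tokens], collapse = "")
}

#' Construct a partial sequence
#'
#' A partial sequence is a length-N token array over the 20 amino acids
#' plus the unknown token, together with a visibility mask. A position is
#' unknown if and only if it is not visible.
#'
#' @param tokens Integer tokens (`1:21`) or a character string with `"X"`
#'   at unknown positions.
#' @return An object of class `"partial_sequence"`: a list with elements
#'   `tokens` (integer) and `visible` (logical).
#' @export
partial_sequence <- function(tokens) {
  if (is.character(tokens)) tokens <- tokenize(tokens)
  tokens <- as.integer(tokens)
  ps <- structure(list(tokens = tokens, visible = tokens != TOK_UNKNOWN),
                  class = "partial_sequence")
  validate_partial_sequence(ps)
}

validate_partial_sequence <- function(ps) {
  stopifnot(inherits(ps, "partial_sequence"),
            length(ps$tokens) == length(ps$visible),
            all(ps$tokens >= 1L & ps$tokens <= 21L))
  if (!all((ps$tokens == TOK_UNKNOWN) == !ps$visible))
    stop("partial_sequence: tokens must be unknown exactly where not visible")
  ps
}

#' @export
print.partial_sequence <- function(x, ...) {
  cat(sprintf("<partial_sequence> %d positions, %d visible (%.1f%%)\n",
              length(x$tokens), sum(x$visible),
              100 * mean(x$visible)))
  cat(untokenize(x$tokens), "\n")
  invisible(x)
}
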