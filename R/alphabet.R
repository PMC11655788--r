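#' Finite alphabets with a blank symbol
#'
#' An alphabet is an ordered set of distinct symbol tokens together with a
#' distinguished blank symbol. The blank represents tape padding: every finite
#' word stands for the bi-infinite sequence obtained by padding it with blanks
#' on both ends, so the blank must belong to the alphabet.
#'
#' @param symbols character vector of distinct symbol tokens (length >= 2).
#' @param blank the blank symbol; must be an element of `symbols`.
#' @return An object of class `vs_alphabet` with fields `symbols`, `blank`,
#'   and `m` (the alphabet size).
#' @examples
#' alphabet(c("_", "NP", "V"), blank = "_")
#' @export
alphabet <- function(symbols, blank = symbols[[1]]) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) stop("alphabet: symbols must be distinct")
  if (length(symbols) < 2) stop("alphabet: need at least 2 symbols")
  if (!blank %in% symbols) stop("alphabet: blank must be one of the symbols")
  structure(list(symbols = symbols, blank = blank, m = length(symbols)),
            class = "vs_alphabet")
}

#' @export
print.vs_alphabet <- function(x, ...) {
  cat("<alphabet m=", x$m, "> {", paste(x$symbols, collapse = ", "),
      "} blank=", x$blank, "\n", sep = "")
  invisible(x)
}

#' Gödel encodings (alphabet orderings)
#'
#' An encoding assigns to each symbol a distinct code in `{0, ..., m-1}`; it
#' is the arbitrary choice whose effect on observables the package is designed
#' to analyse. In blank-anchored mode the blank symbol is forced to code 0, so
#' that implicit tape padding contributes nothing to a Gödel number and word
#' length need not be known to the decoder.
#'
#' @param codes named integer vector: `names(codes)` are the symbols, values
#'   their codes `0..m-1`, each used exactly once. Alternatively a character
#'   vector of symbols, in which case codes `0..m-1` are assigned in order.
#' @param blank the blank symbol (defaults to the symbol with code 0).
#' @param anchored logical; if `TRUE` (default) the blank must have code 0.
#' @return An object of class `godel_encoding`.
#' @examples
#' godel_encoding(c("_" = 0, NP = 1, V = 2), blank = "_")
#' godel_encoding(c("_", "NP", "V", "VP", "S"))  # codes in listed order
#' @export
godel_encoding <- function(codes, blank = NULL, anchored = TRUE) {
  if (is.character(codes) && is.null(names(codes))) {
    codes <- stats::setNames(seq_along(codes) - 1L, codes)
  }
  if (is.null(names(codes)) || anyDuplicated(names(codes)))
    stop("godel_encoding: codes must be named by distinct symbols")
  codes <- vapply(codes, as.integer, integer(1))
  m <- length(codes)
  if (!setequal(codes, 0:(m - 1)))
    stop("godel_encoding: codes must be a bijection onto 0..m-1")
  if (is.null(blank)) blank <- names(codes)[match(0L, codes)]
  if (!blank %in% names(codes)) stop("godel_encoding: unknown blank symbol")
  if (anchored && codes[[blank]] != 0L)
    stop("godel_encoding: blank-anchored encodings require code(blank) = 0")
  structure(list(codes = codes, m = m, blank = blank, anchored = anchored),
            class = "godel_encoding")
}

#' @export
print.godel_encoding <- function(x, ...) {
  cat("<godel_encoding m=", x$m, if (x$anchored) " anchored" else "", "> ",
      paste(names(x$codes), x$codes, sep = "↦", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname godel_encoding
#' @param x a `godel_encoding`.
#' @param w character vector of symbols.
#' @return `encoding_codes()`: the integer code sequence of `w`.
#' @export
encoding_codes <- function(x, w) {
  if (length(w) == 0) return(integer(0))
  idx <- match(w, names(x$codes))
  if (anyNA(idx)) stop("symbol(s) not in alphabet: ",
                       paste(unique(w[is.na(idx)]), collapse = ", "))
  unname(x$codes[idx])
}

#' @rdname godel_encoding
#' @param codes integer code sequence.
#' @return `encoding_symbols()`: the symbols with those codes.
#' @export
encoding_symbols <- function(x, codes) {
  if (length(codes) == 0) return(character(0))
  if (any(codes < 0 | codes >= x$m)) stop("code out of range")
  syms <- names(sort(x$codes))
  syms[codes + 1L]
}

#' The alphabet underlying an encoding
#' @param e a `godel_encoding`.
#' @return The `vs_alphabet` with symbols in code order.
#' @export
encoding_alphabet <- function(e) {
  alphabet(names(sort(e$codes)), blank = e$blank)
}

#' Dotted words (two-sided tapes)
#'
#' A dotted word is a finite two-sided tape split by the dot into a stack side
#' (left of the dot) and an input side (right of the dot). Both sides are
#' stored dot-outward: index 1 is the symbol adjacent to the dot. The tape is
#' implicitly padded with blanks on both ends, so blanks at the outer ends are
#' trimmed to give a canonical representative.
#'
#' @param left,right character vectors over the respective alphabets,
#'   dot-outward order.
#' @param left_blank,right_blank the blank symbols used for trimming.
#' @return An object of class `dotted_word`.
#' @examples
#' dotted_word(left = "S", right = c("NP", "V", "NP"))
#' @export
dotted_word <- function(left = character(0), right = character(0),
                        left_blank = "_", right_blank = "_") {
  structure(list(left = .trim_outer(as.character(left), left_blank),
                 right = .trim_outer(as.character(right), right_blank),
                 left_blank = left_blank, right_blank = right_blank),
            class = "dotted_word")
}

# drop padding blanks at the end far from the dot (dot-outward storage:
# the far end is the tail of the vector)
.trim_outer <- function(w, blank) {
  n <- length(w)
  while (n > 0 && w[n] == blank) n <- n - 1L
  w[seq_len(n)]
}

#' @export
format.dotted_word <- function(x, ...) {
  paste0(paste(rev(x$left), collapse = " "), ".",
         paste(x$right, collapse = " "))
}

#' @export
print.dotted_word <- function(x, ...) {
  cat("<dotted_word> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @rdname dotted_word
#' @param s a `dotted_word`.
#' @return `is_empty_tape()`: `TRUE` iff both sides are empty (the accepting
#'   configuration of a recognizer).
#' @export
is_empty_tape <- function(s) length(s$left) == 0 && length(s$right) == 0

#' Parse a dotted word from text
#'
#' Text form: symbols separated by whitespace with a single `.` separating the
#' two sides, e.g. `"S . NP V NP"` or `"S.NP V NP"` for one-token sides. The
#' left side is given in tape order (outermost first) and is stored reversed
#' (dot-outward).
#'
#' @param text the string to parse.
#' @param left_blank,right_blank blank symbols for the two sides.
#' @return A `dotted_word`.
#' @export
parse_dotted_word <- function(text, left_blank = "_", right_blank = "_") {
  text <- gsub("\\.", " . ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  dot <- which(toks == ".")
  if (length(dot) != 1) stop("expected exactly one dot")
  left_tape <- if (dot > 1) toks[seq_len(dot - 1)] else character(0)
  right <- if (dot < length(toks)) toks[(dot + 1):length(toks)] else character(0)
  dotted_word(left = rev(left_tape), right = right,
              left_blank = left_blank, right_blank = right_blank)
}
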