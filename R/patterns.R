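#' Pattern of equality of a word
#'
#' The pattern of equality of `w` is the set partition of its positions
#' `{1, ..., l}` in which two positions belong to the same block exactly when
#' `w` carries the same symbol there. It is the complete invariant for orbits
#' of words under alphabet bijections: a recoding can map `w` to `u` iff `u`
#' has the same length and the same pattern. In blank-anchored mode the block
#' of positions holding the distinguished `zero` symbol is marked, because
#' anchored recodings fix the blank and hence those positions.
#'
#' @param w nonempty word (character or integer vector).
#' @param zero optional distinguished symbol (the blank, or the digit 0);
#'   when supplied the pattern is anchored and the zero block is marked.
#' @return An object of class `equality_pattern` with fields `blocks` (list of
#'   integer position vectors, sorted by least element), `zero_block` (index
#'   of the marked block or `NA`), and `key` (canonical string; equal keys
#'   iff same orbit class).
#' @examples
#' pattern_of_equality(strsplit("aaabcabc", "")[[1]])
#' @export
pattern_of_equality <- function(w, zero = NULL) {
  l <- length(w)
  if (l == 0) stop("pattern_of_equality: word must be nonempty")
  rgs <- match(w, unique(w))  # restricted growth labels, first appearance = 1
  blocks <- split(seq_len(l), rgs)
  names(blocks) <- NULL
  zb <- NA_integer_
  if (!is.null(zero)) {
    hit <- which(w == zero)
    if (length(hit) > 0) zb <- rgs[hit[1]]
  }
  structure(list(blocks = blocks, zero_block = zb,
                 key = .pattern_key_rgs(rgs, if (is.null(zero)) NULL else zb)),
            class = "equality_pattern")
}

.pattern_key_rgs <- function(rgs, zero_block = NULL) {
  key <- paste(rgs, collapse = ",")
  if (!is.null(zero_block))
    key <- paste0(key, ";z", if (is.na(zero_block)) 0L else zero_block)
  key
}

#' @rdname pattern_of_equality
#' @return `pattern_key()`: just the canonical key string.
#' @export
pattern_key <- function(w, zero = NULL) pattern_of_equality(w, zero)$key

#' @export
print.equality_pattern <- function(x, ...) {
  bl <- vapply(x$blocks, function(b) paste0("{", paste(b, collapse = ","), "}"),
               character(1))
  cat("<equality_pattern> {", paste(bl, collapse = ", "), "}",
      if (!is.na(x$zero_block)) paste0("  zero block #", x$zero_block) else "",
      "\n", sep = "")
  invisible(x)
}

#' Are two words in the same recoding orbit?
#'
#' `TRUE` iff the words have equal length and equal patterns of equality; in
#' anchored mode the blank-position sets must additionally coincide (blanks
#' are fixed by anchored recodings).
#'
#' @param w,u words over alphabets of equal size.
#' @param anchored logical; fix the blank?
#' @param blank_w,blank_u the blank symbol of each word's alphabet.
#' @return Logical scalar.
#' @examples
#' same_orbit(strsplit("aaabcabc", "")[[1]], strsplit("bbbacbac", "")[[1]])
#' @export
same_orbit <- function(w, u, anchored = FALSE, blank_w = "_", blank_u = blank_w) {
  if (length(w) != length(u)) return(FALSE)
  if (anchored) {
    pattern_key(w, zero = blank_w) == pattern_key(u, zero = blank_u)
  } else {
    pattern_key(w) == pattern_key(u)
  }
}

# all k-permutations of 1..n as a matrix (rows), memoized
.arr_cache <- new.env(parent = emptyenv())
.arrangements <- function(n, k) {
  if (k == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  key <- paste(n, k)
  if (!is.null(.arr_cache[[key]])) return(.arr_cache[[key]])
  if (k == 1) {
    out <- matrix(seq_len(n), ncol = 1)
  } else {
    prev <- .arrangements(n, k - 1)
    rows <- list()
    for (i in seq_len(nrow(prev))) {
      rest <- setdiff(seq_len(n), prev[i, ])
      for (r in rest) rows[[length(rows) + 1L]] <- c(prev[i, ], r)
    }
    out <- do.call(rbind, rows)
  }
  .arr_cache[[key]] <- out
  out
}

#' Enumerate the recoding orbit of a word
#'
#' All words of the same length, over the given alphabet, sharing `w`'s
#' pattern of equality — equivalently the images of `w` under all alphabet
#' bijections (anchored: all bijections fixing the blank). The orbit size is
#' `m (m-1) ... (m-k+1)` where `k` is the number of distinct symbols in `w`
#' (anchored: the falling factorial of `m-1` over the distinct non-blank
#' symbols, blank positions held fixed).
#'
#' @param w nonempty word.
#' @param a a [alphabet()] containing `w`'s symbols.
#' @param anchored logical; fix the blank?
#' @return List of words (character vectors) in lexicographic order of their
#'   code sequences under the alphabet's natural order.
#' @examples
#' a <- alphabet(c("a", "b", "c"), blank = "a")
#' length(enumerate_orbit(strsplit("aaabcabc", "")[[1]], a))  # 6
#' @export
enumerate_orbit <- function(w, a, anchored = FALSE) {
  if (length(w) == 0) stop("enumerate_orbit: word must be nonempty")
  if (!all(w %in% a$symbols)) stop("word uses symbols outside the alphabet")
  if (anchored) {
    targets <- setdiff(a$symbols, a$blank)
    distinct <- setdiff(unique(w), a$blank)
  } else {
    targets <- a$symbols
    distinct <- unique(w)
  }
  k <- length(distinct)
  pos <- match(w, distinct)  # NA at blank positions in anchored mode
  arr <- .arrangements(length(targets), k)
  out <- vector("list", nrow(arr))
  for (i in seq_len(nrow(arr))) {
    img <- targets[arr[i, ]]
    word <- ifelse(is.na(pos), w, img[pos])
    out[[i]] <- word
  }
  # lexicographic order by code sequence (alphabet position)
  codes <- vapply(out, function(word)
    paste(sprintf("%02d", match(word, a$symbols) - 1L), collapse = ""),
    character(1))
  out[order(codes)]
}
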