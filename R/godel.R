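#' Gödel encoding of a word
#'
#' Maps a finite word `w = a_1 a_2 ... a_l` to the exact rational
#' `sum_k code(a_k) * m^(-k)` in `[0, 1)`. Trailing blanks (code 0 under a
#' blank-anchored encoding) do not change the value, which is what lets a
#' finite word stand for its blank-padded infinite extension; the empty word
#' maps to 0.
#'
#' @param w character vector of symbols (a word; possibly empty).
#' @param e a [godel_encoding()].
#' @return A `rational` in `[0, 1)`.
#' @examples
#' e <- godel_encoding(c("_", "NP", "V"))
#' godel_encode(c("NP", "V", "NP"), e)  # 16/27
#' @export
godel_encode <- function(w, e) {
  godel_encode_codes(encoding_codes(e, w), e$m)
}

#' @rdname godel_encode
#' @param codes integer code (digit) sequence, most significant first.
#' @param m base (alphabet size).
#' @export
godel_encode_codes <- function(codes, m) {
  l <- length(codes)
  if (l == 0) return(rational(0))
  if (l * log2(m) > 53)
    stop("word too long for exact encoding in base ", m)
  num <- 0
  for (c in codes) num <- num * m + c
  rational(num, m^l)
}

#' Gödel decoding at a fixed depth
#'
#' Inverse of [godel_encode()] on the depth-`l` grid: `x` must equal
#' `N / m^l` for an integer `N`, i.e. be a corner of the depth-`l` cylinder
#' partition; its base-m digits are the code sequence of the decoded word.
#'
#' @param x a `rational` in `[0, 1)`.
#' @param e a [godel_encoding()].
#' @param l word length to decode at.
#' @return The length-`l` word (character vector).
#' @examples
#' e <- godel_encoding(c("_", "NP", "V"))
#' godel_decode(rational(16, 27), e, 3)  # NP V NP
#' @export
godel_decode <- function(x, e, l) {
  encoding_symbols(e, godel_decode_codes(x, e$m, l))
}

#' @rdname godel_decode
#' @param m base (alphabet size).
#' @export
godel_decode_codes <- function(x, m, l) {
  x <- as_rational(x)
  if (length(x) != 1) stop("scalar rational expected")
  if (l == 0) {
    if (x$num != 0) stop("nonzero value cannot be decoded at length 0")
    return(integer(0))
  }
  if (l * log2(m) > 53) stop("depth too large for exact decoding in base ", m)
  scaled <- x$num * m^l
  .rat_guard(scaled, 1)
  if (scaled %% x$den != 0)
    stop("precision error: ", format(x), " is not a corner of the depth-", l,
         " partition in base ", m)
  n <- scaled / x$den
  if (n < 0 || n >= m^l) stop("value out of [0,1) at depth ", l)
  corner_digits(n, m, l)
}

#' Base-m digits of a partition corner
#'
#' The corner `index / m^l` of the depth-`l` partition has a unique base-m
#' expansion with `l` digits; those digits are the code word attached to the
#' corner.
#'
#' @param index integer in `0 .. m^l - 1` (vectorized).
#' @param m base.
#' @param l number of digits.
#' @return Integer vector of digits (most significant first), or a matrix with
#'   one row per index when `index` has length > 1.
#' @examples
#' corner_digits(6, 3, 2)    # 2 0
#' corner_digits(10, 3, 3)   # 1 0 1
#' @export
corner_digits <- function(index, m, l) {
  if (any(index < 0 | index >= m^l)) stop("corner index out of range")
  if (length(index) == 1L) {
    d <- integer(l)
    n <- index
    for (k in l:1) {
      d[k] <- n %% m
      n <- n %/% m
    }
    return(as.integer(d))
  }
  out <- matrix(0L, nrow = length(index), ncol = l)
  n <- index
  for (k in l:1) {
    out[, k] <- as.integer(n %% m)
    n <- n %/% m
  }
  out
}

#' Cylinder interval of a word
#'
#' All infinite extensions of the finite word `w` have Gödel numbers in the
#' half-open interval `[psi(w), psi(w) + m^(-|w|))`; the cylinder set of `w`
#' maps onto exactly this interval.
#'
#' @param w nonempty word (character vector).
#' @param e a [godel_encoding()].
#' @return A [rational_interval()].
#' @examples
#' e <- godel_encoding(c("_", "NP", "V"))
#' cylinder_interval(c("V", "_"), e)  # [6/9, 7/9)
#' @export
cylinder_interval <- function(w, e) {
  if (length(w) == 0) stop("cylinder_interval: word must be nonempty")
  lo <- godel_encode(w, e)
  rational_interval(lo, lo + rational(1, e$m^length(w)))
}

#' Ultrametric on the boundary of the code tree
#'
#' Distance between two (blank-padded) rays of the rooted m-ary tree: 0 if the
#' padded rays are equal, 1 if they differ already at the first symbol, and
#' `m^(-n)` if they share exactly an n-symbol prefix. Satisfies the strong
#' triangle inequality `d(p,q) <= max(d(p,r), d(r,q))`, and two rays are at
#' distance `<= m^(-n)` iff their Gödel numbers fall in the same depth-n
#' interval `[k/m^n, (k+1)/m^n)` for every encoding.
#'
#' @param p,q words (character vectors), interpreted as blank-padded rays.
#' @param m alphabet size.
#' @param blank blank symbol used for padding.
#' @return A `rational` distance in `{0} ∪ {m^(-n)} ∪ {1}`.
#' @export
tree_distance <- function(p, q, m, blank = "_") {
  l <- max(length(p), length(q))
  pp <- c(p, rep(blank, l - length(p)))
  qq <- c(q, rep(blank, l - length(q)))
  if (l == 0 || all(pp == qq)) return(rational(0))
  n <- which(pp != qq)[1] - 1L  # shared prefix length
  if (n == 0) rational(1) else rational(1, m^n)
}

#' Relabel a word along a code permutation
#'
#' A Gödel recoding `pi` (a permutation of the codes with `e_to = pi ∘
#' e_from`) induces a graph automorphism of the code tree. `recode_word`
#' realizes it on words: the returned word's code sequence under `e_to` is
#' `pi` applied to `w`'s code sequence under `e_from`. With `e_to = pi ∘
#' e_from` the symbols themselves are unchanged (only their codes move); with
#' `e_to = e_from` the symbols are relabeled.
#'
#' @param w word (character vector).
#' @param pi integer permutation of `0..m-1`, given as a vector with
#'   `pi[c + 1]` the image of code `c`.
#' @param e_from source encoding.
#' @param e_to target encoding; defaults to `e_from`.
#' @return The relabeled word.
#' @export
recode_word <- function(w, pi, e_from, e_to = e_from) {
  m <- e_from$m
  pi <- as.integer(pi)
  if (length(pi) != m || !setequal(pi, 0:(m - 1)))
    stop("pi must be a permutation of 0..m-1")
  if (e_from$anchored && e_to$anchored && pi[1] != 0L)
    stop("blank-anchored recoding must fix code 0")
  codes <- encoding_codes(e_from, w)
  encoding_symbols(e_to, pi[codes + 1L])
}
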