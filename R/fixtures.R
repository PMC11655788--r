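# Seeded fixture generators for property tests: random words, recodings and
# small versatile-shift machines. All draw from the current RNG stream, so a
# caller-side set.seed() makes them reproducible.

#' Random fixtures for property tests
#'
#' `random_word()` draws a word over an alphabet; `random_recoding()` a code
#' permutation (fixing 0 in anchored mode); `random_vs()` a small versatile
#' shift with domain of dependence `(1, 1)`, literal non-blank match pairs,
#' replacements of length at most 2 per side and no dot shift (so it compiles
#' to an NDA); `random_vs_state()` a starting configuration for it. The
#' bounded replacement lengths keep tape Gödel denominators within exact
#' double range over the step budgets used in the test suites.
#'
#' @param a a [alphabet()].
#' @param min_len,max_len word length range.
#' @param blank_ok may the word contain the blank symbol?
#' @return `random_word()`: a character vector.
#' @export
random_word <- function(a, min_len = 1L, max_len = 5L, blank_ok = FALSE) {
  pool <- if (blank_ok) a$symbols else setdiff(a$symbols, a$blank)
  n <- sample(min_len:max_len, 1)
  if (n == 0) return(character(0))
  sample(pool, n, replace = TRUE)
}

#' @rdname random_word
#' @param m alphabet size.
#' @param anchored must the permutation fix code 0?
#' @return `random_recoding()`: an integer permutation of `0..m-1`.
#' @export
random_recoding <- function(m, anchored = TRUE) {
  if (anchored) c(0L, sample(1:(m - 1))) else sample(0:(m - 1))
}

#' @rdname random_word
#' @param max_rules maximum number of rewrite rules.
#' @param m_left,m_right alphabet sizes (2 or 3).
#' @return `random_vs()`: a [versatile_shift()].
#' @export
random_vs <- function(max_rules = 4L, m_left = 3L, m_right = 3L) {
  stopifnot(m_left >= 2, m_left <= 3, m_right >= 2, m_right <= 3)
  la <- alphabet(c("_", c("p", "q")[seq_len(m_left - 1)]), blank = "_")
  ra <- alphabet(c("_", c("u", "v")[seq_len(m_right - 1)]), blank = "_")
  lp <- setdiff(la$symbols, "_")
  rp <- setdiff(ra$symbols, "_")
  pairs <- expand.grid(l = lp, r = rp, stringsAsFactors = FALSE)
  k <- sample(seq_len(min(max_rules, nrow(pairs))), 1)
  take <- sample(nrow(pairs), k)
  rules <- lapply(take, function(idx) {
    nl <- sample(0:2, 1)
    nr <- sample(0:2, 1)
    vs_rule(left = pairs$l[idx], right = pairs$r[idx],
            new_left = if (nl) sample(la$symbols, nl, replace = TRUE)
                       else character(0),
            new_right = if (nr) sample(ra$symbols, nr, replace = TRUE)
                        else character(0))
  })
  versatile_shift(la, ra, dod = c(1L, 1L), rules = rules)
}

#' @rdname random_word
#' @param vs a [versatile_shift()].
#' @return `random_vs_state()`: a [dotted_word()] over the machine's
#'   alphabets.
#' @export
random_vs_state <- function(vs, max_len = 3L) {
  vs_state(vs,
           left = random_word(vs$left_alphabet, 0L, max_len),
           right = random_word(vs$right_alphabet, 0L, max_len))
}

#' @rdname random_word
#' @param e a [godel_encoding()].
#' @param anchored must the paired encoding share the blank anchor?
#' @return `random_encoding_pair()`: a second encoding of the same alphabet,
#'   related to `e` by a random recoding.
#' @export
random_encoding_pair <- function(e, anchored = TRUE) {
  pi <- random_recoding(e$m, anchored)
  codes <- stats::setNames(pi[e$codes + 1L], names(e$codes))
  godel_encoding(codes, blank = e$blank, anchored = anchored)
}
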