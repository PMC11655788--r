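enc_digits <- function(m) godel_encoding(as.character(0:(m - 1)), blank = "0")

test_that("Gödel encoding reproduces the worked values", {
  e2 <- godel_encoding(c(a = 0, b = 1), blank = "a")
  # b followed by blank padding encodes to 1/2 regardless of padding length
  expect_true(godel_encode("b", e2) == rational(1, 2))
  expect_true(godel_encode(c("b", "a", "a", "a"), e2) == rational(1, 2))
  expect_true(godel_encode(character(0), e2) == rational(0))
  expect_true(godel_encode(c("a", "a", "a"), e2) == rational(0))
  e3 <- enc_digits(3)
  expect_true(godel_encode(c("2", "0"), e3) == rational(6, 9))
  expect_true(godel_encode(c("1", "0", "1"), e3) == rational(10, 27))
  g1 <- godel_encoding(c("_" = 0, NP = 1, V = 2), blank = "_")
  expect_true(godel_encode(c("NP", "V", "NP"), g1) == rational(16, 27))
  expect_error(godel_encode("X", g1), "not in alphabet")
})

test_that("Gödel decoding inverts encoding at partition corners", {
  e3 <- enc_digits(3)
  expect_equal(godel_decode(rational(6, 9), e3, 2), c("2", "0"))
  expect_equal(godel_decode(rational(0), e3, 4), rep("0", 4))
  g1 <- godel_encoding(c("_" = 0, NP = 1, V = 2), blank = "_")
  expect_equal(godel_decode(rational(16, 27), g1, 3), c("NP", "V", "NP"))
  # 1/2 is not a corner of any base-3 partition
  expect_error(godel_decode(rational(1, 2), e3, 3), "precision")
})

test_that("encode/decode round-trips exhaustively on small alphabets", {
  for (m in 2:4) {
    e <- enc_digits(m)
    for (l in 1:4) {
      for (w in all_words(as.character(0:(m - 1)), l)) {
        x <- godel_encode(w, e)
        expect_identical(godel_decode(x, e, l), w)
      }
    }
  }
  # random longer words up to the spec'd sizes
  set.seed(41)
  for (rep in 1:200) {
    m <- sample(2:5, 1)
    l <- sample(1:8, 1)
    e <- enc_digits(m)
    w <- as.character(sample(0:(m - 1), l, replace = TRUE))
    expect_identical(godel_decode(godel_encode(w, e), e, l), w)
  }
})

test_that("cylinder intervals have width m^-l and nest along prefixes", {
  e3 <- enc_digits(3)
  iv <- cylinder_interval("0", e3)
  expect_true(iv$lower == rational(0) && iv$upper == rational(1, 3))
  iv <- cylinder_interval(c("2", "0"), e3)
  expect_true(iv$lower == rational(6, 9) && iv$upper == rational(7, 9))
  e2 <- enc_digits(2)
  iv <- cylinder_interval(c("1", "0"), e2)
  expect_true(iv$lower == rational(1, 2) && iv$upper == rational(3, 4))
  # nesting: prefix w of u implies [u] subset of [w]
  set.seed(7)
  for (rep in 1:50) {
    m <- sample(2:4, 1)
    e <- enc_digits(m)
    u <- as.character(sample(0:(m - 1), sample(2:8, 1), replace = TRUE))
    w <- u[seq_len(sample(length(u) - 1, 1))]
    ivw <- cylinder_interval(w, e)
    ivu <- cylinder_interval(u, e)
    expect_true(rat_cmp(ivw$lower, ivu$lower) <= 0)
    expect_true(rat_cmp(ivu$upper, ivw$upper) <= 0)
  }
})

test_that("the boundary ultrametric measures shared prefixes", {
  expect_true(tree_distance(c("a", "b"), c("a", "b"), 3, blank = "z") ==
                rational(0))
  # blank padding: a word equals itself extended by blanks
  expect_true(tree_distance(c("a", "b"), c("a", "b", "_", "_"), 3) ==
                rational(0))
  expect_true(tree_distance(c("b", "x"), c("c", "x"), 3, blank = "z") ==
                rational(1))
  expect_true(tree_distance(c("0", "1", "2"), c("0", "1", "0"), 3,
                            blank = "z") == rational(1, 9))
})

test_that("ultrametric axioms hold (exhaustive small words, random larger)", {
  syms <- c("a", "b", "c")
  words <- do.call(c, lapply(1:3, function(l) all_words(syms, l)))
  n <- length(words)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- as.double(tree_distance(words[[i]], words[[j]], 3,
                                         blank = "a"))
    }
  }
  expect_true(all(d == t(d)))                     # symmetry
  expect_true(all(diag(d) == 0))                  # identity
  # strong triangle: d[i,j] <= max(d[i,k], d[k,j]) for all triples,
  # vectorized over k
  for (k in seq_len(n)) {
    expect_true(all(d <= outer(d[, k], d[k, ], pmax) + 1e-15))
  }
  # random triples of length-5 words
  set.seed(11)
  for (rep in 1:200) {
    p <- sample(syms, 5, replace = TRUE)
    q <- sample(syms, 5, replace = TRUE)
    r <- sample(syms, 5, replace = TRUE)
    dpq <- as.double(tree_distance(p, q, 3, blank = "a"))
    expect_lte(dpq, max(as.double(tree_distance(p, r, 3, blank = "a")),
                        as.double(tree_distance(r, q, 3, blank = "a"))))
  }
})

test_that("tree distance and interval co-membership agree (depth lemma)", {
  set.seed(5)
  for (rep in 1:60) {
    m <- sample(2:4, 1)
    syms <- letters[1:m]
    a <- alphabet(syms, blank = syms[1])
    p <- sample(syms, 10, replace = TRUE)
    q <- sample(syms, 10, replace = TRUE)
    d <- tree_distance(p, q, m, blank = syms[1])
    # any ordering of the alphabet, not just the canonical one
    e <- godel_encoding(stats::setNames(c(0L, sample(1:(m - 1))), syms),
                        blank = syms[1])
    xp <- godel_encode(p, e)
    xq <- godel_encode(q, e)
    for (depth in 0:10) {
      same_cell <- .cell_index(xp, m, depth) == .cell_index(xq, m, depth)
      expect_identical(rat_cmp(d, rational(1, m^depth)) <= 0, same_cell)
    }
  }
})

test_that("recode_word realizes the tree automorphism of a code permutation", {
  e3 <- enc_digits(3)
  w <- c("1", "2", "1")
  expect_identical(recode_word(w, 0:2, e3), w)
  expect_identical(recode_word(w, c(0L, 2L, 1L), e3), c("2", "1", "2"))
  # passing the recoded target encoding leaves the symbols fixed
  g1 <- godel_encoding(c("_" = 0, NP = 1, V = 2), blank = "_")
  d1 <- godel_encoding(c("_" = 0, V = 1, NP = 2), blank = "_")
  w <- c("NP", "V", "NP")
  expect_identical(recode_word(w, c(0L, 2L, 1L), g1, d1), w)
  expect_identical(encoding_codes(d1, w), c(2L, 1L, 2L))
  expect_error(recode_word(w, c(1L, 0L, 2L), g1, d1), "fix code 0")
  expect_error(recode_word(w, c(0L, 0L, 2L), g1), "permutation")
})
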