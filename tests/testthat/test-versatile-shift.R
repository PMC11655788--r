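recognizer <- build_topdown_recognizer(demo_grammar())

test_that("rule matching is first-match over the DoD windows", {
  s <- parse_dotted_word("S . NP V NP")
  m <- match_rule(recognizer, s)
  expect_equal(m$rule$label, "Predict (S -> NP VP)")
  # the empty tape matches nothing: wildcards bind non-blank symbols only
  expect_null(match_rule(recognizer, parse_dotted_word(".")))
  # mismatched stack top and input with no applicable rule
  expect_null(match_rule(recognizer, parse_dotted_word("NP . V NP")))
})

test_that("stepping rewrites the DoD and trims blank padding", {
  s1 <- vs_step(recognizer, parse_dotted_word("S . NP V NP"))
  expect_equal(format(s1), "VP NP.NP V NP")
  s2 <- vs_step(recognizer, s1)
  expect_equal(format(s2), "VP.V NP")
  # an identity rule is a fixed point
  la <- alphabet(c("_", "x"))
  id <- versatile_shift(la, la, c(1, 1),
                        list(vs_rule("x", "x", "x", "x", label = "id")))
  s <- dotted_word("x", "x")
  expect_equal(format(vs_step(id, s)), format(s))
})

test_that("the recognizer trace matches the printed parse of NP V NP", {
  tr <- run_vs(recognizer, parse_dotted_word("S . NP V NP"))
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 6)
  expect_equal(tr$halt_status, "accepted")
  expect_equal(df$state,
               c("S.NP V NP", "VP NP.NP V NP", "VP.V NP",
                 "NP V.V NP", "NP.NP", "."))
  expect_equal(df$operation,
               c("Predict (S -> NP VP)", "Attach", "Predict (VP -> V NP)",
                 "Attach", "Attach", "Accept"))
})

test_that("degenerate and rejecting runs are classified correctly", {
  tr <- run_vs(recognizer, parse_dotted_word("."))
  expect_equal(length(tr$states), 1)
  expect_equal(tr$halt_status, "accepted")
  tr <- run_vs(recognizer, parse_dotted_word("S . V NP NP"))
  expect_equal(tr$halt_status, "rejected")
  # an empty grammar accepts only the empty tape
  empty <- build_topdown_recognizer(
    cfg(list(), terminals = c("x"), start = "S", blank = "_"))
  expect_equal(run_vs(empty, parse_dotted_word("."))$halt_status, "accepted")
  expect_equal(run_vs(empty, dotted_word(right = "x"))$halt_status, "rejected")
})

test_that("acceptance agrees with brute-force CFG derivation", {
  lang <- cfg_language(demo_grammar(), max_len = 5)
  expect_equal(lang, "NP V NP")
  set.seed(77)
  cases <- c(list(c("NP", "V", "NP")),  # the sentence itself
             replicate(40, sample(c("NP", "V"), sample(1:5, 1), replace = TRUE),
                       simplify = FALSE))
  for (w in cases) {
    tr <- run_vs(recognizer, vs_state(recognizer, left = "S", right = w),
                 max_steps = 50)
    expect_identical(tr$halt_status == "accepted",
                     paste(w, collapse = " ") %in% lang)
  }
})

test_that("stepping is deterministic under first-match semantics", {
  la <- alphabet(c("_", "x", "y"))
  vs <- versatile_shift(la, la, c(1, 1), list(
    vs_rule("x", "?a", "y", "?a", label = "first"),
    vs_rule("x", "x", character(0), character(0), label = "shadowed")))
  s <- dotted_word("x", "x")
  expect_equal(match_rule(vs, s)$rule$label, "first")
  expect_equal(format(vs_step(vs, s)), "y.x")
})

test_that("generalized shifts require symbol-for-symbol substitution", {
  la <- alphabet(c("_", "0", "1"))
  flip <- compile_generalized_shift(la, la, c(0, 1), list(
    vs_rule(character(0), "0", character(0), "1", label = "flip0"),
    vs_rule(character(0), "1", character(0), "0", label = "flip1")))
  expect_equal(format(vs_step(flip, dotted_word(right = c("0", "1")))), ".1 1")
  expect_equal(format(vs_step(flip, dotted_word(right = c("1", "1")))), ".0 1")
  expect_error(
    compile_generalized_shift(la, la, c(0, 1), list(
      vs_rule(character(0), "0", character(0), c("1", "1")))),
    "symbol-for-symbol")
  # a pure left shift via literal rules: the dot moves one cell right
  shift <- compile_generalized_shift(la, la, c(0, 1), list(
    vs_rule(character(0), "0", character(0), "0", shift = 1, label = "s0"),
    vs_rule(character(0), "1", character(0), "1", shift = 1, label = "s1")))
  s <- dotted_word(right = c("1", "0", "1"))
  s1 <- vs_step(shift, s)
  expect_equal(format(s1), "1.0 1")
  expect_equal(format(vs_step(shift, s1)), "1 0.1")
})

test_that("machine and encoding configs round-trip through JSON", {
  path <- tempfile(fileext = ".json")
  write_machine(recognizer, path)
  back <- read_machine(path)
  expect_equal(back$dod, recognizer$dod)
  expect_equal(length(back$rules), length(recognizer$rules))
  tr <- run_vs(back, parse_dotted_word("S . NP V NP"))
  expect_equal(tr$halt_status, "accepted")
  expect_equal(length(tr$states), 6)
  epath <- tempfile(fileext = ".json")
  write_encoding(demo_encodings()$gamma$stack, epath)
  e <- read_encoding(epath)
  expect_equal(e$codes, demo_encodings()$gamma$stack$codes)
  expect_true(e$anchored)
})
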