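demo_setup <- function(which = "gamma") {
  d <- demo_bundle()
  e <- d$encodings[[which]]
  list(d = d, e = e, nda = build_nda(d$vs, e$stack, e$input))
}

test_that("machine configurations encode to the expected phase points", {
  s <- demo_setup()
  p <- encode_state(s$d$input, s$e$stack, s$e$input)
  expect_true(p$y1 == rational(4, 5))
  expect_true(p$y2 == rational(16, 27))
  p <- encode_state(parse_dotted_word("VP . V NP"), s$e$stack, s$e$input)
  expect_true(p$y1 == rational(3, 5))
  expect_true(p$y2 == rational(7, 9))
  p <- encode_state(parse_dotted_word("."), s$e$stack, s$e$input)
  expect_true(p$y1 == rational(0) && p$y2 == rational(0))
})

test_that("attach branches contract the stack axis by the alphabet size", {
  s <- demo_setup()
  br <- s$nda$branches[["1_1"]]  # stack top NP (code 1), input NP (code 1)
  expect_equal(br$label, "Attach")
  expect_true(br$lambda1 == rational(5))
  expect_true(br$a1 == rational(-5) * rational(1, 5))
  # identity rule compiles to the identity branch
  la <- alphabet(c("_", "x"))
  id <- versatile_shift(la, la, c(1, 1),
                        list(vs_rule("x", "x", "x", "x")))
  e <- godel_encoding(c("_", "x"))
  nda <- build_nda(id, e, e)
  br <- nda$branches[["1_1"]]
  expect_true(br$lambda1 == rational(1) && br$a1 == rational(0))
  expect_true(br$lambda2 == rational(1) && br$a2 == rational(0))
})

test_that("build_nda rejects non-anchored encodings and dot shifts", {
  s <- demo_setup()
  free <- godel_encoding(c(NP = 0, "_" = 1, V = 2), blank = "_",
                         anchored = FALSE)
  expect_error(build_nda(s$d$vs, s$e$stack, free), "blank-anchored")
  la <- alphabet(c("_", "x"))
  shifty <- versatile_shift(la, la, c(1, 1),
                            list(vs_rule("x", "x", "x", "x", shift = 1)))
  e <- godel_encoding(c("_", "x"))
  expect_error(build_nda(shifty, e, e), "shift")
})

test_that("the NDA is exactly conjugate to the symbolic dynamics (demo)", {
  d <- demo_bundle()
  for (en in c("gamma", "delta")) {
    e <- d$encodings[[en]]
    expect_null(check_conjugacy(d$vs, e$stack, e$input, d$input))
    # trajectory equals the pointwise encoding of the trace, halting together
    tr <- run_vs(d$vs, d$input)
    nda <- build_nda(d$vs, e$stack, e$input)
    traj <- run_nda(nda, encode_state(d$input, e$stack, e$input))
    expect_true(attr(traj, "halted"))
    expect_equal(length(traj), length(tr$states))
    for (t in seq_along(traj)) {
      q <- encode_state(tr$states[[t]], e$stack, e$input)
      expect_true(traj[[t]]$y1 == q$y1 && traj[[t]]$y2 == q$y2)
    }
  }
})

test_that("the NDA is exactly conjugate on random machines", {
  set.seed(101)
  for (rep in 1:10) {
    vs <- random_vs()
    el <- godel_encoding(vs$left_alphabet$symbols, blank = "_")
    er <- godel_encoding(vs$right_alphabet$symbols, blank = "_")
    s0 <- random_vs_state(vs)
    expect_null(check_conjugacy(vs, el, er, s0, steps = 20))
  }
})

test_that("phase points stay in the unit square along runs", {
  set.seed(55)
  for (rep in 1:10) {
    vs <- random_vs()
    el <- godel_encoding(vs$left_alphabet$symbols, blank = "_")
    er <- godel_encoding(vs$right_alphabet$symbols, blank = "_")
    nda <- build_nda(vs, el, er)
    traj <- run_nda(nda, encode_state(random_vs_state(vs), el, er),
                    steps = 20)
    for (p in traj) {
      expect_true(rat_cmp(p$y1, rational(0)) >= 0 &&
                    rat_cmp(p$y1, rational(1)) < 0)
      expect_true(rat_cmp(p$y2, rational(0)) >= 0 &&
                    rat_cmp(p$y2, rational(1)) < 0)
    }
  }
})

test_that("halting region: (0,0) halts and cells partition the square", {
  s <- demo_setup()
  expect_null(nda_step(s$nda, phase_point(rational(0), rational(0))))
  traj <- run_nda(s$nda, phase_point(rational(0), rational(0)))
  expect_equal(length(traj), 1)
  # every DoD cell is either a branch or a halt cell, exactly once
  keys <- c(names(s$nda$branches), names(s$nda$halts))
  expect_equal(sort(keys),
               sort(as.vector(outer(0:4, 0:2, paste, sep = "_"))))
  expect_equal(length(s$nda$branches), 6)
})

test_that("the serialized cell table is stable and exact", {
  s <- demo_setup()
  tab <- nda_cells(s$nda)
  expect_equal(nrow(tab), 6)
  at <- tab[tab$stack_window == "NP" & tab$input_window == "NP", ]
  expect_equal(at$lambda1, "5")
  expect_equal(at$a1, "-1")
  expect_equal(at$operation, "Attach")
})
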