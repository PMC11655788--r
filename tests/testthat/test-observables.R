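test_that("Amari mean, harmony and dissimilarity compute their forms", {
  expect_equal(amari_mean(rep(0, 10)), 0)
  expect_equal(amari_mean(rep(1, 7)), 1)
  expect_equal(amari_mean(c(0.5, 0.25, 0.25, 0)), 0.25)
  expect_error(amari_mean(numeric(0)), "empty")
  expect_equal(harmony(c(0, 0), diag(2)), 0)
  x <- c(0.2, 0.4, 0.1)
  expect_equal(harmony(x, diag(3)), sum(x^2))
  expect_equal(harmony(c(1, 1), rbind(c(0, 1), c(0, 0))), 1)
  expect_error(harmony(c(1, 1), diag(3)), "square")
  expect_equal(dissimilarity(c(1, 2), c(2, 4)), 0)
  expect_equal(dissimilarity(c(1, 0), c(0, 1)), 1)
  expect_equal(dissimilarity(c(1, 0), c(1, 1)), 1 - 1 / sqrt(2))
  expect_error(dissimilarity(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("step observables assign distinct coefficients per orbit class", {
  obs <- build_step_observable(5, 3, 2, 3, seed = 17)
  # class count equals the brute-force count of anchored pattern-key pairs
  sp <- square_partition_classes(5, 3, 2, 3, anchored = TRUE)
  expect_equal(obs$s, length(unique(sp$cells$key)))
  expect_equal(anyDuplicated(obs$coef), 0)
  # reproducibility, and independence from the global RNG stream
  set.seed(1)
  o2 <- build_step_observable(5, 3, 2, 3, seed = 17)
  expect_identical(obs$coef, o2$coef)
  # degenerate observable: one class, constant function
  o1 <- build_step_observable(2, 2, 1, 1, seed = 1)
  vals <- c(evaluate_step(o1, phase_point(rational(0), rational(0))),
            evaluate_step(o1, phase_point(rational(1, 2), rational(1, 2))))
  expect_equal(length(unique(vals)), if (o1$s == 1) 1 else 2)
})

test_that("evaluate_step is constant on cells and separates classes", {
  obs <- build_step_observable(5, 3, 2, 3, seed = 17)
  p1 <- phase_point(rational(6, 25), rational(10, 27))
  p2 <- phase_point(rational(31, 125), rational(31, 81))  # same cells
  expect_equal(evaluate_step(obs, p1), evaluate_step(obs, p2))
  # cells with different anchored keys get different values
  q <- phase_point(rational(0), rational(0))
  expect_false(evaluate_step(obs, p1) == evaluate_step(obs, q))
})

test_that("rho_pi rigidly permutes partition cells", {
  # identity recoding is the identity map
  p <- phase_point(rational(7, 20), rational(2, 5))
  r <- rho_pi(p, 0:2, 0:2, 1, 1)
  expect_true(r$y1 == p$y1 && r$y2 == p$y2)
  # single-digit relabel: 1/3 + eps -> 2/3 + eps
  p <- phase_point(rational(1, 3) + rational(1, 100),
                   rational(0))
  r <- rho_pi(p, c(0L, 2L, 1L), 0:2, 1, 1)
  expect_true(r$y1 == rational(2, 3) + rational(1, 100))
  expect_true(r$y2 == rational(0))
  # applying pi then its inverse returns the original point
  set.seed(13)
  for (rep in 1:50) {
    pi1 <- random_recoding(3)
    pi2 <- random_recoding(5)
    inv1 <- order(pi1) - 1L
    inv2 <- order(pi2) - 1L
    p <- phase_point(rational(sample(0:80, 1), 81),
                     rational(sample(0:624, 1), 625))
    r <- rho_pi(rho_pi(p, pi1, pi2, 2, 2), inv1, inv2, 2, 2)
    expect_true(r$y1 == p$y1 && r$y2 == p$y2)
  }
})

test_that("alpha is a group representation and fixes step observables", {
  obs <- build_step_observable(3, 3, 2, 2, seed = 3)
  f <- function(x) evaluate_step(obs, x)
  perms <- code_permutations(3, anchored = TRUE)
  set.seed(29)
  pts <- lapply(1:100, function(k)
    phase_point(rational(sample(0:80, 1), 81), rational(sample(0:80, 1), 81)))
  for (a in seq_len(nrow(perms))) {
    for (b in seq_len(nrow(perms))) {
      pa <- perms[a, ]
      pb <- perms[b, ]
      pab <- pa[pb + 1L]  # composition: apply pb, then pa
      lhs <- alpha_pi(f, pab, pab, 2, 2)
      rhs <- alpha_pi(alpha_pi(f, pa, pa, 2, 2), pb, pb, 2, 2)
      for (p in pts[1:10]) expect_equal(lhs(p), rhs(p))
    }
  }
  # invariance: alpha_pi(f) = f for every blank-fixing pair
  for (a in seq_len(nrow(perms))) {
    for (b in seq_len(nrow(perms))) {
      g <- alpha_pi(f, perms[a, ], perms[b, ], 2, 2)
      for (p in pts) expect_equal(g(p), f(p))
    }
  }
})

test_that("step observables are invariant across the demo encodings; Amari is not", {
  d <- demo_bundle()
  rep_step <- verify_invariance(d$vs, d$input, d$encodings, "step",
                                l = 2, r = 3, seed = 17)
  expect_true(rep_step$invariant)
  expect_equal(max(rep_step$max_diff), 0)
  rep_amari <- verify_invariance(d$vs, d$input, d$encodings, "amari")
  expect_false(rep_amari$invariant)
  expect_gt(max(rep_amari$max_diff), 1e-6)
  # any observable is invariant under a single (identity) recoding
  one <- verify_invariance(d$vs, d$input, d$encodings["gamma"], "amari")
  expect_true(one$invariant)
})

test_that("recoding the machine and transporting points agree on classes", {
  # running the recoded automaton visits, at every step, the rho_pi image
  # cell of the original trajectory
  d <- demo_bundle()
  g <- d$encodings$gamma
  dl <- d$encodings$delta
  # delta = pi o gamma
  pi1 <- integer(5)
  pi1[g$stack$codes + 1L] <- dl$stack$codes[names(g$stack$codes)]
  pi2 <- integer(3)
  pi2[g$input$codes + 1L] <- dl$input$codes[names(g$input$codes)]
  nda_g <- build_nda(d$vs, g$stack, g$input)
  nda_d <- build_nda(d$vs, dl$stack, dl$input)
  tg <- run_nda(nda_g, encode_state(d$input, g$stack, g$input))
  td <- run_nda(nda_d, encode_state(d$input, dl$stack, dl$input))
  expect_equal(length(tg), length(td))
  for (t in seq_along(tg)) {
    moved <- rho_pi(tg[[t]], pi1, pi2, d$l, d$r)
    expect_equal(.cell_index(moved$y1, 5, d$l), .cell_index(td[[t]]$y1, 5, d$l))
    expect_equal(.cell_index(moved$y2, 3, d$r), .cell_index(td[[t]]$y2, 3, d$r))
  }
})
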