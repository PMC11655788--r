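# run code under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Amari mean network activity
#'
#' The average activation across all units, a classic mean-field observation
#' model ("synthetic ERP"). It is *not* invariant under Gödel recodings: the
#' MCL coordinates, and with them the mean, depend on the arbitrary code
#' assignment.
#'
#' @param state activation vector (or one row of [run_na()] output).
#' @return Mean activation in `[0, 1]`.
#' @export
amari_mean <- function(state) {
  if (length(state) == 0) stop("empty state")
  mean(state)
}

#' Smolensky harmony
#'
#' The quadratic form `x' W x` of a state with a weight matrix; when applied
#' to neural automaton states, `W` is the network's full recurrent weight
#' matrix.
#'
#' @param state activation vector.
#' @param W square weight matrix of matching dimension.
#' @return Scalar harmony value.
#' @export
harmony <- function(state, W) {
  state <- as.numeric(state)
  if (!is.matrix(W) || nrow(W) != ncol(W) || nrow(W) != length(state))
    stop("W must be square of dimension length(state)")
  as.numeric(state %*% W %*% state)
}

#' Dissimilarity between consecutive microstates
#'
#' One minus the cosine similarity of a state and its precursor.
#'
#' @param x_t,x_prev nonzero activation vectors.
#' @return Value in `[0, 2]`; 0 for identical directions.
#' @export
dissimilarity <- function(x_t, x_prev) {
  nt <- sqrt(sum(x_t^2))
  np <- sqrt(sum(x_prev^2))
  if (nt == 0 || np == 0) stop("dissimilarity undefined for zero-norm states")
  1 - sum(x_t * x_prev) / (nt * np)
}

#' Recoding-invariant step observables
#'
#' A step observable assigns one real coefficient to every orbit class of the
#' rectangle partition at resolution `(l, r)`: cells whose corner digit words
#' share the same (blank-anchored, per-axis) pattern of equality get the same
#' coefficient, and distinct classes get distinct coefficients drawn from a
#' seeded uniform generator. Because recodings permute cells within classes,
#' such a step function is invariant under the full blank-fixing recoding
#' group, while still separating genuinely different machine configurations.
#' Only the two MCL coordinates of a network state matter: over the remaining
#' units the observable is extended cylindrically.
#'
#' @param m_left,m_right alphabet sizes of the stack and input axes.
#' @param l,r partition depths (resolution) on the two axes.
#' @param seed integer seed for the coefficient draw (reproducible).
#' @param mode passed to [square_partition_classes()]; `per_axis` is the
#'   symmetry group under which invariance is guaranteed.
#' @return An object of class `step_observable`.
#' @examples
#' obs <- build_step_observable(5, 3, l = 2, r = 3, seed = 17)
#' obs$s  # number of classes
#' @export
build_step_observable <- function(m_left, m_right, l, r, seed = 17L,
                                  mode = "per_axis") {
  part <- square_partition_classes(m_left, m_right, l, r, mode = mode,
                                   anchored = TRUE)
  s <- part$n_classes
  coef <- .with_seed(seed, {
    co <- stats::runif(s)
    while (anyDuplicated(co)) co <- stats::runif(s)
    co
  })
  structure(list(m_left = m_left, m_right = m_right, l = l, r = r,
                 mode = mode, partition = part, s = s, coef = coef,
                 seed = seed),
            class = "step_observable")
}

#' @export
print.step_observable <- function(x, ...) {
  cat("<step_observable (l,r)=(", x$l, ",", x$r, ") sizes (", x$m_left, ",",
      x$m_right, ") ", x$s, " classes, seed ", x$seed, ">\n", sep = "")
  invisible(x)
}

#' Evaluate a step observable
#'
#' Locates the rectangle cell containing the point's MCL coordinates (exact
#' half-open membership) and returns the coefficient of the cell's orbit
#' class. Network states are snapped back to the rational grid first.
#'
#' @param obs a [build_step_observable()] result.
#' @param x a [phase_point()], or a network activation vector (first two
#'   entries the MCL).
#' @return The class coefficient (scalar).
#' @export
evaluate_step <- function(obs, x) {
  if (!inherits(x, "phase_point")) {
    x <- phase_point(.snap_rational(x[[1]], obs$m_left),
                     .snap_rational(x[[2]], obs$m_right))
  }
  i <- .cell_index(x$y1, obs$m_left, obs$l)
  j <- .cell_index(x$y2, obs$m_right, obs$r)
  obs$coef[obs$partition$class_id[i + 1L, j + 1L]]
}

#' Rigid recoding action on phase points
#'
#' A pair of blank-fixing code permutations acts on the unit square by
#' relabeling the corner digits of each partition cell and translating the
#' cell rigidly onto its image; the offset within the cell is preserved. This
#' is the phase-space lift of a Gödel recoding.
#'
#' @param p a [phase_point()].
#' @param pi1,pi2 code permutations (as in [recode_word()]) for the stack and
#'   input axes; must fix 0.
#' @param l,r partition depths.
#' @return The translated [phase_point()].
#' @export
rho_pi <- function(p, pi1, pi2, l, r) {
  m1 <- length(pi1)
  m2 <- length(pi2)
  if (pi1[1] != 0 || pi2[1] != 0)
    stop("recoding permutations must fix the blank code 0")
  shift_axis <- function(y, pi, m, depth) {
    idx <- .cell_index(y, m, depth)
    d <- corner_digits(idx, m, depth)
    idx2 <- .horner(pi[d + 1L], m)
    y + rational(idx2 - idx, m^depth)
  }
  phase_point(shift_axis(p$y1, pi1, m1, l),
              shift_axis(p$y2, pi2, m2, r))
}

#' Pull back an observable along a recoding
#'
#' Returns the transformed observable `f ∘ rho_pi`. The assignment is a
#' group representation: composing recodings composes the transformed
#' observables.
#'
#' @param f a function of a [phase_point()] (e.g. `function(x)
#'   evaluate_step(obs, x)`).
#' @inheritParams rho_pi
#' @return A function of a phase point.
#' @export
alpha_pi <- function(f, pi1, pi2, l, r) {
  force(f); force(pi1); force(pi2); force(l); force(r)
  function(x) f(rho_pi(x, pi1, pi2, l, r))
}

#' Verify invariance of an observable across encodings
#'
#' Runs the same versatile shift as a neural automaton under each supplied
#' encoding pair, evaluates the observable at every macro step, and reports
#' the maximum absolute pairwise difference per step. An observable is judged
#' invariant when all differences stay below `tol` (exact arithmetic upstream
#' makes true invariance exactly 0; the tolerance absorbs float execution of
#' the network).
#'
#' @param vs a [versatile_shift()].
#' @param s0 initial [dotted_word()].
#' @param encodings named list of encoding pairs, each
#'   `list(stack = <godel_encoding>, input = <godel_encoding>)`.
#' @param observable `"step"`, `"amari"`, `"harmony"` or `"dissimilarity"`.
#' @param l,r step-observable resolution (ignored for the others).
#' @param seed coefficient seed for the step observable.
#' @param steps macro-step budget.
#' @param tol invariance threshold.
#' @return An object of class `invariance_report`: per-step series for each
#'   encoding, per-step `max_diff`, and the `invariant` verdict.
#' @examples
#' \donttest{
#' d <- demo_bundle()
#' verify_invariance(d$vs, d$input, d$encodings, observable = "step",
#'                   l = 2, r = 3)
#' }
#' @export
verify_invariance <- function(vs, s0, encodings,
                              observable = c("step", "amari", "harmony",
                                             "dissimilarity"),
                              l = 2L, r = 3L, seed = 17L, steps = 100L,
                              tol = 1e-9) {
  observable <- match.arg(observable)
  if (is.null(names(encodings)))
    names(encodings) <- paste0("enc", seq_along(encodings))
  obs <- NULL
  if (observable == "step") {
    e1 <- encodings[[1]]
    obs <- build_step_observable(e1$stack$m, e1$input$m, l, r, seed = seed)
  }
  series <- lapply(encodings, function(e) {
    nda <- build_nda(vs, e$stack, e$input)
    na <- build_na(nda)
    states <- run_na(na, s0, steps = steps)
    switch(observable,
      step = apply(states, 1, function(x) evaluate_step(obs, x)),
      amari = apply(states, 1, amari_mean),
      harmony = apply(states, 1, harmony, W = na$W),
      dissimilarity = c(NA_real_, vapply(seq_len(nrow(states) - 1), function(t)
        dissimilarity(states[t + 1, ], states[t, ]), numeric(1))))
  })
  len <- vapply(series, length, integer(1))
  if (length(unique(len)) > 1)
    stop("trajectories halt at different times across encodings")
  mat <- do.call(cbind, series)
  max_diff <- apply(mat, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) 0 else max(v) - min(v)
  })
  structure(list(observable = observable, series = mat,
                 max_diff = max_diff, tol = tol,
                 invariant = all(max_diff <= tol),
                 n_steps = nrow(mat)),
            class = "invariance_report")
}

#' @export
print.invariance_report <- function(x, ...) {
  cat("<invariance_report ", x$observable, "> ",
      if (x$invariant) "INVARIANT" else "NOT invariant",
      " (max step diff ", format(max(x$max_diff), digits = 4),
      ", tol ", x$tol, ")\n", sep = "")
  invisible(x)
}
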