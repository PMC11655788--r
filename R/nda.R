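#' Phase points of a nonlinear dynamical automaton
#'
#' A dotted sequence is represented in the unit square by the Gödel numbers
#' of its two sides: `y1` encodes the stack side (read dot-outward), `y2` the
#' input side. Both coordinates are exact rationals in `[0, 1)`.
#'
#' @param y1,y2 `rational` scalars in `[0, 1)`.
#' @return An object of class `phase_point`.
#' @export
phase_point <- function(y1, y2) {
  y1 <- as_rational(y1)
  y2 <- as_rational(y2)
  if (rat_cmp(y1, rational(0)) < 0 || rat_cmp(y1, rational(1)) >= 0 ||
      rat_cmp(y2, rational(0)) < 0 || rat_cmp(y2, rational(1)) >= 0)
    stop("phase point coordinates must lie in [0, 1)")
  structure(list(y1 = y1, y2 = y2), class = "phase_point")
}

#' @export
format.phase_point <- function(x, ...) {
  sprintf("(%s, %s)", format(x$y1), format(x$y2))
}

#' @export
print.phase_point <- function(x, ...) {
  cat("<phase_point> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Gödel encoding of a machine configuration
#'
#' @param s a [dotted_word()].
#' @param enc_left,enc_right blank-anchored [godel_encoding()]s of the stack
#'   and input alphabets.
#' @return A [phase_point()] `(psi(left), psi(right))`.
#' @examples
#' g <- demo_encodings()$gamma
#' encode_state(parse_dotted_word("S . NP V NP"), g$stack, g$input)  # (4/5, 16/27)
#' @export
encode_state <- function(s, enc_left, enc_right) {
  phase_point(godel_encode(s$left, enc_left),
              godel_encode(s$right, enc_right))
}

#' Compile a versatile shift into a nonlinear dynamical automaton
#'
#' Under a pair of blank-anchored Gödel encodings, a versatile shift becomes a
#' piecewise affine map on the unit square. The square is partitioned into
#' DoD cells: cell `(i, j)` collects all configurations whose window contents
#' have Gödel prefixes `i / m_left^k_l` and `j / m_right^k_r`. On a cell
#' whose window matches a rule with consumed prefix `u` and replacement `v`
#' (per axis), the action on the Gödel number is forced by the conjugacy
#' requirement `encode(step(s)) = branch(encode(s))`:
#' `lambda = m^(|u| - |v|)` and `a = psi(v) - lambda * psi(u)`, a diagonal
#' affine map. Cells without a matching rule carry no branch — they form the
#' halting region (acceptance at the all-blank window, rejection elsewhere).
#' Rules with nonzero dot shift are rejected: moving a symbol across the dot
#' couples the two coordinates and is not expressible as a diagonal affine
#' branch.
#'
#' @param vs a [versatile_shift()].
#' @param enc_left,enc_right blank-anchored encodings matching the machine's
#'   alphabets.
#' @return An object of class `nda` with one affine branch per defined cell.
#' @export
build_nda <- function(vs, enc_left, enc_right) {
  if (!enc_left$anchored || !enc_right$anchored)
    stop("build_nda requires blank-anchored encodings")
  if (!setequal(names(enc_left$codes), vs$left_alphabet$symbols) ||
      !setequal(names(enc_right$codes), vs$right_alphabet$symbols))
    stop("encodings do not match the machine's alphabets")
  k_l <- vs$dod[1]
  k_r <- vs$dod[2]
  m_left <- enc_left$m
  m_right <- enc_right$m
  lsyms <- encoding_symbols(enc_left, 0:(m_left - 1))
  rsyms <- encoding_symbols(enc_right, 0:(m_right - 1))
  lwins <- .all_windows(lsyms, k_l)
  rwins <- .all_windows(rsyms, k_r)
  branches <- list()
  halts <- list()
  for (wi in seq_along(lwins)) {
    u_l <- lwins[[wi]]
    i <- .horner(encoding_codes(enc_left, u_l), m_left)
    for (wj in seq_along(rwins)) {
      u_r <- rwins[[wj]]
      j <- .horner(encoding_codes(enc_right, u_r), m_right)
      key <- paste(i, j, sep = "_")
      s_win <- vs_state(vs, u_l, u_r)
      m <- match_rule(vs, s_win)
      if (is.null(m)) {
        halts[[key]] <- list(i = i, j = j, window_left = u_l,
                             window_right = u_r,
                             reason = if (is_empty_tape(s_win)) "accept"
                                      else "reject")
        next
      }
      rl <- m$rule
      if (rl$shift != 0L)
        stop("build_nda: rule '", rl$label, "' has nonzero shift; ",
             "not representable as a diagonal affine branch")
      v_l <- .substitute(rl$new_left, m$bindings)
      v_r <- .substitute(rl$new_right, m$bindings)
      br1 <- .axis_branch(u_l[seq_len(length(rl$left))], v_l, enc_left)
      br2 <- .axis_branch(u_r[seq_len(length(rl$right))], v_r, enc_right)
      branches[[key]] <- list(
        i = i, j = j, window_left = u_l, window_right = u_r,
        lambda1 = br1$lambda, a1 = br1$a,
        lambda2 = br2$lambda, a2 = br2$a,
        rule_index = m$index, label = rl$label)
    }
  }
  structure(list(vs = vs, enc_left = enc_left, enc_right = enc_right,
                 k_l = k_l, k_r = k_r, m_left = m_left, m_right = m_right,
                 branches = branches, halts = halts),
            class = "nda")
}

.all_windows <- function(syms, k) {
  if (k == 0) return(list(character(0)))
  grids <- expand.grid(rep(list(syms), k), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grids)), function(r) rev(as.character(grids[r, ])))
}

.horner <- function(codes, m) {
  v <- 0
  for (c in codes) v <- v * m + c
  v
}

# affine action on one axis: consumed prefix u replaced by v
.axis_branch <- function(u, v, enc) {
  m <- enc$m
  d <- length(u) - length(v)
  lambda <- if (d >= 0) rational(m^d) else rational(1, m^(-d))
  a <- godel_encode(v, enc) - lambda * godel_encode(u, enc)
  list(lambda = lambda, a = a)
}

#' @export
print.nda <- function(x, ...) {
  cat("<nda ", x$m_left, "^", x$k_l, " x ", x$m_right, "^", x$k_r,
      " cells: ", length(x$branches), " branches, ",
      length(x$halts), " halting>\n", sep = "")
  invisible(x)
}

# exact cell index of a coordinate at depth k
.cell_index <- function(y, m, k) {
  M <- m^k
  .rat_guard(y$num * M, 1)
  (y$num * M) %/% y$den
}

#' Locate the DoD cell of a phase point
#' @param nda an [build_nda()] result.
#' @param p a [phase_point()].
#' @return Integer pair `c(i, j)` (0-based).
#' @export
nda_cell <- function(nda, p) {
  c(.cell_index(p$y1, nda$m_left, nda$k_l),
    .cell_index(p$y2, nda$m_right, nda$k_r))
}

#' One step of the NDA
#'
#' Locates the (half-open) cell containing `p` and applies its affine branch
#' exactly; returns `NULL` when the cell carries no branch (halting region).
#'
#' @param nda an `nda`.
#' @param p a [phase_point()].
#' @return The image `phase_point`, or `NULL` on halt.
#' @export
nda_step <- function(nda, p) {
  ij <- nda_cell(nda, p)
  br <- nda$branches[[paste(ij[1], ij[2], sep = "_")]]
  if (is.null(br)) return(NULL)
  phase_point(br$lambda1 * p$y1 + br$a1,
              br$lambda2 * p$y2 + br$a2)
}

#' Run an NDA trajectory
#'
#' @param nda an `nda`.
#' @param y0 initial [phase_point()].
#' @param steps maximum number of steps.
#' @return List of phase points (time 0 first) with attribute `halted`
#'   (logical: did the trajectory enter the halting region?).
#' @export
run_nda <- function(nda, y0, steps = 100L) {
  traj <- list(y0)
  halted <- FALSE
  for (t in seq_len(steps)) {
    nxt <- nda_step(nda, traj[[length(traj)]])
    if (is.null(nxt)) {
      halted <- TRUE
      break
    }
    traj[[length(traj) + 1L]] <- nxt
  }
  attr(traj, "halted") <- halted
  traj
}

#' Serialize an NDA's cell table
#'
#' One row per defined branch with interval bounds and affine coefficients as
#' exact `"num/den"` strings; suitable for bit-exact regression comparisons.
#'
#' @param nda an `nda`.
#' @return A data frame.
#' @export
nda_cells <- function(nda) {
  rows <- lapply(nda$branches, function(b) {
    cbind(data.frame(i = b$i, j = b$j,
                     stack_window = paste(b$window_left, collapse = " "),
                     input_window = paste(b$window_right, collapse = " "),
                     stringsAsFactors = FALSE),
          cell_bounds(b$i, b$j, nda$m_left, nda$m_right, nda$k_l, nda$k_r),
          data.frame(lambda1 = format(b$lambda1), a1 = format(b$a1),
                     lambda2 = format(b$lambda2), a2 = format(b$a2),
                     operation = b$label, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}
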