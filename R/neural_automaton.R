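#' Compile an NDA into a modular recurrent neural network
#'
#' The neural automaton realizes the piecewise affine map of an [build_nda()]
#' result with three layers. The *machine configuration layer* (MCL, 2
#' saturated-linear units) carries the phase point `(y1, y2)`. For every DoD
#' cell except the all-blank accepting cell there is one *branch group* of 5
#' units: two threshold detectors in the *branch selection layer* (BSL)
#' signalling `y1 >= lo1` and `y2 >= lo2`, one threshold gate that combines
#' them with the detectors of the neighbouring cells (which serve as the
#' upper-bound tests — the topmost intervals need none, since activations stay
#' below 1), and two saturated-linear units in the *linear transformation
#' layer* (LTL) that compute the branch's affine image, strongly inhibited
#' unless their gate fires. The MCL then sums the LTL outputs, of which at
#' most one group is active per macro step.
#'
#' Cells whose window matches no rule receive an identity ("stall") branch:
#' the hardware is laid out uniformly over the partition, so the unit count
#' `n = 2 + 5 * (cells - 1)` depends only on the partition geometry, not on
#' the rule set. [na_macro_step()] still reports a halt on such cells so that
#' network traces agree with the symbolic and NDA traces.
#'
#' Branch coefficients are exact rationals executed in floating point; the
#' detector thresholds are guarded by a margin of 1e-12, far below the
#' coarsest grid spacing that legitimate Gödel numbers can approach a cell
#' boundary by.
#'
#' @param nda an [build_nda()] result.
#' @return An object of class `neural_automaton` with fields `n` (unit
#'   count), `W` (n x n recurrent weight matrix), `bias`, `activation`
#'   (per-unit kind, `"satlin"` or `"threshold"`), `layers` (index sets MCL /
#'   BSL / LTL) and the branch table.
#' @examples
#' na <- build_na(demo_nda("gamma"))
#' na$n  # 72
#' @export
build_na <- function(nda) {
  Ml <- nda$m_left^nda$k_l
  Mr <- nda$m_right^nda$k_r
  cells <- c(nda$branches, nda$halts)
  accept <- vapply(cells, function(b) !is.null(b$reason) && b$reason == "accept",
                   logical(1))
  cells <- cells[!accept]
  # deterministic order: by (i, j)
  ord <- order(vapply(cells, `[[`, numeric(1), "i"),
               vapply(cells, `[[`, numeric(1), "j"))
  cells <- cells[ord]
  B <- length(cells)
  n <- 2L + 5L * B
  branches <- vector("list", B)
  for (b in seq_len(B)) {
    cl <- cells[[b]]
    is_rule <- is.null(cl$reason)
    lam1 <- if (is_rule) cl$lambda1 else rational(1)
    a1 <- if (is_rule) cl$a1 else rational(0)
    lam2 <- if (is_rule) cl$lambda2 else rational(1)
    a2 <- if (is_rule) cl$a2 else rational(0)
    branches[[b]] <- list(
      i = cl$i, j = cl$j, is_rule = is_rule,
      label = if (is_rule) cl$label else "stall",
      lo1 = rational(cl$i, Ml), lo2 = rational(cl$j, Mr),
      hi1 = rational(cl$i + 1, Ml), hi2 = rational(cl$j + 1, Mr),
      lambda1 = lam1, a1 = a1, lambda2 = lam2, a2 = a2)
  }
  ivals <- vapply(branches, `[[`, numeric(1), "i")
  jvals <- vapply(branches, `[[`, numeric(1), "j")
  unit <- function(b, k) 2L + 5L * (b - 1L) + k  # k: 1 Lx, 2 Ly, 3 gate, 4 z1, 5 z2
  W <- matrix(0, n, n)
  bias <- numeric(n)
  activation <- rep("satlin", n)
  delta <- 1e-12
  names <- c("y1", "y2", unlist(lapply(seq_len(B), function(b)
    paste0(c("Lx", "Ly", "g", "z1", "z2"), ".", b))))
  for (b in seq_len(B)) {
    br <- branches[[b]]
    lx <- unit(b, 1); ly <- unit(b, 2); g <- unit(b, 3)
    z1 <- unit(b, 4); z2 <- unit(b, 5)
    activation[c(lx, ly, g)] <- "threshold"
    W[lx, 1] <- 1; bias[lx] <- -(as.double(br$lo1) - delta)
    W[ly, 2] <- 1; bias[ly] <- -(as.double(br$lo2) - delta)
    W[g, lx] <- 1; W[g, ly] <- 1; bias[g] <- -1.5
    # upper-bound tests borrowed from any branch one cell up on each axis
    ux <- which(ivals == br$i + 1)
    if (length(ux)) W[g, unit(ux[1], 1)] <- -1
    uy <- which(jvals == br$j + 1)
    if (length(uy)) W[g, unit(uy[1], 2)] <- -1
    lam1 <- as.double(br$lambda1); a1 <- as.double(br$a1)
    lam2 <- as.double(br$lambda2); a2 <- as.double(br$a2)
    M <- max(abs(lam1) + abs(a1), abs(lam2) + abs(a2)) + 1
    W[z1, 1] <- lam1; W[z1, g] <- M; bias[z1] <- a1 - M
    W[z2, 2] <- lam2; W[z2, g] <- M; bias[z2] <- a2 - M
    W[1, z1] <- 1
    W[2, z2] <- 1
  }
  structure(list(nda = nda, n = n, W = W, bias = bias,
                 activation = activation, unit_names = names,
                 branches = branches,
                 layers = list(
                   MCL = 1:2,
                   BSL = sort(c(vapply(seq_len(B), unit, integer(1), k = 1L),
                                vapply(seq_len(B), unit, integer(1), k = 2L),
                                vapply(seq_len(B), unit, integer(1), k = 3L))),
                   LTL = sort(c(vapply(seq_len(B), unit, integer(1), k = 4L),
                                vapply(seq_len(B), unit, integer(1), k = 5L))))),
            class = "neural_automaton")
}

#' @export
print.neural_automaton <- function(x, ...) {
  cat("<neural_automaton n=", x$n, " units (MCL 2, BSL ",
      length(x$layers$BSL), ", LTL ", length(x$layers$LTL), "), ",
      length(x$branches), " branch groups>\n", sep = "")
  invisible(x)
}

.satlin <- function(v) pmin(1, pmax(0, v))
.thresh <- function(v) as.numeric(v >= 0)

#' One macro step of a neural automaton
#'
#' Applies the three-phase micro-step schedule: the BSL detectors read the
#' MCL, the gates combine detectors, the LTL computes the gated affine
#' images, and the MCL integrates them. All phases run through the recurrent
#' weight matrix `W` and per-unit activations. A halt is signalled (return
#' `NULL`) when no gate fires (the accepting cell) or when the active branch
#' is a stall cell with no rule, mirroring the NDA's halting region.
#'
#' @param na a [build_na()] result.
#' @param state activation vector of length `na$n`.
#' @return The next activation vector, or `NULL` on halt.
#' @export
na_macro_step <- function(na, state) {
  if (length(state) != na$n) stop("state has wrong length")
  B <- length(na$branches)
  unit <- function(b, k) 2L + 5L * (b - 1L) + k
  det <- c(vapply(seq_len(B), unit, integer(1), k = 1L),
           vapply(seq_len(B), unit, integer(1), k = 2L))
  gates <- vapply(seq_len(B), unit, integer(1), k = 3L)
  ltl <- c(vapply(seq_len(B), unit, integer(1), k = 4L),
           vapply(seq_len(B), unit, integer(1), k = 5L))
  x <- state
  x[det] <- .thresh(na$W[det, , drop = FALSE] %*% state + na$bias[det])
  x[gates] <- .thresh(na$W[gates, , drop = FALSE] %*% x + na$bias[gates])
  active <- which(x[gates] > 0)
  if (length(active) == 0) return(NULL)       # accepting cell: no hardware
  if (length(active) > 1)
    stop("internal error: multiple branch gates active")
  if (!na$branches[[active]]$is_rule) return(NULL)  # stall cell: rejection
  x[ltl] <- .satlin(na$W[ltl, , drop = FALSE] %*% x + na$bias[ltl])
  x[1:2] <- .satlin(na$W[1:2, , drop = FALSE] %*% x + na$bias[1:2])
  x
}

#' Run a neural automaton
#'
#' Initializes the MCL from the Gödel encoding of `s0` (all other units 0)
#' and iterates [na_macro_step()] until halt or for `steps` macro steps.
#'
#' @param na a [build_na()] result.
#' @param s0 initial configuration: a [dotted_word()] or a [phase_point()].
#' @param steps maximum number of macro steps.
#' @return Numeric matrix, one row per macro step (time 0 first), one column
#'   per unit (named); attribute `halted` records whether the run entered the
#'   halting region.
#' @export
run_na <- function(na, s0, steps = 100L) {
  if (inherits(s0, "dotted_word"))
    s0 <- encode_state(s0, na$nda$enc_left, na$nda$enc_right)
  x <- numeric(na$n)
  x[1] <- as.double(s0$y1)
  x[2] <- as.double(s0$y2)
  out <- list(x)
  halted <- FALSE
  for (t in seq_len(steps)) {
    nxt <- na_macro_step(na, out[[length(out)]])
    if (is.null(nxt)) {
      halted <- TRUE
      break
    }
    out[[length(out) + 1L]] <- nxt
  }
  states <- do.call(rbind, out)
  colnames(states) <- na$unit_names
  attr(states, "halted") <- halted
  states
}

# snap a float to the nearest grid rational p / m^L, smallest L within tol
.snap_rational <- function(x, m, tol = 1e-9, max_den = 2^45) {
  den <- 1
  L <- 0
  while (den <= max_den) {
    p <- round(x * den)
    if (abs(x - p / den) <= tol && p >= 0 && p < den + 1)
      return(rational(p, den))
    den <- den * m
    L <- L + 1
  }
  stop("activation ", x, " is not within ", tol, " of any base-", m,
       " grid point")
}

#' Read the machine configuration off a network state
#'
#' Extracts the two MCL activations and snaps them back to exact rationals on
#' the base-m grids (tolerance 1e-9 absorbs float execution of the network).
#'
#' @param state activation vector or a single row of [run_na()] output.
#' @param na the [build_na()] result that produced it.
#' @return A [phase_point()].
#' @export
read_mcl <- function(state, na) {
  phase_point(.snap_rational(state[[1]], na$nda$m_left),
              .snap_rational(state[[2]], na$nda$m_right))
}
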