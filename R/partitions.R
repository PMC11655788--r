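#' Code permutations of an alphabet
#'
#' All permutations of the codes `0..m-1`; in anchored mode only those fixing
#' 0 (the blank code), i.e. the subgroup isomorphic to the symmetric group on
#' `m-1` elements.
#'
#' @param m alphabet size.
#' @param anchored logical; restrict to permutations fixing 0?
#' @return Integer matrix, one permutation per row; entry `[p, c+1]` is the
#'   image of code `c`.
#' @export
code_permutations <- function(m, anchored = FALSE) {
  if (anchored) {
    arr <- .arrangements(m - 1, m - 1)
    cbind(0L, matrix(as.integer(arr), nrow = nrow(arr)))
  } else {
    arr <- .arrangements(m, m)
    matrix(as.integer(arr) - 1L, nrow = nrow(arr))
  }
}

# canonical pattern keys for the rows of a digit matrix
.digit_row_keys <- function(digits, anchored) {
  apply(digits, 1, function(d) {
    rgs <- match(d, unique(d))
    zb <- NULL
    if (anchored) {
      hit <- which(d == 0L)
      zb <- if (length(hit)) rgs[hit[1]] else NA_integer_
    }
    .pattern_key_rgs(rgs, zb)
  })
}

#' Invariant partition of the unit interval
#'
#' Assigns every depth-`l` cylinder interval `[k/m^l, (k+1)/m^l)` to the orbit
#' class of its corner digit word. Two intervals are in the same class iff a
#' Gödel recoding can map one onto the other; classes are exactly the orbits
#' of words under alphabet bijections.
#'
#' @param m alphabet size (>= 2).
#' @param l depth (word length, >= 1).
#' @param anchored logical; restrict recodings to those fixing the blank
#'   (code 0)?
#' @return An object of class `interval_partition`: list with `index`
#'   (0-based corner indices), `key` (class key per index), and `classes`
#'   (named list splitting indices by key).
#' @examples
#' p <- interval_partition_classes(3, 3)
#' table(lengths(p$classes))  # class sizes 3 and 6, totalling 27
#' @export
interval_partition_classes <- function(m, l, anchored = FALSE) {
  if (m < 2 || l < 1) stop("need m >= 2 and l >= 1")
  idx <- 0:(m^l - 1)
  digits <- corner_digits(idx, m, l)
  if (l == 1) digits <- matrix(digits, ncol = 1)
  keys <- .digit_row_keys(digits, anchored)
  structure(list(m = m, l = l, anchored = anchored,
                 index = idx, key = keys,
                 classes = split(idx, keys)),
            class = "interval_partition")
}

#' @export
print.interval_partition <- function(x, ...) {
  cat("<interval_partition m=", x$m, " l=", x$l,
      if (x$anchored) " anchored" else "", "> ",
      length(x$classes), " classes over ", length(x$index), " intervals\n",
      sep = "")
  invisible(x)
}

#' Invariant partition of the unit square
#'
#' The phase space of a dotted-sequence machine is the unit square: axis 1
#' carries the Gödel number of the stack side at depth `l` (base `m_left`),
#' axis 2 the input side at depth `r` (base `m_right`). Every rectangle cell
#' `[i/m_left^l, (i+1)/m_left^l) x [j/m_right^r, (j+1)/m_right^r)` is assigned
#' to the orbit class of its corner digit words. In `per_axis` mode (the
#' default) the two sides are recoded independently — the natural symmetry
#' when stack and input alphabets differ — and the class key is the pair of
#' one-dimensional pattern keys; in `joint` mode (equal alphabet sizes only) a
#' single shared permutation acts on both coordinates and the key is the
#' pattern of the concatenated digit word.
#'
#' @param m_left,m_right alphabet sizes of the two axes.
#' @param l,r depths on the two axes.
#' @param mode `"per_axis"` or `"joint"`.
#' @param anchored logical; restrict to blank-fixing recodings?
#' @return An object of class `square_partition`: the cell table
#'   (`cells`: data frame with `i`, `j`, `key`, `class_id`), the named list
#'   `classes`, and a `class_id` lookup matrix of dimension
#'   `m_left^l x m_right^r`.
#' @examples
#' sp <- square_partition_classes(3, 3, 2, 3, mode = "joint")
#' nrow(sp$cells)  # 3^5 cells
#' @export
square_partition_classes <- function(m_left, m_right, l, r,
                                     mode = c("per_axis", "joint"),
                                     anchored = FALSE) {
  mode <- match.arg(mode)
  if (mode == "joint" && m_left != m_right)
    stop("joint mode requires equal alphabet sizes on both axes")
  ni <- m_left^l
  nj <- m_right^r
  di <- corner_digits(0:(ni - 1), m_left, l)
  if (l == 1) di <- matrix(di, ncol = 1)
  dj <- corner_digits(0:(nj - 1), m_right, r)
  if (r == 1) dj <- matrix(dj, ncol = 1)
  grid <- expand.grid(i = 0:(ni - 1), j = 0:(nj - 1))
  if (mode == "per_axis") {
    ki <- .digit_row_keys(di, anchored)
    kj <- .digit_row_keys(dj, anchored)
    keys <- paste(ki[grid$i + 1L], kj[grid$j + 1L], sep = "|")
  } else {
    joint <- cbind(di[grid$i + 1L, , drop = FALSE],
                   dj[grid$j + 1L, , drop = FALSE])
    keys <- .digit_row_keys(joint, anchored)
  }
  class_id <- match(keys, unique(sort(keys)))
  cells <- data.frame(i = grid$i, j = grid$j, key = keys, class_id = class_id,
                      stringsAsFactors = FALSE)
  lookup <- matrix(NA_integer_, nrow = ni, ncol = nj)
  lookup[cbind(cells$i + 1L, cells$j + 1L)] <- cells$class_id
  structure(list(m_left = m_left, m_right = m_right, l = l, r = r,
                 mode = mode, anchored = anchored,
                 cells = cells, classes = split(cells[c("i", "j")], keys),
                 class_id = lookup, n_classes = max(class_id)),
            class = "square_partition")
}

#' @export
print.square_partition <- function(x, ...) {
  cat("<square_partition ", x$m_left, "^", x$l, " x ", x$m_right, "^", x$r,
      " mode=", x$mode, if (x$anchored) " anchored" else "", "> ",
      x$n_classes, " classes over ", nrow(x$cells), " cells\n", sep = "")
  invisible(x)
}

#' Bounds of a rectangle cell
#' @param i,j 0-based cell indices (vectorized).
#' @param m_left,m_right,l,r partition geometry.
#' @return Data frame with bounds as `"num/den"` strings.
#' @export
cell_bounds <- function(i, j, m_left, m_right, l, r) {
  dl <- m_left^l
  dr <- m_right^r
  data.frame(
    x_lo = format(rational(i, dl)), x_hi = format(rational(i + 1, dl)),
    y_lo = format(rational(j, dr)), y_hi = format(rational(j + 1, dr)),
    stringsAsFactors = FALSE)
}

#' Orbit of a rectangle cell under Gödel recodings
#'
#' Computes, directly from the cell's corner digit words, the set of cells it
#' can be mapped to by relabeling digits: independently per axis
#' (`per_axis`), or by one shared permutation of a common alphabet (`joint`).
#' The result is the partition class of [square_partition_classes()] that
#' contains the cell.
#'
#' @param i,j 0-based indices of the cell.
#' @inheritParams square_partition_classes
#' @return Data frame of cells (`i`, `j`, sorted) with interval bounds as
#'   `"num/den"` strings.
#' @examples
#' # six cells sharing the pattern of cell (6, 10) at m = 3, (l, r) = (2, 3)
#' rectangle_orbit(6, 10, 3, 3, 2, 3, mode = "joint")
#' @export
rectangle_orbit <- function(i, j, m_left, m_right, l, r,
                            mode = c("per_axis", "joint"), anchored = FALSE) {
  mode <- match.arg(mode)
  if (mode == "joint" && m_left != m_right)
    stop("joint mode requires equal alphabet sizes on both axes")
  di <- corner_digits(i, m_left, l)
  dj <- corner_digits(j, m_right, r)
  reindex <- function(d, m) {
    v <- 0
    for (x in d) v <- v * m + x
    v
  }
  if (mode == "per_axis") {
    pi1 <- code_permutations(m_left, anchored)
    pi2 <- code_permutations(m_right, anchored)
    is <- unique(apply(pi1, 1, function(p) reindex(p[di + 1L], m_left)))
    js <- unique(apply(pi2, 1, function(p) reindex(p[dj + 1L], m_right)))
    cellset <- expand.grid(i = is, j = js)
  } else {
    pis <- code_permutations(m_left, anchored)
    cellset <- unique(do.call(rbind, lapply(seq_len(nrow(pis)), function(k) {
      p <- pis[k, ]
      data.frame(i = reindex(p[di + 1L], m_left),
                 j = reindex(p[dj + 1L], m_right))
    })))
  }
  cellset <- cellset[order(cellset$i, cellset$j), , drop = FALSE]
  rownames(cellset) <- NULL
  cbind(cellset, cell_bounds(cellset$i, cellset$j, m_left, m_right, l, r))
}
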