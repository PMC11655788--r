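#' Exact rational numbers
#'
#' Gödel numbers, cylinder-interval endpoints and affine branch coefficients
#' all have denominators that are powers of the alphabet size. Membership in
#' half-open intervals must be decided exactly, so these quantities are kept
#' as reduced integer fractions; floating point only enters in the neural
#' network layer. Numerators and denominators are stored as doubles but are
#' required to stay below 2^53, where double arithmetic on integers is exact;
#' any operation that would leave that range raises an error rather than
#' silently losing precision.
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), nonzero; recycled against `num`.
#' @return An object of class `rational` (vector-like), always in reduced
#'   canonical form with positive denominator.
#' @examples
#' rational(6, 9)                 # 2/3
#' rational(1, 3) + rational(1, 9)
#' rational(2, 3) == rational(6, 9)
#' @export
rational <- function(num, den = 1) {
  num <- as.numeric(num)
  den <- as.numeric(den)
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  if (any(den == 0)) stop("rational: zero denominator")
  if (any(num != trunc(num)) || any(den != trunc(den)))
    stop("rational: numerator and denominator must be integer-valued")
  .rat_guard(num, den)
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  g <- .gcd(abs(num), den)
  g[g == 0] <- 1
  new_rational(num / g, den / g)
}

new_rational <- function(num, den) {
  structure(list(num = num, den = den), class = "rational")
}

.RAT_MAX <- 2^53

.rat_guard <- function(num, den) {
  if (any(abs(num) > .RAT_MAX) || any(abs(den) > .RAT_MAX))
    stop("rational: integer overflow beyond 2^53; problem size too large for exact arithmetic")
  invisible(NULL)
}

# vectorized Euclid on nonnegative integer-valued doubles
.gcd <- function(a, b) {
  while (any(b > 0)) {
    r <- ifelse(b > 0, a %% b, a)
    a <- ifelse(b > 0, b, a)
    b <- ifelse(b > 0, r, 0)
  }
  a
}

is_rational <- function(x) inherits(x, "rational")

as_rational <- function(x) {
  if (is_rational(x)) return(x)
  if (is.numeric(x)) {
    if (any(x != trunc(x)))
      stop("as_rational: non-integer numeric; construct with rational(num, den)")
    return(rational(x, 1))
  }
  stop("cannot coerce to rational")
}

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) new_rational(x$num[i], x$den[i])

#' @export
format.rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num),
         sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
print.rational <- function(x, ...) {
  cat("<rational> ", paste(format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.rational <- function(x, ...) format(x)

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' Parse "num/den" strings
#'
#' Inverse of `format()` on rationals; used by the JSON readers, where all
#' exact values are serialized as `"num/den"` strings.
#'
#' @param s character vector like `"6/9"` or `"2"`.
#' @return A `rational` vector.
#' @export
parse_rational <- function(s) {
  parts <- strsplit(as.character(s), "/", fixed = TRUE)
  num <- vapply(parts, function(p) as.numeric(p[[1]]), numeric(1))
  den <- vapply(parts, function(p) if (length(p) > 1) as.numeric(p[[2]]) else 1,
                numeric(1))
  rational(num, den)
}

#' @export
Ops.rational <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(new_rational(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rationals")
  }
  e1 <- as_rational(e1)
  e2 <- as_rational(e2)
  switch(.Generic,
    "+" = rat_add(e1, e2),
    "-" = rat_add(e1, new_rational(-e2$num, e2$den)),
    "*" = rat_mul(e1, e2),
    "/" = rat_mul(e1, new_rational(sign(e2$num) * e2$den, abs(e2$num))),
    "==" = e1$num == e2$num & e1$den == e2$den,
    "!=" = !(e1$num == e2$num & e1$den == e2$den),
    "<"  = rat_cmp(e1, e2) < 0,
    "<=" = rat_cmp(e1, e2) <= 0,
    ">"  = rat_cmp(e1, e2) > 0,
    ">=" = rat_cmp(e1, e2) >= 0,
    stop(.Generic, " not defined for rationals")
  )
}

# addition via lcm of the (reduced) denominators; the scale factors d2/g and
# d1/g stay small when one denominator divides the other, the common case for
# base-m grids
rat_add <- function(x, y) {
  g <- .gcd(x$den, y$den)
  f1 <- y$den / g
  f2 <- x$den / g
  num <- x$num * f1 + y$num * f2
  den <- x$den * f1
  .rat_guard(num, den)
  rational(num, den)
}

rat_mul <- function(x, y) {
  # cross-reduce before multiplying to delay overflow
  g1 <- .gcd(abs(x$num), y$den)
  g2 <- .gcd(abs(y$num), x$den)
  g1[g1 == 0] <- 1
  g2[g2 == 0] <- 1
  num <- (x$num / g1) * (y$num / g2)
  den <- (x$den / g2) * (y$den / g1)
  .rat_guard(num, den)
  rational(num, den)
}

rat_cmp <- function(x, y) {
  g <- .gcd(x$den, y$den)
  a <- x$num * (y$den / g)
  b <- y$num * (x$den / g)
  .rat_guard(a, b)
  sign(a - b)
}

#' Concatenate rationals
#' @param ... `rational` vectors (or integer-valued numerics).
#' @return A single `rational` vector.
#' @export
c_rational <- function(...) {
  xs <- lapply(list(...), as_rational)
  new_rational(unlist(lapply(xs, `[[`, "num")),
               unlist(lapply(xs, `[[`, "den")))
}

#' Half-open rational intervals
#'
#' The image of a cylinder set under a Gödel encoding is a half-open interval
#' `[lower, upper)` with endpoints on a base-m grid. The half-open convention
#' makes the depth-l intervals a partition of `[0, 1)`.
#'
#' @param lower,upper `rational` scalars with `0 <= lower < upper <= 1`.
#' @return An object of class `rational_interval`.
#' @export
rational_interval <- function(lower, upper) {
  lower <- as_rational(lower)
  upper <- as_rational(upper)
  if (any(rat_cmp(lower, rational(0)) < 0) || any(rat_cmp(upper, lower) <= 0) ||
      any(rat_cmp(upper, rational(1)) > 0))
    stop("rational_interval: need 0 <= lower < upper <= 1")
  structure(list(lower = lower, upper = upper), class = "rational_interval")
}

#' @export
format.rational_interval <- function(x, ...) {
  sprintf("[%s, %s)", format(x$lower), format(x$upper))
}

#' @export
print.rational_interval <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Interval membership (exact)
#' @param x a `rational` scalar.
#' @param interval a `rational_interval`.
#' @return `TRUE` iff `lower <= x < upper`.
#' @export
in_interval <- function(x, interval) {
  x <- as_rational(x)
  rat_cmp(x, interval$lower) >= 0 & rat_cmp(x, interval$upper) < 0
}
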