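#' Rewrite rules for versatile shifts
#'
#' A rule matches the tape content in the machine's domain of dependence (the
#' finite window around the dot) and substitutes a new dotted word for it,
#' after which the dot may be shifted. Patterns and replacements are given
#' dot-outward (index 1 adjacent to the dot). A token starting with `?` is a
#' wildcard variable binding any single non-blank symbol; the same variable
#' may appear on both sides of the match (forcing equality, as in the attach
#' rule of a top-down recognizer) and in the replacements.
#'
#' @param left,right match patterns (character vectors, dot-outward; possibly
#'   empty).
#' @param new_left,new_right replacement dotted word (dot-outward; lengths may
#'   differ from the match).
#' @param shift integer dot shift applied after substitution; positive values
#'   move symbols from the input side to the stack side (the left shift).
#' @param label human-readable operation label used in traces.
#' @return An object of class `vs_rule`.
#' @export
vs_rule <- function(left, right, new_left, new_right, shift = 0L,
                    label = NULL) {
  left <- as.character(left); right <- as.character(right)
  new_left <- as.character(new_left); new_right <- as.character(new_right)
  vars <- function(x) x[startsWith(x, "?")]
  unbound <- setdiff(c(vars(new_left), vars(new_right)),
                     c(vars(left), vars(right)))
  if (length(unbound))
    stop("vs_rule: unbound wildcard(s) in replacement: ",
         paste(unbound, collapse = ", "))
  if (is.null(label))
    label <- sprintf("%s.%s -> %s.%s",
                     paste(rev(left), collapse = " "),
                     paste(right, collapse = " "),
                     paste(rev(new_left), collapse = " "),
                     paste(new_right, collapse = " "))
  structure(list(left = left, right = right, new_left = new_left,
                 new_right = new_right, shift = as.integer(shift),
                 label = label),
            class = "vs_rule")
}

#' Versatile shifts
#'
#' A versatile shift is a dotted-sequence rewriting machine: its next move is
#' completely determined by the tape content in the domain of dependence, a
#' window of `k_l` symbols left and `k_r` symbols right of the dot. The
#' matched window is replaced by a dotted word of arbitrary length (this is
#' what distinguishes it from a generalized shift, where substitution is
#' symbol-for-symbol) and the dot is shifted. Rules are tried in order;
#' the first match fires.
#'
#' @param left_alphabet,right_alphabet [alphabet()]s of the stack and input
#'   sides.
#' @param dod integer pair `c(k_l, k_r)` with `k_l + k_r >= 1`.
#' @param rules list of [vs_rule()]s; match pattern lengths must not exceed
#'   the window lengths.
#' @return An object of class `versatile_shift`.
#' @export
versatile_shift <- function(left_alphabet, right_alphabet, dod, rules) {
  stopifnot(inherits(left_alphabet, "vs_alphabet"),
            inherits(right_alphabet, "vs_alphabet"))
  dod <- as.integer(dod)
  if (length(dod) != 2 || any(dod < 0) || sum(dod) < 1)
    stop("dod must be c(k_l, k_r) with at least one positive entry")
  ok_syms <- function(x, a) all(x[!startsWith(x, "?")] %in% a$symbols)
  for (rl in rules) {
    if (!inherits(rl, "vs_rule")) stop("rules must be vs_rule objects")
    if (length(rl$left) > dod[1] || length(rl$right) > dod[2])
      stop("rule pattern exceeds the domain of dependence")
    if (!ok_syms(rl$left, left_alphabet) || !ok_syms(rl$new_left, left_alphabet) ||
        !ok_syms(rl$right, right_alphabet) || !ok_syms(rl$new_right, right_alphabet))
      stop("rule uses symbols outside the alphabets")
  }
  structure(list(left_alphabet = left_alphabet,
                 right_alphabet = right_alphabet,
                 dod = dod, rules = rules),
            class = "versatile_shift")
}

#' @export
print.versatile_shift <- function(x, ...) {
  cat("<versatile_shift dod=(", x$dod[1], ",", x$dod[2], ") ",
      length(x$rules), " rules>\n", sep = "")
  for (rl in x$rules) cat("  ", rl$label, "\n", sep = "")
  invisible(x)
}

#' Dotted word for a machine's tape
#' @param vs a `versatile_shift`.
#' @param left,right sides, dot-outward.
#' @return A [dotted_word()] with the machine's blanks.
#' @export
vs_state <- function(vs, left = character(0), right = character(0)) {
  dotted_word(left, right,
              left_blank = vs$left_alphabet$blank,
              right_blank = vs$right_alphabet$blank)
}

# pad a side to window length n with the blank
.window <- function(side, n, blank) {
  if (n == 0) return(character(0))
  c(side, rep(blank, max(0, n - length(side))))[seq_len(n)]
}

# try to match one rule against the (already padded) DoD windows;
# returns the bindings environment as a named list, or NULL
.match_pattern <- function(pattern, window, blank, bindings) {
  for (k in seq_along(pattern)) {
    tok <- pattern[k]
    sym <- window[k]
    if (startsWith(tok, "?")) {
      if (sym == blank) return(NULL)  # wildcards bind non-blank symbols
      if (!is.null(bindings[[tok]])) {
        if (bindings[[tok]] != sym) return(NULL)
      } else bindings[[tok]] <- sym
    } else if (tok != sym) return(NULL)
  }
  bindings
}

#' First matching rule for a state
#'
#' Rules are matched against the DoD windows of `s` (sides padded with blanks
#' as needed) in list order; the first match wins, which makes the step map a
#' function even for overlapping rules.
#'
#' @param vs a [versatile_shift()].
#' @param s a [dotted_word()].
#' @return `NULL` if no rule matches (the machine halts), otherwise a list
#'   with `index`, `rule`, and the wildcard `bindings`.
#' @export
match_rule <- function(vs, s) {
  for (idx in seq_along(vs$rules)) {
    rl <- vs$rules[[idx]]
    b <- list()
    b <- .match_pattern(rl$left,
                        .window(s$left, length(rl$left), vs$left_alphabet$blank),
                        vs$left_alphabet$blank, b)
    if (is.null(b) && length(rl$left) > 0) next
    if (is.null(b)) b <- list()
    b2 <- .match_pattern(rl$right,
                         .window(s$right, length(rl$right), vs$right_alphabet$blank),
                         vs$right_alphabet$blank, b)
    if (is.null(b2) && length(rl$right) > 0) next
    if (is.null(b2)) b2 <- b
    return(list(index = idx, rule = rl, bindings = b2))
  }
  NULL
}

.substitute <- function(x, bindings) {
  if (length(x) == 0) return(x)
  vapply(x, function(tok)
    if (startsWith(tok, "?")) bindings[[tok]] else tok, character(1),
    USE.NAMES = FALSE)
}

#' One step of a versatile shift
#'
#' Replaces the matched DoD content by the rule's dotted replacement, then
#' applies the dot shift, materializing blank padding as needed. Returns
#' `NULL` when no rule matches (halt); use [run_vs()] for full traces.
#'
#' @param vs a [versatile_shift()].
#' @param s a [dotted_word()].
#' @return The successor `dotted_word`, or `NULL` on halt.
#' @examples
#' vs <- build_topdown_recognizer(demo_grammar())
#' s <- parse_dotted_word("S . NP V NP")
#' format(vs_step(vs, s))  # "VP NP.NP V NP"
#' @export
vs_step <- function(vs, s) {
  m <- match_rule(vs, s)
  if (is.null(m)) return(NULL)
  rl <- m$rule
  lb <- vs$left_alphabet$blank
  rb <- vs$right_alphabet$blank
  nl <- length(rl$left)
  nr <- length(rl$right)
  old_left <- .window(s$left, max(nl, length(s$left)), lb)
  old_right <- .window(s$right, max(nr, length(s$right)), rb)
  left <- c(.substitute(rl$new_left, m$bindings),
            if (nl < length(old_left)) old_left[(nl + 1):length(old_left)])
  right <- c(.substitute(rl$new_right, m$bindings),
             if (nr < length(old_right)) old_right[(nr + 1):length(old_right)])
  f <- rl$shift
  while (f > 0) {  # left shift: input head crosses the dot onto the stack
    sym <- if (length(right)) right[1] else rb
    right <- right[-1]
    if (!sym %in% vs$left_alphabet$symbols)
      stop("shift moves symbol '", sym, "' outside the stack alphabet")
    left <- c(sym, left)
    f <- f - 1L
  }
  while (f < 0) {
    sym <- if (length(left)) left[1] else lb
    left <- left[-1]
    if (!sym %in% vs$right_alphabet$symbols)
      stop("shift moves symbol '", sym, "' outside the input alphabet")
    right <- c(sym, right)
    f <- f + 1L
  }
  vs_state(vs, left, right)
}

#' Run a versatile shift to halting
#'
#' Iterates [vs_step()] from `s0`. The run is *accepted* when the tape becomes
#' empty (the all-blank configuration), *rejected* when no rule matches a
#' nonempty configuration, and cut off at `max_steps` otherwise (versatile
#' shifts built from grammars with left recursion need not terminate).
#'
#' @param vs a [versatile_shift()].
#' @param s0 initial [dotted_word()].
#' @param max_steps step budget (>= 1).
#' @return An object of class `vs_trace`: `states` (list of dotted words,
#'   time 0 first), `ops` (operation label applied at each time; the final
#'   entry is `"Accept"`, `"Reject"` or `"..."`), and `halt_status`
#'   (`accepted`, `rejected` or `max_steps`).
#' @export
run_vs <- function(vs, s0, max_steps = 100L) {
  stopifnot(max_steps >= 1)
  states <- list(s0)
  ops <- character(0)
  status <- "max_steps"
  repeat {
    s <- states[[length(states)]]
    if (is_empty_tape(s)) {
      ops <- c(ops, "Accept")
      status <- "accepted"
      break
    }
    if (length(states) > max_steps) {
      ops <- c(ops, "...")
      break
    }
    m <- match_rule(vs, s)
    if (is.null(m)) {
      ops <- c(ops, "Reject")
      status <- "rejected"
      break
    }
    ops <- c(ops, m$rule$label)
    states[[length(states) + 1L]] <- vs_step(vs, s)
  }
  structure(list(states = states, ops = ops, halt_status = status),
            class = "vs_trace")
}

#' @export
print.vs_trace <- function(x, ...) {
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  cat("halt:", x$halt_status, "\n")
  invisible(x)
}

#' @export
as.data.frame.vs_trace <- function(x, ...) {
  data.frame(t = seq_along(x$states) - 1L,
             state = vapply(x$states, format, character(1)),
             operation = x$ops,
             stringsAsFactors = FALSE)
}

#' Context-free grammars for top-down recognition
#'
#' @param productions list of productions, each `list(lhs = , rhs = )` with a
#'   single nonterminal `lhs` and a nonempty `rhs` symbol vector.
#' @param terminals character vector of terminal symbols; defaults to the
#'   right-hand-side symbols that never occur as a left-hand side.
#' @param start start symbol; defaults to the first production's `lhs`.
#' @param blank blank symbol token.
#' @return An object of class `cfg`.
#' @examples
#' g <- cfg(list(list(lhs = "S", rhs = c("NP", "VP")),
#'               list(lhs = "VP", rhs = c("V", "NP"))))
#' @export
cfg <- function(productions, terminals = NULL, start = NULL, blank = "_") {
  lhs <- vapply(productions, function(p) p$lhs, character(1))
  rhs_syms <- unique(unlist(lapply(productions, function(p) p$rhs)))
  nonterminals <- unique(lhs)
  if (is.null(terminals)) terminals <- setdiff(rhs_syms, nonterminals)
  if (is.null(start)) start <- lhs[1]
  if (any(lengths(lapply(productions, function(p) p$rhs)) == 0))
    stop("empty productions are not supported")
  structure(list(productions = productions, terminals = terminals,
                 nonterminals = nonterminals, start = start, blank = blank),
            class = "cfg")
}

#' Compile a CFG into a top-down recognizer versatile shift
#'
#' Builds the standard predict/attach machine with domain of dependence
#' `(1, 1)`: for each production `X -> Y1 ... Yp` a predict rule replaces
#' stack-top `X` by the right-hand side with `Y1` nearest the dot (note the
#' reversed order on the stack), leaving the input untouched; a single attach
#' rule cancels equal stack-top and input symbols. All rules have shift 0.
#' Predict rules fire only while input remains (the wildcard binds a
#' non-blank input symbol). Left-recursive grammars compile but may loop; the
#' step budget of [run_vs()] is the only guard.
#'
#' @param g a [cfg()].
#' @return A [versatile_shift()] whose stack alphabet is blank + terminals +
#'   nonterminals and whose input alphabet is blank + terminals.
#' @examples
#' vs <- build_topdown_recognizer(demo_grammar())
#' run_vs(vs, parse_dotted_word("S . NP V NP"))
#' @export
build_topdown_recognizer <- function(g) {
  stopifnot(inherits(g, "cfg"))
  stack_a <- alphabet(c(g$blank, g$terminals, g$nonterminals), blank = g$blank)
  input_a <- alphabet(c(g$blank, g$terminals), blank = g$blank)
  rules <- lapply(g$productions, function(p)
    vs_rule(left = p$lhs, right = "?a",
            new_left = p$rhs, new_right = "?a",
            label = sprintf("Predict (%s -> %s)", p$lhs,
                            paste(p$rhs, collapse = " "))))
  rules <- c(rules, list(
    vs_rule(left = "?a", right = "?a",
            new_left = character(0), new_right = character(0),
            label = "Attach")))
  versatile_shift(stack_a, input_a, dod = c(1L, 1L), rules = rules)
}

#' Wrap a generalized shift as a versatile shift
#'
#' A generalized shift substitutes the DoD content symbol-for-symbol and then
#' shifts the dot; it is the special case of a versatile shift in which every
#' rule's replacement has exactly the length of its match on each side.
#' Length-changing rules are rejected.
#'
#' @inheritParams versatile_shift
#' @return A [versatile_shift()].
#' @export
compile_generalized_shift <- function(left_alphabet, right_alphabet, dod,
                                      rules) {
  for (rl in rules) {
    if (length(rl$new_left) != length(rl$left) ||
        length(rl$new_right) != length(rl$right))
      stop("generalized shift requires symbol-for-symbol substitution; ",
           "rule '", rl$label, "' changes length")
  }
  versatile_shift(left_alphabet, right_alphabet, dod, rules)
}
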