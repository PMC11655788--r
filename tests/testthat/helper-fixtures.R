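# shared helpers: word conversions and independent brute-force oracles

str2word <- function(s) strsplit(s, "")[[1]]
wordstr <- function(w) paste(w, collapse = "")

# orbit oracle: images of w under all alphabet bijections (anchored: all
# bijections fixing the blank), independent of enumerate_orbit's
# injective-assignment construction
oracle_orbit <- function(w, a, anchored = FALSE) {
  perms <- code_permutations(a$m, anchored)
  idx <- match(w, a$symbols)  # 1-based, code = idx - 1
  imgs <- apply(perms, 1, function(p) wordstr(a$symbols[p[idx] + 1L]))
  sort(unique(imgs))
}

# brute-force CFG language up to a terminal-string length (no empty
# productions, so sentential forms only grow)
cfg_language <- function(g, max_len) {
  frontier <- list(g$start)
  out <- character(0)
  seen <- character(0)
  while (length(frontier)) {
    f <- frontier[[1]]
    frontier <- frontier[-1]
    key <- paste(f, collapse = " ")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (length(f) > max_len) next
    nt <- which(f %in% g$nonterminals)
    if (!length(nt)) {
      out <- c(out, key)
      next
    }
    i <- nt[1]
    for (p in g$productions) {
      if (p$lhs == f[i])
        frontier[[length(frontier) + 1L]] <-
          append(f[-i], p$rhs, after = i - 1L)
    }
  }
  sort(unique(out))
}

# all words of length l over symbols (list of character vectors)
all_words <- function(symbols, l) {
  g <- expand.grid(rep(list(symbols), l), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(r) as.character(unlist(g[r, ])))
}

# exact conjugacy check for one machine/state over a step budget; returns a
# description of the first violation, or NULL
check_conjugacy <- function(vs, enc_l, enc_r, s0, steps = 20L) {
  nda <- build_nda(vs, enc_l, enc_r)
  s <- s0
  for (t in seq_len(steps)) {
    p <- encode_state(s, enc_l, enc_r)
    s_next <- vs_step(vs, s)
    p_next <- nda_step(nda, p)
    if (is.null(s_next) != is.null(p_next))
      return(sprintf("halting mismatch at t=%d (%s)", t, format(s)))
    if (is.null(s_next)) return(NULL)
    q <- encode_state(s_next, enc_l, enc_r)
    if (!(q$y1 == p_next$y1) || !(q$y2 == p_next$y2))
      return(sprintf("conjugacy broken at t=%d: %s vs %s",
                     t, format(q), format(p_next)))
    s <- s_next
  }
  NULL
}
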