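#' The worked neurolinguistic example
#'
#' A toy model of syntactic language processing: the sentence "the dog chased
#' the cat" is abstracted (after folding the lexical rules into the terminals
#' `NP` and `V`) to the context-free grammar `S -> NP VP`, `VP -> V NP`, and
#' the pre-tokenized input `NP V NP` is parsed by the top-down recognizer
#' versatile shift. `demo_grammar()` returns that grammar; `demo_encodings()`
#' returns the two Gödelization pairs used throughout the worked example —
#' `gamma` (`NP↦1, V↦2` on the input side; `NP↦1, V↦2, VP↦3, S↦4` on the
#' stack side) and `delta` (`NP↦2, V↦1`; `VP↦1, S↦2, V↦3, NP↦4`), both
#' blank-anchored.
#'
#' @return `demo_grammar()`: a [cfg()]. `demo_encodings()`: named list with
#'   elements `gamma` and `delta`, each `list(stack = , input = )`.
#' @export
demo_grammar <- function() {
  cfg(list(list(lhs = "S", rhs = c("NP", "VP")),
           list(lhs = "VP", rhs = c("V", "NP"))),
      terminals = c("NP", "V"), start = "S", blank = "_")
}

#' @rdname demo_grammar
#' @export
demo_encodings <- function() {
  list(
    gamma = list(
      stack = godel_encoding(c("_" = 0, NP = 1, V = 2, VP = 3, S = 4),
                             blank = "_"),
      input = godel_encoding(c("_" = 0, NP = 1, V = 2), blank = "_")),
    delta = list(
      stack = godel_encoding(c("_" = 0, VP = 1, S = 2, V = 3, NP = 4),
                             blank = "_"),
      input = godel_encoding(c("_" = 0, V = 1, NP = 2), blank = "_")))
}

#' @rdname demo_grammar
#' @param encoding `"gamma"` or `"delta"`.
#' @return `demo_nda()`: the compiled [build_nda()] for the recognizer under
#'   the chosen encoding.
#' @export
demo_nda <- function(encoding = c("gamma", "delta")) {
  encoding <- match.arg(encoding)
  e <- demo_encodings()[[encoding]]
  build_nda(build_topdown_recognizer(demo_grammar()), e$stack, e$input)
}

#' @rdname demo_grammar
#' @return `demo_bundle()`: list with the recognizer `vs`, the `encodings`,
#'   the `input` dotted word `S . NP V NP`, and the observable resolution
#'   `l = 2, r = 3`.
#' @export
demo_bundle <- function() {
  vs <- build_topdown_recognizer(demo_grammar())
  list(vs = vs,
       encodings = demo_encodings(),
       input = vs_state(vs, left = "S", right = c("NP", "V", "NP")),
       l = 2L, r = 3L)
}

#' Run the end-to-end demo
#'
#' Parses `NP V NP` with the top-down recognizer and writes, per chosen
#' encoding: the symbolic trace, the exact NDA trajectory, the neural
#' automaton trajectory (all 72 units), and the step-observable and Amari
#' series. With both encodings an invariance report is also written: the
#' step series agree exactly across encodings while the Amari series differ.
#' All outputs are TSV (plus one JSON report) and deterministic given the
#' seed.
#'
#' @param encoding `"gamma"`, `"delta"` or `"both"`.
#' @param out_dir output directory (created if missing).
#' @param seed coefficient seed for the step observable.
#' @param steps macro-step budget.
#' @return Invisibly, the list of written file paths.
#' @export
run_demo <- function(encoding = c("both", "gamma", "delta"),
                     out_dir = ".", seed = 17L, steps = 50L) {
  encoding <- match.arg(encoding)
  which_enc <- if (encoding == "both") c("gamma", "delta") else encoding
  d <- demo_bundle()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  trace <- run_vs(d$vs, d$input, max_steps = steps)
  emit(as.data.frame(trace), "trace.tsv")
  obs <- build_step_observable(5, 3, d$l, d$r, seed = seed)
  for (en in which_enc) {
    e <- d$encodings[[en]]
    nda <- build_nda(d$vs, e$stack, e$input)
    traj <- run_nda(nda, encode_state(d$input, e$stack, e$input),
                    steps = steps)
    emit(data.frame(t = seq_along(traj) - 1L,
                    y1 = vapply(traj, function(p) format(p$y1), character(1)),
                    y2 = vapply(traj, function(p) format(p$y2), character(1))),
         sprintf("nda_trajectory_%s.tsv", en))
    na <- build_na(nda)
    states <- run_na(na, d$input, steps = steps)
    emit(data.frame(t = seq_len(nrow(states)) - 1L, states,
                    check.names = FALSE),
         sprintf("na_trajectory_%s.tsv", en))
    cells <- t(vapply(seq_len(nrow(states)), function(t) {
      p <- read_mcl(states[t, ], na)
      c(.cell_index(p$y1, 5, d$l), .cell_index(p$y2, 3, d$r))
    }, numeric(2)))
    emit(data.frame(t = seq_len(nrow(states)) - 1L,
                    step_observable = apply(states, 1, evaluate_step,
                                            obs = obs),
                    amari = apply(states, 1, amari_mean),
                    cell_i = cells[, 1], cell_j = cells[, 2],
                    class_id = obs$partition$class_id[cells + 1]),
         sprintf("observables_%s.tsv", en))
  }
  if (length(which_enc) == 2) {
    rep_step <- verify_invariance(d$vs, d$input, d$encodings, "step",
                                  l = d$l, r = d$r, seed = seed,
                                  steps = steps)
    rep_amari <- verify_invariance(d$vs, d$input, d$encodings, "amari",
                                   steps = steps)
    path <- file.path(out_dir, "invariance_report.json")
    jsonlite::write_json(list(
      step = list(invariant = rep_step$invariant,
                  max_diff = max(rep_step$max_diff)),
      amari = list(invariant = rep_amari$invariant,
                   max_diff = max(rep_amari$max_diff))),
      path, auto_unbox = TRUE, digits = NA)
    files <- c(files, path)
  }
  invisible(files)
}
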