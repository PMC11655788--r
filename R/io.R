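# JSON (and YAML, normalized to JSON) configuration readers and writers.
#
# Encoding config schema:
#   {"codes": {"_": 0, "NP": 1, ...}, "blank": "_", "anchored": true}
# Machine config schema:
#   {"left_alphabet": [...], "right_alphabet": [...],
#    "left_blank": "_", "right_blank": "_", "dod": [1, 1],
#    "rules": [{"left": [...], "right": [...],
#               "new_left": [...], "new_right": [...],
#               "shift": 0, "label": "..."}]}
# Rule sides are dot-outward; wildcards are spelled "?a". A single "blank"
# field may replace left_blank/right_blank when both sides share it.

.read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

#' Read and write encoding configurations
#'
#' @param path file path (`.json`, or `.yaml`/`.yml` with the yaml package).
#' @return `read_encoding()`: a [godel_encoding()].
#' @export
read_encoding <- function(path) {
  cfg <- .read_config(path)
  codes <- unlist(cfg$codes)
  godel_encoding(codes, blank = cfg$blank,
                 anchored = isTRUE(cfg$anchored) || is.null(cfg$anchored))
}

#' @rdname read_encoding
#' @param e a [godel_encoding()].
#' @export
write_encoding <- function(e, path) {
  jsonlite::write_json(list(codes = as.list(e$codes), blank = e$blank,
                            anchored = e$anchored),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read and write versatile-shift machine configurations
#'
#' @param path file path (`.json`, or `.yaml`/`.yml`).
#' @return `read_machine()`: a [versatile_shift()].
#' @export
read_machine <- function(path) {
  cfg <- .read_config(path)
  lb <- cfg$left_blank %||% cfg$blank %||% "_"
  rb <- cfg$right_blank %||% cfg$blank %||% "_"
  la <- alphabet(unlist(cfg$left_alphabet), blank = lb)
  ra <- alphabet(unlist(cfg$right_alphabet), blank = rb)
  as_chr <- function(x) if (is.null(x)) character(0) else as.character(unlist(x))
  rules <- lapply(cfg$rules, function(rl)
    vs_rule(left = as_chr(rl$left), right = as_chr(rl$right),
            new_left = as_chr(rl$new_left), new_right = as_chr(rl$new_right),
            shift = rl$shift %||% 0L, label = rl$label %||% NULL))
  versatile_shift(la, ra, dod = unlist(cfg$dod), rules = rules)
}

#' @rdname read_machine
#' @param vs a [versatile_shift()].
#' @export
write_machine <- function(vs, path) {
  rules <- lapply(vs$rules, function(rl)
    list(left = rl$left, right = rl$right,
         new_left = rl$new_left, new_right = rl$new_right,
         shift = rl$shift, label = rl$label))
  jsonlite::write_json(
    list(left_alphabet = vs$left_alphabet$symbols,
         right_alphabet = vs$right_alphabet$symbols,
         left_blank = vs$left_alphabet$blank,
         right_blank = vs$right_alphabet$blank,
         dod = vs$dod, rules = rules),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
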