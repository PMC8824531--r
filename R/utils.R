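# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator with `seed`,
#' evaluates `expr`, and restores the previous state so library calls never
#' disturb user-level randomness.
#'
#' @param seed integer seed (< 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage label, keeping the
# result inside the 32-bit signed range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

abort_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

#' Structured log line
#'
#' Writes a `timestamp | stage | message` line to `stderr` (and to a file
#' connection when one is configured via `options(eegdecode.log_file=)`).
#' @param stage short stage tag.
#' @param fmt,... `sprintf` message.
#' @keywords internal
log_msg <- function(stage, fmt, ...) {
  line <- sprintf("%s | %s | %s",
                  format(Sys.time(), tz = "UTC", "%Y-%m-%dT%H:%M:%SZ"),
                  stage, sprintf(fmt, ...))
  if (isTRUE(getOption("eegdecode.verbose", FALSE))) message(line)
  lf <- getOption("eegdecode.log_file", NULL)
  if (!is.null(lf)) cat(line, "\n", file = lf, append = TRUE)
  invisible(line)
}

# Stratified fold assignment: returns an integer vector of fold ids in
# 1..k, balanced within each class, deterministic given the seed.
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
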