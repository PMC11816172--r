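#' Derive a child seed from a root seed and a stage label
#'
#' All stochastic stages draw their own seed deterministically from a single
#' root seed, so partial reruns of a pipeline reproduce bit-identical output.
#'
#' @param seed integer root seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # 2^31 - 1 is prime; intermediates stay below 2^53 so doubles are exact
  as.integer(((abs(seed) %% 2147483647) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wg_log <- function(..., logfile = NULL) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  invisible(msg)
}

# stable significant-digit formatting used by all TSV writers
format_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(signif(x, digits), format = "g", digits = digits))
}
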