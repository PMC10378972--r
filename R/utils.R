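# Small shared helpers.

#' Derive a reproducible stream seed from a master seed and labels
#'
#' Hashes the label strings with a 31-based rolling hash and folds the
#' master seed in modulo 2^31 - 1, so every (seed, label...) combination
#' gets a fixed stream seed independent of iteration order.
#'
#' @param seed master integer seed.
#' @param ... label components (coerced to character).
#' @return a positive integer below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = ":")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 + h) %% 2147483629 + 1)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
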