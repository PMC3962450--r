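# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' Hashes a global seed together with an arbitrary set of string labels into
#' a 32-bit integer seed. Used to give every subject, scan and pipeline stage
#' its own deterministic random stream, so that e.g. adding subjects to a
#' cohort never changes the data of existing subjects.
#'
#' @param seed Integer global seed.
#' @param ... Further labels (coerced to character) identifying the stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  lab <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Multiplicative log-normal scaling factors with unit mean and a given
# coefficient of variation. cv = 0 returns exactly 1.
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stop("coefficient of variation must be non-negative")
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# Classed conditions so callers (and the CLI) can map failures to causes.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("dtiretest_config_error",
                                             "error", "condition")))
}
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("dtiretest_data_error",
                                             "error", "condition")))
}

METRICS <- c("FA", "MD", "AD", "RD")

# Write a data.frame as a TSV with fixed, locale-independent formatting.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
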