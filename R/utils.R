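#' Derive a reproducible sub-stream seed
#'
#' All stochastic operations in the package take a single integer seed and,
#' internally, derive one sub-seed per named stage so that adding a stage
#' never perturbs the random numbers of another. The derivation hashes the
#' stage label into a 31-bit integer offset.
#'
#' @param seed integer master seed.
#' @param label character stage label, e.g. `"genotypes"`.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

#' Natural sort of chromosome labels
#'
#' Sorts labels like `1A < 1B < 2A < ... < 7D` (leading integer first, then
#' the remainder lexicographically). Purely alphanumeric labels fall back to
#' numeric-then-alphabetic ordering.
#'
#' @param x character vector of chromosome labels.
#' @return `x` sorted naturally.
#' @export
chrom_sort <- function(x) {
  u <- unique(as.character(x))
  num <- suppressWarnings(as.numeric(sub("^([0-9]+).*$", "\\1", u)))
  num[is.na(num)] <- Inf
  rest <- sub("^[0-9]+", "", u)
  u[order(num, rest)]
}

## internal: write a TSV with '.' for NA, locale-independent
write_tsv_dot <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    col <- df2[[j]]
    if (is.numeric(col)) col <- format(col, digits = 15, trim = TRUE, scientific = NA)
    col <- as.character(col)
    col[is.na(df2[[j]]) | col == "NA"] <- "."
    df2[[j]] <- col
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_dot <- function(path, numeric_cols = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(numeric_cols)) {
    for (nm in intersect(numeric_cols, names(df))) df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
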