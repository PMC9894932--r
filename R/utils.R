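#' @keywords internal
"_PACKAGE"

#' @importFrom utils read.delim write.table adist head
#' @importFrom stats median setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a UTF-8 TSV file into a character data frame
#'
#' All columns are read as character; empty strings are the missing-value
#' convention of the package's tabular dialect and are converted to `NA`.
#'
#' @param path file path.
#' @param keep_empty keep empty strings instead of converting to `NA`.
#' @return a `data.frame` of character columns.
#' @keywords internal
read_tsv_chr <- function(path, keep_empty = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(), fileEncoding = "UTF-8",
                          comment.char = "")
  if (!keep_empty) df[] <- lapply(df, function(x) ifelse(x == "", NA_character_, x))
  df
}

write_tsv_chr <- function(df, path) {
  df2 <- df
  df2[] <- lapply(df2, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Deterministic polynomial string hash into 0..(mod-1).
# Horner scheme over UTF-8 code points; mod kept < 2^31 so doubles are exact.
string_hash <- function(s, mod) {
  vapply(s, function(one) {
    h <- 0
    for (b in utf8ToInt(one)) h <- (h * 131 + b) %% 1000000007
    as.integer(h %% mod)
  }, integer(1), USE.NAMES = FALSE)
}

# Percent rounding used in report headlines: half away from zero.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

collapse_ws <- function(x) gsub("\\s+", " ", trimws(x))

# Run code under a local, seeded RNG stream without disturbing the caller's.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
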