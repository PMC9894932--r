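## Chemical-name canonicalization.
##
## Metabolite names extracted from different registries use inconsistent
## conventions for stereochemistry prefixes, Greek letters, quotes and
## dashes.  Names are made comparable by lower-casing, collapsing
## whitespace, and applying an ordered table of rewrite rules, e.g. the
## stereo prefix "cis-" is rewritten to "z-" and the symbol "α" to
## "alpha".  The rule table is data, shipped as a TSV and overridable.

#' Default name-normalization rule table
#'
#' Ordered rewrite rules applied by [normalize_name()]. Unicode
#' punctuation is unified first (curly quotes, en/em dashes, minus sign),
#' then Greek letters are spelled out anywhere in the name, then
#' stereo-descriptor prefixes are rewritten at the start of the name only
#' ("cis-" to "z-", "trans-" to "e-").  Prefix rules are anchored so that
#' interior substrings (e.g. the "cis" in "precisely") are never touched.
#'
#' @return a `data.frame` with columns `rule_id`, `pattern`, `replacement`,
#'   `anchor` (one of `"PREFIX"`, `"ANYWHERE"`), in application order.
#' @seealso [normalize_name()], [load_rule_table()]
#' @export
default_rule_table <- function() {
  path <- system.file("extdata", "normalization_rules.tsv",
                      package = "microexposome", mustWork = TRUE)
  load_rule_table(path)
}

#' Load a name-normalization rule table from TSV
#'
#' @param path TSV with columns `pattern`, `replacement`, `anchor`
#'   (`PREFIX` or `ANYWHERE`) and optionally `rule_id`; row order is
#'   application order.  When `path` is `NULL` the shipped default table
#'   is returned.
#' @return rule table `data.frame` (possibly empty).
#' @export
load_rule_table <- function(path = NULL) {
  if (is.null(path)) return(default_rule_table())
  df <- read_tsv_chr(path, keep_empty = TRUE)
  if (nrow(df) == 0) {
    return(data.frame(rule_id = character(), pattern = character(),
                      replacement = character(), anchor = character(),
                      stringsAsFactors = FALSE))
  }
  need <- c("pattern", "replacement")
  if (!all(need %in% names(df))) {
    stop("rule table ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"anchor" %in% names(df)) df$anchor <- "ANYWHERE"
  if (!"rule_id" %in% names(df)) df$rule_id <- sprintf("rule%03d", seq_len(nrow(df)))
  if (anyDuplicated(df$rule_id)) {
    stop("duplicate rule_id in ", path, ": ",
         paste(unique(df$rule_id[duplicated(df$rule_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$pattern == "" | is.na(df$pattern))) {
    stop("rule table ", path, " has an empty pattern", call. = FALSE)
  }
  bad <- !df$anchor %in% c("PREFIX", "ANYWHERE")
  if (any(bad)) {
    stop("unknown anchor value(s): ", paste(unique(df$anchor[bad]), collapse = ", "),
         call. = FALSE)
  }
  df$replacement[is.na(df$replacement)] <- ""
  df[, c("rule_id", "pattern", "replacement", "anchor")]
}

#' Canonicalize a chemical name
#'
#' Lower-cases, trims and collapses whitespace, then applies the rewrite
#' rules in table order: `PREFIX` rules fire only at the start of the name,
#' `ANYWHERE` rules replace every literal occurrence.  The result is stable
#' under re-application for the shipped rule table (and any table whose
#' replacements do not reintroduce patterns).
#'
#' @param name character vector of names (non-empty strings).
#' @param rules rule table as returned by [load_rule_table()].
#' @return character vector of canonical names.
#' @examples
#' \donttest{
#' normalize_name("cis-Aconitic acid")   # "z-aconitic acid"
#' }
#' @export
normalize_name <- function(name, rules = default_rule_table()) {
  if (any(is.na(name) | !nzchar(trimws(name)))) {
    stop("normalize_name: empty or missing name", call. = FALSE)
  }
  out <- collapse_ws(tolower(name))
  for (i in seq_len(nrow(rules))) {
    pat <- tolower(rules$pattern[i])
    rep <- tolower(rules$replacement[i])
    if (rules$anchor[i] == "PREFIX") {
      hit <- startsWith(out, pat)
      out[hit] <- paste0(rep, substring(out[hit], nchar(pat) + 1L))
    } else {
      out <- gsub(pat, rep, out, fixed = TRUE)
    }
  }
  out
}

# Match-time key: normalized name with the terminal "-ate" / "-ic acid"
# carboxylate equivalence folded in, so e.g. "z-aconitate" and
# "z-aconitic acid" compare equal without rewriting either display name.
name_match_key <- function(name, rules = default_rule_table()) {
  out <- normalize_name(name, rules)
  sub("ate$", "ic acid", out)
}
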