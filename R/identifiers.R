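## Identifier namespaces and canonical-case rules.
##
## The matching cascade relies on identifiers being stored in one canonical
## form per namespace: uppercase InChIKey, "CHEBI:"-prefixed ChEBI, bare
## positive-integer PubChem CID, uppercase HMDB accession.  BiGG and MetaNetX
## ids are case-sensitive community identifiers and are kept verbatim.

#' Identifier namespaces, in cascade-priority order
#'
#' The hierarchical matching order used throughout the package: InChIKey
#' outranks ChEBI, which outranks PubChem CID, then HMDB, BiGG and MetaNetX.
#' Fuzzy name matching sits below every identifier namespace.
#'
#' @format character vector of column names used in registry tables.
#' @export
ID_NAMESPACES <- c("inchikey", "chebi", "pubchem_cid", "hmdb", "bigg", "metanetx")

#' Match levels in decreasing confidence order
#' @format character vector; `FUZZY_NAME` is always last.
#' @export
MATCH_LEVELS <- c("INCHIKEY", "CHEBI", "PUBCHEM", "HMDB", "BIGG", "METANETX", "FUZZY_NAME")

#' Registry source labels
#' @format character vector of the recognized source enums.
#' @export
SOURCE_LABELS <- c("CURATED", "GUT_GSMM_A", "GUT_GSMM_B", "HUMAN_GSMM", "OTHER")

#' Test whether strings are well-formed InChIKeys
#'
#' A valid InChIKey is 27 characters in hyphenated 14-10-1 blocks of
#' uppercase letters (connectivity block, proton/stereo block, flag).
#'
#' @param x character vector.
#' @return logical vector; `NA` inputs give `FALSE`.
#' @examples
#' is_valid_inchikey("BSYNRYMUTXBXSQ-UHFFFAOYSA-N")
#' @export
is_valid_inchikey <- function(x) {
  !is.na(x) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

canonical_inchikey <- function(x) {
  out <- toupper(trimws(x))
  out[!is.na(out) & out == ""] <- NA_character_
  bad <- !is.na(out) & !is_valid_inchikey(out)
  if (any(bad)) {
    warning(sum(bad), " value(s) dropped: not 14-10-1 InChIKey format", call. = FALSE)
    out[bad] <- NA_character_
  }
  out
}

canonical_chebi <- function(x) {
  out <- trimws(x)
  out[!is.na(out) & out == ""] <- NA_character_
  has <- !is.na(out)
  out[has] <- sub("^(chebi[:_]\\s*)+", "", out[has], ignore.case = TRUE)
  num <- has & grepl("^[0-9]+$", out)
  out[num] <- paste0("CHEBI:", out[num])
  bad <- has & !grepl("^CHEBI:[0-9]+$", out)
  if (any(bad)) {
    warning(sum(bad), " value(s) dropped: not a numeric ChEBI id", call. = FALSE)
    out[bad] <- NA_character_
  }
  out
}

canonical_pubchem <- function(x) {
  out <- trimws(x)
  out[!is.na(out) & out == ""] <- NA_character_
  has <- !is.na(out)
  out[has] <- sub("^CID:?\\s*", "", out[has], ignore.case = TRUE)
  bad <- has & !grepl("^[1-9][0-9]*$", out)
  if (any(bad)) {
    warning(sum(bad), " value(s) dropped: PubChem CID must be a positive integer",
            call. = FALSE)
    out[bad] <- NA_character_
  }
  out
}

canonical_hmdb <- function(x) {
  out <- toupper(trimws(x))
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

canonical_plain <- function(x) {
  out <- trimws(x)
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

# Apply every namespace's canonical-case rule to the matching columns of a
# registry entry table; returns list(entries, changes) where changes records
# original -> canonical rewrites for the provenance log.
canonicalize_identifier_columns <- function(entries) {
  canon <- list(inchikey = canonical_inchikey, chebi = canonical_chebi,
                pubchem_cid = canonical_pubchem, hmdb = canonical_hmdb,
                bigg = canonical_plain, metanetx = canonical_plain)
  changes <- list()
  for (ns in names(canon)) {
    if (!ns %in% names(entries)) next
    before <- entries[[ns]]
    after <- canon[[ns]](before)
    diff <- which(!is.na(before) & (is.na(after) | before != after))
    if (length(diff)) {
      changes[[ns]] <- data.frame(row = diff, namespace = ns,
                                  original = before[diff],
                                  canonical = after[diff],
                                  stringsAsFactors = FALSE)
    }
    entries[[ns]] <- after
  }
  list(entries = entries,
       changes = if (length(changes)) do.call(rbind, changes)
                 else data.frame(row = integer(), namespace = character(),
                                 original = character(), canonical = character(),
                                 stringsAsFactors = FALSE))
}
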