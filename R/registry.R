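## Metabolite registries: tabular + SBML readers, de-duplication, filtering.

#' Columns of the registry tabular dialect
#'
#' UTF-8 TSV, header required, empty string = missing.  `local_id` is
#' optional on input (row-derived ids are generated); all other columns are
#' created as missing when absent.
#' @format character vector of canonical column names.
#' @export
REGISTRY_COLUMNS <- c("local_id", "name", "synonyms", "inchikey", "chebi",
                      "pubchem_cid", "hmdb", "bigg", "metanetx", "smiles",
                      "is_substrate", "is_modeling_artifact", "chemont_class")

new_registry <- function(entries, source_label, provenance = "") {
  source_label <- match.arg(source_label, SOURCE_LABELS)
  for (col in REGISTRY_COLUMNS) {
    if (!col %in% names(entries)) {
      entries[[col]] <- if (col %in% c("is_substrate", "is_modeling_artifact")) {
        rep(FALSE, nrow(entries))
      } else rep(NA_character_, nrow(entries))
    }
  }
  entries <- entries[, REGISTRY_COLUMNS, drop = FALSE]
  entries$is_substrate <- parse_flag(entries$is_substrate)
  entries$is_modeling_artifact <- parse_flag(entries$is_modeling_artifact)
  rownames(entries) <- NULL
  structure(list(source_label = source_label, entries = entries,
                 provenance = provenance),
            class = "metabolite_registry")
}

parse_flag <- function(x) {
  if (is.logical(x)) { x[is.na(x)] <- FALSE; return(x) }
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes", "y")
  out
}

validate_registry <- function(reg) {
  stopifnot(inherits(reg, "metabolite_registry"))
  e <- reg$entries
  dup <- e$local_id[duplicated(e$local_id)]
  if (length(dup)) {
    stop("duplicate local_id in ", reg$source_label, " registry: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  empty <- which(is.na(e$name) | !nzchar(trimws(e$name)))
  if (length(empty)) {
    stop("empty metabolite name at row(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  invisible(reg)
}

#' @export
print.metabolite_registry <- function(x, ...) {
  cat("<metabolite_registry> source:", x$source_label,
      "| entries:", nrow(x$entries), "\n")
  for (ns in ID_NAMESPACES) {
    n <- sum(!is.na(x$entries[[ns]]))
    if (n > 0) cat(sprintf("  %-12s %d\n", ns, n))
  }
  invisible(x)
}

#' Read a metabolite registry from a TSV file
#'
#' Parses the registry tabular dialect (see [REGISTRY_COLUMNS]): one entry
#' per data row, identifiers folded to canonical case (uppercase InChIKey,
#' `CHEBI:`-prefixed ChEBI, bare positive-integer PubChem CID, uppercase
#' HMDB).  Case-folding rewrites are recorded in the registry's provenance
#' log (`attr(reg, "canonicalization_log")`).
#'
#' @param path TSV file with a header row containing at least `name`.
#' @param source_label one of `r paste(SOURCE_LABELS, collapse = ", ")`.
#' @return a `metabolite_registry`.
#' @export
read_registry_table <- function(path, source_label) {
  df <- read_tsv_chr(path)
  if (!"name" %in% names(df)) {
    stop("registry file ", path, " has no 'name' column in its header",
         call. = FALSE)
  }
  if (nrow(df) > 0 && !"local_id" %in% names(df)) {
    df$local_id <- sprintf("row%05d", seq_len(nrow(df)))
  }
  cc <- canonicalize_identifier_columns(df)
  reg <- new_registry(cc$entries, source_label, provenance = path)
  validate_registry(reg)
  attr(reg, "canonicalization_log") <- cc$changes
  reg
}

#' Write a metabolite registry to TSV
#'
#' Inverse of [read_registry_table()]: all populated fields round-trip.
#'
#' @param reg a `metabolite_registry`.
#' @param path output file path.
#' @export
write_registry_table <- function(reg, path) {
  validate_registry(reg)
  e <- reg$entries
  e$is_substrate <- ifelse(e$is_substrate, "true", "false")
  e$is_modeling_artifact <- ifelse(e$is_modeling_artifact, "true", "false")
  write_tsv_chr(e, path)
}

#' Default compartment-suffix list for SBML species ids
#'
#' BiGG-style species ids carry a trailing compartment tag
#' (`glc__D_c`, `glc__D[e]`, ...).  Stripping the tag yields the base
#' species key under which compartment-duplicated species are collapsed.
#' @return character vector of suffixes, longest first.
#' @export
default_compartment_suffixes <- function() {
  comp <- c("c", "e", "p", "m", "x", "r", "g", "n", "l", "v", "u", "i")
  c(paste0("[", comp, "]"), paste0("_", comp))
}

strip_compartment_suffix <- function(id, suffixes = default_compartment_suffixes()) {
  out <- id
  for (suf in suffixes) {
    hit <- endsWith(out, suf)
    out[hit] <- substring(out[hit], 1L, nchar(out[hit]) - nchar(suf))
  }
  out
}

## CURIE / identifiers.org URI fragments recognized in SBML annotations.
.curie_map <- list(
  inchikey    = "inchikey[:/]([A-Za-z-]+)",
  chebi       = "chebi[:/]CHEBI[:%3A]+([0-9]+)",
  pubchem_cid = "pubchem\\.compound[:/]([0-9]+)",
  hmdb        = "hmdb[:/](HMDB[0-9]+)",
  bigg        = "bigg\\.metabolite[:/]([A-Za-z0-9_]+)",
  metanetx    = "metanetx\\.chemical[:/]([A-Za-z0-9_]+)"
)

#' Read the species list of an SBML model as a metabolite registry
#'
#' Species ids are stripped of their compartment suffix and species sharing
#' a base key are collapsed into one entry; CURIE-style cross-references in
#' the species annotation blocks (identifiers.org URIs) populate the
#' identifier columns.  SBML Levels 2 and 3 are supported; namespaces are
#' ignored so vendor dialects parse uniformly.
#'
#' @param path SBML file.
#' @param source_label registry source enum.
#' @param suffixes compartment suffixes to strip, see
#'   [default_compartment_suffixes()].
#' @return a `metabolite_registry`; the number of id-less species skipped is
#'   reported as a warning and stored in `attr(reg, "skipped")`.
#' @export
read_sbml_species <- function(path, source_label,
                              suffixes = default_compartment_suffixes()) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  sp <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  skipped <- 0L
  rows <- list()
  for (node in sp) {
    id <- xml2::xml_attr(node, "id")
    if (is.na(id) || !nzchar(id)) { skipped <- skipped + 1L; next }
    id <- sub("^M_", "", id)
    nm <- xml2::xml_attr(node, "name")
    base <- strip_compartment_suffix(id, suffixes)
    ids <- sbml_species_identifiers(node)
    rows[[length(rows) + 1L]] <- c(list(base = base,
                                        name = if (is.na(nm) || !nzchar(nm)) base else nm),
                                   ids)
  }
  if (skipped > 0) warning(skipped, " species without id skipped", call. = FALSE)
  if (!length(rows)) {
    reg <- new_registry(data.frame(local_id = character(), name = character(),
                                   stringsAsFactors = FALSE),
                        source_label, provenance = path)
    attr(reg, "skipped") <- skipped
    return(reg)
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r[c("base", "name", ID_NAMESPACES)], stringsAsFactors = FALSE,
                  optional = TRUE)
  }))
  names(df) <- c("local_id", "name", ID_NAMESPACES)
  ## collapse compartment-duplicated species: same base key -> one entry,
  ## identifiers unioned (first non-missing wins per namespace)
  collapsed <- lapply(split(df, factor(df$local_id, levels = unique(df$local_id))),
                      function(g) {
    out <- g[1, , drop = FALSE]
    for (col in c("name", ID_NAMESPACES)) {
      v <- g[[col]][!is.na(g[[col]])]
      out[[col]] <- if (length(v)) v[[1]] else NA_character_
    }
    out
  })
  df <- do.call(rbind, collapsed)
  cc <- canonicalize_identifier_columns(df)
  reg <- new_registry(cc$entries, source_label, provenance = path)
  validate_registry(reg)
  attr(reg, "skipped") <- skipped
  attr(reg, "canonicalization_log") <- cc$changes
  reg
}

sbml_species_identifiers <- function(node) {
  res <- xml2::xml_find_all(node, ".//*[local-name()='li']")
  uris <- xml2::xml_attr(res, "resource")
  uris <- uris[!is.na(uris)]
  out <- setNames(rep(NA_character_, length(ID_NAMESPACES)), ID_NAMESPACES)
  for (ns in names(.curie_map)) {
    m <- regmatches(uris, regexec(.curie_map[[ns]], uris))
    hit <- vapply(m, length, integer(1)) == 2L
    if (any(hit)) out[[ns]] <- m[[which(hit)[1]]][2]
  }
  as.list(out)
}

#' De-duplicate a registry by shared identifiers or identical names
#'
#' Entries sharing any identifier (same namespace, same canonical value) or
#' the same normalized name are merged transitively (connected components of
#' the share graph) into one entry whose identifiers are the union of the
#' group's.  When two members of a merge group disagree on a namespace's
#' value, the value kept comes from the member with the highest-priority
#' identifier evidence (InChIKey outranks ChEBI, and so on down the
#' cascade); every conflict is logged.
#'
#' @param reg a validated `metabolite_registry`.
#' @param rules normalization rule table used for name comparison.
#' @return the merged registry, with `attr(,"merge_log")` (one row per
#'   merged-away entry) and `attr(,"conflict_log")`.
#' @export
deduplicate_registry <- function(reg, rules = default_rule_table()) {
  validate_registry(reg)
  e <- reg$entries
  n <- nrow(e)
  if (n <= 1) {
    attr(reg, "merge_log") <- empty_merge_log()
    attr(reg, "conflict_log") <- empty_conflict_log()
    return(reg)
  }
  keys <- c(lapply(ID_NAMESPACES, function(ns) {
    ifelse(is.na(e[[ns]]), NA_character_, paste0(ns, "=", e[[ns]]))
  }), list(paste0("name=", name_match_key(e$name, rules))))
  ## connected components over entries linked by any shared key
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  edges <- integer(0)
  for (k in keys) {
    grp <- split(seq_len(n)[!is.na(k)], k[!is.na(k)])
    for (idx in grp) {
      if (length(idx) > 1) edges <- c(edges, rbind(idx[-length(idx)], idx[-1]))
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  merge_log <- empty_merge_log()
  conflict_log <- empty_conflict_log()
  kept <- logical(n)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) { kept[idx] <- TRUE; next }
    ## representative = first row; identifier values resolved by cascade
    ## priority of each member's best identifier, then row order
    best_level <- vapply(idx, function(i) {
      lv <- which(!is.na(unlist(e[i, ID_NAMESPACES], use.names = FALSE)))
      if (length(lv)) min(lv) else length(ID_NAMESPACES) + 1L
    }, integer(1))
    ord <- idx[order(best_level, idx)]
    rep_i <- idx[1]
    kept[rep_i] <- TRUE
    for (ns in ID_NAMESPACES) {
      vals <- e[[ns]][ord]
      vals <- vals[!is.na(vals)]
      if (length(unique(vals)) > 1) {
        conflict_log <- rbind(conflict_log, data.frame(
          kept_local_id = e$local_id[rep_i], namespace = ns,
          kept_value = vals[[1]],
          discarded_values = paste(setdiff(unique(vals), vals[[1]]), collapse = ";"),
          stringsAsFactors = FALSE))
      }
      e[[ns]][rep_i] <- if (length(vals)) vals[[1]] else NA_character_
    }
    syn <- unique(c(strsplit(e$synonyms[rep_i] %||% NA_character_, ";")[[1]],
                    e$name[setdiff(idx, rep_i)]))
    syn <- syn[!is.na(syn) & nzchar(syn)]
    if (length(syn)) e$synonyms[rep_i] <- paste(syn, collapse = ";")
    smiles <- e$smiles[idx]; smiles <- smiles[!is.na(smiles)]
    if (length(smiles)) e$smiles[rep_i] <- smiles[[1]]
    e$is_substrate[rep_i] <- any(e$is_substrate[idx])
    merge_log <- rbind(merge_log, data.frame(
      kept_local_id = e$local_id[rep_i],
      merged_local_id = e$local_id[setdiff(idx, rep_i)],
      merged_name = e$name[setdiff(idx, rep_i)],
      stringsAsFactors = FALSE))
  }
  out <- new_registry(e[kept, , drop = FALSE], reg$source_label, reg$provenance)
  attr(out, "merge_log") <- merge_log
  attr(out, "conflict_log") <- conflict_log
  out
}

empty_merge_log <- function() {
  data.frame(kept_local_id = character(), merged_local_id = character(),
             merged_name = character(), stringsAsFactors = FALSE)
}
empty_conflict_log <- function() {
  data.frame(kept_local_id = character(), namespace = character(),
             kept_value = character(), discarded_values = character(),
             stringsAsFactors = FALSE)
}

#' Default modeling-artifact name patterns
#'
#' GSMM species lists contain pseudo-metabolites with a modeling function
#' that are not real compounds (macromolecule pools, biomass sinks).  The
#' default exclusion list matches these case-insensitively as whole words.
#' @return character vector of patterns.
#' @export
default_artifact_patterns <- function() {
  c("RNA", "DNA", "tRNA", "protein", "biomass", "peptide chain")
}

#' Remove modeling-artifact pseudo-metabolites from a registry
#'
#' Entries whose name matches one of `patterns` (case-insensitive,
#' whole-word) are flagged `is_modeling_artifact` and removed.  Removal is
#' strictly name-driven: an entry carrying an InChIKey is removed only when
#' its name matches a pattern, never on structural grounds.
#'
#' @param reg a `metabolite_registry`.
#' @param patterns non-empty character vector of name patterns.
#' @return filtered registry with `attr(,"exclusion_log")` listing removed
#'   entries and `attr(,"n_excluded")`.
#' @export
exclude_modeling_artifacts <- function(reg, patterns = default_artifact_patterns()) {
  validate_registry(reg)
  if (!length(patterns)) stop("patterns must be non-empty", call. = FALSE)
  rx <- paste0("\\b(", paste(vapply(patterns, function(p)
    gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", p), character(1)), collapse = "|"), ")\\b")
  hit <- grepl(rx, reg$entries$name, ignore.case = TRUE, perl = TRUE)
  log <- data.frame(local_id = reg$entries$local_id[hit],
                    name = reg$entries$name[hit], stringsAsFactors = FALSE)
  e <- reg$entries
  e$is_modeling_artifact[hit] <- TRUE
  out <- new_registry(e[!hit, , drop = FALSE], reg$source_label, reg$provenance)
  attr(out, "exclusion_log") <- log
  attr(out, "n_excluded") <- sum(hit)
  out
}
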