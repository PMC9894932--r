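## Curated evidence of microbial origin.
##
## Three evidence types support a metabolite's gut-microbial origin:
## production by human faecal bacteria grown in vitro, reduced
## concentrations upon antibiotic treatment, and reduced concentrations in
## germ-free animals relative to conventional animals.  This module loads
## literature-derived evidence records and computes the per-metabolite
## evidence profiles, the one/two/three-types-of-evidence partition, the
## combined-evidence filter, chemical-class summaries and concentration
## medians.

#' Evidence types of microbial origin
#' @format character vector of the three evidence enums.
#' @export
EVIDENCE_TYPES <- c("FAECAL_IN_VITRO", "ANTIBIOTIC_REDUCTION", "GERMFREE_REDUCTION")

#' Biospecimen enums
#' @format character vector.
#' @export
BIOSPECIMENS <- c("BLOOD", "URINE", "FAECES", "GUT_CONTENT", "CULTURE_MEDIUM")

## Alias tables: literature-derived tables are vocabulary-heterogeneous.
.evidence_aliases <- c(
  "faecal_in_vitro" = "FAECAL_IN_VITRO", "faecal in vitro" = "FAECAL_IN_VITRO",
  "fecal in vitro" = "FAECAL_IN_VITRO", "in vitro" = "FAECAL_IN_VITRO",
  "faecal" = "FAECAL_IN_VITRO", "produced by faecal bacteria" = "FAECAL_IN_VITRO",
  "antibiotic_reduction" = "ANTIBIOTIC_REDUCTION",
  "antibiotic reduction" = "ANTIBIOTIC_REDUCTION",
  "antibiotic" = "ANTIBIOTIC_REDUCTION", "antibiotics" = "ANTIBIOTIC_REDUCTION",
  "germfree_reduction" = "GERMFREE_REDUCTION", "germfree" = "GERMFREE_REDUCTION",
  "germ-free" = "GERMFREE_REDUCTION", "germ free" = "GERMFREE_REDUCTION",
  "germ-free reduction" = "GERMFREE_REDUCTION")

.biospecimen_aliases <- c(
  "blood" = "BLOOD", "plasma" = "BLOOD", "serum" = "BLOOD",
  "urine" = "URINE",
  "faeces" = "FAECES", "feces" = "FAECES", "stool" = "FAECES",
  "faecal sample" = "FAECES",
  "gut_content" = "GUT_CONTENT", "gut content" = "GUT_CONTENT",
  "caecal content" = "GUT_CONTENT", "cecal content" = "GUT_CONTENT",
  "intestinal content" = "GUT_CONTENT",
  "culture_medium" = "CULTURE_MEDIUM", "culture medium" = "CULTURE_MEDIUM",
  "medium" = "CULTURE_MEDIUM", "supernatant" = "CULTURE_MEDIUM")

resolve_alias <- function(x, table, what) {
  key <- tolower(collapse_ws(x))
  direct <- match(x, unname(table))           # already canonical
  via <- unname(table[key])
  out <- ifelse(!is.na(direct), unname(table)[direct], via)
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop("unknown ", what, " value(s) at row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Load a curated evidence table
#'
#' TSV with columns `metabolite_id`, `evidence_type`, `publication`, and
#' optionally `organism`, `biospecimen`, `substrate`, `antibiotic`,
#' `bacterial_source`.  Evidence-type and biospecimen strings are resolved
#' through alias tables (e.g. `"plasma"` and `"serum"` map to `BLOOD`,
#' `"germfree"` to `GERMFREE_REDUCTION`); unresolvable values raise a
#' row-numbered error.  Substrate, antibiotic and bacterial-source fields
#' are kept only for the evidence types that record them (substrates for in
#' vitro and in vivo challenge studies, antibiotics for antibiotic studies,
#' bacterial source for germ-free conventionalization studies).
#'
#' @param path evidence TSV.
#' @return `data.frame` of validated evidence records.
#' @export
load_evidence_table <- function(path) {
  df <- read_tsv_chr(path)
  need <- c("metabolite_id", "evidence_type")
  if (!all(need %in% names(df))) {
    stop("evidence table ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (col in c("publication", "organism", "biospecimen", "substrate",
                "antibiotic", "bacterial_source")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_character_, nrow(df))
  }
  if (nrow(df) == 0) return(df[, c(need, "publication", "organism", "biospecimen",
                                   "substrate", "antibiotic", "bacterial_source")])
  df$evidence_type <- resolve_alias(df$evidence_type, .evidence_aliases,
                                    "evidence type")
  has_bs <- !is.na(df$biospecimen)
  df$biospecimen[has_bs] <- resolve_alias(df$biospecimen[has_bs],
                                          .biospecimen_aliases, "biospecimen")
  ## fields recorded only for the relevant evidence types
  df$antibiotic[df$evidence_type != "ANTIBIOTIC_REDUCTION"] <- NA_character_
  df$bacterial_source[df$evidence_type != "GERMFREE_REDUCTION"] <- NA_character_
  df[, c("metabolite_id", "evidence_type", "publication", "organism",
         "biospecimen", "substrate", "antibiotic", "bacterial_source")]
}

#' Per-metabolite evidence profiles
#'
#' Aggregates evidence records into one profile per distinct metabolite:
#' per-type record counts, total record count, and the set of evidence
#' types present (types with at least one record).  Record counts are
#' conserved: the `record_count` column sums to the number of input
#' records.
#'
#' @param records evidence records as from [load_evidence_table()].
#' @return `data.frame` with columns `metabolite_id`,
#'   `n_faecal_in_vitro`, `n_antibiotic_reduction`, `n_germfree_reduction`,
#'   `record_count`, `n_types`.
#' @export
evidence_profiles <- function(records) {
  cols <- c(FAECAL_IN_VITRO = "n_faecal_in_vitro",
            ANTIBIOTIC_REDUCTION = "n_antibiotic_reduction",
            GERMFREE_REDUCTION = "n_germfree_reduction")
  if (nrow(records) == 0) {
    out <- data.frame(metabolite_id = character(), stringsAsFactors = FALSE)
    for (cl in cols) out[[cl]] <- integer()
    out$record_count <- integer(); out$n_types <- integer()
    return(out)
  }
  bad <- !records$evidence_type %in% names(cols)
  if (any(bad)) stop("unknown evidence type: ",
                     paste(unique(records$evidence_type[bad]), collapse = ", "),
                     call. = FALSE)
  tab <- table(factor(records$metabolite_id, levels = unique(records$metabolite_id)),
               factor(records$evidence_type, levels = names(cols)))
  out <- data.frame(metabolite_id = rownames(tab), stringsAsFactors = FALSE)
  for (i in seq_along(cols)) out[[cols[[i]]]] <- as.integer(tab[, i])
  out$record_count <- as.integer(rowSums(tab))
  out$n_types <- as.integer(rowSums(tab > 0))
  rownames(out) <- NULL
  out
}

#' Partition metabolites by their number of evidence types
#'
#' Every metabolite with at least one record falls in exactly one bucket
#' (supported by one, two, or all three types of evidence); bucket sizes
#' sum to the number of metabolites.
#'
#' @param profiles as from [evidence_profiles()].
#' @return list with `by_types` (named counts for `"1"`, `"2"`, `"3"`) and
#'   `n_metabolites`.
#' @export
venn_partition_by_evidence <- function(profiles) {
  if (any(profiles$n_types == 0)) {
    stop("profile(s) with zero evidence types: ",
         paste(profiles$metabolite_id[profiles$n_types == 0], collapse = ", "),
         call. = FALSE)
  }
  by_types <- vapply(1:3, function(k) sum(profiles$n_types == k), integer(1))
  names(by_types) <- as.character(1:3)
  list(by_types = by_types, n_metabolites = nrow(profiles))
}

#' Combined-evidence filter
#'
#' Selects metabolites produced by human faecal bacteria in vitro AND
#' showing reduced concentrations in vivo (upon antibiotic treatment OR in
#' germ-free animals).  These metabolites are expected to be largely or
#' exclusively produced by the gut microbiota.
#'
#' @param profiles as from [evidence_profiles()].
#' @return character vector of metabolite ids.
#' @export
combined_evidence_filter <- function(profiles) {
  keep <- profiles$n_faecal_in_vitro > 0 &
    (profiles$n_antibiotic_reduction > 0 | profiles$n_germfree_reduction > 0)
  profiles$metabolite_id[keep]
}

#' Load a chemical class-mapping table
#'
#' @param path TSV with columns `chemont_class`, `upper_level_class`.
#' @return named character vector mapping ChemOnt class to upper-level class.
#' @export
load_class_mapping <- function(path) {
  df <- read_tsv_chr(path)
  need <- c("chemont_class", "upper_level_class")
  if (!all(need %in% names(df))) {
    stop("class mapping ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  setNames(df$upper_level_class, df$chemont_class)
}

#' Per-class metabolite counts, total and by evidence type
#'
#' Counts metabolites (not records) per upper-level chemical class: a
#' per-type column counts the metabolites in that class having at least one
#' record of that type.  Metabolites whose class is absent from the mapping
#' are reported in an `"unmapped"` row with a warning, never dropped, so
#' totals always sum to the number of metabolites.
#'
#' @param profiles as from [evidence_profiles()].
#' @param classes `data.frame` with `metabolite_id`, `chemont_class`.
#' @param class_mapping optional named vector from [load_class_mapping()]
#'   collapsing ChemOnt classes to upper-level classes; when `NULL` the
#'   `chemont_class` labels are used directly.
#' @return `data.frame` with columns `class`, `total`,
#'   `n_faecal_in_vitro`, `n_antibiotic_reduction`, `n_germfree_reduction`,
#'   sorted by decreasing total.
#' @export
class_summary <- function(profiles, classes, class_mapping = NULL) {
  lab <- classes$chemont_class[match(profiles$metabolite_id, classes$metabolite_id)]
  if (!is.null(class_mapping)) {
    mapped <- unname(class_mapping[lab])
    unm <- !is.na(lab) & is.na(mapped)
    if (any(unm)) {
      warning(sum(unm), " metabolite(s) with unmapped ChemOnt class", call. = FALSE)
      mapped[unm] <- "unmapped"
    }
    lab <- mapped
  }
  miss <- is.na(lab)
  if (any(miss)) {
    warning(sum(miss), " metabolite(s) without class label reported as 'unmapped'",
            call. = FALSE)
    lab[miss] <- "unmapped"
  }
  agg <- lapply(split(seq_len(nrow(profiles)), lab), function(idx) {
    data.frame(total = length(idx),
               n_faecal_in_vitro = sum(profiles$n_faecal_in_vitro[idx] > 0),
               n_antibiotic_reduction = sum(profiles$n_antibiotic_reduction[idx] > 0),
               n_germfree_reduction = sum(profiles$n_germfree_reduction[idx] > 0))
  })
  out <- cbind(data.frame(class = names(agg), stringsAsFactors = FALSE),
               do.call(rbind, agg))
  out <- out[order(-out$total, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Unit conversion factors to nmol/L (volume basis) and nmol/g (mass basis).
.unit_factors <- list(
  volume = c("nmol/l" = 1, "umol/l" = 1e3, "µmol/l" = 1e3,
             "mmol/l" = 1e6, "mol/l" = 1e9, "pmol/l" = 1e-3),
  mass = c("nmol/g" = 1, "umol/g" = 1e3, "µmol/g" = 1e3,
           "mmol/g" = 1e6, "pmol/g" = 1e-3))

#' Load a concentration table
#'
#' TSV with columns `metabolite_id`, `biospecimen`, `analytical_method`
#' (`GC`, `LC` or `OTHER`), `value`, `unit`.  Values are converted to
#' nmol/L (volume-based units) or nmol/g (mass-based units, used for
#' faeces); the conversion factor applied to each row is logged in
#' `attr(,"unit_log")`.
#'
#' @param path concentration TSV.
#' @return `data.frame` with numeric `value` in canonical units and a
#'   `basis` column (`volume`/`mass`).
#' @export
load_concentration_table <- function(path) {
  df <- read_tsv_chr(path)
  need <- c("metabolite_id", "biospecimen", "value", "unit")
  if (!all(need %in% names(df))) {
    stop("concentration table ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"analytical_method" %in% names(df)) df$analytical_method <- "OTHER"
  df$analytical_method <- toupper(df$analytical_method)
  bad_m <- !df$analytical_method %in% c("GC", "LC", "OTHER")
  if (any(bad_m)) stop("unknown analytical_method: ",
                       paste(unique(df$analytical_method[bad_m]), collapse = ", "),
                       call. = FALSE)
  has_bs <- !is.na(df$biospecimen)
  df$biospecimen[has_bs] <- resolve_alias(df$biospecimen[has_bs],
                                          .biospecimen_aliases, "biospecimen")
  raw <- suppressWarnings(as.numeric(df$value))
  if (anyNA(raw)) stop("non-numeric concentration value at row(s): ",
                       paste(which(is.na(raw)), collapse = ", "), call. = FALSE)
  unit <- tolower(trimws(df$unit))
  basis <- ifelse(unit %in% names(.unit_factors$volume), "volume",
                  ifelse(unit %in% names(.unit_factors$mass), "mass", NA))
  if (anyNA(basis)) stop("unknown unit(s): ",
                         paste(unique(unit[is.na(basis)]), collapse = ", "),
                         call. = FALSE)
  factor <- ifelse(basis == "volume", .unit_factors$volume[unit],
                   .unit_factors$mass[unit])
  out <- df[, c("metabolite_id", "biospecimen", "analytical_method")]
  out$value <- raw * factor
  if (any(out$value < 0)) stop("negative concentration value at row(s): ",
                               paste(which(out$value < 0), collapse = ", "),
                               call. = FALSE)
  out$basis <- basis
  out$original_unit <- df$unit
  attr(out, "unit_log") <- data.frame(row = seq_len(nrow(df)),
                                      original_unit = df$unit, factor = unname(factor),
                                      stringsAsFactors = FALSE)
  out
}

#' Median concentration per metabolite and biospecimen
#'
#' Aggregated concentrations are summarized as the median of the group's
#' values (even-sized groups: arithmetic mean of the two central values).
#' All values within a group must share a unit basis — mixing volume-based
#' (nmol/L) and mass-based (nmol/g) values in one group is an error naming
#' the group.
#'
#' @param conc as from [load_concentration_table()].
#' @return `data.frame` with `metabolite_id`, `biospecimen`,
#'   `median_value`, `basis`, `n`.
#' @export
concentration_summary <- function(conc) {
  key <- paste(conc$metabolite_id, conc$biospecimen, sep = "\r")
  groups <- split(seq_len(nrow(conc)), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(idx) {
    b <- unique(conc$basis[idx])
    if (length(b) > 1) {
      stop("mixed incompatible units in group ",
           conc$metabolite_id[idx[1]], " / ", conc$biospecimen[idx[1]],
           call. = FALSE)
    }
    data.frame(metabolite_id = conc$metabolite_id[idx[1]],
               biospecimen = conc$biospecimen[idx[1]],
               median_value = stats::median(conc$value[idx]),
               basis = b, n = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load precursor links
#'
#' Substrates recorded in experiments are assumed precursors of the
#' microbial metabolites formed; the relation is many-to-many (one
#' precursor can yield several metabolites and vice versa).
#'
#' @param path TSV with columns `precursor`, `metabolite_id`, optionally
#'   `context`.
#' @return validated `data.frame`.
#' @export
load_precursor_links <- function(path) {
  df <- read_tsv_chr(path)
  need <- c("precursor", "metabolite_id")
  if (!all(need %in% names(df))) {
    stop("precursor table ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"context" %in% names(df)) df$context <- NA_character_
  df
}
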