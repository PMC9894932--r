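## Packaged catalog fixtures.

#' Combined-evidence metabolite catalog
#'
#' The published listing of metabolites whose microbial origin is
#' simultaneously supported by in vitro production by human faecal
#' bacteria and by an in vivo concentration reduction (under antibiotics
#' or in germ-free animals): 108 metabolites from 17 upper-level chemical
#' classes.  The two evidence flags are implied by inclusion in the
#' listing; which in vivo type(s) each metabolite carries is not resolved
#' at this granularity, so [catalog_evidence_records()] represents the in
#' vivo evidence as a single antibiotic-reduction record.
#'
#' @return `data.frame` with `metabolite_id`, `name`, `upper_level_class`,
#'   `has_faecal_in_vitro`, `has_in_vivo_reduction`.
#' @export
combined_evidence_catalog <- function() {
  read_tsv_chr(system.file("extdata", "combined_evidence_catalog.tsv",
                           package = "microexposome", mustWork = TRUE))
}

#' Expand the combined-evidence catalog into evidence records
#'
#' One faecal-in-vitro record plus one in vivo (antibiotic-reduction)
#' record per catalog metabolite, suitable for [evidence_profiles()] and
#' [combined_evidence_filter()].
#'
#' @param catalog as returned by [combined_evidence_catalog()].
#' @return evidence-record `data.frame`.
#' @export
catalog_evidence_records <- function(catalog = combined_evidence_catalog()) {
  rbind(
    data.frame(metabolite_id = catalog$metabolite_id,
               evidence_type = "FAECAL_IN_VITRO",
               publication = NA_character_, organism = "bacteria",
               biospecimen = "CULTURE_MEDIUM", substrate = NA_character_,
               antibiotic = NA_character_, bacterial_source = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(metabolite_id = catalog$metabolite_id,
               evidence_type = "ANTIBIOTIC_REDUCTION",
               publication = NA_character_, organism = NA_character_,
               biospecimen = NA_character_, substrate = NA_character_,
               antibiotic = NA_character_, bacterial_source = NA_character_,
               stringsAsFactors = FALSE))
}

#' Per-class metabolite counts of the curated database
#'
#' The published per-upper-level-class breakdown of the curated microbial
#' metabolites: 33 classes, 457 metabolites in total, with per-evidence-type
#' metabolite counts (257 produced by faecal bacteria, 209 reduced by
#' antibiotics, 170 reduced in germ-free animals).
#'
#' @return `data.frame` with `upper_level_class`, `total`,
#'   `n_faecal_in_vitro`, `n_antibiotic_reduction`, `n_germfree_reduction`
#'   (integer columns).
#' @export
class_counts_catalog <- function() {
  df <- read_tsv_chr(system.file("extdata", "class_counts_catalog.tsv",
                                 package = "microexposome", mustWork = TRUE))
  for (col in c("total", "n_faecal_in_vitro", "n_antibiotic_reduction",
                "n_germfree_reduction")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}
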