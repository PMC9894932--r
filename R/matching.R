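## Cross-registry identity resolution.
##
## Metabolite lists from different sources are matched by a hierarchical
## identifier cascade — InChIKey first, then ChEBI, PubChem CID, HMDB,
## BiGG, MetaNetX — with "leftover" semantics: an entry matched at one
## level is removed from consideration at all lower levels.  Entries that
## match at no identifier level fall through to fuzzy matching on
## normalized names; fuzzy candidates below similarity 1.0 are born with
## status REVIEW and are merged only when a review-decisions file accepts
## them, mirroring a manual-checking step.

level_for_namespace <- c(inchikey = "INCHIKEY", chebi = "CHEBI",
                         pubchem_cid = "PUBCHEM", hmdb = "HMDB",
                         bigg = "BIGG", metanetx = "METANETX")

empty_matches <- function() {
  data.frame(registry_a = character(), id_a = character(), name_a = character(),
             registry_b = character(), id_b = character(), name_b = character(),
             level = character(), score = numeric(), status = character(),
             stringsAsFactors = FALSE)
}

#' Hierarchical identifier matching between two registries
#'
#' For each identifier namespace in cascade order, entries of the two
#' registries sharing a canonical identifier value are matched at that
#' level and removed from consideration at lower levels.  Every entry
#' appears in at most one identifier-level match; matches are one-to-one
#' (value collisions within a registry are paired in `local_id` order) and
#' the output is independent of entry order.  Identifier-level matches are
#' always `ACCEPTED` with score 1.  Matched pairs disagreeing in a
#' lower-priority namespace are recorded in `attr(,"conflict_log")`.
#'
#' @param reg_a,reg_b validated, de-duplicated `metabolite_registry`
#'   objects.
#' @param skeleton use only the 14-character InChIKey connectivity block at
#'   the `INCHIKEY` level (reduced-confidence structural matching);
#'   default `FALSE` matches the full 27-character key.
#' @return match `data.frame`; leftover (unmatched) entry ids are in
#'   `attr(,"leftover_a")` / `attr(,"leftover_b")`.
#' @export
cascade_match <- function(reg_a, reg_b, skeleton = FALSE) {
  validate_registry(reg_a); validate_registry(reg_b)
  ea <- reg_a$entries; eb <- reg_b$entries
  free_a <- setNames(rep(TRUE, nrow(ea)), ea$local_id)
  free_b <- setNames(rep(TRUE, nrow(eb)), eb$local_id)
  matches <- list()
  conflicts <- list()
  for (ns in names(level_for_namespace)) {
    va <- ea[[ns]]; vb <- eb[[ns]]
    if (ns == "inchikey" && skeleton) {
      va <- substr(va, 1, 14); vb <- substr(vb, 1, 14)
    }
    ia <- which(free_a & !is.na(va))
    ib <- which(free_b & !is.na(vb))
    if (!length(ia) || !length(ib)) next
    shared <- intersect(va[ia], vb[ib])
    for (val in sort(shared)) {
      ca <- ia[va[ia] == val]; ca <- ca[order(ea$local_id[ca])]
      cb <- ib[vb[ib] == val]; cb <- cb[order(eb$local_id[cb])]
      k <- min(length(ca), length(cb))
      for (j in seq_len(k)) {
        i <- ca[j]; m <- cb[j]
        matches[[length(matches) + 1L]] <- data.frame(
          registry_a = reg_a$source_label, id_a = ea$local_id[i],
          name_a = ea$name[i],
          registry_b = reg_b$source_label, id_b = eb$local_id[m],
          name_b = eb$name[m],
          level = level_for_namespace[[ns]], score = 1, status = "ACCEPTED",
          stringsAsFactors = FALSE)
        free_a[i] <- FALSE; free_b[m] <- FALSE
        ## lower-priority namespaces disagreeing on this matched pair
        for (ns2 in names(level_for_namespace)) {
          x <- ea[[ns2]][i]; y <- eb[[ns2]][m]
          if (!is.na(x) && !is.na(y) && x != y) {
            conflicts[[length(conflicts) + 1L]] <- data.frame(
              id_a = ea$local_id[i], id_b = eb$local_id[m],
              matched_level = level_for_namespace[[ns]],
              namespace = ns2, value_a = x, value_b = y,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(matches)) do.call(rbind, matches) else empty_matches()
  out <- out[order(match(out$level, MATCH_LEVELS), out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "leftover_a") <- ea$local_id[free_a]
  attr(out, "leftover_b") <- eb$local_id[free_b]
  attr(out, "conflict_log") <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(id_a = character(), id_b = character(), matched_level = character(),
               namespace = character(), value_a = character(), value_b = character(),
               stringsAsFactors = FALSE)
  out
}

token_sort <- function(x) {
  vapply(strsplit(x, " ", fixed = TRUE),
         function(t) paste(sort(t), collapse = " "), character(1))
}

# Normalized indel similarity between two string vectors (cross matrix):
# 1 - d_indel / (nchar(a) + nchar(b)), where d_indel is the edit distance
# with insertions and deletions costing 1 and substitutions disallowed
# (cost 2 = delete + insert).
indel_similarity_matrix <- function(a, b) {
  d <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))
  den <- outer(nchar(a), nchar(b), "+")
  s <- 1 - d / den
  s[den == 0] <- 1
  s
}

#' Fuzzy name matching between leftover entries
#'
#' Candidate pairs are scored by normalized indel similarity on normalized
#' names with token-sort preprocessing; pairs scoring at or above
#' `threshold` are resolved one-to-one greedily by descending score (ties
#' broken lexicographically by the two names).  Pairs whose names are equal
#' after normalization (including the terminal carboxylate "-ate"/"-ic
#' acid" equivalence) score 1.0 and are `ACCEPTED`; every other selected
#' pair has status `REVIEW` and is merged downstream only on explicit
#' acceptance.  All scored candidates (selected or not) are kept in
#' `attr(,"candidates")` for the review file.
#'
#' @param leftover_a,leftover_b `data.frame`s of unmatched entries (columns
#'   `local_id`, `name`), typically the registries subset by
#'   `attr(cascade_match(...), "leftover_a")`.
#' @param source_a,source_b source labels for the output.
#' @param rules normalization rule table.
#' @param threshold similarity threshold in \\[0, 1\\]; default 0.92.
#' @return match `data.frame` of selected pairs.
#' @export
fuzzy_match_names <- function(leftover_a, leftover_b,
                              source_a = "OTHER", source_b = "OTHER",
                              rules = default_rule_table(), threshold = 0.92) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]", call. = FALSE)
  }
  out <- empty_matches()
  attr(out, "candidates") <- empty_matches()
  if (nrow(leftover_a) == 0 || nrow(leftover_b) == 0) return(out)
  key_a <- name_match_key(leftover_a$name, rules)
  key_b <- name_match_key(leftover_b$name, rules)
  ts_a <- token_sort(key_a); ts_b <- token_sort(key_b)
  sim <- indel_similarity_matrix(ts_a, ts_b)
  sim[key_a == rep(key_b, each = nrow(leftover_a))] <- 1
  idx <- which(sim >= threshold, arr.ind = TRUE)
  if (!nrow(idx)) return(out)
  cand <- data.frame(
    registry_a = source_a, id_a = leftover_a$local_id[idx[, 1]],
    name_a = leftover_a$name[idx[, 1]],
    registry_b = source_b, id_b = leftover_b$local_id[idx[, 2]],
    name_b = leftover_b$name[idx[, 2]],
    level = "FUZZY_NAME", score = sim[idx],
    status = "REVIEW", stringsAsFactors = FALSE)
  cand$status[cand$score >= 1] <- "ACCEPTED"
  cand <- cand[order(-cand$score, cand$name_a, cand$name_b), , drop = FALSE]
  ## greedy one-to-one assignment by descending score
  used_a <- character(0); used_b <- character(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$id_a[i] %in% used_a || cand$id_b[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, cand$id_a[i]); used_b <- c(used_b, cand$id_b[i])
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL; rownames(cand) <- NULL
  attr(out, "candidates") <- cand
  out
}

#' Match two registries by the full cascade
#'
#' Convenience wrapper: identifier cascade first, then fuzzy matching on
#' the leftovers.
#'
#' @inheritParams cascade_match
#' @inheritParams fuzzy_match_names
#' @return combined match `data.frame` with the fuzzy `attr(,"candidates")`
#'   and cascade `attr(,"conflict_log")` carried over.
#' @export
match_registries <- function(reg_a, reg_b, rules = default_rule_table(),
                             threshold = 0.92, skeleton = FALSE) {
  casc <- cascade_match(reg_a, reg_b, skeleton = skeleton)
  la <- reg_a$entries[reg_a$entries$local_id %in% attr(casc, "leftover_a"), ,
                      drop = FALSE]
  lb <- reg_b$entries[reg_b$entries$local_id %in% attr(casc, "leftover_b"), ,
                      drop = FALSE]
  fuz <- fuzzy_match_names(la, lb, reg_a$source_label, reg_b$source_label,
                           rules = rules, threshold = threshold)
  out <- rbind(casc, fuz)
  rownames(out) <- NULL
  attr(out, "candidates") <- attr(fuz, "candidates")
  attr(out, "conflict_log") <- attr(casc, "conflict_log")
  out
}

venn_source_of <- function(source_label) {
  c(CURATED = "CURATED", GUT_GSMM_A = "GUT_GSMM", GUT_GSMM_B = "GUT_GSMM",
    HUMAN_GSMM = "HUMAN_GSMM", OTHER = "OTHER")[source_label]
}

#' Build canonical entity clusters from accepted matches
#'
#' Takes the transitive closure of accepted matches over all registry
#' entries: every entry belongs to exactly one cluster, unmatched entries
#' form singletons.  `REVIEW` matches are included only when a
#' review-decisions table accepts them; a pair both accepted and rejected
#' is an error.
#'
#' @param registries list of `metabolite_registry` objects (distinct source
#'   labels).
#' @param matches match `data.frame` (rows with status `ACCEPTED` merge
#'   directly).
#' @param review_decisions optional `data.frame` with columns `id_a`,
#'   `id_b`, `registry_a`, `registry_b`, `decision` (`ACCEPT`/`REJECT`)
#'   applying to `REVIEW` rows.
#' @return an `entity_clusters` object: `$members` has one row per entry
#'   (`cluster_id`, `source`, `venn_source`, `local_id`, `name`,
#'   identifier columns, `smiles`, `is_substrate`); `$n_clusters`.
#' @export
build_entity_clusters <- function(registries, matches = empty_matches(),
                                  review_decisions = NULL) {
  stopifnot(is.list(registries))
  ents <- do.call(rbind, lapply(registries, function(r) {
    validate_registry(r)
    cbind(data.frame(source = r$source_label, stringsAsFactors = FALSE),
          r$entries)
  }))
  rownames(ents) <- NULL
  ents$key <- paste(ents$source, ents$local_id, sep = ":")
  if (anyDuplicated(ents$key)) {
    stop("duplicate (source, local_id) across registries", call. = FALSE)
  }
  use <- matches$status == "ACCEPTED"
  if (!is.null(review_decisions) && nrow(review_decisions)) {
    pk <- function(df) paste(df$registry_a, df$id_a, df$registry_b, df$id_b,
                             sep = ":")
    dec <- toupper(review_decisions$decision)
    keyd <- pk(review_decisions)
    contra <- intersect(keyd[dec == "ACCEPT"], keyd[dec == "REJECT"])
    if (length(contra)) {
      stop("contradictory review decisions for pair(s): ",
           paste(contra, collapse = "; "), call. = FALSE)
    }
    accepted_pairs <- keyd[dec == "ACCEPT"]
    use <- use | (matches$status == "REVIEW" & pk(matches) %in% accepted_pairs)
  }
  mm <- matches[use, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(ents), directed = FALSE)
  if (nrow(mm)) {
    ka <- match(paste(mm$registry_a, mm$id_a, sep = ":"), ents$key)
    kb <- match(paste(mm$registry_b, mm$id_b, sep = ":"), ents$key)
    if (anyNA(ka) || anyNA(kb)) {
      stop("match references an entry absent from the registries", call. = FALSE)
    }
    g <- igraph::add_edges(g, rbind(ka, kb))
  }
  comp <- igraph::components(g)$membership
  ## stable cluster ids in order of first appearance
  first <- !duplicated(comp)
  relabel <- setNames(seq_len(sum(first)), comp[first])
  members <- ents
  members$cluster_id <- sprintf("EC%05d", relabel[as.character(comp)])
  members$venn_source <- unname(venn_source_of(members$source))
  members$key <- NULL
  members <- members[, c("cluster_id", "source", "venn_source", "local_id",
                         "name", ID_NAMESPACES, "smiles", "is_substrate",
                         "chemont_class")]
  structure(list(members = members, n_clusters = length(relabel)),
            class = "entity_clusters")
}

#' @export
print.entity_clusters <- function(x, ...) {
  cat("<entity_clusters>", x$n_clusters, "clusters over",
      nrow(x$members), "entries\n")
  print(table(x$members$venn_source))
  invisible(x)
}

#' Flag species appearing only in uptake/exchange reactions of an SBML model
#'
#' A heuristic substrate screen: a reaction is treated as an
#' exchange/boundary reaction when its id matches `EX_`/`R_EX_` or it has
#' an empty reactant or product side; species occurring in no other
#' reaction are flagged as likely uptaken substrates.  Because most GSMM
#' reactions are bi-directional, consumed and produced metabolites cannot
#' be discriminated systematically — the heuristic is advisory and a
#' warning says so.
#'
#' @param path SBML file.
#' @param suffixes compartment suffixes for base-key reduction.
#' @return character vector of base species keys.
#' @export
flag_uptake_only_species <- function(path,
                                     suffixes = default_compartment_suffixes()) {
  doc <- xml2::read_xml(path)
  rxns <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  seen <- list()
  for (r in rxns) {
    rid <- xml2::xml_attr(r, "id")
    reac <- xml2::xml_attr(
      xml2::xml_find_all(r, ".//*[local-name()='listOfReactants']//*[local-name()='speciesReference']"),
      "species")
    prod <- xml2::xml_attr(
      xml2::xml_find_all(r, ".//*[local-name()='listOfProducts']//*[local-name()='speciesReference']"),
      "species")
    is_ex <- (!is.na(rid) && grepl("^(R_)?EX_", rid)) ||
      length(reac) == 0 || length(prod) == 0
    for (s in unique(c(reac, prod))) {
      base <- strip_compartment_suffix(sub("^M_", "", s), suffixes)
      seen[[base]] <- c(seen[[base]], is_ex)
    }
  }
  flagged <- names(seen)[vapply(seen, all, logical(1))]
  if (length(flagged)) {
    warning("uptake/exchange heuristic flagged ", length(flagged),
            " species; GSMM reaction bi-directionality makes systematic ",
            "substrate discrimination impossible - review the list",
            call. = FALSE)
  }
  flagged
}

#' Exclude substrate metabolites from the GSMM prediction set
#'
#' Clusters whose gut-GSMM members are flagged `is_substrate`, or whose gut
#' member ids/names appear in `substrate_ids`, lose their gut-GSMM
#' membership (they no longer count as predicted microbial metabolites);
#' clusters left without members are dropped.  An optional SBML model
#' enables the uptake/exchange heuristic of [flag_uptake_only_species()].
#'
#' @param clusters an `entity_clusters` object.
#' @param substrate_ids explicit substrate list (matched against gut member
#'   `local_id` and `name`); may be empty.
#' @param heuristic_sbml optional SBML path for the uptake-only heuristic.
#' @return filtered `entity_clusters` with `attr(,"exclusion_log")`.
#' @export
exclude_substrates <- function(clusters, substrate_ids = character(),
                               heuristic_sbml = NULL) {
  stopifnot(inherits(clusters, "entity_clusters"))
  if (!is.null(heuristic_sbml)) {
    substrate_ids <- union(substrate_ids, flag_uptake_only_species(heuristic_sbml))
  }
  m <- clusters$members
  gut <- m$venn_source == "GUT_GSMM"
  hit <- gut & (m$is_substrate | m$local_id %in% substrate_ids |
                  m$name %in% substrate_ids)
  bad_clusters <- unique(m$cluster_id[hit])
  drop <- gut & m$cluster_id %in% bad_clusters
  log <- m[drop, c("cluster_id", "source", "local_id", "name"), drop = FALSE]
  m <- m[!drop, , drop = FALSE]
  out <- structure(list(members = m, n_clusters = length(unique(m$cluster_id))),
                   class = "entity_clusters")
  attr(out, "exclusion_log") <- log
  out
}

## exclusive region keys over the three-set design
.venn_regions <- c("CURATED", "GUT_GSMM", "HUMAN_GSMM",
                   "CURATED&GUT_GSMM", "CURATED&HUMAN_GSMM",
                   "GUT_GSMM&HUMAN_GSMM", "CURATED&GUT_GSMM&HUMAN_GSMM")

venn_derive <- function(regions) {
  g <- grepl("GUT_GSMM", names(regions))
  c_ <- grepl("CURATED", names(regions))
  h <- grepl("HUMAN_GSMM", names(regions))
  gut_total <- sum(regions[g])
  gut_and_curated <- sum(regions[g & c_])
  gut_not_human <- sum(regions[g & !h])
  gut_unique <- unname(regions["GUT_GSMM"])
  list(
    gut_total = gut_total,
    curated_total = sum(regions[c_]),
    human_total = sum(regions[h]),
    gut_and_curated = gut_and_curated,
    gut_not_human = gut_not_human,
    gut_unique = gut_unique,
    pct_gut_not_human = if (gut_total > 0)
      round_half_away(100 * gut_not_human / gut_total) else NA_real_,
    pct_gut_unique = if (gut_total > 0)
      round_half_away(100 * gut_unique / gut_total) else NA_real_,
    pct_gut_in_curated = if (gut_total > 0)
      round_half_away(100 * gut_and_curated / gut_total) else NA_real_,
    frac_gut_not_human = if (gut_total > 0) gut_not_human / gut_total else NA_real_,
    frac_gut_unique = if (gut_total > 0) gut_unique / gut_total else NA_real_,
    frac_gut_in_curated = if (gut_total > 0) gut_and_curated / gut_total else NA_real_)
}

new_venn_report <- function(regions) {
  stopifnot(setequal(names(regions), .venn_regions), all(regions >= 0))
  regions <- regions[.venn_regions]
  structure(list(regions = regions, derived = venn_derive(regions)),
            class = "venn_report")
}

#' Three-set Venn partition of entity clusters
#'
#' Counts clusters in each of the 7 exclusive regions over
#' \{CURATED, GUT_GSMM, HUMAN_GSMM\} (the two gut-GSMM source labels are
#' pooled into one GUT_GSMM set).  Derived quantities — the predicted-set
#' size, its overlap with the curated set, the not-in-human subset and the
#' unique subset — are reported with exact fractions and headline
#' percentages rounded half away from zero.
#'
#' @param clusters an `entity_clusters` object.
#' @return a `venn_report`: `$regions` (named counts summing to the number
#'   of clusters with at least one in-design member) and `$derived`.
#' @export
compute_venn <- function(clusters) {
  stopifnot(inherits(clusters, "entity_clusters"))
  m <- clusters$members[clusters$members$venn_source != "OTHER", , drop = FALSE]
  sets <- split(m$venn_source, m$cluster_id)
  keys <- vapply(sets, function(s) {
    paste(intersect(c("CURATED", "GUT_GSMM", "HUMAN_GSMM"), unique(s)),
          collapse = "&")
  }, character(1))
  counts <- setNames(integer(length(.venn_regions)), .venn_regions)
  tab <- table(keys)
  counts[names(tab)] <- as.integer(tab)
  new_venn_report(counts)
}

#' Venn report from printed summary cardinalities
#'
#' Reconstructs the 7 exclusive regions from the aggregate cardinalities a
#' summary table or figure legend typically reports: the total predicted
#' gut set, its overlap with the curated set, its not-in-human subset, and
#' its unique subset (in neither of the other two).  Regions outside the
#' gut set that the aggregates do not constrain default to 0 and do not
#' affect the derived gut-centric percentages.
#'
#' @param curated_total size of the curated set.
#' @param gut_total size of the pooled gut-GSMM predicted set.
#' @param gut_and_curated size of the gut/curated overlap.
#' @param gut_not_human size of the gut subset absent from the human GSMM.
#' @param gut_unique size of the gut subset absent from both other sets.
#' @param curated_and_human_only,human_only unconstrained regions
#'   (defaults 0).
#' @return a `venn_report`.
#' @export
venn_from_cardinalities <- function(curated_total, gut_total, gut_and_curated,
                                    gut_not_human, gut_unique,
                                    curated_and_human_only = 0, human_only = 0) {
  gut_and_human <- gut_total - gut_not_human
  triple <- gut_and_curated + gut_and_human - (gut_total - gut_unique)
  regions <- c(
    "CURATED" = curated_total - gut_and_curated - curated_and_human_only,
    "GUT_GSMM" = gut_unique,
    "HUMAN_GSMM" = human_only,
    "CURATED&GUT_GSMM" = gut_and_curated - triple,
    "CURATED&HUMAN_GSMM" = curated_and_human_only,
    "GUT_GSMM&HUMAN_GSMM" = gut_and_human - triple,
    "CURATED&GUT_GSMM&HUMAN_GSMM" = triple)
  if (any(regions < 0)) {
    stop("inconsistent cardinalities: a derived region is negative", call. = FALSE)
  }
  new_venn_report(regions)
}

#' @export
print.venn_report <- function(x, ...) {
  cat("<venn_report> regions over {CURATED, GUT_GSMM, HUMAN_GSMM}\n")
  for (k in names(x$regions)) cat(sprintf("  %-28s %d\n", k, x$regions[[k]]))
  d <- x$derived
  cat(sprintf("  predicted gut set: %d; in curated: %d (~%d%%); not in human: %d (~%d%%); unique: %d (~%d%%)\n",
              d$gut_total, d$gut_and_curated, d$pct_gut_in_curated,
              d$gut_not_human, d$pct_gut_not_human,
              d$gut_unique, d$pct_gut_unique))
  invisible(x)
}

#' Predicted unique microbial metabolites
#'
#' Clusters present in the gut-GSMM set but in neither the human GSMM nor
#' the curated set.  One row per cluster (representative gut entry),
#' sorted by name, with identifiers and SMILES where present.
#'
#' @param clusters an `entity_clusters` object (after substrate exclusion).
#' @return `data.frame` with `cluster_id`, `local_id`, `name`, the
#'   identifier columns and `smiles`.
#' @export
unique_microbial_list <- function(clusters) {
  stopifnot(inherits(clusters, "entity_clusters"))
  m <- clusters$members
  src <- split(m$venn_source, m$cluster_id)
  uniq <- names(src)[vapply(src, function(s)
    setequal(intersect(unique(s), c("CURATED", "GUT_GSMM", "HUMAN_GSMM")),
             "GUT_GSMM"), logical(1))]
  gm <- m[m$cluster_id %in% uniq & m$venn_source == "GUT_GSMM", , drop = FALSE]
  ## one representative per cluster: cascade-priority identifier union
  rows <- lapply(split(gm, gm$cluster_id), function(g) {
    out <- g[1, c("cluster_id", "local_id", "name", ID_NAMESPACES, "smiles"),
             drop = FALSE]
    for (col in c(ID_NAMESPACES, "smiles")) {
      v <- g[[col]][!is.na(g[[col]])]
      out[[col]] <- if (length(v)) v[[1]] else NA_character_
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(tolower(out$name)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
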