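## Seeded synthetic data with machine-checkable ground truth.
##
## No public accession carries the registries this pipeline consumes, so
## the package generates linked registries with controlled overlap,
## per-namespace identifier dropout and rule-inverting name corruption;
## evidence fixtures with exact per-type marginals; and SMILES panels from
## parametric scaffolds.  Every generator takes a mandatory seed, runs one
## seeded pseudo-random stream, and emits a ground-truth object that
## brute-force analysis of the emitted files reproduces.

#' Synthetic study-design configuration
#'
#' Defaults mirror the summary cardinalities of the curated/predicted
#' comparison: a curated set of 457, a pooled gut-GSMM prediction set of
#' 2325 overlapping it in 251 entries (67 of them also in the human set),
#' 598 entries shared with the human GSMM, and 1543 gut-only entries.
#' Identifier dropout is per-namespace and deliberately uneven (structure
#' keys and model-native ids survive more often than HMDB accessions, as
#' in real GSMM extracts); 20% of overlapping entries carry a corrupted
#' name produced by inverting the normalization rules.
#'
#' @param n_curated,n_gut,n_human registry sizes.
#' @param overlap_gut_curated,overlap_gut_human,overlap_curated_human
#'   pairwise overlap sizes (each includes the triple overlap).
#' @param overlap_triple three-way overlap size.
#' @param dropout named per-namespace probabilities of an identifier being
#'   absent from a registry copy.
#' @param name_corruption probability that an overlapping entry's name is
#'   corrupted (de-normalized) in the gut registry copy.
#' @param substrate_fraction fraction of gut-only entries flagged as
#'   substrate metabolites.
#' @param seed mandatory integer seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_curated = 457, n_gut = 2325, n_human = 2400,
                             overlap_gut_curated = 251,
                             overlap_gut_human = 598,
                             overlap_curated_human = 167,
                             overlap_triple = 67,
                             dropout = c(inchikey = 0.3, chebi = 0.3,
                                         pubchem_cid = 0.4, hmdb = 0.5,
                                         bigg = 0.3, metanetx = 0.3),
                             name_corruption = 0.2,
                             substrate_fraction = 0.1,
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  dr <- setNames(rep(0, length(ID_NAMESPACES)), ID_NAMESPACES)
  dr[names(dropout)] <- dropout
  if (any(dr < 0 | dr > 1) || name_corruption < 0 || name_corruption > 1 ||
      substrate_fraction < 0 || substrate_fraction > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  regions <- c(
    triple = overlap_triple,
    gc = overlap_gut_curated - overlap_triple,
    gh = overlap_gut_human - overlap_triple,
    ch = overlap_curated_human - overlap_triple,
    c_only = n_curated - overlap_gut_curated -
      (overlap_curated_human - overlap_triple),
    g_only = n_gut - overlap_gut_curated -
      (overlap_gut_human - overlap_triple),
    h_only = n_human - overlap_gut_human -
      (overlap_curated_human - overlap_triple))
  if (any(regions < 0)) {
    stop("infeasible overlap design: negative region size (",
         paste(names(regions)[regions < 0], collapse = ", "), ")",
         call. = FALSE)
  }
  structure(list(n_curated = n_curated, n_gut = n_gut, n_human = n_human,
                 regions = regions, dropout = dr,
                 name_corruption = name_corruption,
                 substrate_fraction = substrate_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

## Name pool: chemistry-flavoured names built from morphemes the
## normalization rules know about, so corruption can invert them.
.name_stems <- c("butyric acid", "propionic acid", "valeric acid", "acetic acid",
  "caproic acid", "indole", "cresol", "phenylacetic acid", "hippuric acid",
  "cholic acid", "deoxycholic acid", "lithocholic acid", "tyrosine",
  "tryptophan", "alanine", "glycine", "ornithine", "putrescine", "spermidine",
  "cadaverine", "equol", "enterolactone", "ferulic acid", "gallic acid",
  "lactic acid", "succinic acid", "fumaric acid", "glucose", "glycerol",
  "taurine", "dopamine", "tyramine", "piperidine", "trigonelline",
  "benzoic acid", "salicylic acid", "vanillic acid", "catechol", "phenol",
  "uracil", "adenine", "xanthine", "riboflavin", "thiamin", "urobilin",
  "coumaric acid", "quinic acid", "pantothenic acid", "spermine", "betaine")
.name_mods1 <- c("", "2-", "3-", "4-", "5-", "z-", "e-", "alpha-", "beta-",
                 "gamma-", "omega-", "n-")
.name_mods2 <- c("", "hydroxy-", "methyl-", "amino-", "oxo-", "dihydro-",
                 "keto-", "acetyl-", "methoxy-", "dehydro-", "iso", "nor",
                 "homo", "phenyl-", "indolyl-", "sulfo-")

generate_name_pool <- function(n) {
  combos <- expand.grid(m2 = .name_mods2, m1 = .name_mods1, stem = .name_stems,
                        stringsAsFactors = FALSE)
  pool <- unique(paste0(combos$m1, combos$m2, combos$stem))
  if (n > length(pool)) {
    extra <- paste0(pool[seq_len(n - length(pool))], " ",
                    seq_len(n - length(pool)))
    pool <- c(pool, extra)
  }
  sample(pool, n)
}

random_inchikey <- function(n) {
  blk <- function(k) replicate(n, paste(sample(LETTERS, k, TRUE), collapse = ""))
  paste0(blk(14), "-", blk(10), "-N")
}

## De-normalize a name: re-introduce stereo prefixes and Greek letters and
## add case noise, i.e. invert the shipped rule table.
corrupt_name <- function(name) {
  inv <- c("z-" = "cis-", "e-" = "trans-", "alpha" = "α", "beta" = "β",
           "gamma" = "γ", "omega" = "ω")
  out <- name
  for (i in seq_along(inv)) {
    pat <- names(inv)[i]
    if (startsWith(pat, "z") || startsWith(pat, "e")) {
      if (startsWith(out, pat)) out <- paste0(inv[[i]], substring(out, nchar(pat) + 1))
    } else {
      out <- sub(pat, inv[[i]], out, fixed = TRUE)
    }
  }
  ## title-case the first letter and double one space for case/ws noise
  out <- paste0(toupper(substring(out, 1, 1)), substring(out, 2))
  sub(" ", "  ", out)
}

#' Generate linked metabolite registries with planted ground truth
#'
#' Draws a universe of synthetic metabolites, assigns each to the Venn
#' region the configuration prescribes, and emits three registries
#' (CURATED, GUT_GSMM_A, HUMAN_GSMM).  Copies of one universe entry share
#' all identifiers except where per-namespace dropout removed them;
#' a configured fraction of overlapping entries gets a corrupted
#' (de-normalized) name in the gut copy; a configured fraction of gut-only
#' entries is flagged as substrate.  Deterministic for a fixed config.
#'
#' @param config a [synthetic_config()].
#' @return list with `registries` (named list of `metabolite_registry`),
#'   and `ground_truth`: `pairs` (planted cross-registry equivalences with
#'   an `identifier_link` flag saying whether at least one namespace
#'   survived dropout on both sides), `membership`, `region_counts`,
#'   `substrates` (gut local_ids), `corrupted` (gut local_ids).
#' @export
generate_linked_registries <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    reg <- config$regions
    n_univ <- sum(reg)
    region_of <- rep(names(reg), reg)
    universe <- data.frame(
      universe_id = sprintf("U%05d", seq_len(n_univ)),
      name = generate_name_pool(n_univ),
      inchikey = random_inchikey(n_univ),
      chebi = paste0("CHEBI:", sample(10000:99999, n_univ)),
      pubchem_cid = as.character(sample(1:10000000, n_univ)),
      hmdb = sprintf("HMDB%07d", sample(1:9999999, n_univ)),
      bigg = paste0("bigg_", seq_len(n_univ)),
      metanetx = sprintf("MNXM%05d", seq_len(n_univ)),
      smiles = sample(smiles_scaffold_pool(), n_univ, replace = TRUE),
      region = sample(region_of),
      stringsAsFactors = FALSE)
    universe$in_curated <- universe$region %in% c("triple", "gc", "ch", "c_only")
    universe$in_gut <- universe$region %in% c("triple", "gc", "gh", "g_only")
    universe$in_human <- universe$region %in% c("triple", "gh", "ch", "h_only")

    make_copy <- function(idx, prefix) {
      e <- universe[idx, c("name", ID_NAMESPACES, "smiles"), drop = FALSE]
      e$local_id <- sprintf("%s%05d", prefix, seq_along(idx))
      for (ns in ID_NAMESPACES) {
        p <- config$dropout[[ns]]
        if (p > 0) e[[ns]][stats::runif(nrow(e)) < p] <- NA_character_
      }
      e$universe_id <- universe$universe_id[idx]
      e
    }
    cur <- make_copy(which(universe$in_curated), "CUR")
    gut <- make_copy(which(universe$in_gut), "GUT")
    hum <- make_copy(which(universe$in_human), "HUM")

    ## name corruption on overlapping entries, applied to the gut copy
    overlapping <- universe$universe_id[universe$region %in%
                                          c("triple", "gc", "gh")]
    cand <- which(gut$universe_id %in% overlapping)
    corrupt <- cand[stats::runif(length(cand)) < config$name_corruption]
    gut$name[corrupt] <- vapply(gut$name[corrupt], corrupt_name, character(1))

    ## substrate flags on gut-only entries
    g_only_ids <- universe$universe_id[universe$region == "g_only"]
    gonly_rows <- which(gut$universe_id %in% g_only_ids)
    n_sub <- round(config$substrate_fraction * length(gonly_rows))
    sub_rows <- sort(sample(gonly_rows, n_sub))
    gut$is_substrate <- FALSE
    gut$is_substrate[sub_rows] <- TRUE

    planted_pairs <- function(ea, la, eb, lb) {
      shared <- intersect(ea$universe_id, eb$universe_id)
      ia <- match(shared, ea$universe_id); ib <- match(shared, eb$universe_id)
      id_link <- vapply(seq_along(shared), function(k) {
        any(!is.na(unlist(ea[ia[k], ID_NAMESPACES])) &
              !is.na(unlist(eb[ib[k], ID_NAMESPACES])))
      }, logical(1))
      data.frame(registry_a = rep(la, length(shared)), id_a = ea$local_id[ia],
                 registry_b = rep(lb, length(shared)), id_b = eb$local_id[ib],
                 universe_id = shared, identifier_link = id_link,
                 stringsAsFactors = FALSE)
    }
    gt_pairs <- rbind(planted_pairs(cur, "CURATED", gut, "GUT_GSMM_A"),
                      planted_pairs(cur, "CURATED", hum, "HUMAN_GSMM"),
                      planted_pairs(gut, "GUT_GSMM_A", hum, "HUMAN_GSMM"))

    strip <- function(e) {
      u <- e$universe_id; e$universe_id <- NULL
      e <- e[, c("local_id", setdiff(names(e), "local_id")), drop = FALSE]
      attr(e, "universe_id") <- u
      e
    }
    registries <- list(
      CURATED = new_registry(strip(cur), "CURATED", "synthetic"),
      GUT_GSMM_A = new_registry(strip(gut), "GUT_GSMM_A", "synthetic"),
      HUMAN_GSMM = new_registry(strip(hum), "HUMAN_GSMM", "synthetic"))
    list(registries = registries,
         ground_truth = list(
           pairs = gt_pairs,
           membership = universe[, c("universe_id", "region", "in_curated",
                                     "in_gut", "in_human")],
           region_counts = config$regions,
           substrates = gut$local_id[gut$is_substrate],
           corrupted = gut$local_id[corrupt],
           entry_map = rbind(
             data.frame(registry = "CURATED", local_id = cur$local_id,
                        universe_id = cur$universe_id, stringsAsFactors = FALSE),
             data.frame(registry = "GUT_GSMM_A", local_id = gut$local_id,
                        universe_id = gut$universe_id, stringsAsFactors = FALSE),
             data.frame(registry = "HUMAN_GSMM", local_id = hum$local_id,
                        universe_id = hum$universe_id, stringsAsFactors = FALSE))))
  })
}

#' Generate an evidence fixture with exact marginal counts
#'
#' Emits evidence records whose per-type record counts equal
#' `record_marginals` exactly.  When `bucket_sizes` and
#' `type_metabolite_counts` are supplied, the assignment of evidence-type
#' sets to metabolites is additionally constrained so that exactly
#' `bucket_sizes[k]` metabolites carry `k` evidence types and exactly
#' `type_metabolite_counts[t]` metabolites carry type `t` (the defaults
#' reproduce the curated database's published margins).  Which metabolite
#' gets which set, and how surplus records spread over metabolites, is
#' seeded-random.
#'
#' @param record_marginals records per type
#'   (faecal in vitro, antibiotic, germ-free).
#' @param n_metabolites number of distinct metabolites.
#' @param bucket_sizes metabolites supported by exactly 1, 2, 3 types, or
#'   `NULL` for unconstrained random assignment.
#' @param type_metabolite_counts metabolites carrying each type
#'   (required with `bucket_sizes`).
#' @param seed mandatory seed.
#' @return list with `records` (evidence `data.frame`) and `ground_truth`
#'   (`type_sets` per metabolite, marginals, bucket sizes).
#' @export
generate_evidence_fixture <- function(record_marginals = c(1182, 418, 248),
                                      n_metabolites = 457,
                                      bucket_sizes = c(318, 99, 40),
                                      type_metabolite_counts = c(257, 209, 170),
                                      seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(record_marginals) == 3, all(record_marginals >= 0))
  if (n_metabolites == 0 && sum(record_marginals) > 0) {
    stop("n_metabolites = 0 with positive record marginals", call. = FALSE)
  }
  if (sum(record_marginals) == 0) {
    rec <- data.frame(metabolite_id = character(), evidence_type = character(),
                      publication = character(), organism = character(),
                      biospecimen = character(), substrate = character(),
                      stringsAsFactors = FALSE)
    return(list(records = rec,
                ground_truth = list(type_sets = matrix(FALSE, 0, 3),
                                    record_marginals = record_marginals)))
  }
  with_seed(seed, {
    mids <- sprintf("M%04d", seq_len(n_metabolites))
    has <- matrix(FALSE, n_metabolites, 3,
                  dimnames = list(mids, EVIDENCE_TYPES))
    if (!is.null(bucket_sizes)) {
      if (is.null(type_metabolite_counts)) {
        stop("type_metabolite_counts required with bucket_sizes", call. = FALSE)
      }
      stopifnot(sum(bucket_sizes) == n_metabolites)
      if (sum(bucket_sizes * 1:3) != sum(type_metabolite_counts)) {
        stop("bucket sizes and per-type metabolite counts are inconsistent",
             call. = FALSE)
      }
      sol <- solve_two_type_split(bucket_sizes, type_metabolite_counts)
      ord <- sample(n_metabolites)
      sets <- c(rep(list(1:3), bucket_sizes[3]),
                rep(list(c(1, 2)), sol$fa), rep(list(c(1, 3)), sol$fg),
                rep(list(c(2, 3)), sol$ag),
                rep(list(1), sol$f1), rep(list(2), sol$a1), rep(list(3), sol$g1))
      for (i in seq_along(sets)) has[ord[i], sets[[i]]] <- TRUE
    } else {
      ## unconstrained: every metabolite gets one random type, drawn with
      ## probability proportional to the record marginals so no type's
      ## carrier count can plausibly exceed its record budget
      pr <- record_marginals / sum(record_marginals)
      for (i in seq_len(n_metabolites)) has[i, sample(3, 1, prob = pr)] <- TRUE
      for (t in 1:3) {
        need_any <- record_marginals[t] > 0 && !any(has[, t])
        if (need_any) has[sample(n_metabolites, 1), t] <- TRUE
      }
    }
    for (t in 1:3) {
      if (record_marginals[t] > 0 && sum(has[, t]) > record_marginals[t]) {
        stop("record marginal for ", EVIDENCE_TYPES[t],
             " smaller than the number of metabolites carrying that type",
             call. = FALSE)
      }
      if (record_marginals[t] == 0) has[, t] <- FALSE
    }
    if (any(rowSums(has) == 0)) {
      ## metabolites stripped of all types (zero marginals) are dropped
      has <- has[rowSums(has) > 0, , drop = FALSE]
    }
    rows <- list()
    orgs <- list(c("bacteria"), c("human", "mouse", "rat", "monkey"),
                 c("mouse", "rat"))
    specs <- list(c("CULTURE_MEDIUM"), c("BLOOD", "URINE", "FAECES"),
                  c("BLOOD", "URINE", "FAECES", "GUT_CONTENT"))
    for (t in 1:3) {
      carriers <- rownames(has)[has[, t]]
      if (!length(carriers)) next
      extra <- record_marginals[t] - length(carriers)
      assign_to <- c(carriers,
                     if (extra > 0) sample(carriers, extra, replace = TRUE))
      rows[[t]] <- data.frame(
        metabolite_id = assign_to,
        evidence_type = EVIDENCE_TYPES[t],
        publication = sprintf("PUB%03d", sample(165, length(assign_to), TRUE)),
        organism = sample(orgs[[t]], length(assign_to), TRUE),
        biospecimen = sample(specs[[t]], length(assign_to), TRUE),
        substrate = ifelse(stats::runif(length(assign_to)) < 0.3,
                           sample(.name_stems, length(assign_to), TRUE),
                           NA_character_),
        stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rows)
    rec <- rec[sample(nrow(rec)), , drop = FALSE]
    rownames(rec) <- NULL
    list(records = rec,
         ground_truth = list(type_sets = has,
                             record_marginals = record_marginals,
                             bucket_sizes = if (!is.null(bucket_sizes))
                               bucket_sizes else as.vector(table(factor(
                                 rowSums(has), levels = 1:3)))))
  })
}

## Find two-type overlap counts (faecal+antibiotic, faecal+germfree,
## antibiotic+germfree) consistent with the bucket sizes and per-type
## metabolite counts; first feasible solution in a deterministic scan.
solve_two_type_split <- function(bucket_sizes, tmc) {
  b2 <- bucket_sizes[2]; b3 <- bucket_sizes[3]
  for (fa in 0:b2) for (fg in 0:(b2 - fa)) {
    ag <- b2 - fa - fg
    f1 <- tmc[1] - b3 - fa - fg
    a1 <- tmc[2] - b3 - fa - ag
    g1 <- tmc[3] - b3 - fg - ag
    if (f1 >= 0 && a1 >= 0 && g1 >= 0 && f1 + a1 + g1 == bucket_sizes[1]) {
      return(list(fa = fa, fg = fg, ag = ag, f1 = f1, a1 = a1, g1 = g1))
    }
  }
  stop("bucket sizes and per-type metabolite counts admit no assignment",
       call. = FALSE)
}

smiles_scaffold_pool <- function() {
  chains <- vapply(1:7, function(k) paste(rep("C", k), collapse = ""),
                   character(1))
  subs <- c("O", "N", "Cl", "C", "CC", "C(=O)O", "OC", "CO")
  mono <- paste0("c1ccc(", subs, ")cc1")
  pairs <- expand.grid(i = seq_along(subs), j = seq_along(subs))
  pairs <- pairs[pairs$i <= pairs$j, ]
  di <- paste0("c1cc(", subs[pairs$i], ")ccc1", subs[pairs$j])
  unique(c(chains, paste0(chains, "O"), paste0(chains, "C(=O)O"),
           paste0(chains, "N"), paste0("OC", chains, "O"),
           paste0(chains, "S"), paste0("OC(=O)", chains, "C(=O)O"),
           paste0("CC(=O)", chains), paste0("CC(=O)O", chains),
           paste0("N", chains, "C(=O)O"),
           paste0("c1ccc(", chains, ")cc1"), mono, di))}

#' Generate a panel of valid SMILES
#'
#' Draws from parametric scaffolds (linear alkanes, alcohols, carboxylic
#' acids, amines, diols, mono- and di-substituted benzenes); the first
#' `n - duplicates` strings are structurally distinct, followed by
#' `duplicates` copies of the first scaffold.
#'
#' @param n panel size (>= 1).
#' @param seed mandatory seed.
#' @param duplicates number of duplicate copies at the end of the panel.
#' @return character vector of `n` SMILES.
#' @export
generate_smiles_panel <- function(n, seed, duplicates = 0) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n >= 1, duplicates >= 0, duplicates < n)
  pool <- smiles_scaffold_pool()
  n_distinct <- n - duplicates
  if (n_distinct > length(pool)) {
    stop("at most ", length(pool), " distinct scaffolds available", call. = FALSE)
  }
  with_seed(seed, {
    base <- sample(pool, n_distinct)
    c(base, rep(base[1], duplicates))
  })
}

#' Write synthetic registries and ground truth to a directory
#'
#' Emits the registry TSV dialect the pipeline consumes plus a
#' `ground_truth.json` sidecar; file headers record the seed via the
#' provenance JSON.
#'
#' @param sim result of [generate_linked_registries()].
#' @param dir output directory (created if needed).
#' @param config the generating [synthetic_config()] (for provenance).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$registries)) {
    write_registry_table(sim$registries[[nm]],
                         file.path(dir, paste0("registry_", nm, ".tsv")))
  }
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(region_counts = as.list(gt$region_counts),
         substrates = gt$substrates, corrupted = gt$corrupted,
         pairs = gt$pairs, membership = gt$membership,
         seed = if (!is.null(config)) config$seed else NULL),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
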