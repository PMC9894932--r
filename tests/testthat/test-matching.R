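reg_pair_fixture <- function() {
  a <- data.frame(
    local_id = c("a1", "a2", "a3", "a4"),
    name = c("Butyric Acid", "cis-aconitate", "Glucose", "Thing one"),
    inchikey = c("FERIUCNNQQJTOY-UHFFFAOYSA-N", NA, NA, NA),
    chebi = c("CHEBI:30772", NA, NA, NA),
    metanetx = c(NA, NA, NA, "MNXM999"),
    stringsAsFactors = FALSE)
  b <- data.frame(
    local_id = c("b1", "b2", "b3", "b4"),
    name = c("butyric acid", "z-aconitate", "Fructose", "Thing two"),
    inchikey = c("FERIUCNNQQJTOY-UHFFFAOYSA-N", NA, NA, NA),
    chebi = c("CHEBI:99999", NA, NA, NA),   # conflicts with a1's ChEBI
    metanetx = c(NA, NA, NA, "MNXM999"),
    stringsAsFactors = FALSE)
  list(a = tiny_registry("CURATED", a), b = tiny_registry("GUT_GSMM_A", b))
}

test_that("the cascade matches top-down with leftover semantics", {
  fx <- reg_pair_fixture()
  m <- cascade_match(fx$a, fx$b)
  ## shared InChIKey beats the conflicting ChEBI: matched at INCHIKEY once
  a1 <- m[m$id_a == "a1", ]
  expect_equal(nrow(a1), 1)
  expect_equal(a1$level, "INCHIKEY")
  expect_equal(a1$status, "ACCEPTED")
  ## the ChEBI disagreement is logged
  cl <- attr(m, "conflict_log")
  expect_true(any(cl$namespace == "chebi" & cl$id_a == "a1"))
  ## a MetaNetX-only pair matches at METANETX
  expect_equal(m$level[m$id_a == "a4"], "METANETX")
  ## unmatched entries are leftovers
  expect_setequal(attr(m, "leftover_a"), c("a2", "a3"))
})

test_that("identifier matching is invariant to entry order", {
  fx <- reg_pair_fixture()
  key <- function(m) sort(paste(m$id_a, m$id_b, m$level))
  m1 <- cascade_match(fx$a, fx$b)
  perm <- fx
  perm$a$entries <- perm$a$entries[c(3, 1, 4, 2), ]
  perm$b$entries <- perm$b$entries[c(2, 4, 1, 3), ]
  m2 <- cascade_match(perm$a, perm$b)
  expect_identical(key(m1), key(m2))
})

test_that("fuzzy matching accepts only normalization-equal names", {
  fx <- reg_pair_fixture()
  m <- cascade_match(fx$a, fx$b)
  la <- fx$a$entries[fx$a$entries$local_id %in% attr(m, "leftover_a"), ]
  lb <- fx$b$entries[fx$b$entries$local_id %in% attr(m, "leftover_b"), ]
  fz <- fuzzy_match_names(la, lb, "CURATED", "GUT_GSMM_A", threshold = 0.92)
  ## "cis-aconitate" == "z-aconitate" after rules -> score 1, auto-accepted
  ac <- fz[fz$id_a == "a2", ]
  expect_equal(ac$id_b, "b2")
  expect_equal(ac$score, 1)
  expect_equal(ac$status, "ACCEPTED")
  ## "Glucose" vs "Fructose" stays below 0.92 (checked against LCS oracle)
  expect_false("a3" %in% fz$id_a)
  oracle <- lcs_similarity("glucose", "fructose")
  expect_lt(oracle, 0.92)
  expect_equal(1 - adist("glucose", "fructose",
                         costs = list(ins = 1, del = 1, sub = 2))[1] /
                 (7 + 8), oracle)
  expect_error(fuzzy_match_names(la, lb, threshold = 1.5), "threshold")
})

test_that("case-folded identical names score 1.0 and are accepted", {
  la <- data.frame(local_id = "x", name = "Butyric Acid", stringsAsFactors = FALSE)
  lb <- data.frame(local_id = "y", name = "butyric  acid", stringsAsFactors = FALSE)
  fz <- fuzzy_match_names(la, lb)
  expect_equal(fz$score, 1)
  expect_equal(fz$status, "ACCEPTED")
})

test_that("fuzzy selection is greedy one-to-one with deterministic ties", {
  la <- data.frame(local_id = c("p", "q"),
                   name = c("indole acetic acid", "indole lactic acid"),
                   stringsAsFactors = FALSE)
  lb <- data.frame(local_id = c("r"),
                   name = c("indole acetic acid"), stringsAsFactors = FALSE)
  fz <- fuzzy_match_names(la, lb, threshold = 0.6)
  expect_equal(nrow(fz), 1)           # one-to-one: r is consumed once
  expect_equal(fz$id_a, "p")          # the higher score wins
  cand <- attr(fz, "candidates")
  expect_equal(nrow(cand), 2)         # all candidates kept for review
})

test_that("identifier precision and recall are exact on planted links", {
  sc <- synthetic_config(n_curated = 120, n_gut = 150, n_human = 130,
                         overlap_gut_curated = 100, overlap_gut_human = 40,
                         overlap_curated_human = 30, overlap_triple = 20,
                         dropout = c(inchikey = 0), name_corruption = 0,
                         seed = 11)
  sim <- generate_linked_registries(sc)
  m <- cascade_match(sim$registries$CURATED, sim$registries$GUT_GSMM_A)
  truth <- sim$ground_truth$pairs
  truth <- truth[truth$registry_a == "CURATED" & truth$registry_b == "GUT_GSMM_A", ]
  got <- paste(m$id_a, m$id_b)
  want <- paste(truth$id_a, truth$id_b)
  expect_setequal(got, want)                       # precision = recall = 1
  expect_true(all(m$level == "INCHIKEY"))          # zero dropout: top level
})

test_that("clusters are the transitive closure and form a partition", {
  regs <- list(
    tiny_registry("CURATED", data.frame(local_id = "a", name = "X",
                                        stringsAsFactors = FALSE)),
    tiny_registry("GUT_GSMM_A", data.frame(local_id = "b", name = "X",
                                           stringsAsFactors = FALSE)),
    tiny_registry("HUMAN_GSMM", data.frame(local_id = "c", name = "X",
                                           stringsAsFactors = FALSE)))
  link <- function(ra, ia, rb, ib, status = "ACCEPTED", level = "INCHIKEY") {
    data.frame(registry_a = ra, id_a = ia, name_a = "X",
               registry_b = rb, id_b = ib, name_b = "X",
               level = level, score = 1, status = status,
               stringsAsFactors = FALSE)
  }
  ## no matches: singletons
  cl0 <- build_entity_clusters(regs)
  expect_equal(cl0$n_clusters, 3)
  ## chain a-b, b-c -> one cluster (independent components oracle agrees)
  mm <- rbind(link("CURATED", "a", "GUT_GSMM_A", "b"),
              link("GUT_GSMM_A", "b", "HUMAN_GSMM", "c"))
  cl <- build_entity_clusters(regs, mm)
  expect_equal(cl$n_clusters, 1)
  comp <- brute_components(3, matrix(c(1, 2, 2, 3), ncol = 2, byrow = TRUE))
  expect_equal(cl$n_clusters, length(unique(comp)))
  ## every entry in exactly one cluster
  expect_equal(nrow(cl$members), 3)
  expect_equal(anyDuplicated(paste(cl$members$source, cl$members$local_id)), 0)

  ## REVIEW pairs only merge on acceptance; rejected stays split
  rv <- link("CURATED", "a", "GUT_GSMM_A", "b", status = "REVIEW",
             level = "FUZZY_NAME")
  expect_equal(build_entity_clusters(regs, rv)$n_clusters, 3)
  dec_acc <- data.frame(registry_a = "CURATED", id_a = "a",
                        registry_b = "GUT_GSMM_A", id_b = "b",
                        decision = "ACCEPT", stringsAsFactors = FALSE)
  expect_equal(build_entity_clusters(regs, rv, dec_acc)$n_clusters, 2)
  dec_rej <- dec_acc; dec_rej$decision <- "REJECT"
  expect_equal(build_entity_clusters(regs, rv, dec_rej)$n_clusters, 3)
  ## contradictory decisions are fatal
  expect_error(build_entity_clusters(regs, rv, rbind(dec_acc, dec_rej)),
               "contradictory")
})

test_that("substrate exclusion removes flagged clusters from the gut set", {
  gut <- data.frame(local_id = c("g1", "g2", "g3"),
                    name = c("diet sugar", "true product", "listed compound"),
                    is_substrate = c(TRUE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  regs <- list(tiny_registry("GUT_GSMM_A", gut))
  cl <- build_entity_clusters(regs)
  ## flagged + explicitly listed are removed; empty list + no heuristic = no-op
  expect_identical(exclude_substrates(cl)$members$local_id, c("g2", "g3"))
  out <- exclude_substrates(cl, substrate_ids = "listed compound")
  expect_identical(out$members$local_id, "g2")
  expect_equal(nrow(attr(out, "exclusion_log")), 2)
  noop <- exclude_substrates(build_entity_clusters(list(
    tiny_registry("GUT_GSMM_A", gut[2, , drop = FALSE]))))
  expect_equal(noop$n_clusters, 1)
})

test_that("the uptake/exchange heuristic flags boundary-only species", {
  p <- write_toy_sbml(with_noid_species = FALSE)
  expect_warning(flagged <- flag_uptake_only_species(p), "bi-directionality")
  expect_identical(flagged, "x")    # glc__D and but occur in R_conv too
})

test_that("venn regions match brute-force set enumeration", {
  ## disjoint registries: all intersections zero
  mk <- function(lab, pre, n) {
    tiny_registry(lab, data.frame(local_id = paste0(pre, seq_len(n)),
                                  name = paste0(pre, " cpd ", seq_len(n)),
                                  stringsAsFactors = FALSE))
  }
  cl <- build_entity_clusters(list(mk("CURATED", "c", 2),
                                   mk("GUT_GSMM_A", "g", 3),
                                   mk("HUMAN_GSMM", "h", 4)))
  v <- compute_venn(cl)
  expect_equal(unname(v$regions[c("CURATED", "GUT_GSMM", "HUMAN_GSMM")]),
               c(2, 3, 4))
  expect_true(all(v$regions[grepl("&", names(v$regions))] == 0))

  ## random overlap designs <= 500 entries vs ground-truth enumeration
  for (seed in c(4, 9, 21)) {
    sc <- synthetic_config(n_curated = 120, n_gut = 200, n_human = 160,
                           overlap_gut_curated = 60, overlap_gut_human = 70,
                           overlap_curated_human = 40, overlap_triple = 25,
                           dropout = c(inchikey = 0), name_corruption = 0,
                           substrate_fraction = 0, seed = seed)
    sim <- generate_linked_registries(sc)
    regs <- sim$registries
    mm <- rbind(cascade_match(regs$CURATED, regs$GUT_GSMM_A),
                cascade_match(regs$CURATED, regs$HUMAN_GSMM),
                cascade_match(regs$GUT_GSMM_A, regs$HUMAN_GSMM))
    v <- compute_venn(build_entity_clusters(regs, mm))
    gt <- sim$ground_truth$membership
    brute <- brute_venn_regions(gt[, c("in_curated", "in_gut", "in_human")])
    for (k in names(brute)) expect_equal(unname(v$regions[k]),
                                         unname(as.integer(brute[k])))
    expect_equal(sum(v$regions), nrow(gt))
  }
})

test_that("region counts and cluster partition survive permutation", {
  sc <- synthetic_config(n_curated = 50, n_gut = 80, n_human = 60,
                         overlap_gut_curated = 20, overlap_gut_human = 25,
                         overlap_curated_human = 15, overlap_triple = 10,
                         dropout = c(inchikey = 0), name_corruption = 0,
                         seed = 2)
  sim <- generate_linked_registries(sc)
  regs <- sim$registries
  run <- function(rs) {
    mm <- rbind(cascade_match(rs$CURATED, rs$GUT_GSMM_A),
                cascade_match(rs$CURATED, rs$HUMAN_GSMM),
                cascade_match(rs$GUT_GSMM_A, rs$HUMAN_GSMM))
    compute_venn(build_entity_clusters(rs, mm))$regions
  }
  v1 <- run(regs)
  set.seed(1)
  regs$CURATED$entries <- regs$CURATED$entries[sample(50), ]
  regs$GUT_GSMM_A$entries <- regs$GUT_GSMM_A$entries[sample(80), ]
  expect_identical(run(regs), v1)
})

test_that("the unique-microbial list recovers the planted gut-only set", {
  sc <- synthetic_config(n_curated = 60, n_gut = 100, n_human = 80,
                         overlap_gut_curated = 25, overlap_gut_human = 30,
                         overlap_curated_human = 20, overlap_triple = 10,
                         dropout = c(inchikey = 0), name_corruption = 0,
                         substrate_fraction = 0, seed = 13)
  sim <- generate_linked_registries(sc)
  regs <- sim$registries
  mm <- rbind(cascade_match(regs$CURATED, regs$GUT_GSMM_A),
              cascade_match(regs$CURATED, regs$HUMAN_GSMM),
              cascade_match(regs$GUT_GSMM_A, regs$HUMAN_GSMM))
  cl <- build_entity_clusters(regs, mm)
  uniq <- unique_microbial_list(cl)
  gt <- sim$ground_truth
  planted <- gt$entry_map$local_id[
    gt$entry_map$registry == "GUT_GSMM_A" &
      gt$entry_map$universe_id %in%
        gt$membership$universe_id[gt$membership$region == "g_only"]]
  expect_setequal(uniq$local_id, planted)
  expect_false(is.unsorted(tolower(uniq$name)))
  ## a cluster present in CURATED and GUT is never in the unique list
  shared <- gt$pairs[gt$pairs$registry_a == "CURATED" &
                       gt$pairs$registry_b == "GUT_GSMM_A", ]
  expect_length(intersect(uniq$local_id, shared$id_b), 0)
})

test_that("summary cardinalities reconstruct consistent venn regions", {
  v <- venn_from_cardinalities(curated_total = 50, gut_total = 100,
                               gut_and_curated = 20, gut_not_human = 70,
                               gut_unique = 55)
  expect_equal(sum(v$regions[grepl("GUT_GSMM", names(v$regions))]), 100)
  expect_equal(v$derived$gut_unique, 55)
  expect_equal(v$derived$pct_gut_not_human, 70)
  expect_error(venn_from_cardinalities(10, 100, 90, 95, 1), "inconsistent")
})
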