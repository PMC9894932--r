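ev_row <- function(id, type, spec = NA, pub = "PUB001") {
  data.frame(metabolite_id = id, evidence_type = type, publication = pub,
             organism = NA_character_, biospecimen = spec,
             substrate = NA_character_, antibiotic = NA_character_,
             bacterial_source = NA_character_, stringsAsFactors = FALSE)
}

test_that("evidence tables load through the alias vocabulary", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("metabolite_id\tevidence_type\tpublication\tbiospecimen",
               "m1\tfaecal in vitro\tP1\tculture medium",
               "m1\tgermfree\tP2\tplasma",
               "m2\tantibiotic\tP3\tserum",
               "m2\tGERMFREE_REDUCTION\tP4\tcaecal content",
               "m3\tin vitro\tP5\tsupernatant"), p)
  rec <- load_evidence_table(p)
  expect_equal(nrow(rec), 5)
  expect_equal(rec$evidence_type,
               c("FAECAL_IN_VITRO", "GERMFREE_REDUCTION", "ANTIBIOTIC_REDUCTION",
                 "GERMFREE_REDUCTION", "FAECAL_IN_VITRO"))
  expect_equal(rec$biospecimen,
               c("CULTURE_MEDIUM", "BLOOD", "BLOOD", "GUT_CONTENT",
                 "CULTURE_MEDIUM"))
  ## unknown vocabulary -> row-numbered error
  writeLines(c("metabolite_id\tevidence_type", "m1\tmetagenomics"), p)
  expect_error(load_evidence_table(p), "unknown evidence type.*row\\(s\\) 1")
})

test_that("profiles conserve record counts and type sets", {
  rec <- rbind(ev_row("m1", "FAECAL_IN_VITRO"), ev_row("m1", "FAECAL_IN_VITRO"),
               ev_row("m1", "GERMFREE_REDUCTION"),
               ev_row("m2", "ANTIBIOTIC_REDUCTION"))
  p <- evidence_profiles(rec)
  expect_equal(nrow(p), 2)
  m1 <- p[p$metabolite_id == "m1", ]
  expect_equal(m1$record_count, 3)
  expect_equal(m1$n_faecal_in_vitro, 2)
  expect_equal(m1$n_types, 2)
  expect_equal(sum(p$record_count), nrow(rec))
  expect_equal(nrow(evidence_profiles(rec[0, ])), 0)

  ## conservation over a random fixture
  fx <- generate_evidence_fixture(c(40, 25, 10), n_metabolites = 12,
                                  bucket_sizes = NULL, seed = 3)
  pp <- evidence_profiles(fx$records)
  expect_equal(sum(pp$record_count), nrow(fx$records))
  expect_equal(sum(pp$n_faecal_in_vitro), 40)
  expect_equal(sum(pp$n_germfree_reduction), 10)
})

test_that("the evidence-type partition is disjoint and exhaustive", {
  rec <- rbind(ev_row("a", "FAECAL_IN_VITRO"),
               ev_row("a", "ANTIBIOTIC_REDUCTION"),
               ev_row("a", "GERMFREE_REDUCTION"),
               ev_row("b", "FAECAL_IN_VITRO"))
  part <- venn_partition_by_evidence(evidence_profiles(rec))
  expect_equal(unname(part$by_types), c(1, 0, 1))
  expect_equal(part$n_metabolites, 2)

  ## random fixture vs brute-force recount of type-set sizes
  fx <- generate_evidence_fixture(c(60, 40, 30), n_metabolites = 50,
                                  bucket_sizes = NULL, seed = 17)
  p <- evidence_profiles(fx$records)
  part <- venn_partition_by_evidence(p)
  brute <- table(factor(
    vapply(split(fx$records$evidence_type, fx$records$metabolite_id),
           function(x) length(unique(x)), integer(1)), levels = 1:3))
  expect_equal(unname(part$by_types), as.vector(brute))
  expect_equal(sum(part$by_types), part$n_metabolites)

  bad <- data.frame(metabolite_id = "z", n_faecal_in_vitro = 0,
                    n_antibiotic_reduction = 0, n_germfree_reduction = 0,
                    record_count = 0, n_types = 0)
  expect_error(venn_partition_by_evidence(bad), "zero evidence types")
})

test_that("combined-evidence filter equals the set expression F & (A | G)", {
  rec <- rbind(ev_row("only_f", "FAECAL_IN_VITRO"),
               ev_row("f_and_a", "FAECAL_IN_VITRO"),
               ev_row("f_and_a", "ANTIBIOTIC_REDUCTION"),
               ev_row("f_and_g", "FAECAL_IN_VITRO"),
               ev_row("f_and_g", "GERMFREE_REDUCTION"),
               ev_row("a_and_g", "ANTIBIOTIC_REDUCTION"),
               ev_row("a_and_g", "GERMFREE_REDUCTION"))
  p <- evidence_profiles(rec)
  got <- combined_evidence_filter(p)
  expect_setequal(got, c("f_and_a", "f_and_g"))

  ## property on a random fixture: result == F intersect (A union G)
  fx <- generate_evidence_fixture(c(80, 50, 40), n_metabolites = 60,
                                  bucket_sizes = NULL, seed = 23)
  p <- evidence_profiles(fx$records)
  got <- combined_evidence_filter(p)
  r <- fx$records
  F <- unique(r$metabolite_id[r$evidence_type == "FAECAL_IN_VITRO"])
  A <- unique(r$metabolite_id[r$evidence_type == "ANTIBIOTIC_REDUCTION"])
  G <- unique(r$metabolite_id[r$evidence_type == "GERMFREE_REDUCTION"])
  expect_setequal(got, intersect(F, union(A, G)))
  expect_true(all(got %in% F))
})

test_that("class summaries count metabolites (not records) per class", {
  rec <- rbind(ev_row("m1", "FAECAL_IN_VITRO"), ev_row("m1", "FAECAL_IN_VITRO"),
               ev_row("m2", "FAECAL_IN_VITRO"),
               ev_row("m2", "GERMFREE_REDUCTION"),
               ev_row("m3", "ANTIBIOTIC_REDUCTION"))
  p <- evidence_profiles(rec)
  classes <- data.frame(metabolite_id = c("m1", "m2", "m3"),
                        chemont_class = c("Phenols", "Phenols", "Indoles"),
                        stringsAsFactors = FALSE)
  cs <- class_summary(p, classes)
  expect_equal(sum(cs$total), 3)
  ph <- cs[cs$class == "Phenols", ]
  expect_equal(ph$total, 2)
  expect_equal(ph$n_faecal_in_vitro, 2)   # metabolites, not the 3 records
  expect_equal(ph$n_germfree_reduction, 1)

  ## unmapped class -> "unmapped" bucket with warning, conservation holds
  mapping <- c(Phenols = "Phenols")
  expect_warning(cs2 <- class_summary(p, classes, mapping), "unmapped")
  expect_equal(sum(cs2$total), 3)
  expect_true("unmapped" %in% cs2$class)

  ## single metabolite, single class
  cs3 <- class_summary(p[1, ], classes[1, ])
  expect_equal(nrow(cs3), 1)
  expect_equal(cs3$total, 1)

  ## random fixture: per-type columns equal independent recount
  fx <- generate_evidence_fixture(c(70, 30, 30), n_metabolites = 40,
                                  bucket_sizes = NULL, seed = 31)
  p <- evidence_profiles(fx$records)
  set.seed(1)
  cls <- data.frame(metabolite_id = p$metabolite_id,
                    chemont_class = sample(LETTERS[1:5], nrow(p), TRUE),
                    stringsAsFactors = FALSE)
  cs4 <- class_summary(p, cls)
  for (cl in cs4$class) {
    ids <- cls$metabolite_id[cls$chemont_class == cl]
    r <- fx$records[fx$records$metabolite_id %in% ids, ]
    expect_equal(cs4$n_antibiotic_reduction[cs4$class == cl],
                 length(unique(r$metabolite_id[
                   r$evidence_type == "ANTIBIOTIC_REDUCTION"])))
  }
})

test_that("concentration summaries convert units and take group medians", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("metabolite_id\tbiospecimen\tanalytical_method\tvalue\tunit",
               "m1\tblood\tGC\t1\tnmol/L",
               "m1\tblood\tGC\t3\tnmol/L",
               "m1\tblood\tLC\t5\tnmol/L",
               "m2\tblood\tLC\t2\tnmol/L",
               "m2\tblood\tLC\t4\tnmol/L",
               "m3\turine\tGC\t10\tumol/L"), p)
  conc <- load_concentration_table(p)
  cs <- concentration_summary(conc)
  expect_equal(cs$median_value[cs$metabolite_id == "m1"], 3)
  ## even-sized group: mean of the central pair
  expect_equal(cs$median_value[cs$metabolite_id == "m2"], 3)
  ## 10 umol/L -> 10000 nmol/L
  expect_equal(cs$median_value[cs$metabolite_id == "m3"], 10000)
  expect_equal(cs$n[cs$metabolite_id == "m1"], 3)

  ## mixed volume/mass units in one group -> error naming the group
  writeLines(c("metabolite_id\tbiospecimen\tanalytical_method\tvalue\tunit",
               "m1\tfaeces\tGC\t1\tnmol/L",
               "m1\tfaeces\tGC\t2\tnmol/g"), p)
  expect_error(concentration_summary(load_concentration_table(p)),
               "mixed incompatible units.*m1")
})

test_that("packaged catalogs are internally consistent and queryable", {
  catalog <- combined_evidence_catalog()
  expect_equal(nrow(catalog), 108)
  expect_length(unique(catalog$upper_level_class), 17)
  ## class summary over the catalog's amino-acid rows
  p <- evidence_profiles(catalog_evidence_records(catalog))
  cls <- data.frame(metabolite_id = catalog$metabolite_id,
                    chemont_class = catalog$upper_level_class,
                    stringsAsFactors = FALSE)
  cs <- class_summary(p, cls)
  expect_equal(cs$total[cs$class == "Amino acids, peptides, and analogues"], 20)
  expect_equal(sum(cs$total), 108)

  cc <- class_counts_catalog()
  expect_equal(nrow(cc), 33)
  expect_equal(sum(cc$total), 457)
  expect_equal(sum(cc$n_faecal_in_vitro), 257)
  expect_equal(sum(cc$n_antibiotic_reduction), 209)
  expect_equal(sum(cc$n_germfree_reduction), 170)
})

test_that("class mappings and precursor links load and validate", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chemont_class\tupper_level_class",
               "Cresols\tPhenols", "Catechols\tPhenols"), p)
  mp <- load_class_mapping(p)
  expect_equal(unname(mp["Cresols"]), "Phenols")
  writeLines(c("wrong\theader", "a\tb"), p)
  expect_error(load_class_mapping(p), "must have columns")

  writeLines(c("precursor\tmetabolite_id\tcontext",
               "cholic acid\tm1\tin vitro",
               "cholic acid\tm2\tin vitro",
               "tyrosine\tm1\tgerm-free"), p)
  pl <- load_precursor_links(p)
  expect_equal(nrow(pl), 3)          # many-to-many permitted
  expect_equal(length(unique(pl$precursor)), 2)
})
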