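## End-to-end orchestration: load -> normalize -> dedupe/filter -> evidence
## summaries -> cascade/fuzzy match -> clusters -> substrate exclusion ->
## Venn/unique list -> similarity network -> results report.

#' Load a pipeline configuration from YAML
#'
#' See [pipeline_config_template()] for the recognized keys and their
#' defaults.  Referenced input paths are checked up front so that a
#' missing file is a configuration error raised before any computation.
#'
#' @param path YAML file.
#' @return a validated config list.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  defaults <- list(fuzzy_threshold = 0.92, tanimoto_threshold = 0.8,
                   fp_scheme = "PATH_HASH", fp_length = 1024L,
                   build_network = TRUE, seed = 1L, log_level = "info")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (cfg$fuzzy_threshold < 0 || cfg$fuzzy_threshold > 1) {
    stop("fuzzy_threshold out of range", call. = FALSE)
  }
  if (cfg$tanimoto_threshold <= 0 || cfg$tanimoto_threshold > 1) {
    stop("tanimoto_threshold out of range", call. = FALSE)
  }
  if (is.null(cfg$out_dir)) stop("config needs out_dir", call. = FALSE)
  for (p in c(unlist(lapply(cfg$registries, `[[`, "path")),
              cfg$evidence, cfg$concentrations, cfg$class_mapping,
              cfg$rule_table, cfg$substrate_list, cfg$review_decisions)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input does not exist: ", p, call. = FALSE)
    }
  }
  cfg
}

#' Write a pipeline configuration template with all defaults explicit
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
pipeline_config_template <- function(path) {
  tpl <- list(
    registries = list(
      list(path = "curated.tsv", source_label = "CURATED", format = "tsv"),
      list(path = "gut_model.tsv", source_label = "GUT_GSMM_A", format = "tsv"),
      list(path = "human_model.xml", source_label = "HUMAN_GSMM", format = "sbml")),
    evidence = "evidence.tsv",
    concentrations = NULL, class_mapping = NULL, rule_table = NULL,
    substrate_list = NULL, review_decisions = NULL,
    fuzzy_threshold = 0.92, tanimoto_threshold = 0.8,
    fp_scheme = "PATH_HASH", fp_length = 1024L, build_network = TRUE,
    seed = 1L, out_dir = "results", log_level = "info",
    synthetic = NULL)
  yaml::write_yaml(tpl, path)
  invisible(path)
}

stage_log <- function(log_path, stage, t0, note) {
  line <- sprintf("%s\t%.3fs\t%s", stage,
                  as.numeric(Sys.time()) - t0, note)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the full harmonization pipeline
#'
#' Stages run in order; any stage failure aborts with a stage-named error.
#' When the config carries a `synthetic` block instead of input paths, the
#' synthetic dataset (linked registries + evidence fixture) is generated
#' into `out_dir/synthetic/` first and the run proceeds on those files, so
#' a full run is reproducible from a seed alone.  Fuzzy `REVIEW`
#' candidates are written to `review_candidates.tsv`; without a
#' review-decisions file they stay unmerged (a warning says so).
#'
#' @param config config list or YAML path.
#' @return a `results_report` list (also written as `report.json`), with
#'   all stage artifacts under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  config <- validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  t0 <- as.numeric(Sys.time())
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## stage: synthetic inputs
  if (!is.null(config$synthetic)) {
    run_stage("simulate", {
      sc <- do.call(synthetic_config,
                    c(config$synthetic$registries %||% list(),
                      list(seed = config$seed)))
      sim <- generate_linked_registries(sc)
      syn_dir <- file.path(out_dir, "synthetic")
      write_synthetic_dataset(sim, syn_dir, sc)
      ev <- do.call(generate_evidence_fixture,
                    c(config$synthetic$evidence %||% list(),
                      list(seed = config$seed + 1L)))
      ## evidence ids refer to curated registry entries
      cur_ids <- sim$registries$CURATED$entries$local_id
      ev$records$metabolite_id <- cur_ids[
        match(ev$records$metabolite_id, sprintf("M%04d", seq_along(cur_ids)))]
      ev$records <- ev$records[!is.na(ev$records$metabolite_id), , drop = FALSE]
      write_tsv_chr(ev$records, file.path(syn_dir, "evidence.tsv"))
      config$registries <- lapply(names(sim$registries), function(nm) {
        list(path = file.path(syn_dir, paste0("registry_", nm, ".tsv")),
             source_label = nm, format = "tsv")
      })
      config$evidence <- file.path(syn_dir, "evidence.tsv")
      assign("ground_truth", sim$ground_truth, envir = environment(run_stage))
      stage_log(log_path, "simulate", t0,
                paste0("universe=", nrow(sim$ground_truth$membership)))
    })
  }

  rules <- run_stage("rules", {
    if (!is.null(config$rule_table)) load_rule_table(config$rule_table)
    else default_rule_table()
  })

  ## stage: load + dedupe + artifact filter
  registries <- run_stage("load", {
    regs <- lapply(config$registries, function(r) {
      fmt <- r$format %||% "tsv"
      reg <- if (fmt == "sbml") read_sbml_species(r$path, r$source_label)
             else read_registry_table(r$path, r$source_label)
      reg
    })
    names(regs) <- vapply(regs, `[[`, character(1), "source_label")
    regs
  })
  registries <- run_stage("clean", {
    lapply(registries, function(r) {
      r <- deduplicate_registry(r, rules)
      if (r$source_label != "CURATED") r <- exclude_modeling_artifacts(r)
      write_registry_table(r, file.path(out_dir,
                                        paste0("clean_", r$source_label, ".tsv")))
      r
    })
  })
  stage_log(log_path, "load+clean", t0,
            paste(vapply(registries, function(r)
              paste0(r$source_label, "=", nrow(r$entries)), character(1)),
              collapse = " "))

  ## stage: evidence summaries
  evidence <- NULL
  if (!is.null(config$evidence)) {
    evidence <- run_stage("evidence", {
      records <- load_evidence_table(config$evidence)
      profiles <- evidence_profiles(records)
      write_tsv_chr(profiles, file.path(out_dir, "evidence_profiles.tsv"))
      buckets <- if (nrow(profiles)) venn_partition_by_evidence(profiles)
                 else list(by_types = c("1" = 0L, "2" = 0L, "3" = 0L),
                           n_metabolites = 0L)
      combined <- combined_evidence_filter(profiles)
      cls <- NULL
      if ("CURATED" %in% names(registries)) {
        ce <- registries$CURATED$entries
        if (any(!is.na(ce$chemont_class)) && nrow(profiles)) {
          mapping <- if (!is.null(config$class_mapping))
            load_class_mapping(config$class_mapping) else NULL
          cls <- class_summary(profiles,
                               data.frame(metabolite_id = ce$local_id,
                                          chemont_class = ce$chemont_class,
                                          stringsAsFactors = FALSE),
                               mapping)
          write_tsv_chr(cls, file.path(out_dir, "class_summary.tsv"))
        }
      }
      conc <- NULL
      if (!is.null(config$concentrations)) {
        conc <- concentration_summary(load_concentration_table(config$concentrations))
        write_tsv_chr(conc, file.path(out_dir, "concentration_summary.tsv"))
      }
      list(records = records, profiles = profiles, buckets = buckets,
           combined = combined, class_summary = cls, concentrations = conc)
    })
    stage_log(log_path, "evidence", t0,
              paste0("records=", nrow(evidence$records),
                     " metabolites=", evidence$buckets$n_metabolites))
  }

  ## stage: cross-registry matching
  matches <- run_stage("match", {
    if (length(registries) < 2) {
      m <- empty_matches()
      write_tsv_chr(m, file.path(out_dir, "review_candidates.tsv"))
      attr(m, "n_review") <- 0L
      m
    } else {
      pairs <- utils::combn(names(registries), 2, simplify = FALSE)
      all_m <- lapply(pairs, function(p) {
        match_registries(registries[[p[1]]], registries[[p[2]]], rules = rules,
                         threshold = config$fuzzy_threshold)
      })
      cands <- do.call(rbind, lapply(all_m, attr, "candidates"))
      write_tsv_chr(cands %||% empty_matches(),
                    file.path(out_dir, "review_candidates.tsv"))
      m <- do.call(rbind, all_m)
      rownames(m) <- NULL
      attr(m, "n_review") <- sum(m$status == "REVIEW")
      m
    }
  })
  review <- NULL
  if (!is.null(config$review_decisions)) {
    review <- read_tsv_chr(config$review_decisions)
  } else if (attr(matches, "n_review") > 0) {
    warning(attr(matches, "n_review"),
            " fuzzy candidate(s) need review; no review-decisions file ",
            "given, REVIEW pairs left unmerged", call. = FALSE)
  }
  write_tsv_chr(matches, file.path(out_dir, "matches.tsv"))
  stage_log(log_path, "match", t0, paste0("matches=", nrow(matches)))

  ## stage: clusters, substrate exclusion, venn, unique list
  clusters <- run_stage("cluster", {
    build_entity_clusters(registries, matches, review)
  })
  substrate_ids <- character(0)
  if (!is.null(config$substrate_list)) {
    substrate_ids <- readLines(config$substrate_list, warn = FALSE)
    substrate_ids <- substrate_ids[nzchar(substrate_ids)]
  }
  clusters <- run_stage("substrates", {
    exclude_substrates(clusters, substrate_ids)
  })
  venn <- run_stage("venn", compute_venn(clusters))
  uniq <- run_stage("unique_list", unique_microbial_list(clusters))
  write_tsv_chr(clusters$members, file.path(out_dir, "clusters.tsv"))
  write_tsv_chr(uniq, file.path(out_dir, "unique_microbial_metabolites.tsv"))
  jsonlite::write_json(list(regions = as.list(venn$regions),
                            derived = venn$derived),
                       file.path(out_dir, "venn.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log(log_path, "venn", t0,
            paste0("clusters=", clusters$n_clusters, " unique=", nrow(uniq)))

  ## stage: similarity network over cluster representatives
  net_stats <- NULL
  if (isTRUE(config$build_network)) {
    net_stats <- run_stage("network", {
      m <- clusters$members[!is.na(clusters$members$smiles), , drop = FALSE]
      reps <- m[!duplicated(m$cluster_id), , drop = FALSE]
      if (nrow(reps) >= 1) {
        ent <- data.frame(local_id = reps$cluster_id, name = reps$name,
                          source = reps$venn_source, smiles = reps$smiles,
                          stringsAsFactors = FALSE)
        if (!is.null(evidence) && nrow(evidence$profiles)) {
          idx <- match(reps$local_id, evidence$profiles$metabolite_id)
          ent$record_count <- ifelse(is.na(idx), 0L,
                                     evidence$profiles$record_count[idx])
        }
        g <- build_similarity_network(ent, threshold = config$tanimoto_threshold,
                                      scheme = config$fp_scheme,
                                      fp_length = config$fp_length)
        export_graph(g, file.path(out_dir, "similarity_network.graphml"),
                     "graphml")
        export_graph(g, file.path(out_dir, "similarity_network.sif"), "sif")
        list(nodes = igraph::vcount(g), edges = igraph::ecount(g),
             unparseable = attr(g, "n_unparseable"))
      } else list(nodes = 0L, edges = 0L, unparseable = 0L)
    })
    stage_log(log_path, "network", t0,
              paste0("nodes=", net_stats$nodes, " edges=", net_stats$edges))
  }

  ## stage: results report
  report <- run_stage("report", {
    rep <- list(
      records_by_type = if (is.null(evidence)) NULL else
        as.list(setNames(
          vapply(EVIDENCE_TYPES, function(t)
            sum(evidence$records$evidence_type == t), integer(1)),
          EVIDENCE_TYPES)),
      total_records = if (is.null(evidence)) 0L else nrow(evidence$records),
      n_metabolites_with_evidence = if (is.null(evidence)) 0L else
        evidence$buckets$n_metabolites,
      evidence_venn_buckets = if (is.null(evidence)) NULL else
        as.list(evidence$buckets$by_types),
      combined_evidence_count = if (is.null(evidence)) 0L else
        length(evidence$combined),
      combined_evidence_classes = if (is.null(evidence) ||
                                        is.null(evidence$class_summary)) NULL else
        nrow(evidence$class_summary),
      venn_regions = as.list(venn$regions),
      venn_derived = venn$derived,
      unique_list_size = nrow(uniq),
      network = net_stats,
      provenance = list(
        package_version = as.character(utils::packageVersion("microexposome")),
        seed = config$seed,
        fuzzy_threshold = config$fuzzy_threshold,
        tanimoto_threshold = config$tanimoto_threshold,
        rule_table_hash = string_hash(paste(rules$pattern, rules$replacement,
                                            collapse = ";"), 1e9)))
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    rep
  })
  if (exists("ground_truth", inherits = FALSE)) {
    report$ground_truth <- ground_truth
  }
  stage_log(log_path, "report", t0, "done")
  class(report) <- "results_report"
  invisible(report)
}

#' @export
print.results_report <- function(x, ...) {
  cat("<results_report>\n")
  cat("  evidence records:", x$total_records, "on",
      x$n_metabolites_with_evidence, "metabolites\n")
  if (!is.null(x$evidence_venn_buckets)) {
    cat("  evidence buckets (1/2/3 types):",
        paste(unlist(x$evidence_venn_buckets), collapse = "/"), "\n")
  }
  cat("  combined evidence:", x$combined_evidence_count, "metabolites\n")
  d <- x$venn_derived
  cat(sprintf("  predicted gut set %d | in curated %d (~%d%%) | not in human %d (~%d%%) | unique %d (~%d%%)\n",
              d$gut_total, d$gut_and_curated, d$pct_gut_in_curated,
              d$gut_not_human, d$pct_gut_not_human, d$gut_unique,
              d$pct_gut_unique))
  if (!is.null(x$network)) {
    cat("  network:", x$network$nodes, "nodes,", x$network$edges, "edges\n")
  }
  invisible(x)
}
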