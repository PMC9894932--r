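## Tanimoto-thresholded chemical similarity networks.

#' Build a chemical similarity network
#'
#' Computes fingerprints for every entry's SMILES and connects two nodes
#' exactly when their Tanimoto coefficient is at or above `threshold`
#' (default 0.8).  Entries without a valid SMILES are kept as isolated
#' nodes and counted in `attr(,"n_unparseable")`.  Extra columns of
#' `entries` (e.g. `source`, `record_count`, evidence-type combination,
#' upper-level class) become node attributes, so the figure encodings —
#' node size by record count, colour by evidence types or by source model —
#' are reproducible from the exported graph.
#'
#' @param entries `data.frame` with an id column (`local_id` or `name`)
#'   and a `smiles` column; any further columns become node attributes.
#' @param threshold Tanimoto threshold in (0, 1].
#' @param scheme,fp_length fingerprint scheme and bit length, see
#'   [fingerprint_from_smiles()].
#' @return an undirected `igraph` graph with edge attribute `weight` and
#'   graph attributes `scheme`, `fp_length`, `threshold`.
#' @export
build_similarity_network <- function(entries, threshold = 0.8,
                                     scheme = "PATH_HASH", fp_length = 1024L) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single number in (0, 1]", call. = FALSE)
  }
  if (!"smiles" %in% names(entries)) stop("entries need a 'smiles' column",
                                          call. = FALSE)
  ids <- if ("local_id" %in% names(entries)) entries$local_id else entries$name
  if (anyDuplicated(ids)) stop("duplicate node ids in entries", call. = FALSE)
  scheme <- match.arg(scheme, FP_SCHEMES)
  n <- nrow(entries)
  fps <- fingerprint_batch(entries$smiles, scheme, fp_length)
  n_unparseable <- sum(!is.na(entries$smiles) &
                         vapply(fps, is.null, logical(1)))
  ## dense bit matrix -> all-pairs Tanimoto by cross products
  have <- which(!vapply(fps, is.null, logical(1)))
  edges <- matrix(integer(0), ncol = 2); weights <- numeric(0)
  if (length(have) >= 2) {
    M <- matrix(0, nrow = length(have), ncol = fp_length)
    for (k in seq_along(have)) {
      b <- fps[[have[k]]]$bits
      if (length(b)) M[k, b + 1L] <- 1
    }
    common <- tcrossprod(M)
    nb <- rowSums(M)
    un <- outer(nb, nb, "+") - common
    sim <- ifelse(un > 0, common / un, 0)
    hit <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      edges <- cbind(have[hit[, 1]], have[hit[, 2]])
      weights <- sim[hit]
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(ids))
  for (col in setdiff(names(entries), c("local_id", "smiles"))) {
    ## "name" is igraph's vertex-id attribute; keep display names as "label"
    attr_name <- if (col == "name") "label" else col
    g <- igraph::set_vertex_attr(g, attr_name, value = entries[[col]])
  }
  g <- igraph::set_vertex_attr(g, "smiles", value = entries$smiles)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
    g <- igraph::set_edge_attr(g, "weight", value = weights)
  }
  g <- igraph::set_graph_attr(g, "scheme", scheme)
  g <- igraph::set_graph_attr(g, "fp_length", as.integer(fp_length))
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  attr(g, "n_unparseable") <- n_unparseable
  g
}

#' Export a similarity network
#'
#' GraphML is the primary, attribute-bearing format and round-trips node
#' count, edge count, weights and attributes.  SIF carries topology only:
#' one `a sim b` line per edge plus one bare-id line per isolated node.
#' The edge-list TSV carries `id_a`, `id_b`, `weight`.
#'
#' @param graph an `igraph` graph from [build_similarity_network()].
#' @param path output file.
#' @param format one of `"graphml"`, `"sif"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif", "edgelist")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown export format: ",
                                              format[1], call. = FALSE))
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "sif") {
    el <- igraph::as_edgelist(graph, names = TRUE)
    lines <- if (nrow(el)) paste(el[, 1], "sim", el[, 2]) else character(0)
    iso <- igraph::V(graph)$name[igraph::degree(graph) == 0]
    writeLines(c(lines, iso), path)
  } else {
    el <- igraph::as_edgelist(graph, names = TRUE)
    df <- data.frame(id_a = el[, 1], id_b = el[, 2],
                     weight = if (nrow(el)) igraph::E(graph)$weight else numeric(0),
                     stringsAsFactors = FALSE)
    write_tsv_chr(df, path)
  }
  invisible(path)
}

#' Import a GraphML file
#' @param path GraphML file written by [export_graph()].
#' @return an `igraph` graph.
#' @export
import_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
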