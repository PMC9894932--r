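## Hashed topological fingerprints from SMILES.
##
## SMILES are parsed with ChemmineR/ChemmineOB into an atom/bond graph;
## two deterministic hashed bit-set schemes are provided:
##   PATH_HASH    - all simple linear paths of 1..7 atoms, each path's
##                  canonical element/bond-order string hashed to a bit
##                  (Daylight-style path fingerprint);
##   CIRCULAR_R2  - per-atom circular environments of radius 0, 1 and 2
##                  built from iterated neighbourhood invariants
##                  (ECFP-style).
## Fingerprints from the same scheme and length are comparable with the
## Tanimoto coefficient |A n B| / |A u B|.

FP_SCHEMES <- c("PATH_HASH", "CIRCULAR_R2")

## SMILES -> atom/bond graph via OpenBabel (ChemmineOB), reading the V2000
## molfile it emits.  OpenBabel handles aromatic perception and kekulizes,
## so identical SMILES always yield identical graphs.
parse_smiles_graph <- function(smiles) {
  txt <- ChemmineOB::convertFormat("SMI", "SDF", smiles)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("OpenBabel produced no structure")
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1) stop("no atoms parsed")
  atom_lines <- lines[4 + seq_len(n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  adj <- vector("list", n_atoms)
  if (!is.na(n_bonds) && n_bonds > 0) {
    bond_lines <- lines[4 + n_atoms + seq_len(n_bonds)]
    a <- as.integer(substr(bond_lines, 1, 3))
    b <- as.integer(substr(bond_lines, 4, 6))
    o <- as.integer(substr(bond_lines, 7, 9))
    for (i in seq_len(n_bonds)) {
      adj[[a[i]]] <- rbind(adj[[a[i]]], c(b[i], o[i]))
      adj[[b[i]]] <- rbind(adj[[b[i]]], c(a[i], o[i]))
    }
  }
  list(elements = elements, adj = adj, n = n_atoms)
}

path_strings <- function(g, max_atoms = 7L) {
  out <- character(0)
  if (g$n == 0) return(out)
  walk <- function(path, bonds_so_far) {
    last <- path[length(path)]
    s_fwd <- path_label(g, path, bonds_so_far)
    s_rev <- path_label(g, rev(path), rev(bonds_so_far))
    out[[length(out) + 1L]] <<- if (s_fwd <= s_rev) s_fwd else s_rev
    if (length(path) >= max_atoms) return()
    nb <- g$adj[[last]]
    if (is.null(nb)) return()
    for (i in seq_len(nrow(nb))) {
      nxt <- nb[i, 1]
      if (nxt %in% path) next
      walk(c(path, nxt), c(bonds_so_far, nb[i, 2]))
    }
  }
  for (start in seq_len(g$n)) walk(start, integer(0))
  unique(out)
}

path_label <- function(g, path, bonds) {
  parts <- g$elements[path[1]]
  for (i in seq_along(bonds)) {
    parts <- c(parts, bonds[i], g$elements[path[i + 1]])
  }
  paste(parts, collapse = "|")
}

circular_strings <- function(g, radius = 2L) {
  if (g$n == 0) return(character(0))
  deg <- vapply(g$adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  inv <- paste0(g$elements, ":", deg)
  out <- inv
  for (r in seq_len(radius)) {
    nxt <- character(g$n)
    for (i in seq_len(g$n)) {
      nb <- g$adj[[i]]
      env <- if (is.null(nb)) character(0) else
        sort(paste0(nb[, 2], "~", inv[nb[, 1]]))
      nxt[i] <- paste0(inv[i], "(", paste(env, collapse = ","), ")")
    }
    inv <- nxt
    out <- c(out, paste0("r", r, ":", inv))
  }
  unique(out)
}

#' Hashed fingerprint of a molecule from its SMILES
#'
#' @param smiles a single SMILES string.
#' @param scheme `"PATH_HASH"` (linear paths of up to 7 atoms) or
#'   `"CIRCULAR_R2"` (circular environments up to radius 2).
#' @param length number of bits; default 1024.
#' @return a `chem_fp` object (`bits`: sorted 0-based positions, `length`,
#'   `scheme`, `smiles`), or `NULL` with a warning when the SMILES cannot
#'   be parsed — callers treat unparseable molecules as skipped, never as a
#'   crash.
#' @examples
#' \donttest{
#' fp <- fingerprint_from_smiles("CCO")
#' tanimoto(fp, fp)   # 1
#' }
#' @export
fingerprint_from_smiles <- function(smiles, scheme = c("PATH_HASH", "CIRCULAR_R2"),
                                    length = 1024L) {
  scheme <- match.arg(scheme)
  stopifnot(is.character(smiles), length(smiles) == 1)
  g <- tryCatch(parse_smiles_graph(smiles), error = function(e) NULL)
  if (is.null(g)) {
    warning("unparseable SMILES skipped: ", smiles, call. = FALSE)
    return(NULL)
  }
  feats <- switch(scheme,
                  PATH_HASH = path_strings(g),
                  CIRCULAR_R2 = circular_strings(g))
  new_chem_fp(sort(unique(string_hash(feats, length))), length, scheme, smiles)
}

new_chem_fp <- function(bits, length, scheme, smiles) {
  structure(list(bits = as.integer(bits), length = as.integer(length),
                 scheme = scheme, smiles = smiles), class = "chem_fp")
}

#' @export
print.chem_fp <- function(x, ...) {
  cat("<chem_fp>", x$scheme, "length", x$length, "|",
      length(x$bits), "bits set |", x$smiles, "\n")
  invisible(x)
}

#' Tanimoto coefficient between two fingerprints
#'
#' `|A n B| / |A u B|` over the set bit positions; defined as 0 when both
#' fingerprints are empty (so featureless or unparseable inputs never form
#' spurious cliques).  Both fingerprints must share scheme and length.
#'
#' @param fp_a,fp_b `chem_fp` objects.
#' @return similarity in \\[0, 1\\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  stopifnot(inherits(fp_a, "chem_fp"), inherits(fp_b, "chem_fp"))
  if (fp_a$scheme != fp_b$scheme || fp_a$length != fp_b$length) {
    stop("fingerprints not comparable: scheme/length mismatch (",
         fp_a$scheme, "/", fp_a$length, " vs ", fp_b$scheme, "/", fp_b$length,
         ")", call. = FALSE)
  }
  u <- length(union(fp_a$bits, fp_b$bits))
  if (u == 0) return(0)
  length(intersect(fp_a$bits, fp_b$bits)) / u
}

## Fingerprint a vector of SMILES with de-duplication; returns a list of
## chem_fp (NULL for unparseable), one per input, with one warning per
## distinct bad SMILES.
fingerprint_batch <- function(smiles, scheme = "PATH_HASH", length = 1024L) {
  uniq <- unique(smiles[!is.na(smiles)])
  cache <- setNames(vector("list", base::length(uniq)), uniq)
  for (s in uniq) {
    cache[[s]] <- suppressWarnings(fingerprint_from_smiles(s, scheme, length))
    if (is.null(cache[[s]])) warning("unparseable SMILES skipped: ", s,
                                     call. = FALSE)
  }
  lapply(smiles, function(s) if (is.na(s)) NULL else cache[[s]])
}
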