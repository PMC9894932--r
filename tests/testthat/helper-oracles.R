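# Independent brute-force oracles used to cross-check the implementation.

# Connected components by BFS over an explicit edge list (1-based node ids).
brute_components <- function(n, edges) {
  comp <- rep(NA_integer_, n)
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# All-pairs shared-identifier / shared-name-key edges over a registry's
# entries; the criterion mirrors the documented merge rule.
brute_dedup_components <- function(reg) {
  e <- reg$entries
  n <- nrow(e)
  keyfun <- function(i) {
    vals <- c()
    for (ns in ID_NAMESPACES) {
      if (!is.na(e[[ns]][i])) vals <- c(vals, paste0(ns, "=", e[[ns]][i]))
    }
    c(vals, paste0("name=", microexposome:::name_match_key(e$name[i])))
  }
  keys <- lapply(seq_len(n), keyfun)
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (length(intersect(keys[[i]], keys[[j]]))) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  brute_components(n, edges)
}

# Indel similarity by an explicit LCS dynamic program:
# sim = 2*LCS / (nchar(a) + nchar(b)).
lcs_similarity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n + m == 0) return(1)
  L <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    L[i + 1, j + 1] <- if (x[i] == y[j]) L[i, j] + 1L else max(L[i, j + 1], L[i + 1, j])
  }
  2 * L[n + 1, m + 1] / (n + m)
}

# Exclusive three-set Venn region counts from a logical membership matrix
# (columns in_curated, in_gut, in_human), one row per entity.
brute_venn_regions <- function(membership) {
  key <- apply(membership, 1, function(r) {
    paste(c("CURATED", "GUT_GSMM", "HUMAN_GSMM")[as.logical(r)], collapse = "&")
  })
  table(key[nzchar(key)])
}

# O(n^2) edge enumeration over a fingerprint list.
brute_edges <- function(fps, threshold) {
  out <- list()
  n <- length(fps)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.null(fps[[i]]) || is.null(fps[[j]])) next
    s <- tanimoto(fps[[i]], fps[[j]])
    if (s >= threshold) out[[length(out) + 1]] <- c(i, j, s)
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, out)
}
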