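# Independent oracles and random-instance generators used across tests.

# Random spectrum with well-separated peaks (as in centroided MS/MS data).
rand_spectrum <- function(n_peaks = 8, mz_min = 50, mz_max = 800,
                          precursor = NA_real_) {
  mz <- sort(runif(n_peaks, mz_min, mz_max))
  keep <- c(TRUE, diff(mz) > 0.1)
  mz <- mz[keep]
  spectrum(mz, runif(length(mz), 0.01, 1), precursor_mz = precursor,
           collision_energy = sample(c(10, 20, 40), 1))
}

# Maximum-cardinality bipartite matching size (Kuhn's augmenting paths)
# over the ppm-tolerance adjacency; independent of match_peaks().
bipartite_max_matching_size <- function(mza, mzb, tol_ppm) {
  na <- length(mza); nb <- length(mzb)
  if (na == 0 || nb == 0) return(0L)
  adj <- outer(mza, mzb, function(a, b)
    abs(a - b) <= tol_ppm * 1e-6 * pmax(a, b))
  match_b <- rep(0L, nb)
  try_kuhn <- function(i, seen) {
    for (j in which(adj[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_b[j] == 0L || Recall(match_b[j], seen)) {
        match_b[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0L
  for (i in seq_len(na))
    if (try_kuhn(i, rep(FALSE, nb))) size <- size + 1L
  size
}

# Colored-isomorphism test used by the brute-force MCES oracle; applies
# igraph VF2 directly with its own label encoding.
oracle_iso <- function(g1, g2) {
  if (igraph::vcount(g1) != igraph::vcount(g2) ||
      igraph::ecount(g1) != igraph::ecount(g2)) return(FALSE)
  labs <- unique(c(igraph::V(g1)$element, igraph::V(g2)$element))
  ords <- unique(c(igraph::edge_attr(g1, "order"),
                   igraph::edge_attr(g2, "order"), 1))
  igraph::V(g1)$color <- match(igraph::V(g1)$element, labs)
  igraph::V(g2)$color <- match(igraph::V(g2)$element, labs)
  if (igraph::ecount(g1) > 0) {
    igraph::E(g1)$color <- match(igraph::E(g1)$order, ords)
    igraph::E(g2)$color <- match(igraph::E(g2)$order, ords)
  }
  igraph::isomorphic(g1, g2, method = "vf2")
}

# Drop vertices without incident edges (the MCES distance is defined on
# edge-induced subgraphs, so isolated vertices carry no information).
drop_isolated <- function(g)
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))

# Brute-force MCES: enumerate every pair of equal-size edge keep-sets.
brute_mces <- function(g1, g2) {
  e1 <- igraph::ecount(g1); e2 <- igraph::ecount(g2)
  for (r in seq(min(e1, e2), 0, by = -1)) {
    if (r == 0) return(e1 + e2)
    k1 <- utils::combn(e1, r, simplify = FALSE)
    k2 <- utils::combn(e2, r, simplify = FALSE)
    for (a in k1) for (b in k2) {
      s1 <- igraph::subgraph_from_edges(g1, a, delete.vertices = TRUE)
      s2 <- igraph::subgraph_from_edges(g2, b, delete.vertices = TRUE)
      if (oracle_iso(s1, s2)) return((e1 - r) + (e2 - r))
    }
  }
  e1 + e2
}

# Random small molecular graph (simple, possibly disconnected).
rand_molgraph <- function(n_vertices = 5, n_edges = 4,
                          elements = c("C", "C", "C", "N", "O")) {
  all_pairs <- t(utils::combn(n_vertices, 2))
  pick <- sample.int(nrow(all_pairs), min(n_edges, nrow(all_pairs)))
  molecular_graph(sample(elements, n_vertices, replace = TRUE),
                  cbind(all_pairs[pick, , drop = FALSE],
                        sample(1:2, length(pick), replace = TRUE)))
}

# Independent subformula check: expand.grid over element counts with its
# own monoisotopic mass table.
ORACLE_MASSES <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151, S = 31.97207069)
naive_decomposable <- function(peak_mz, formula, tol_ppm,
                               adduct_mass = 1.00727646688) {
  counts <- sapply(strsplit(gsub("([A-Z][a-z]?)([0-9]*)", "\\1:\\2;",
                                 formula), ";")[[1]], function(tok) {
    kv <- strsplit(tok, ":")[[1]]
    n <- if (length(kv) < 2 || kv[2] == "") 1L else as.integer(kv[2])
    stats::setNames(n, kv[1])
  })
  names(counts) <- gsub(":.*", "", gsub("[0-9;]", "", names(counts)))
  grid <- do.call(expand.grid, lapply(counts, function(n) 0:n))
  masses <- as.matrix(grid) %*% ORACLE_MASSES[names(counts)] + adduct_mass
  any(abs(masses - peak_mz) <= tol_ppm * 1e-6 * pmax(masses, peak_mz))
}

# Default schema feature columns of a hit dataset.
feature_cols <- function(df) df[, default_feature_schema()$name]
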