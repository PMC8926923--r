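#' Tanimoto coefficient of two fingerprints
#'
#' The Jaccard index of two sets of molecular-property indices: the size
#' of the intersection divided by the size of the union. Fingerprint
#' semantics are user-defined; any binary property universe works.
#'
#' @param a,b Vectors of property indices (any atomic type); duplicates
#'   are ignored.
#' @return Similarity in `[0, 1]`; two empty sets count as identical (1).
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Hydrogen-free molecular graph
#'
#' Atoms are element-labeled vertices, bonds are edges labeled with their
#' multiplicity; hydrogens are excluded. Connectivity is not required.
#'
#' @param atoms Character vector of element symbols (vertex labels);
#'   entries equal to `"H"` are dropped together with their bonds.
#' @param bonds Matrix or data.frame with columns `from`, `to`, `order`
#'   (1-based atom indices, bond multiplicity).
#' @return An igraph object with vertex attribute `element` and edge
#'   attribute `order`, of class `molecular_graph`/`igraph`.
#' @export
molecular_graph <- function(atoms, bonds) {
  atoms <- as.character(atoms)
  bonds <- as.matrix(bonds)
  if (nrow(bonds) > 0 && ncol(bonds) < 3)
    stop("bonds need columns from, to, order")
  heavy <- which(atoms != "H")
  remap <- match(seq_along(atoms), heavy)
  g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  igraph::V(g)$element <- atoms[heavy]
  if (nrow(bonds) > 0) {
    keep <- atoms[bonds[, 1]] != "H" & atoms[bonds[, 2]] != "H"
    bonds <- bonds[keep, , drop = FALSE]
    if (nrow(bonds) > 0) {
      g <- igraph::add_edges(g,
        rbind(remap[bonds[, 1]], remap[bonds[, 2]]),
        order = as.numeric(bonds[, 3]))
    }
  }
  class(g) <- c("molecular_graph", class(g))
  g
}

#' Parse a SMILES string into a molecular graph
#'
#' Uses ChemmineR/ChemmineOB to interpret the SMILES; hydrogens are left
#' implicit and therefore absent from the graph.
#'
#' @param smiles A single SMILES string.
#' @return A [molecular_graph()].
#' @export
smiles_to_graph <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("smiles_to_graph requires the ChemmineR package")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  sdf <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- gsub("_.*$", "", rownames(ab))
  if (length(atoms) == 0) stop("cannot parse SMILES: ", smiles)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0)
    matrix(numeric(), ncol = 3)
  else cbind(from = bb[, 1], to = bb[, 2], order = bb[, 3])
  molecular_graph(atoms, bonds)
}

edge_type_signature <- function(g, eids = igraph::E(g)) {
  if (length(eids) == 0) return(character())
  ends <- igraph::ends(g, eids, names = FALSE)
  el <- igraph::V(g)$element
  a <- el[ends[, 1]]
  b <- el[ends[, 2]]
  ord <- igraph::edge_attr(g, "order", eids)
  sort(paste(pmin(a, b), pmax(a, b), ord, sep = "-"))
}

colored_copy <- function(g, elements, orders) {
  igraph::V(g)$color <- match(igraph::V(g)$element, elements)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$color <- match(igraph::E(g)$order, orders)
  g
}

iso_molgraph <- function(g1, g2) {
  if (igraph::vcount(g1) != igraph::vcount(g2) ||
      igraph::ecount(g1) != igraph::ecount(g2)) return(FALSE)
  elements <- sort(unique(c(igraph::V(g1)$element, igraph::V(g2)$element)))
  orders <- sort(unique(c(igraph::edge_attr(g1, "order"),
                          igraph::edge_attr(g2, "order"))))
  igraph::isomorphic(colored_copy(g1, elements, orders),
                     colored_copy(g2, elements, orders),
                     method = "vf2")
}

edge_subgraph <- function(g, eids) {
  igraph::subgraph_from_edges(g, eids, delete.vertices = TRUE)
}

#' Exact MCES edge-deletion distance between two molecular graphs
#'
#' The minimum total number of edges that must be removed from the two
#' graphs so that the remaining edge-induced subgraphs are isomorphic
#' (element labels and bond multiplicities must match; the common subgraph
#' need not be connected). This is the maximum common edge subgraph
#' problem, which is NP-complete; the solver is exact and intended for
#' small molecules only. A useful consequence: two non-isomorphic graphs
#' with the same number of edges are at distance at least 2.
#'
#' @param g1,g2 [molecular_graph()] objects (or igraphs with `element`
#'   vertex and `order` edge attributes).
#' @param max_size Refuse instances with more than this many combined
#'   edges (default 30); the search is exponential in the worst case.
#' @return Non-negative integer distance; 0 iff the graphs are isomorphic.
#' @examples
#' butane <- molecular_graph(rep("C", 4),
#'   cbind(from = 1:3, to = 2:4, order = 1))
#' isobutane <- molecular_graph(rep("C", 4),
#'   cbind(from = c(1, 1, 1), to = 2:4, order = 1))
#' mces_distance(butane, isobutane)  # 2
#' @export
mces_distance <- function(g1, g2, max_size = 30) {
  e1 <- igraph::ecount(g1); e2 <- igraph::ecount(g2)
  if (e1 + e2 > max_size)
    stop("combined edge count ", e1 + e2, " exceeds max_size = ", max_size,
         "; the exact solver is limited to small molecules")
  if (e2 > e1) { tmp <- g1; g1 <- g2; g2 <- tmp; tmp <- e1; e1 <- e2
                 e2 <- tmp }
  # upper bound on the common edge count from edge-type multisets
  sig1 <- table(edge_type_signature(g1))
  sig2 <- table(edge_type_signature(g2))
  shared <- intersect(names(sig1), names(sig2))
  r_ub <- sum(pmin(as.integer(sig1[shared]), as.integer(sig2[shared])))
  for (r in seq(min(r_ub, e2), 0, by = -1)) {
    if (r == 0) return(e1 + e2)
    keep1 <- utils::combn(e1, r, simplify = FALSE)
    keep2 <- utils::combn(e2, r, simplify = FALSE)
    sub1 <- lapply(keep1, function(k) edge_subgraph(g1, k))
    sub2 <- lapply(keep2, function(k) edge_subgraph(g2, k))
    s1 <- vapply(keep1, function(k)
      paste(edge_type_signature(g1, igraph::E(g1)[k]), collapse = "|"),
      character(1))
    s2 <- vapply(keep2, function(k)
      paste(edge_type_signature(g2, igraph::E(g2)[k]), collapse = "|"),
      character(1))
    for (i in seq_along(sub1)) {
      js <- which(s2 == s1[i])
      for (j in js) {
        if (iso_molgraph(sub1[[i]], sub2[[j]]))
          return((e1 - r) + (e2 - r))
      }
    }
  }
  e1 + e2
}

strip_stereo <- function(smiles) gsub("[@/\\\\]", "", smiles)

canonical_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("canonical_smiles requires the ChemmineOB package")
  out <- trimws(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  if (!nzchar(out)) stop("cannot parse SMILES: ", smiles)
  out
}

#' Are two structures identical in 2D?
#'
#' Compares atom identity and connectivity (with bond multiplicities)
#' while ignoring stereo-configuration: stereo markers are stripped from
#' both SMILES and the canonical forms are compared. Enantiomers and
#' diastereomers therefore count as identical, which matches how MS/MS
#' annotation correctness is judged.
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @return Logical.
#' @export
structures_identical_2d <- function(smiles_a, smiles_b) {
  identical(canonical_smiles(strip_stereo(smiles_a)),
            canonical_smiles(strip_stereo(smiles_b)))
}
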