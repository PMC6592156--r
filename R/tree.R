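#' Pearson correlation between two amino-acid indices
#'
#' Computed over the 20-residue value vectors, pairwise-complete on the
#' letters both indices score. Returns `NA` (a missing edge, not an
#' error) when fewer than 3 letters are shared.
#'
#' @param a,b [property_index()] objects.
#' @return Pearson r, or `NA_real_`.
#' @export
index_correlation <- function(a, b) {
  ok <- !is.na(a$values) & !is.na(b$values)
  if (sum(ok) < 3L) return(NA_real_)
  va <- a$values[ok]; vb <- b$values[ok]
  if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
  cor(va, vb)
}

#' Minimum spanning tree over amino-acid property similarity
#'
#' Builds the complete weighted graph on the supplied indices with edge
#' weight `w = 1 - |r|`, `r` the Pearson correlation between the two
#' indices' residue value vectors, and extracts the minimum spanning tree
#' with Kruskal's algorithm. Ties between equal-weight edges are broken
#' deterministically by the lexicographic order of the accession pair, so
#' the returned tree is reproducible across runs and platforms. If some
#' edges are missing (too few shared residues) and the graph is
#' disconnected, a spanning forest is returned with a warning.
#'
#' @param indices List of two or more [property_index()] objects.
#' @return A `property_graph`: list with `nodes` (data.table `accession`,
#'   `description`, `category`, and annotation columns `q`, `L`,
#'   `direction`, filled by [annotate_graph()]), `edges` (MST edge list
#'   with `from`, `to`, `weight`, `r`), `n_components`, `total_weight`.
#' @export
build_mst <- function(indices) {
  if (length(indices) < 2L) stop("at least 2 indices required")
  accs <- vapply(indices, `[[`, character(1), "accession")
  if (anyDuplicated(accs)) stop("duplicate index accessions")
  ord <- order(accs)
  indices <- indices[ord]; accs <- accs[ord]
  k <- length(indices)
  pairs <- combn(k, 2)
  r <- vapply(seq_len(ncol(pairs)), function(e) {
    index_correlation(indices[[pairs[1, e]]], indices[[pairs[2, e]]])
  }, numeric(1))
  edges <- data.table(from = accs[pairs[1, ]], to = accs[pairs[2, ]], r = r)
  edges <- edges[!is.na(r)]
  edges[, weight := 1 - abs(r)]

  mst_edges <- kruskal_mst(edges, accs)
  n_comp <- k - nrow(mst_edges)
  if (n_comp > 1L)
    warning("property graph is disconnected: returning a spanning forest ",
            "with ", n_comp, " components")
  nodes <- data.table(
    accession = accs,
    description = vapply(indices, `[[`, character(1), "description"),
    category = vapply(indices, `[[`, character(1), "category"),
    q = NA_real_, L = NA_real_, direction = "none")
  structure(list(nodes = nodes, edges = mst_edges, n_components = n_comp,
                 total_weight = sum(mst_edges$weight)),
            class = "property_graph")
}

# Kruskal with union-find; edges sorted by (weight, from, to) where
# from < to lexicographically.
kruskal_mst <- function(edges, node_ids) {
  e <- copy(as.data.table(edges))
  swap <- e$from > e$to
  if (any(swap)) e[swap, c("from", "to") := .(to, from)]
  setorder(e, weight, from, to)
  parent <- seq_along(node_ids)
  names(parent) <- node_ids
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(e))
  fi <- match(e$from, node_ids); ti <- match(e$to, node_ids)
  for (row in seq_len(nrow(e))) {
    a <- find(fi[row]); b <- find(ti[row])
    if (a != b) {
      parent[a] <- b
      keep[row] <- TRUE
    }
  }
  e[keep]
}

#' @export
print.property_graph <- function(x, ...) {
  cat(sprintf("property_graph: %d nodes, %d MST edges, %d component(s), total weight %.4f\n",
              nrow(x$nodes), nrow(x$edges), x$n_components, x$total_weight))
  invisible(x)
}

#' Annotate a property graph with enrichment results
#'
#' Attaches `q`, `L` and the dispersion direction to each node from a
#' lessening-scan table. Nodes without a significant result (or absent
#' from the table) carry direction `"none"`; accessions in the table that
#' are not in the graph trigger a warning and are ignored.
#'
#' @param graph A `property_graph` from [build_mst()].
#' @param enrichment A [lessening_scan()] result (or [enrichment_table()]
#'   subset) keyed by `accession`.
#' @param q_threshold Nodes with `q` at or above this keep direction
#'   `"none"` (default 0.005).
#' @return The annotated `property_graph`.
#' @export
annotate_graph <- function(graph, enrichment, q_threshold = 0.005) {
  enr <- as.data.table(enrichment)
  unknown <- setdiff(enr$accession, graph$nodes$accession)
  if (length(unknown))
    warning("enrichment accession(s) not in graph: ",
            paste(head(unknown, 5), collapse = ", "))
  enr <- enr[accession %in% graph$nodes$accession]
  nodes <- copy(graph$nodes)
  i <- match(enr$accession, nodes$accession)
  nodes$q[i] <- enr$q
  nodes$L[i] <- enr$L
  sig <- !is.na(enr$q) & enr$q < q_threshold
  nodes$direction[i[sig]] <- enr$direction[sig]
  graph$nodes <- nodes
  graph
}

#' Export a property graph
#'
#' Writes the MST with node attributes (category, q, L, direction) as
#' GraphML or DOT via igraph, or as a plain TSV edge list.
#'
#' @param graph A `property_graph`.
#' @param path Output file.
#' @param format `"graphml"`, `"dot"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_property_graph <- function(graph,
                                  path,
                                  format = c("graphml", "dot", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    fwrite(graph$edges, path, sep = "\t")
    return(invisible(path))
  }
  nodes <- copy(graph$nodes)
  nodes[is.na(q), q := -1]  # GraphML has no NA; -1 marks "not tested"
  nodes[is.na(L), L := -1]
  g <- igraph::graph_from_data_frame(
    graph$edges[, .(from, to, weight, r)], directed = FALSE,
    vertices = as.data.frame(nodes))
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Convert a property graph to an igraph object
#'
#' @param graph A `property_graph`.
#' @return An undirected igraph graph with the same nodes, edges and
#'   attributes.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, .(from, to, weight, r)], directed = FALSE,
    vertices = as.data.frame(graph$nodes))
}
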