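#' Construct a protein-protein interaction graph
#'
#' Builds an undirected simple graph from parallel vectors of interacting
#' protein identifiers. Self-interactions and duplicate interactions (in
#' either orientation) are removed. Vertex order is the order of first
#' appearance in the input (scanning each pair left to right), and is the
#' row/column order of every matrix derived from the graph.
#'
#' @param from,to character vectors of equal length; one interaction per
#'   element pair.
#' @param vertices optional character vector of vertex IDs to include even
#'   when isolated; appended (in the given order) after vertices seen in
#'   `from`/`to`.
#' @return An object of class `ProteinGraph`: a list with elements
#'   `vertices` (character), `edges` (two-column integer matrix of vertex
#'   indices, smaller index first) and `adj` (per-vertex integer neighbour
#'   index list).
#' @examples
#' g <- protein_graph(c("a", "b", "a"), c("b", "c", "a"))
#' g$vertices
#' @export
protein_graph <- function(from, to, vertices = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("'from' and 'to' must have equal length")
  }
  ids <- unique(c(rbind(from, to)))
  if (!is.null(vertices)) {
    ids <- unique(c(ids, as.character(vertices)))
  }
  n <- length(ids)
  idx <- seq_len(n)
  names(idx) <- ids
  i <- unname(idx[from])
  j <- unname(idx[to])
  keep <- i != j
  i <- i[keep]
  j <- j[keep]
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  if (length(lo)) {
    dup <- duplicated(lo * (n + 1) + hi)
    lo <- lo[!dup]
    hi <- hi[!dup]
  }
  adj <- vector("list", n)
  for (k in idx) adj[[k]] <- integer(0)
  if (length(lo)) {
    tab <- split(c(hi, lo), c(lo, hi))
    for (nm in names(tab)) {
      adj[[as.integer(nm)]] <- sort(unique(tab[[nm]]))
    }
  }
  structure(
    list(vertices = ids,
         edges = cbind(i = lo, j = hi),
         adj = adj),
    class = "ProteinGraph"
  )
}

#' @export
print.ProteinGraph <- function(x, ...) {
  cat(sprintf("ProteinGraph: %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Number of vertices / edges of a ProteinGraph
#' @param g a `ProteinGraph`.
#' @return integer count.
#' @export
n_vertices <- function(g) length(g$vertices)

#' @rdname n_vertices
#' @export
n_edges <- function(g) nrow(g$edges)

#' Neighbours of a vertex
#' @param g a `ProteinGraph`.
#' @param v a vertex ID.
#' @return character vector of neighbouring vertex IDs.
#' @export
neighbors_of <- function(g, v) {
  i <- vertex_index(g, v)
  g$vertices[g$adj[[i]]]
}

# Resolve vertex IDs to indices; errors on unknown IDs.
vertex_index <- function(g, v) {
  i <- match(as.character(v), g$vertices)
  if (anyNA(i)) {
    stop("vertex not in graph: ", paste(v[is.na(i)], collapse = ", "))
  }
  i
}

#' Convert a ProteinGraph to an igraph object
#'
#' @param g a `ProteinGraph`.
#' @return an [igraph::graph] with the same vertex order and edge set.
#' @export
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$vertices), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$vertices)
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(ig, t(g$edges))
  }
  ig
}

#' Read a PPI network from an edge-list file
#'
#' The file holds one interaction per line as two whitespace- or
#' TAB-separated protein IDs; extra columns are ignored, as are blank lines
#' and lines starting with `#`. Self-interactions and repeated interactions
#' are removed.
#'
#' @param path path to the edge-list file.
#' @return a [protein_graph()].
#' @export
load_network <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read network file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(protein_graph(character(0), character(0)))
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("line %d of %s has fewer than 2 fields",
                 lineno[bad[1]], path))
  }
  protein_graph(vapply(toks, `[[`, "", 1L),
                vapply(toks, `[[`, "", 2L))
}

#' Write a PPI network as an edge list
#'
#' Edges are emitted with the lexicographically smaller ID first and sorted,
#' so output is canonical: `load_network()` followed by `write_network()`
#' round-trips the edge set exactly.
#'
#' @param g a `ProteinGraph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path) {
  a <- g$vertices[g$edges[, 1]]
  b <- g$vertices[g$edges[, 2]]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  o <- order(lo, hi)
  writeLines(paste(lo[o], hi[o], sep = "\t"), path)
  invisible(path)
}

#' Jaccard-weighted adjacency matrix
#'
#' For each interaction the confidence weight is the Jaccard similarity of
#' the two neighbourhoods, `|N(u) n N(v)| / |N(u) u N(v)|`. Each diagonal
#' entry is the maximum off-diagonal weight of its row (a self-loop as
#' strong as the strongest incident similarity); isolated vertices get
#' diagonal 1 so their flow column is well defined. Non-adjacent distinct
#' pairs stay 0.
#'
#' Peripheral edges whose endpoints share no neighbour have Jaccard weight
#' 0, which would disconnect the flow there; `floor` keeps every true edge
#' at a small positive weight. Set `floor = 0` for the literal formula.
#'
#' @param g a `ProteinGraph` with at least one vertex.
#' @param floor minimum weight applied to true edges, in `[0, 1)`.
#' @return a symmetric sparse `Matrix` with vertex IDs as dimnames.
#' @export
build_adjacency <- function(g, floor = 0.01) {
  stopifnot(length(g$vertices) >= 1, floor >= 0, floor < 1)
  n <- length(g$vertices)
  ei <- g$edges[, 1]
  ej <- g$edges[, 2]
  wt <- numeric(length(ei))
  for (k in seq_along(ei)) {
    ni <- g$adj[[ei[k]]]
    nj <- g$adj[[ej[k]]]
    wt[k] <- length(intersect(ni, nj)) / length(union(ni, nj))
  }
  wt <- pmax(wt, floor)
  diagw <- numeric(n)
  for (k in seq_along(ei)) {
    diagw[ei[k]] <- max(diagw[ei[k]], wt[k])
    diagw[ej[k]] <- max(diagw[ej[k]], wt[k])
  }
  deg <- lengths(g$adj)
  diagw[deg == 0] <- 1
  A <- Matrix::sparseMatrix(
    i = c(ei, ej, seq_len(n)),
    j = c(ej, ei, seq_len(n)),
    x = c(wt, wt, diagw),
    dims = c(n, n),
    dimnames = list(g$vertices, g$vertices)
  )
  Matrix::drop0(A)
}

#' Column-stochastic flow matrix
#'
#' Normalizes each column of a weighted adjacency matrix to sum to 1, giving
#' the transition matrix of the random walk that the Markov Cluster
#' Algorithm iterates. A column summing to 0 (possible only with
#' `floor = 0`) is replaced by the unit column on its own diagonal.
#'
#' @param A square weighted adjacency `Matrix`.
#' @return a sparse column-stochastic `Matrix`.
#' @export
build_flow_matrix <- function(A) {
  stopifnot(nrow(A) == ncol(A))
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  cs <- Matrix::colSums(A)
  zero <- which(cs == 0)
  if (length(zero)) {
    A[cbind(zero, zero)] <- 1
    cs[zero] <- 1
  }
  M <- A %*% Matrix::Diagonal(x = 1 / cs)
  dimnames(M) <- dimnames(A)
  Matrix::drop0(M)
}

#' Test column-stochasticity
#'
#' @param M a matrix.
#' @param tol tolerance on each column sum's deviation from 1.
#' @return `TRUE` if all entries are non-negative and every column sums to 1
#'   within `tol`.
#' @export
is_column_stochastic <- function(M, tol = 1e-9) {
  min(M) >= 0 && all(abs(Matrix::colSums(M) - 1) <= tol)
}
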