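# BFS from one source over the adjacency list: shortest-path distance and
# number of distinct shortest paths to every vertex. Distances are Inf for
# unreachable vertices.
bfs_paths <- function(g, src) {
  n <- length(g$vertices)
  dist <- rep(Inf, n)
  npaths <- numeric(n)
  dist[src] <- 0
  npaths[src] <- 1
  queue <- integer(n)
  queue[1] <- src
  head <- 1L
  tail <- 1L
  adj <- g$adj
  while (head <= tail) {
    u <- queue[head]
    head <- head + 1L
    du <- dist[u]
    for (v in adj[[u]]) {
      if (is.infinite(dist[v])) {
        dist[v] <- du + 1
        npaths[v] <- npaths[u]
        tail <- tail + 1L
        queue[tail] <- v
      } else if (dist[v] == du + 1) {
        npaths[v] <- npaths[v] + npaths[u]
      }
    }
  }
  list(dist = dist, npaths = npaths)
}

#' n-connection indicator between two proteins
#'
#' Two distinct proteins are n-connected when their shortest-path distance
#' in the whole network is at most `n` (default mode `at_most`; a direct
#' interaction is a 1-connection). Mode `exact` requires the distance to be
#' exactly `n`. A vertex is never connected to itself.
#'
#' @param g a `ProteinGraph`.
#' @param u,v vertex IDs.
#' @param n path-length bound (the features below use n = 2 by default;
#'   n = 3 is the other scale of interest).
#' @param mode `"at_most"` or `"exact"`.
#' @return 0 or 1.
#' @export
connect <- function(g, u, v, n = 2, mode = c("at_most", "exact")) {
  mode <- match.arg(mode)
  iu <- vertex_index(g, u)
  iv <- vertex_index(g, v)
  if (iu == iv) return(0L)
  d <- bfs_paths(g, iu)$dist[iv]
  if (mode == "at_most") {
    as.integer(d >= 1 && d <= n)
  } else {
    as.integer(d == n)
  }
}

#' Number of shortest paths of length exactly n
#'
#' Counts the distinct shortest paths between two proteins, returning 0
#' unless the shortest-path distance equals `n`.
#'
#' @inheritParams connect
#' @return non-negative integer count.
#' @export
path_num <- function(g, u, v, n = 2) {
  iu <- vertex_index(g, u)
  iv <- vertex_index(g, v)
  if (iu == iv) return(0)
  b <- bfs_paths(g, iu)
  if (b$dist[iv] == n) b$npaths[iv] else 0
}

#' Connection ratio of a protein to a complex
#'
#' Fraction of complex members that are n-connected to `v` (`v` itself, if
#' a member, contributes 0 while staying in the denominator).
#'
#' @param g a `ProteinGraph`.
#' @param v a vertex ID.
#' @param C character vector of complex member IDs (non-empty).
#' @param n path-length bound.
#' @param mode see [connect()].
#' @return value in `[0, 1]`.
#' @export
connect_ratio <- function(g, v, C, n = 2, mode = c("at_most", "exact")) {
  mode <- match.arg(mode)
  C <- unique(as.character(C))
  if (!length(C)) stop("empty complex")
  iv <- vertex_index(g, v)
  ic <- vertex_index(g, C)
  d <- bfs_paths(g, iv)$dist[ic]
  d[ic == iv] <- Inf
  if (mode == "at_most") {
    sum(d >= 1 & d <= n) / length(C)
  } else {
    sum(d == n) / length(C)
  }
}

#' Shortest-path ratio of a protein to a complex
#'
#' Mean over complex members of the number of length-`n` shortest paths
#' from `v` (members at a different distance contribute 0).
#'
#' @inheritParams connect_ratio
#' @return non-negative value (not bounded by 1).
#' @export
path_ratio <- function(g, v, C, n = 2) {
  C <- unique(as.character(C))
  if (!length(C)) stop("empty complex")
  iv <- vertex_index(g, v)
  ic <- vertex_index(g, C)
  b <- bfs_paths(g, iv)
  cnt <- ifelse(b$dist[ic] == n, b$npaths[ic], 0)
  cnt[ic == iv] <- 0
  sum(cnt) / length(C)
}

#' n-connection density of a complex
#'
#' Sum of the n-connection indicator over all ordered member pairs, divided
#' by `|C|^2` (the diagonal contributes 0 but stays in the denominator).
#' Distances are taken in the whole network, not the induced subgraph.
#'
#' @param g a `ProteinGraph`.
#' @param C character vector of member IDs, `|C| >= 2`.
#' @param n path-length bound.
#' @param mode see [connect()].
#' @return value in `[0, 1)` (strictly below 1 because of the diagonal).
#' @export
density <- function(g, C, n = 2, mode = c("at_most", "exact")) {
  mode <- match.arg(mode)
  C <- unique(as.character(C))
  if (length(C) < 2) stop("density requires a complex of size >= 2")
  ic <- vertex_index(g, C)
  s <- length(ic)
  total <- 0
  for (i in ic) {
    d <- bfs_paths(g, i)$dist[ic]
    d[ic == i] <- Inf
    total <- total + if (mode == "at_most") sum(d >= 1 & d <= n) else sum(d == n)
  }
  total / (s * s)
}

#' Density change from adding a protein to a complex
#'
#' `Den(C + v, n) - Den(C, n)`: positive when `v` is at least as well
#' connected to the members as they are among themselves.
#'
#' @inheritParams density
#' @param v a vertex ID not already in `C`.
#' @return a signed value.
#' @export
density_diff <- function(g, v, C, n = 2, mode = c("at_most", "exact")) {
  mode <- match.arg(mode)
  C <- unique(as.character(C))
  if (v %in% C) stop("density_diff: v is already a member of C")
  density(g, c(C, v), n, mode) - density(g, C, n, mode)
}

#' Co-expression value of a complex
#'
#' Sum of pairwise co-expression over ordered distinct member pairs,
#' divided by `|C|^2` (self terms excluded from the sum but not the
#' denominator).
#'
#' @param C character vector of member IDs, `|C| >= 2`.
#' @param ctx a [coexpression_context()].
#' @return the complex co-expression value.
#' @export
eco_complex <- function(C, ctx) {
  C <- unique(as.character(C))
  if (length(C) < 2) stop("eco_complex requires a complex of size >= 2")
  E <- ctx$eco[C, C]
  sum(E) / (length(C)^2)
}

#' Co-expression value between a protein and a complex
#'
#' Mean pairwise co-expression of `v` with the members (`v` itself, if a
#' member, contributes 0).
#'
#' @param v a vertex ID.
#' @param C character vector of member IDs (non-empty).
#' @param ctx a [coexpression_context()].
#' @return the protein-complex co-expression value.
#' @export
eco_protein_complex <- function(v, C, ctx) {
  C <- unique(as.character(C))
  if (!length(C)) stop("empty complex")
  vals <- ctx$eco[v, C]
  vals[C == v] <- 0
  sum(vals) / length(C)
}

#' Co-expressed pair ratio of a complex
#'
#' Fraction of ordered distinct member pairs whose co-expression indicator
#' is 1, over `|C|^2`.
#'
#' @inheritParams eco_complex
#' @return value in `[0, 1)`.
#' @export
co_ratio <- function(C, ctx) {
  C <- unique(as.character(C))
  if (!length(C)) stop("empty complex")
  sum(ctx$co[C, C]) / (length(C)^2)
}

#' Co-expression change from adding a protein to a complex
#'
#' `E_co(C + v) - E_co(C)`.
#'
#' @inheritParams eco_protein_complex
#' @return a signed value.
#' @export
co_diff <- function(v, C, ctx) {
  C <- unique(as.character(C))
  if (v %in% C) stop("co_diff: v is already a member of C")
  eco_complex(c(C, v), ctx) - eco_complex(C, ctx)
}

#' Number and ratio of members co-expressed with a protein
#'
#' `co_pro_num` counts members whose co-expression indicator with `v` is 1;
#' `co_pro_ratio` divides by `|C|`.
#'
#' @inheritParams eco_protein_complex
#' @return integer count / value in `[0, 1]`.
#' @export
co_pro_num <- function(v, C, ctx) {
  C <- unique(as.character(C))
  if (!length(C)) stop("empty complex")
  vals <- ctx$co[v, C]
  vals[C == v] <- 0L
  sum(vals)
}

#' @rdname co_pro_num
#' @export
co_pro_ratio <- function(v, C, ctx) {
  co_pro_num(v, C, ctx) / length(unique(as.character(C)))
}

#' The seven-feature vector of a protein against a complex
#'
#' The features scored by the refinement stage, in fixed order:
#' `connect_ratio`, `path_ratio`, `den_diff` (graph topology at `n`),
#' `eco`, `co_diff`, `co_pro_num`, `co_pro_ratio` (co-expression). For a
#' deletion candidate the caller strips `v` from the complex first and
#' scores `v` against the remainder.
#'
#' @param g a `ProteinGraph`.
#' @param v a vertex ID with `v` not in `C`.
#' @param C character vector of member IDs.
#' @param ctx a [coexpression_context()].
#' @param n path-length bound for the topology features (default 2).
#' @return named numeric vector of length 7.
#' @export
feature_vector <- function(g, v, C, ctx, n = 2) {
  C <- unique(as.character(C))
  if (v %in% C) stop("feature_vector: v must not be a member of C")
  c(connect_ratio = connect_ratio(g, v, C, n),
    path_ratio = path_ratio(g, v, C, n),
    den_diff = density_diff(g, v, C, n),
    eco = eco_protein_complex(v, C, ctx),
    co_diff = co_diff(v, C, ctx),
    co_pro_num = co_pro_num(v, C, ctx),
    co_pro_ratio = co_pro_ratio(v, C, ctx))
}
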