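# Shared fixtures and independent oracles (igraph-based) for the suite.

# random G(n, p) ProteinGraph with vertices v1..vn, deterministic per seed
random_graph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  pr <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pr)) < p
  protein_graph(ids[pr[1, keep]], ids[pr[2, keep]], vertices = ids)
}

path_graph <- function(ids) {
  protein_graph(ids[-length(ids)], ids[-1])
}

cycle_graph <- function(ids) {
  protein_graph(ids, c(ids[-1], ids[1]))
}

clique_graph <- function(ids) {
  pr <- utils::combn(length(ids), 2)
  protein_graph(ids[pr[1, ]], ids[pr[2, ]])
}

# igraph oracle: full shortest-path distance matrix
oracle_distances <- function(g) {
  d <- igraph::distances(as_igraph(g))
  dimnames(d) <- list(g$vertices, g$vertices)
  d
}

# igraph oracle: number of shortest paths from u to every vertex
oracle_path_counts <- function(g, u) {
  ig <- as_igraph(g)
  res <- igraph::all_shortest_paths(ig, from = u)$res
  ends <- vapply(res, function(p) igraph::as_ids(p)[length(p)], "")
  cnt <- table(ends)
  out <- stats::setNames(numeric(length(g$vertices)), g$vertices)
  out[names(cnt)] <- as.numeric(cnt)
  out[u] <- 0
  out
}

# component membership oracle
oracle_components <- function(g) {
  comp <- igraph::components(as_igraph(g))$membership
  stats::setNames(comp, g$vertices)
}

# brute-force Jaccard of neighbourhoods via plain set operations
oracle_jaccard <- function(g, u, v) {
  nu <- neighbors_of(g, u)
  nv <- neighbors_of(g, v)
  length(intersect(nu, nv)) / length(union(nu, nv))
}

# hand-rolled coexpression context for formula-level feature tests
manual_ctx <- function(eco, eco_avg) {
  co <- (eco > eco_avg) * 1L
  diag(co) <- 0L
  structure(list(eco = eco, co = co, eco_avg = eco_avg,
                 has_expression = TRUE),
            class = "coexpression_context")
}
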