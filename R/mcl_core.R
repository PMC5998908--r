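#' Parameters of the Markov Cluster Algorithm
#'
#' @param inflation inflation exponent `r` (> 1); larger values give
#'   finer-grained clusters. Default 2.
#' @param prune_w prune-threshold multiplier `w` (>= 0); the per-column
#'   prune threshold is the support mean minus `w` times the support
#'   (population) variance. Default 1.
#' @param tol convergence tolerance on the maximum absolute entrywise
#'   change between iterations.
#' @param max_iter iteration cap.
#' @return a list of class `MclParams`.
#' @export
mcl_params <- function(inflation = 2, prune_w = 1, tol = 1e-6,
                       max_iter = 100) {
  stopifnot(inflation > 1, prune_w >= 0, tol > 0, max_iter >= 1)
  structure(list(inflation = inflation, prune_w = prune_w,
                 tol = tol, max_iter = max_iter),
            class = "MclParams")
}

#' MCL expansion step
#'
#' Squares the flow matrix, `M %*% M`: flow spreads along walks of length
#' two. The product of column-stochastic matrices is column-stochastic.
#'
#' @param M column-stochastic sparse matrix.
#' @return the squared matrix.
#' @export
expand <- function(M) {
  Matrix::drop0(M %*% M)
}

#' MCL inflation step
#'
#' Raises every entry to the power `r` and renormalizes each column to sum
#' to 1, sharpening the contrast between strong and weak flow.
#'
#' @param M column-stochastic sparse matrix.
#' @param r inflation exponent (> 1).
#' @return the inflated column-stochastic matrix.
#' @export
inflate <- function(M, r = 2) {
  stopifnot(r > 1)
  M <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
  M@x <- M@x^r
  cs <- Matrix::colSums(M)
  if (any(cs == 0)) {
    stop("inflate: column with all-zero entries violates the flow-matrix invariant")
  }
  Matrix::drop0(M %*% Matrix::Diagonal(x = 1 / cs))
}

#' MCL pruning step
#'
#' Per column, over the support `L_j = {k : M(k,j) > 0}`, computes the mean
#' `avg(j)` and the threshold `thd(j) = avg(j) - w * var(j)` where `var(j)`
#' is the population variance of the support values. Entries strictly below
#' `thd(j)` are zeroed and the column is renormalized to sum 1. The column
#' maximum is always `>= avg(j) >= thd(j)`, so a column can never be
#' emptied. When the variance is large, `thd(j)` may be non-positive and
#' the column passes through unchanged (up to renormalization).
#'
#' @param M column-stochastic sparse matrix.
#' @param w threshold multiplier (>= 0).
#' @return the pruned, renormalized matrix.
#' @export
prune <- function(M, w = 1) {
  stopifnot(w >= 0)
  M <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
  M <- Matrix::drop0(M)
  p <- M@p
  x <- M@x
  n <- ncol(M)
  for (j in seq_len(n)) {
    a <- p[j] + 1L
    b <- p[j + 1L]
    if (b < a) next
    v <- x[a:b]
    avg <- mean(v)
    thd <- avg - w * mean((v - avg)^2)
    if (max(v) < thd) {
      stop("prune: threshold exceeds column maximum (internal error)")
    }
    v[v < thd] <- 0
    x[a:b] <- v / sum(v)
  }
  M@x <- x
  Matrix::drop0(M)
}

#' Run the Markov Cluster Algorithm to convergence
#'
#' Iterates expansion, inflation and pruning on an initial column-stochastic
#' flow matrix until the maximum absolute entrywise change drops below
#' `params$tol` or `params$max_iter` iterations have run. Each iteration
#' feeds the pruned, renormalized matrix of the previous one. The loop is
#' fully deterministic.
#'
#' @param M initial flow matrix, e.g. from [build_flow_matrix()].
#' @param params an [mcl_params()] object.
#' @return a list with elements `matrix` (the final flow matrix),
#'   `iterations` and `converged`. Non-convergence at `max_iter` produces a
#'   warning, not an error.
#' @export
run_mcl <- function(M, params = mcl_params()) {
  stopifnot(inherits(params, "MclParams"))
  if (!is_column_stochastic(M, tol = 1e-7)) {
    stop("run_mcl: input matrix is not column-stochastic")
  }
  M <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
  it <- 0L
  converged <- FALSE
  while (it < params$max_iter) {
    it <- it + 1L
    M1 <- prune(inflate(expand(M), params$inflation), params$prune_w)
    if (!is_column_stochastic(M1, tol = 1e-7)) {
      stop("run_mcl: column-stochasticity lost at iteration ", it)
    }
    delta <- max(abs(M1 - M))
    M <- M1
    if (delta < params$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("MCL did not converge in %d iterations", it))
  }
  list(matrix = M, iterations = it, converged = converged)
}

#' Extract clusters from a converged flow matrix
#'
#' Each column's attractor is its argmax row (ties broken towards the lowest
#' vertex index); vertices sharing an attractor form one cluster, and
#' attractors that flow to each other are merged by union-find. At exact
#' convergence most columns hold a single non-zero entry and the argmax rule
#' reduces to that; at an iteration cap it degrades gracefully.
#'
#' @param M converged flow matrix from [run_mcl()].
#' @param vertices vertex IDs in matrix order; defaults to the matrix
#'   dimnames.
#' @return an object of class `ClusterPartition`: a list with `clusters`
#'   (list of character vectors, ordered by their lowest vertex index) and
#'   `attractors` (one attractor ID per cluster). Clusters are pairwise
#'   disjoint and cover all vertices.
#' @export
extract_clusters <- function(M, vertices = colnames(M)) {
  M <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
  n <- ncol(M)
  if (is.null(vertices)) {
    vertices <- as.character(seq_len(n))
  }
  stopifnot(length(vertices) == n)
  p <- M@p
  ri <- M@i
  x <- M@x
  attractor <- integer(n)
  for (j in seq_len(n)) {
    a <- p[j] + 1L
    b <- p[j + 1L]
    if (b < a) {
      attractor[j] <- j
      next
    }
    v <- x[a:b]
    rows <- ri[a:b] + 1L
    best <- rows[v == max(v)]
    attractor[j] <- min(best)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (j in seq_len(n)) {
    ra <- find(j)
    rb <- find(attractor[j])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), root)
  ord <- order(vapply(groups, min, 1L))
  groups <- groups[ord]
  clusters <- lapply(groups, function(ix) vertices[ix])
  attrs <- vapply(groups, function(ix) {
    vertices[min(attractor[ix])]
  }, "")
  structure(list(clusters = unname(clusters), attractors = unname(attrs)),
            class = "ClusterPartition")
}

#' @export
print.ClusterPartition <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("ClusterPartition: %d clusters over %d vertices (sizes %s)\n",
              length(x$clusters), sum(sizes),
              paste(sort(sizes, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Cluster a PPI graph with edge-weighted MCL
#'
#' Convenience wrapper: builds the Jaccard-weighted adjacency matrix and its
#' column-stochastic flow matrix, runs MCL and extracts the cluster
#' partition.
#'
#' @param g a `ProteinGraph`.
#' @param params an [mcl_params()] object.
#' @param floor minimum edge weight, see [build_adjacency()].
#' @return a list with `partition` (a `ClusterPartition`), `iterations` and
#'   `converged`.
#' @export
mcl_cluster <- function(g, params = mcl_params(), floor = 0.01) {
  A <- build_adjacency(g, floor = floor)
  M <- build_flow_matrix(A)
  res <- run_mcl(M, params)
  list(partition = extract_clusters(res$matrix, g$vertices),
       iterations = res$iterations,
       converged = res$converged)
}
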