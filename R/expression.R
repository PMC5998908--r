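#' Read a gene-expression time-course matrix
#'
#' Expects a TSV with a protein/gene ID in column 1 followed by `m` numeric
#' expression values (the yeast metabolic-cycle data this format mirrors has
#' m = 36 intervals). A header line is detected by a non-numeric second
#' field and skipped. Lines starting with `#` are ignored. Duplicate IDs
#' keep the first occurrence with a warning.
#'
#' @param path path to the TSV file.
#' @return a numeric matrix, one row per protein (rownames are IDs), one
#'   column per time point. All values are non-negative.
#' @export
load_expression <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read expression file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    stop("expression file is empty: ", path)
  }
  toks <- strsplit(lines, "[ \t]+")
  first <- toks[[1]]
  if (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))) {
    toks <- toks[-1]
    lineno <- lineno[-1]
    if (!length(toks)) stop("expression file has only a header: ", path)
  }
  m <- length(toks[[1]]) - 1L
  if (m < 1L) {
    stop(sprintf("line %d of %s has no expression values", lineno[1], path))
  }
  bad <- which(vapply(toks, length, 1L) != m + 1L)
  if (length(bad)) {
    stop(sprintf("line %d of %s: expected %d values, found %d",
                 lineno[bad[1]], path, m,
                 length(toks[[bad[1]]]) - 1L))
  }
  ids <- vapply(toks, `[[`, "", 1L)
  vals <- suppressWarnings(
    t(vapply(toks, function(tk) as.numeric(tk[-1]), numeric(m)))
  )
  if (anyNA(vals)) {
    stop(sprintf("line %d of %s: non-numeric expression value",
                 lineno[which(rowSums(is.na(vals)) > 0)[1]], path))
  }
  if (min(vals) < 0) {
    stop("expression values must be non-negative")
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sprintf("%d duplicate ID(s) in %s; keeping first occurrence",
                    sum(dup), path))
    vals <- vals[!dup, , drop = FALSE]
    ids <- ids[!dup]
  }
  rownames(vals) <- ids
  vals
}

#' Max-normalize expression rows
#'
#' Divides each protein's time course by its maximum, so every
#' non-degenerate row peaks at exactly 1 and profiles of proteins with
#' different dynamic ranges become comparable. All-zero rows are left as
#' zeros. The operation is idempotent.
#'
#' @param x numeric expression matrix (rows = proteins).
#' @return the normalized matrix, values in `[0, 1]`.
#' @export
normalize_expression <- function(x) {
  x <- as.matrix(x)
  mx <- apply(x, 1, max)
  mx[mx == 0] <- 1
  x / mx
}

#' Co-expression value of two normalized profiles
#'
#' Sums `ln((a_l + b_l) / |a_l - b_l|)` over time points: profiles that rise
#' and fall together (small differences, large sums) score high. Two
#' numerical guards keep the score finite: the absolute difference is
#' clamped below at `delta`, and time points where `a_l + b_l < delta`
#' (both silent) are skipped as carrying no signal. The score is symmetric
#' in its arguments.
#'
#' @param a,b numeric vectors of equal length (max-normalized profiles).
#' @param delta clamp on the per-timepoint absolute difference; also the
#'   both-silent cutoff. Default `1e-3`.
#' @return the co-expression value (a single number, possibly negative).
#' @export
pairwise_eco <- function(a, b, delta = 1e-3) {
  if (length(a) != length(b)) {
    stop("profiles differ in length")
  }
  s <- a + b
  d <- pmax(abs(a - b), delta)
  keep <- s >= delta
  sum(log(s[keep] / d[keep]))
}

#' All-pairs co-expression matrix
#'
#' @param N normalized expression matrix (rows = proteins).
#' @param delta see [pairwise_eco()].
#' @return symmetric numeric matrix of pairwise co-expression values, zero
#'   diagonal.
#' @export
eco_matrix <- function(N, delta = 1e-3) {
  N <- as.matrix(N)
  k <- nrow(N)
  E <- matrix(0, k, k, dimnames = list(rownames(N), rownames(N)))
  if (k < 2) return(E)
  for (i in seq_len(k - 1)) {
    rows <- (i + 1):k
    a <- N[i, ]
    s <- sweep(N[rows, , drop = FALSE], 2, a, "+")
    d <- pmax(abs(sweep(N[rows, , drop = FALSE], 2, a, "-")), delta)
    term <- log(s / d)
    term[s < delta] <- 0
    v <- rowSums(term)
    E[i, rows] <- v
    E[rows, i] <- v
  }
  E
}

#' Network-average co-expression value
#'
#' The mean pairwise co-expression over a pair scope: by default all
#' unordered pairs of network proteins that have expression data; the
#' `edges` scope restricts to interacting pairs. Pairs with a missing
#' expression row are excluded.
#'
#' @param g a `ProteinGraph`.
#' @param N normalized expression matrix.
#' @param scope `"all_pairs"` (default) or `"edges"`.
#' @param delta see [pairwise_eco()].
#' @return the average co-expression value.
#' @export
average_eco <- function(g, N, scope = c("all_pairs", "edges"),
                        delta = 1e-3) {
  scope <- match.arg(scope)
  have <- g$vertices[g$vertices %in% rownames(N)]
  if (scope == "all_pairs") {
    if (length(have) < 2) stop("no eligible protein pair with expression data")
    E <- eco_matrix(N[have, , drop = FALSE], delta = delta)
    return(mean(E[upper.tri(E)]))
  }
  a <- g$vertices[g$edges[, 1]]
  b <- g$vertices[g$edges[, 2]]
  ok <- a %in% rownames(N) & b %in% rownames(N)
  if (!any(ok)) stop("no eligible interacting pair with expression data")
  vals <- mapply(function(u, v) pairwise_eco(N[u, ], N[v, ], delta),
                 a[ok], b[ok])
  mean(vals)
}

#' Binary co-expression indicator
#'
#' `Co(u, v) = 1` iff the pairwise co-expression value strictly exceeds the
#' network average; pairs with missing expression score 0.
#'
#' @param a,b normalized profiles, or `NULL` for a protein with no
#'   expression row.
#' @param eco_avg the network-average co-expression value, see
#'   [average_eco()].
#' @param delta see [pairwise_eco()].
#' @return 0 or 1.
#' @export
co_indicator <- function(a, b, eco_avg, delta = 1e-3) {
  if (is.null(a) || is.null(b)) return(0L)
  as.integer(pairwise_eco(a, b, delta) > eco_avg)
}

#' Precompute co-expression state for a network
#'
#' Bundles everything the feature and refinement stages need: the pairwise
#' co-expression matrix over the graph's vertices (0 for pairs involving a
#' protein absent from the expression data), the network-average value and
#' the binary co-expression indicator matrix. Proteins without expression
#' data score `Co = 0` against everyone and are excluded from the average.
#'
#' @param g a `ProteinGraph`.
#' @param N normalized expression matrix (see [normalize_expression()]), or
#'   `NULL` for a topology-only context in which every co-expression
#'   feature is 0.
#' @param scope pair scope for the average, see [average_eco()].
#' @param delta see [pairwise_eco()].
#' @return a list of class `coexpression_context` with elements `eco`
#'   (|V| x |V| matrix), `co` (0/1 matrix), `eco_avg`, `has_expression`
#'   (logical scalar: whether any expression data was supplied).
#' @export
coexpression_context <- function(g, N, scope = c("all_pairs", "edges"),
                                 delta = 1e-3) {
  scope <- match.arg(scope)
  n <- length(g$vertices)
  eco <- matrix(0, n, n, dimnames = list(g$vertices, g$vertices))
  co <- matrix(0L, n, n, dimnames = list(g$vertices, g$vertices))
  if (is.null(N)) {
    return(structure(list(eco = eco, co = co, eco_avg = 0,
                          has_expression = FALSE),
                     class = "coexpression_context"))
  }
  have <- g$vertices[g$vertices %in% rownames(N)]
  if (length(have) >= 2) {
    E <- eco_matrix(N[have, , drop = FALSE], delta = delta)
    eco[have, have] <- E
  }
  avg <- average_eco(g, N, scope = scope, delta = delta)
  if (length(have) >= 2) {
    co[have, have] <- (eco[have, have] > avg) * 1L
    diag(co) <- 0L
  }
  structure(list(eco = eco, co = co, eco_avg = avg, has_expression = TRUE),
            class = "coexpression_context")
}
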