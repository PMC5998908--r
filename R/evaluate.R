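#' Read / write complex catalogues
#'
#' One complex per line, whitespace-separated protein IDs; `#` comment
#' lines and blank lines are ignored. Duplicate IDs within a line are
#' collapsed.
#'
#' @param path file path.
#' @return `read_complexes`: a list of character vectors.
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read complex file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(strsplit(trimws(lines), "[ \t]+"), unique)
}

#' @rdname read_complexes
#' @param S list of complexes (character vectors).
#' @return `write_complexes`: `path`, invisibly.
#' @export
write_complexes <- function(S, path) {
  writeLines(vapply(S, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' Overlap score between two complexes
#'
#' `O(Cp, Cb) = |Cp n Cb|^2 / (|Cp| * |Cb|)`: 1 for identical sets, 0 for
#' disjoint ones.
#'
#' @param cp,cb non-empty character vectors of protein IDs.
#' @return value in `[0, 1]`.
#' @export
overlap_score <- function(cp, cb) {
  cp <- unique(as.character(cp))
  cb <- unique(as.character(cb))
  if (!length(cp) || !length(cb)) stop("overlap_score: empty complex")
  length(intersect(cp, cb))^2 / (length(cp) * length(cb))
}

#' Matched-complex counts at an overlap threshold
#'
#' `Ncp` counts predicted complexes whose overlap score with at least one
#' benchmark complex reaches `omega`; `Ncb` counts benchmark complexes
#' matched by at least one prediction.
#'
#' @param P list of predicted complexes.
#' @param B list of benchmark complexes.
#' @param omega overlap-score threshold in `(0, 1]`, default 0.2.
#' @return named integer vector `c(ncp, ncb)`.
#' @export
match_counts <- function(P, B, omega = 0.2) {
  stopifnot(omega > 0, omega <= 1)
  if (!length(P) || !length(B)) {
    return(c(ncp = 0L, ncb = 0L))
  }
  O <- matrix(0, length(P), length(B))
  for (i in seq_along(P)) {
    for (j in seq_along(B)) {
      O[i, j] <- overlap_score(P[[i]], B[[j]])
    }
  }
  c(ncp = sum(apply(O >= omega, 1, any)),
    ncb = sum(apply(O >= omega, 2, any)))
}

#' Precision, Recall and F-Measure from match counts
#'
#' `Precision = Ncp / |P|`, `Recall = Ncb / |B|`, and F-Measure their
#' harmonic mean (0 when both are 0).
#'
#' @param ncp number of matched predicted complexes.
#' @param n_predicted total number of predicted complexes (> 0).
#' @param ncb number of matched benchmark complexes.
#' @param n_benchmark total number of benchmark complexes (> 0).
#' @return named numeric vector `c(precision, recall, f_measure)`.
#' @export
precision_recall_f <- function(ncp, n_predicted, ncb, n_benchmark) {
  if (n_predicted <= 0 || n_benchmark <= 0) {
    stop("precision_recall_f: set sizes must be positive")
  }
  ncp <- unname(ncp)
  ncb <- unname(ncb)
  precision <- ncp / n_predicted
  recall <- ncb / n_benchmark
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f_measure = f)
}

#' Clustering-wise Sn, PPV and geometric accuracy
#'
#' Over the intersection-size matrix `T[i, j] = |B_i n P_j|`: sensitivity
#' `Sn` is the row-max sum over the total benchmark size, positive
#' predictive value `PPV` the column-max sum over the grand total of `T`,
#' and `Acc` their geometric mean. Predictions with no overlap against any
#' benchmark contribute 0 to both the PPV numerator and denominator. If
#' `T` is all zero, `PPV` is reported as 0 with a message.
#'
#' @param P list of predicted complexes (non-empty).
#' @param B list of benchmark complexes (non-empty).
#' @return named numeric vector `c(sn, ppv, acc)`.
#' @export
sn_ppv_acc <- function(P, B) {
  stopifnot(length(P) >= 1, length(B) >= 1)
  P <- lapply(P, function(x) unique(as.character(x)))
  B <- lapply(B, function(x) unique(as.character(x)))
  T <- matrix(0, length(B), length(P))
  for (i in seq_along(B)) {
    for (j in seq_along(P)) {
      T[i, j] <- length(intersect(B[[i]], P[[j]]))
    }
  }
  sn <- sum(apply(T, 1, max)) / sum(lengths(B))
  tot <- sum(T)
  if (tot == 0) {
    message("sn_ppv_acc: no overlap between predictions and benchmark; PPV = 0")
    ppv <- 0
  } else {
    ppv <- sum(apply(T, 2, max)) / tot
  }
  c(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Full evaluation of a predicted complex set against a benchmark
#'
#' Combines the overlap-based counts ([match_counts()]), Precision /
#' Recall / F-Measure and the clustering-wise Sn / PPV / Acc into one
#' report.
#'
#' @param P list of predicted complexes.
#' @param B list of benchmark complexes.
#' @param omega overlap-score match threshold, default 0.2.
#' @param min_benchmark_size if set, benchmark complexes smaller than this
#'   are removed first (the usual variant keeps complexes of size >= 3).
#' @return an object of class `EvalReport`: a list with `n_predicted`,
#'   `n_benchmark`, `ncp`, `ncb`, `sn`, `ppv`, `acc`, `precision`,
#'   `recall`, `f_measure` and `omega`.
#' @export
evaluate_complexes <- function(P, B, omega = 0.2,
                               min_benchmark_size = NULL) {
  if (!is.null(min_benchmark_size)) {
    B <- B[lengths(B) >= min_benchmark_size]
  }
  stopifnot(length(P) >= 1, length(B) >= 1)
  mc <- match_counts(P, B, omega)
  prf <- precision_recall_f(mc["ncp"], length(P), mc["ncb"], length(B))
  spa <- sn_ppv_acc(P, B)
  structure(list(n_predicted = length(P), n_benchmark = length(B),
                 ncp = unname(mc["ncp"]), ncb = unname(mc["ncb"]),
                 sn = unname(spa["sn"]), ppv = unname(spa["ppv"]),
                 acc = unname(spa["acc"]),
                 precision = unname(prf["precision"]),
                 recall = unname(prf["recall"]),
                 f_measure = unname(prf["f_measure"]),
                 omega = omega),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport (omega = %g)\n", x$omega))
  cat(sprintf("  |P| = %d  Ncp = %d    |B| = %d  Ncb = %d\n",
              x$n_predicted, x$ncp, x$n_benchmark, x$ncb))
  cat(sprintf("  Sn = %.4f  PPV = %.4f  Acc = %.4f\n", x$sn, x$ppv, x$acc))
  cat(sprintf("  Precision = %.4f  Recall = %.4f  F-Measure = %.4f\n",
              x$precision, x$recall, x$f_measure))
  invisible(x)
}
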