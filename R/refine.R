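#' Filtering bounds for candidate complexes
#'
#' Each of the three complex-level features gets an `(upper, lower)` pair:
#' a complex with any feature below its lower bound is discarded, one with
#' all features at or above their upper bounds is reserved as-is, and
#' anything in between is sent to the modification stage. Defaults are
#' `(0.18, 0.06)` for `Den(C,2)`, `(80, 50)` for `E_co(C)` and
#' `(0.75, 0.20)` for `CoRatio(C)`.
#'
#' @param den,eco,co_ratio numeric `(upper, lower)` pairs.
#' @return a list of class `FilterBounds`.
#' @export
filter_bounds <- function(den = c(0.18, 0.06), eco = c(80, 50),
                          co_ratio = c(0.75, 0.20)) {
  for (b in list(den, eco, co_ratio)) {
    stopifnot(length(b) == 2, b[1] >= b[2])
  }
  structure(list(den = den, eco = eco, co_ratio = co_ratio),
            class = "FilterBounds")
}

#' Refinement parameters
#'
#' @param weights the seven feature weights of the linear score, in
#'   [feature_vector()] order. The shipped defaults
#'   `(0.01, 0.02, 0.01, 0.24, 0.36, 0.03, 0.33)` were fitted by logistic
#'   regression on add/delete decisions over random complexes; the
#'   co-expression features carry most of the weight.
#' @param add_threshold minimum probability `P(v, C)` for adding an outside
#'   neighbour (default 0.8, the strict setting — adding precision rises
#'   sharply between 0.5 and 0.8).
#' @param delete_threshold probability below which the weakest member is
#'   deleted (default 0.5, the logistic decision boundary).
#' @param max_passes cap on delete/add sweeps per complex.
#' @param min_size smallest complex reported (default 3; smaller candidates
#'   are dropped, mirroring the usual benchmark handling).
#' @return a list of class `RefineParams`.
#' @export
refine_params <- function(weights = c(0.01, 0.02, 0.01, 0.24, 0.36, 0.03, 0.33),
                          add_threshold = 0.8, delete_threshold = 0.5,
                          max_passes = 5, min_size = 3) {
  stopifnot(length(weights) == 7,
            add_threshold >= 0, add_threshold <= 1,
            delete_threshold >= 0, delete_threshold <= 1,
            max_passes >= 1, min_size >= 1)
  structure(list(weights = weights, add_threshold = add_threshold,
                 delete_threshold = delete_threshold,
                 max_passes = max_passes, min_size = min_size),
            class = "RefineParams")
}

#' Logistic membership score
#'
#' `P(v, C) = 1 / (1 + exp(-L))` with `L` the weighted sum of the seven
#' features. The intercept is fixed at 0, so an all-zero feature vector
#' scores exactly 0.5.
#'
#' @param f feature vector of length 7 (see [feature_vector()]).
#' @param w weight vector of length 7.
#' @return a probability in `(0, 1)`.
#' @export
logistic_score <- function(f, w = refine_params()$weights) {
  if (length(f) != 7 || length(w) != 7) {
    stop("logistic_score expects 7 features and 7 weights")
  }
  stats::plogis(sum(w * f))
}

#' Classify a candidate complex as reserve / discard / modify
#'
#' Computes the complex-level vector `(Den(C,2), E_co(C), CoRatio(C))` and
#' applies the bounds: any feature below its lower bound discards the
#' complex, all features at or above their upper bounds reserve it, and
#' the middle ground goes to modification. With a topology-only context
#' (no expression data) only the density bounds apply.
#'
#' @param C character vector of member IDs (`|C| >= 2`).
#' @param g a `ProteinGraph`.
#' @param ctx a [coexpression_context()].
#' @param bounds a [filter_bounds()] object.
#' @return one of `"reserve"`, `"discard"`, `"modify"`.
#' @export
classify_complex <- function(C, g, ctx, bounds = filter_bounds()) {
  den <- density(g, C, 2)
  if (ctx$has_expression) {
    vec <- c(den, eco_complex(C, ctx), co_ratio(C, ctx))
    lower <- c(bounds$den[2], bounds$eco[2], bounds$co_ratio[2])
    upper <- c(bounds$den[1], bounds$eco[1], bounds$co_ratio[1])
  } else {
    vec <- den
    lower <- bounds$den[2]
    upper <- bounds$den[1]
  }
  classify_vector(vec, lower, upper)
}

# The three-way rule on a feature vector and its bound vectors: any feature
# below a lower bound discards, all at/above the uppers reserves, else modify.
classify_vector <- function(vec, lower, upper) {
  if (any(vec < lower)) return("discard")
  if (all(vec >= upper)) return("reserve")
  "modify"
}

#' Modify a median-quality complex
#'
#' Alternating delete/add sweeps, one change per sweep for determinism:
#' the deletion sweep scores every member `v` against `C` minus `v` and
#' removes the lowest scorer if its probability falls below the delete
#' threshold; the addition sweep scores every outside neighbour (adjacent
#' to at least one member) against `C` and adds the highest scorer if its
#' probability exceeds the add threshold. Ties break towards the
#' alphabetically first protein. Sweeps repeat until nothing changes or
#' `max_passes` is reached.
#'
#' @param C character vector of member IDs.
#' @param g a `ProteinGraph`.
#' @param ctx a [coexpression_context()].
#' @param params a [refine_params()] object.
#' @return the modified complex (character vector), or `NULL` if it shrank
#'   below `min_size`.
#' @export
modify_complex <- function(C, g, ctx, params = refine_params()) {
  C <- sort(unique(as.character(C)))
  w <- params$weights
  for (pass in seq_len(params$max_passes)) {
    changed <- FALSE
    # deletion sweep: weakest member out if below threshold
    scores <- vapply(C, function(v) {
      logistic_score(feature_vector(g, v, setdiff(C, v), ctx), w)
    }, 1)
    worst <- names(scores)[order(scores, names(scores))][1]
    if (scores[worst] < params$delete_threshold) {
      C <- setdiff(C, worst)
      changed <- TRUE
      if (length(C) < params$min_size) return(NULL)
    }
    # addition sweep: strongest outside neighbour in if above threshold
    nb <- sort(setdiff(
      unique(g$vertices[unlist(g$adj[vertex_index(g, C)])]), C))
    if (length(nb)) {
      scores <- vapply(nb, function(v) {
        logistic_score(feature_vector(g, v, C, ctx), w)
      }, 1)
      best <- names(scores)[order(-scores, names(scores))][1]
      if (scores[best] > params$add_threshold) {
        C <- sort(c(C, best))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  C
}

#' Filter and modify a set of candidate complexes
#'
#' The full post-clustering stage: candidates below `min_size` are dropped,
#' the rest are classified ([classify_complex()]); reserved complexes pass
#' through unchanged, discarded ones are removed, and median complexes go
#' through [modify_complex()]. Exact duplicates in the result are
#' collapsed.
#'
#' @param S list of complexes (character vectors).
#' @param g a `ProteinGraph`.
#' @param ctx a [coexpression_context()].
#' @param bounds a [filter_bounds()] object.
#' @param params a [refine_params()] object.
#' @return the refined complex list, with an attribute `counts` giving the
#'   number of candidates dropped for size, reserved, discarded, modified,
#'   and lost during modification.
#' @export
refine_all <- function(S, g, ctx, bounds = filter_bounds(),
                       params = refine_params()) {
  S <- lapply(S, function(C) sort(unique(as.character(C))))
  big <- lengths(S) >= params$min_size
  counts <- c(dropped_small = sum(!big), reserved = 0L, discarded = 0L,
              modified = 0L, dropped_modified = 0L)
  out <- list()
  for (C in S[big]) {
    verdict <- classify_complex(C, g, ctx, bounds)
    if (verdict == "discard") {
      counts["discarded"] <- counts["discarded"] + 1L
    } else if (verdict == "reserve") {
      counts["reserved"] <- counts["reserved"] + 1L
      out[[length(out) + 1L]] <- C
    } else {
      counts["modified"] <- counts["modified"] + 1L
      C2 <- modify_complex(C, g, ctx, params)
      if (is.null(C2)) {
        counts["dropped_modified"] <- counts["dropped_modified"] + 1L
      } else {
        out[[length(out) + 1L]] <- C2
      }
    }
  }
  keys <- vapply(out, paste, "", collapse = "\r")
  out <- out[!duplicated(keys)]
  attr(out, "counts") <- counts
  out
}

#' Generate labelled training samples for the membership score
#'
#' Grows random connected complexes (target size uniform on 3..10) by
#' repeated random neighbour addition, then labels every possible addition
#' (an outside neighbour) and deletion (a member) by whether it strictly
#' improves the complex's best overlap score against a benchmark
#' catalogue. The feature vector of each candidate is recorded; the run is
#' fully determined by `seed`.
#'
#' @param g a `ProteinGraph`.
#' @param ctx a [coexpression_context()].
#' @param benchmark list of benchmark complexes (character vectors).
#' @param n_complexes number of random complexes to grow.
#' @param seed integer RNG seed.
#' @return data frame with the seven feature columns, `label` (1 =
#'   improves, 0 = not) and `type` (`"add"` / `"delete"`).
#' @export
generate_training_samples <- function(g, ctx, benchmark, n_complexes = 50,
                                      seed = 1) {
  stopifnot(length(benchmark) >= 1)
  set.seed(seed)
  best_overlap <- function(C) {
    max(vapply(benchmark, function(B) overlap_score(C, B), 1))
  }
  rows <- list()
  for (rep in seq_len(n_complexes)) {
    size <- sample(3:10, 1)
    C <- sample(g$vertices, 1)
    repeat {
      if (length(C) >= size) break
      nb <- setdiff(unique(g$vertices[unlist(g$adj[vertex_index(g, C)])]), C)
      if (!length(nb)) break
      C <- c(C, sample(nb, 1))
    }
    if (length(C) < 3) next
    base <- best_overlap(C)
    nb <- sort(setdiff(
      unique(g$vertices[unlist(g$adj[vertex_index(g, C)])]), C))
    for (v in nb) {
      rows[[length(rows) + 1L]] <- c(
        feature_vector(g, v, C, ctx),
        label = as.integer(best_overlap(c(C, v)) > base), type = "add")
    }
    for (v in sort(C)) {
      rows[[length(rows) + 1L]] <- c(
        feature_vector(g, v, setdiff(C, v), ctx),
        label = as.integer(best_overlap(setdiff(C, v)) > base),
        type = "delete")
    }
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  for (nm in setdiff(names(df), "type")) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Fit membership-score weights by logistic regression
#'
#' Maximum-likelihood logistic regression of the labels on the seven raw
#' features with the intercept fixed at 0, matching the form of the linear
#' score `L`.
#'
#' @param samples data frame from [generate_training_samples()] (feature
#'   columns plus `label`).
#' @return named weight vector of length 7.
#' @export
fit_weights <- function(samples) {
  feats <- c("connect_ratio", "path_ratio", "den_diff", "eco",
             "co_diff", "co_pro_num", "co_pro_ratio")
  stopifnot(all(feats %in% names(samples)), "label" %in% names(samples))
  if (length(unique(samples$label)) < 2) {
    stop("fit_weights needs both positive and negative samples")
  }
  fml <- stats::as.formula(paste("label ~ 0 +", paste(feats, collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, data = samples, family = stats::binomial())
  )
  stats::coef(fit)
}
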