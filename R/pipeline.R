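#' Detect protein complexes in a PPI network
#'
#' The full detection method: Jaccard edge weighting, Markov clustering of
#' the flow matrix, extraction of the cluster partition, then filtering and
#' modification of the candidates using topology and co-expression
#' features. Without expression data the co-expression features are all 0
#' and filtering falls back to the density bounds alone.
#'
#' @param g a `ProteinGraph`.
#' @param expression optional raw expression matrix (rows named by protein
#'   ID); it is max-normalized internally.
#' @param mcl an [mcl_params()] object.
#' @param floor minimum edge weight, see [build_adjacency()].
#' @param bounds a [filter_bounds()] object.
#' @param refine_params a [refine_params()] object.
#' @param eco_scope pair scope for the network-average co-expression, see
#'   [average_eco()].
#' @param refine set `FALSE` to return the raw MCL clusters (size-filtered
#'   only).
#' @return a list of class `complex_detection` with `complexes` (the final
#'   list), `raw_clusters` (all MCL clusters), `iterations`, `converged`,
#'   `counts` (refinement bookkeeping) and `ctx` (the co-expression
#'   context, reusable for evaluation of individual complexes).
#' @export
detect_complexes <- function(g, expression = NULL, mcl = mcl_params(),
                             floor = 0.01, bounds = filter_bounds(),
                             refine_params = mclcomplex::refine_params(),
                             eco_scope = "all_pairs", refine = TRUE) {
  res <- mcl_cluster(g, params = mcl, floor = floor)
  raw <- res$partition$clusters
  N <- if (is.null(expression)) NULL else normalize_expression(expression)
  ctx <- coexpression_context(g, N, scope = eco_scope)
  if (refine) {
    complexes <- refine_all(raw, g, ctx, bounds, refine_params)
    counts <- attr(complexes, "counts")
    attr(complexes, "counts") <- NULL
  } else {
    complexes <- raw[lengths(raw) >= refine_params$min_size]
    counts <- c(dropped_small = sum(lengths(raw) < refine_params$min_size))
  }
  structure(list(complexes = complexes, raw_clusters = raw,
                 iterations = res$iterations, converged = res$converged,
                 counts = counts, ctx = ctx),
            class = "complex_detection")
}

#' @export
print.complex_detection <- function(x, ...) {
  cat(sprintf("complex_detection: %d complexes (from %d MCL clusters, %d iterations)\n",
              length(x$complexes), length(x$raw_clusters), x$iterations))
  invisible(x)
}

#' Pipeline configuration
#'
#' File paths plus every tunable parameter of the detection method, with
#' the method's standard defaults (inflation 2, prune multiplier 1, match
#' threshold omega 0.2, the default filter bounds and feature weights).
#'
#' @param network path to the PPI edge-list file.
#' @param expression optional path to the expression TSV.
#' @param benchmark optional path to a benchmark complex catalogue.
#' @param out_dir optional output directory for artifact files.
#' @param omega overlap-score match threshold for evaluation.
#' @param inflation,prune_w,tol,max_iter see [mcl_params()].
#' @param floor see [build_adjacency()].
#' @param bounds see [filter_bounds()].
#' @param refine_params see [refine_params()].
#' @param eco_scope see [average_eco()].
#' @return a list of class `PipelineConfig`.
#' @export
pipeline_config <- function(network, expression = NULL, benchmark = NULL,
                            out_dir = NULL, omega = 0.2, inflation = 2,
                            prune_w = 1, tol = 1e-6, max_iter = 100,
                            floor = 0.01, bounds = filter_bounds(),
                            refine_params = mclcomplex::refine_params(),
                            eco_scope = "all_pairs") {
  structure(list(network = network, expression = expression,
                 benchmark = benchmark, out_dir = out_dir, omega = omega,
                 inflation = inflation, prune_w = prune_w, tol = tol,
                 max_iter = max_iter, floor = floor, bounds = bounds,
                 refine_params = refine_params, eco_scope = eco_scope),
            class = "PipelineConfig")
}

#' Run the detection pipeline from files
#'
#' Loads the network (and, if given, expression data and a benchmark
#' catalogue), runs [detect_complexes()], optionally evaluates against the
#' benchmark, and — when `out_dir` is set — writes the raw clusters, the
#' refined complexes, the evaluation report and a JSON manifest holding
#' every parameter and count needed to replay the run.
#'
#' @param cfg a [pipeline_config()].
#' @return a list with `detection` (see [detect_complexes()]) and `report`
#'   (an `EvalReport`, or `NULL` without a benchmark).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  g <- load_network(cfg$network)
  expr <- NULL
  if (!is.null(cfg$expression)) {
    if (!file.exists(cfg$expression)) {
      stop("expression stage: file not found: ", cfg$expression)
    }
    expr <- load_expression(cfg$expression)
  }
  det <- detect_complexes(
    g, expression = expr,
    mcl = mcl_params(cfg$inflation, cfg$prune_w, cfg$tol, cfg$max_iter),
    floor = cfg$floor, bounds = cfg$bounds,
    refine_params = cfg$refine_params, eco_scope = cfg$eco_scope)
  report <- NULL
  if (!is.null(cfg$benchmark)) {
    if (!file.exists(cfg$benchmark)) {
      stop("evaluation stage: file not found: ", cfg$benchmark)
    }
    B <- read_complexes(cfg$benchmark)
    report <- evaluate_complexes(det$complexes, B, omega = cfg$omega)
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_complexes(det$raw_clusters,
                    file.path(cfg$out_dir, "clusters_raw.txt"))
    write_complexes(det$complexes,
                    file.path(cfg$out_dir, "complexes.txt"))
    manifest <- list(
      inputs = list(network = cfg$network, expression = cfg$expression,
                    benchmark = cfg$benchmark),
      parameters = list(inflation = cfg$inflation, prune_w = cfg$prune_w,
                        tol = cfg$tol, max_iter = cfg$max_iter,
                        floor = cfg$floor, omega = cfg$omega,
                        bounds = unclass(cfg$bounds),
                        refine = unclass(cfg$refine_params),
                        eco_scope = cfg$eco_scope),
      counts = as.list(det$counts),
      n_raw_clusters = length(det$raw_clusters),
      n_complexes = length(det$complexes),
      mcl_iterations = det$iterations,
      report = if (!is.null(report)) unclass(report))
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(detection = det, report = report)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [load_expression()]: one row per protein, ID first.
#'
#' @param x expression matrix with rownames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], trim = TRUE, digits = 10)),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
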