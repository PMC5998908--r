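#' Specification of a synthetic planted-complex data set
#'
#' Describes a planted-partition PPI network with matching co-expression
#' profiles: each planted complex is an Erdos-Renyi block with edge
#' probability `p_in`, every other vertex pair gets an edge with
#' probability `p_out`, and each complex shares a noisy common periodic
#' expression signal over `m` time points (three full periods by default,
#' echoing the oscillatory structure of yeast metabolic-cycle expression
#' data; background proteins get independent noise profiles).
#'
#' @param n_complexes number of planted complexes.
#' @param size_range integer `(min, max)` complex size.
#' @param p_in within-complex edge probability.
#' @param p_out background / between-complex edge probability
#'   (`0 <= p_out < p_in <= 1`).
#' @param n_background number of background proteins.
#' @param m number of expression time points (default 36).
#' @param amplitude_range per-protein amplitude, uniform on this interval.
#' @param noise_sd standard deviation of the additive expression noise on
#'   complex members.
#' @param periods full periods of the latent signal over the `m` points.
#' @param seed integer RNG seed; runs are bit-reproducible.
#' @return a list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_complexes = 8, size_range = c(4, 10),
                           p_in = 0.85, p_out = 0.01, n_background = 60,
                           m = 36, amplitude_range = c(0.5, 1.5),
                           noise_sd = 0.1, periods = 3, seed = 1) {
  stopifnot(n_complexes >= 1,
            length(size_range) == 2, size_range[1] >= 2,
            size_range[1] <= size_range[2],
            p_out >= 0, p_out < p_in, p_in <= 1,
            n_background >= 0, m >= 2,
            amplitude_range[1] > 0,
            amplitude_range[1] <= amplitude_range[2],
            noise_sd >= 0, periods >= 1)
  structure(list(n_complexes = n_complexes, size_range = size_range,
                 p_in = p_in, p_out = p_out, n_background = n_background,
                 m = m, amplitude_range = amplitude_range,
                 noise_sd = noise_sd, periods = periods,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Simulate a planted-partition PPI network
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `graph` (a `ProteinGraph` over all proteins,
#'   including any left isolated by chance) and `truth` (the list of
#'   planted complexes).
#' @export
simulate_network <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  sizes <- sample(seq(spec$size_range[1], spec$size_range[2]),
                  spec$n_complexes, replace = TRUE)
  truth <- lapply(seq_len(spec$n_complexes), function(k) {
    sprintf("C%02d_%02d", k, seq_len(sizes[k]))
  })
  ids <- c(unlist(truth), if (spec$n_background > 0) {
    sprintf("BG%03d", seq_len(spec$n_background))
  })
  block <- c(rep(seq_len(spec$n_complexes), sizes),
             rep(0L, spec$n_background))
  n <- length(ids)
  pr <- utils::combn(n, 2)
  same <- block[pr[1, ]] != 0L & block[pr[1, ]] == block[pr[2, ]]
  p <- ifelse(same, spec$p_in, spec$p_out)
  keep <- stats::runif(ncol(pr)) < p
  g <- protein_graph(ids[pr[1, keep]], ids[pr[2, keep]], vertices = ids)
  list(graph = g, truth = truth)
}

#' Simulate matching co-expression profiles
#'
#' Each planted complex draws one latent sinusoid (random phase,
#' `spec$periods` full periods over the `m` intervals, range `[0, 1]`);
#' members emit amplitude-scaled copies plus Gaussian noise, clipped at 0.
#' Background proteins emit independent uniform noise profiles, so they
#' are mutually dissimilar and dissimilar from every complex.
#'
#' @param truth list of planted complexes (from [simulate_network()]).
#' @param proteins character vector of all protein IDs to cover.
#' @param spec a [synthetic_spec()].
#' @return a non-negative expression matrix with one row per protein.
#' @export
simulate_expression <- function(truth, proteins, spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed + 1L)
  m <- spec$m
  t_frac <- (seq_len(m) - 1) / m
  X <- matrix(0, length(proteins), m, dimnames = list(proteins, NULL))
  member <- rep(FALSE, length(proteins))
  names(member) <- proteins
  for (C in truth) {
    phase <- stats::runif(1, 0, 2 * pi)
    latent <- 0.5 + 0.5 * sin(2 * pi * spec$periods * t_frac + phase)
    for (v in C) {
      amp <- stats::runif(1, spec$amplitude_range[1], spec$amplitude_range[2])
      X[v, ] <- pmax(0, amp * latent + stats::rnorm(m, 0, spec$noise_sd))
      member[v] <- TRUE
    }
  }
  for (v in proteins[!member]) {
    X[v, ] <- stats::runif(m)
  }
  X
}

#' Simulate a complete synthetic data set
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `graph`, `truth` and `expression`.
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  net <- simulate_network(spec)
  expr <- simulate_expression(net$truth, net$graph$vertices, spec)
  list(graph = net$graph, truth = net$truth, expression = expr)
}
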