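test_that("logistic_score is the zero-intercept logistic of the weighted sum", {
  expect_equal(logistic_score(rep(0, 7), rep(1, 7)), 0.5)
  expect_equal(logistic_score(c(log(3), rep(0, 6)), c(1, rep(0, 6))), 0.75)
  f <- c(0.5, 1, 0.1, 40, 0, 2, 0.5)
  f2 <- f
  f2[5] <- f[5] + 1  # raise co_diff, weight 0.36 > 0
  w <- refine_params()$weights
  expect_gt(logistic_score(f2, w), logistic_score(f, w))
  expect_error(logistic_score(rep(0, 6), rep(1, 7)), "7 features")
})

test_that("the three-way filter rule follows the bounds", {
  b <- filter_bounds()
  lower <- c(b$den[2], b$eco[2], b$co_ratio[2])
  upper <- c(b$den[1], b$eco[1], b$co_ratio[1])
  cls <- function(v) mclcomplex:::classify_vector(v, lower, upper)
  expect_equal(cls(c(0.30, 90, 0.80)), "reserve")
  expect_equal(cls(c(0.30, 40, 0.80)), "discard")  # E_co below 50
  expect_equal(cls(c(0.10, 60, 0.50)), "modify")
  expect_equal(cls(c(0.18, 80, 0.75)), "reserve")  # bounds are inclusive
  expect_error(filter_bounds(eco = c(40, 50)))
})

test_that("classify_complex discriminates dense cliques from junk (topology-only)", {
  g <- protein_graph(
    c("a", "a", "a", "b", "b", "c", "a", "p", "q"),
    c("b", "c", "d", "c", "d", "d", "p", "q", "r"),
    vertices = c("a", "b", "c", "d", "p", "q", "r", "x", "y", "z"))
  ctx <- coexpression_context(g, NULL)
  expect_false(ctx$has_expression)
  expect_equal(classify_complex(c("a", "b", "c", "d"), g, ctx), "reserve")
  expect_equal(classify_complex(c("x", "y", "z"), g, ctx), "discard")
  # one distance-2 pair among four members: Den = 2/16 between 0.06 and 0.18
  expect_equal(classify_complex(c("p", "r", "x", "y"), g, ctx), "modify")
})

test_that("modify_complex deletes a spurious member and keeps a stable complex", {
  g <- protein_graph(
    c("a", "a", "a", "b", "b", "c"),
    c("b", "c", "d", "c", "d", "d"),
    vertices = c("a", "b", "c", "d", "junk"))
  ctx <- coexpression_context(g, NULL)
  out <- modify_complex(c("a", "b", "c", "d", "junk"), g, ctx)
  expect_equal(out, c("a", "b", "c", "d"))

  # with thresholds at the extremes the sweep is the identity
  p_id <- refine_params(add_threshold = 1, delete_threshold = 0)
  expect_equal(modify_complex(c("a", "b", "c", "d", "junk"), g, ctx, p_id),
               c("a", "b", "c", "d", "junk"))
})

test_that("modify_complex adds a missing member with matching expression", {
  ids <- sprintf("m%d", 1:5)
  pr <- utils::combn(5, 2)
  g <- protein_graph(ids[pr[1, ]], ids[pr[2, ]],
                     vertices = c(ids, "u1", "u2"))
  set.seed(42)
  latent <- 0.5 + 0.5 * sin(2 * pi * 3 * (0:35) / 36)
  X <- rbind(
    t(vapply(1:5, function(i) pmax(0, latent + rnorm(36, 0, 0.05)),
             numeric(36))),
    matrix(runif(2 * 36), 2))
  rownames(X) <- c(ids, "u1", "u2")
  ctx <- coexpression_context(g, normalize_expression(X))
  out <- modify_complex(ids[1:4], g, ctx)
  expect_true("m5" %in% out)
})

test_that("refine_all orchestrates size filter, classify and modify", {
  expect_equal(length(refine_all(list(), protein_graph("a", "b"),
                                 coexpression_context(protein_graph("a", "b"),
                                                      NULL))), 0L)

  g <- clique_graph(c("a", "b", "c", "d"))
  ctx <- coexpression_context(g, NULL)
  out <- refine_all(list(c("a", "b", "c", "d"), c("a", "b")), g, ctx)
  expect_equal(out[[1]], c("a", "b", "c", "d"))  # reserved unchanged
  expect_equal(attr(out, "counts")[["dropped_small"]], 1L)
  expect_equal(attr(out, "counts")[["reserved"]], 1L)

  # duplicates collapse
  out2 <- refine_all(list(c("a", "b", "c", "d"), c("d", "c", "b", "a")),
                     g, ctx)
  expect_length(out2, 1L)
})

test_that("refine_all output sizes respect min_size on a synthetic run", {
  d <- simulate_dataset(synthetic_spec(n_complexes = 4, n_background = 20,
                                       seed = 17))
  res <- mcl_cluster(d$graph)
  ctx <- coexpression_context(d$graph, normalize_expression(d$expression))
  out <- refine_all(res$partition$clusters, d$graph, ctx)
  expect_true(all(lengths(out) >= 3))
})

test_that("raising the E_co lower bound never increases survivors", {
  d <- simulate_dataset(synthetic_spec(seed = 11))
  res <- mcl_cluster(d$graph)
  ctx <- coexpression_context(d$graph, normalize_expression(d$expression))
  counts <- vapply(c(0, 25, 50, 75, 100, 150), function(lb) {
    out <- refine_all(res$partition$clusters, d$graph, ctx,
                      bounds = filter_bounds(eco = c(200, lb)))
    length(out)
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("fit_weights recovers a dominant separating feature and sign symmetry", {
  feats <- c("connect_ratio", "path_ratio", "den_diff", "eco",
             "co_diff", "co_pro_num", "co_pro_ratio")
  set.seed(7)
  n <- 300
  X <- as.data.frame(matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, feats)))
  sep <- X
  sep$label <- as.integer(sep$co_diff > 0)
  w_sep <- suppressWarnings(fit_weights(sep))
  expect_gt(w_sep[["co_diff"]], 0)
  expect_equal(names(which.max(abs(w_sep))), "co_diff")

  w_true <- c(0.5, -0.3, 0.2, 0.1, 1, 0, -0.5)
  X$label <- rbinom(n, 1, plogis(as.matrix(X[feats]) %*% w_true))
  w1 <- fit_weights(X)
  Xf <- X
  Xf$label <- 1 - X$label
  w2 <- fit_weights(Xf)
  expect_equal(unname(w1), -unname(w2), tolerance = 1e-6)

  one <- X[X$label == 1, ]
  expect_error(fit_weights(one), "both positive and negative")
})

test_that("training-sample generation is seeded and labels completions positive", {
  g <- clique_graph(c("a", "b", "c", "d"))
  ctx <- coexpression_context(g, NULL)
  bench <- list(c("a", "b", "c", "d"))
  s1 <- generate_training_samples(g, ctx, bench, n_complexes = 6, seed = 2)
  s2 <- generate_training_samples(g, ctx, bench, n_complexes = 6, seed = 2)
  expect_identical(s1, s2)
  adds <- s1[s1$type == "add", ]
  expect_true(nrow(adds) > 0)
  # every possible addition completes the lone benchmark complex
  expect_true(all(adds$label == 1))
  dels <- s1[s1$type == "delete", ]
  expect_true(all(dels$label == 0))
})
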