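test_that("connect and path_num follow shortest-path distances", {
  p3 <- path_graph(c("a", "b", "c"))
  expect_equal(connect(p3, "a", "c", 2), 1L)
  expect_equal(connect(p3, "a", "c", 1), 0L)
  expect_equal(connect(p3, "a", "a", 5), 0L)
  c4 <- cycle_graph(c("a", "b", "c", "d"))
  expect_equal(connect(c4, "a", "c", 2, mode = "at_most"), 1L)
  expect_equal(connect(c4, "a", "c", 2, mode = "exact"), 1L)
  expect_equal(connect(c4, "a", "b", 2, mode = "exact"), 0L)

  expect_equal(path_num(c4, "a", "c", 2), 2)  # a-b-c and a-d-c
  expect_equal(path_num(p3, "a", "c", 2), 1)
  expect_equal(path_num(p3, "a", "b", 2), 0)  # adjacent: shortest length 1
  expect_error(connect(p3, "a", "zz", 2), "not in graph")
})

test_that("connect_ratio and path_ratio average over the complex", {
  star <- protein_graph(rep("hub", 3), c("l1", "l2", "l3"))
  expect_equal(connect_ratio(star, "hub", c("l1", "l2", "l3"), 2), 1)
  expect_equal(path_ratio(star, "hub", c("l1", "l2", "l3"), 1), 1)
  # leaves are pairwise at distance 2 through the hub
  expect_equal(connect_ratio(star, "l1", c("l2", "l3"), 2), 1)
  expect_equal(connect_ratio(star, "l1", c("l2", "l3"), 1), 0)

  two <- protein_graph(c("a", "x"), c("b", "y"))
  expect_equal(connect_ratio(two, "a", c("x", "y"), 3), 0)
  expect_equal(path_ratio(two, "a", c("x", "y"), 3), 0)
  expect_error(connect_ratio(two, "a", character(0), 2), "empty")
})

test_that("density matches hand enumeration over ordered pairs", {
  tri <- clique_graph(c("a", "b", "c"))
  expect_equal(density(tri, c("a", "b", "c"), 2), 6 / 9)
  k4 <- clique_graph(c("a", "b", "c", "d"))
  expect_equal(density(k4, c("a", "b", "c", "d"), 2), 12 / 16)
  g <- protein_graph(c("a", "x"), c("b", "y"))
  expect_equal(density(g, c("a", "x"), 2), 0)
  expect_error(density(g, "a", 2), "size >= 2")
})

test_that("density_diff reflects how the new member attaches", {
  g <- protein_graph(c("a", "a", "b", "a"), c("b", "c", "c", "d"),
                     vertices = c("a", "b", "c", "d", "iso"))
  C <- c("a", "b", "c")
  # d reaches b and c at distance 2 through a
  expect_equal(density_diff(g, "d", C, 2), 12 / 16 - 6 / 9)
  expect_lt(density_diff(g, "iso", C, 2), 0)
  k4 <- clique_graph(c("a", "b", "c", "d"))
  k4p <- protein_graph(c("a", "a", "a", "b", "b", "c", "e", "e", "e", "e"),
                       c("b", "c", "d", "c", "d", "d", "a", "b", "c", "d"))
  expect_gte(density_diff(k4p, "e", c("a", "b", "c", "d"), 2), 0)
  expect_error(density_diff(k4, "a", c("a", "b"), 2), "already a member")
})

test_that("complex co-expression aggregates use the printed |C|^2 form", {
  ids <- c("a", "b", "c")
  E <- matrix(0, 3, 3, dimnames = list(ids, ids))
  E["a", "b"] <- E["b", "a"] <- 3
  E["a", "c"] <- E["c", "a"] <- 1
  E["b", "c"] <- E["c", "b"] <- -2
  ctx <- manual_ctx(E, eco_avg = 0.5)

  expect_equal(eco_complex(c("a", "b"), ctx), (3 + 3) / 4)
  expect_equal(eco_complex(ids, ctx), 2 * (3 + 1 - 2) / 9)
  expect_error(eco_complex("a", ctx), "size >= 2")

  expect_equal(eco_protein_complex("a", "b", ctx), 3)  # single-member mean
  expect_equal(eco_protein_complex("c", c("a", "b"), ctx), (1 - 2) / 2)
  # a member equal to v contributes 0 but stays in the denominator
  expect_equal(eco_protein_complex("a", c("a", "b"), ctx), 3 / 2)
})

test_that("co-expression indicator aggregates follow the formulas", {
  ids <- c("a", "b", "c", "d", "e")
  E <- matrix(0, 5, 5, dimnames = list(ids, ids))
  co_pairs <- rbind(c("a", "b"), c("a", "c"), c("b", "c"), c("d", "a"),
                    c("d", "b"))
  for (k in seq_len(nrow(co_pairs))) {
    E[co_pairs[k, 1], co_pairs[k, 2]] <- 10
    E[co_pairs[k, 2], co_pairs[k, 1]] <- 10
  }
  ctx <- manual_ctx(E, eco_avg = 5)

  # all three pairs of {a,b,c} co-expressed: 6 ordered pairs over 9
  expect_equal(co_ratio(c("a", "b", "c"), ctx), 6 / 9)
  expect_equal(co_pro_num("d", c("a", "b", "c", "e"), ctx), 2)
  expect_equal(co_pro_ratio("d", c("a", "b", "c", "e"), ctx), 0.5)
  expect_equal(co_pro_num("e", c("a", "b"), ctx), 0)

  # CoDiff: adding a member co-expressed with everyone raises E_co(C)
  expect_gt(co_diff("a", c("b", "c"), ctx), 0)
  expect_lt(co_diff("e", c("a", "b"), ctx), 0)
})

test_that("feature_vector has the fixed seven-feature order", {
  d <- simulate_dataset(synthetic_spec(n_complexes = 2,
                                       size_range = c(5, 5),
                                       n_background = 6, seed = 13))
  g <- d$graph
  ctx <- coexpression_context(g, normalize_expression(d$expression))
  C <- d$truth[[1]]
  v <- d$truth[[2]][1]
  f <- feature_vector(g, v, C, ctx)
  expect_named(f, c("connect_ratio", "path_ratio", "den_diff", "eco",
                    "co_diff", "co_pro_num", "co_pro_ratio"))
  expect_equal(unname(f["eco"]), eco_protein_complex(v, C, ctx))
  expect_equal(unname(f["path_ratio"]), path_ratio(g, v, C, 2))
  expect_error(feature_vector(g, C[1], C, ctx), "must not be a member")

  # an isolated protein scores zero on every connectivity feature
  giso <- protein_graph(c("a", "a", "b"), c("b", "c", "c"),
                       vertices = c("a", "b", "c", "iso"))
  ctx0 <- coexpression_context(giso, NULL)
  fi <- feature_vector(giso, "iso", c("a", "b", "c"), ctx0)
  expect_equal(unname(fi[c("connect_ratio", "path_ratio", "eco",
                           "co_pro_num", "co_pro_ratio")]),
               rep(0, 5))
  expect_lte(unname(fi["den_diff"]), 0)
})

test_that("topology features agree with igraph oracles on random graphs", {
  for (seed in 1:10) {
    g <- random_graph(sample(8:30, 1), stats::runif(1, 0.08, 0.3),
                      seed + 500)
    D <- oracle_distances(g)
    ids <- g$vertices
    us <- sample(ids, 4)
    for (u in us) {
      cnt <- oracle_path_counts(g, u)
      for (v in sample(ids, 5)) {
        for (n in 2:3) {
          expect_equal(connect(g, u, v, n),
                       as.integer(u != v && D[u, v] >= 1 & D[u, v] <= n))
          expect_equal(path_num(g, u, v, n),
                       if (u != v && D[u, v] == n) unname(cnt[v]) else 0)
        }
      }
    }
    C <- sample(ids, 5)
    for (n in 2:3) {
      den_oracle <- {
        s <- 0
        for (a in C) for (b in C) {
          if (a != b && D[a, b] <= n) s <- s + 1
        }
        s / length(C)^2
      }
      expect_equal(density(g, C, n), den_oracle)
    }
    # density is monotone non-decreasing in n under at_most
    dens <- vapply(1:4, function(n) density(g, C, n), 1)
    expect_true(all(diff(dens) >= 0))
  }
})
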