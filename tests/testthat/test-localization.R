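test_that("induced-subgraph metrics match hand enumeration", {
  p <- path_graph(5)
  expect_equal(
    unlist(module_metrics(p, c("1", "2", "3"))[, 2:4]),
    c(total_edges = 2, lcc_size = 3, lcc_edges = 2)
  )
  expect_equal(
    unlist(module_metrics(p, c("1", "3", "5"))[, 2:4]),
    c(total_edges = 0, lcc_size = 1, lcc_edges = 0)
  )
  tr <- triangle_graph()
  expect_equal(
    unlist(module_metrics(tr, c("a", "b", "c"))[, 2:4]),
    c(total_edges = 3, lcc_size = 3, lcc_edges = 3)
  )
  expect_error(module_metrics(p, character(0)), "empty")
  # tie between equal components resolved toward the smallest member:
  # triangle abc vs triangle-with-chord xyz (extra edge) of same size
  g <- as_interactome(data.frame(
    from = c("a", "b", "x", "y", "z"),
    to = c("b", "c", "y", "z", "x")
  ))
  m <- module_metrics(g, c("a", "b", "c", "x", "y", "z"))
  expect_equal(m$lcc_size, 3)
  expect_equal(m$lcc_edges, 2) # the "abc" path, not the "xyz" triangle
})

test_that("degree bins merge sparse intervals up to the occupancy floor", {
  cyc <- cycle_graph(6)
  b <- degree_bins(cyc, min_occupancy = 3)
  expect_equal(length(b$bin_nodes), 1)
  expect_equal(lengths(b$bin_nodes), 6)

  st <- star_graph(9)
  b <- degree_bins(st, min_occupancy = 2)
  # lone hub (degree 9) absorbed into the leaf bin
  expect_equal(length(b$bin_nodes), 1)
  expect_equal(lengths(b$bin_nodes), 10)
  b <- degree_bins(st, min_occupancy = 1)
  expect_equal(length(b$bin_nodes), 2) # raw base-2 bins unmerged

  expect_error(degree_bins(cyc, min_occupancy = 7), "exceeds")
  # every node in exactly one bin; bins at least at the floor
  set.seed(3)
  g <- simulate_interactome(300, 2, seed = 5)
  b <- degree_bins(g, min_occupancy = 25)
  expect_equal(sort(unlist(b$bin_nodes)), seq_len(igraph::vcount(g)))
  expect_true(all(lengths(b$bin_nodes) >= 25))
})

test_that("degree-matched samples preserve the per-bin histogram exactly", {
  g <- simulate_interactome(400, 2, seed = 8)
  bins <- degree_bins(g, min_occupancy = 30)
  nm <- igraph::V(g)$name
  set.seed(11)
  for (rep in 1:25) {
    mod <- sample(nm, 20)
    smp <- sample_degree_matched(bins, mod)
    expect_equal(length(smp), 20)
    expect_equal(anyDuplicated(smp), 0)
    hist_of <- function(v) tabulate(bins$bin_of[match(v, nm)], length(bins$bin_nodes))
    expect_identical(hist_of(smp), hist_of(mod))
  }
  # determinism under a fixed seed
  mod <- sample(nm, 15)
  expect_identical(
    sample_degree_matched(bins, mod, seed = 4),
    sample_degree_matched(bins, mod, seed = 4)
  )
})

test_that("sampling is uniform within a single bin and forced when saturated", {
  cyc <- cycle_graph(6)
  bins <- degree_bins(cyc, min_occupancy = 6)
  # module = all nodes: the only valid sample is the full node set
  smp <- sample_degree_matched(bins, as.character(1:6), seed = 1)
  expect_setequal(smp, as.character(1:6))
  # size-2 module: all 15 unordered pairs equally likely
  withr::with_seed(20, {
    draws <- replicate(3000, paste(sort(sample_degree_matched(bins, c("1", "2"))), collapse = "-"))
  })
  freq <- table(draws) / 3000
  expect_equal(length(freq), 15)
  se <- sqrt((1 / 15) * (14 / 15) / 3000)
  expect_true(all(abs(freq - 1 / 15) < 3 * se))
})

test_that("6-cycle localization z-test matches the exhaustive null", {
  cyc <- cycle_graph(6)
  # independent oracle: enumerate all 15 size-2 subsets
  null <- enumerate_null(cyc, 2)
  lcc <- null["lcc_size", ]
  expect_equal(mean(lcc), 1.4)
  expect_equal(sqrt(mean((lcc - mean(lcc))^2)), 0.4899, tolerance = 1e-4)
  fit <- localize_module(cyc, c("1", "2"), n_perm = 1000, min_occupancy = 6, seed = 2)
  row <- fit$result[fit$result$metric == "lcc_size", ]
  se_mean <- 0.4899 / sqrt(1000)
  expect_lt(abs(row$null_mean - 1.4), 3 * se_mean)
  se_sd <- 0.4899 / sqrt(2 * 999)
  expect_lt(abs(row$null_sd - 0.4899), 3 * se_sd)
  # z ~ (2 - 1.4)/0.4899 = 1.2247, p ~ 0.110
  expect_equal(row$z, 1.2247, tolerance = 0.1)
  expect_equal(row$p_value, pnorm(row$z, lower.tail = FALSE))
})

test_that("degenerate nulls are flagged with the boundary p-value convention", {
  # module = all nodes of a regular graph: every sample identical
  cyc <- cycle_graph(6)
  fit <- localize_module(cyc, as.character(1:6), n_perm = 50, min_occupancy = 6, seed = 1)
  expect_true(all(fit$result$degenerate))
  expect_true(all(is.na(fit$result$z)))
  expect_true(all(fit$result$p_value == 1)) # observed == null mean
  expect_error(localize_module(cyc, "1", n_perm = 1), "at least 2")
})

test_that("Monte-Carlo null converges to exhaustive enumeration on regular graphs", {
  for (case in list(list(n = 6, k = 2), list(n = 8, k = 3))) {
    cyc <- cycle_graph(case$n)
    null <- enumerate_null(cyc, case$k)
    fit <- localize_module(cyc, as.character(seq_len(case$k)),
      n_perm = 1000, min_occupancy = case$n, seed = 9
    )
    for (i in 1:3) {
      mu <- mean(null[i, ])
      sdv <- sqrt(mean((null[i, ] - mu)^2))
      row <- fit$result[i, ]
      expect_lt(abs(row$null_mean - mu), 3 * max(sdv, 1e-9) / sqrt(1000))
      expect_lt(abs(row$null_sd - sdv), 3 * max(sdv, 1e-9) / sqrt(2 * 999) + 1e-9)
    }
  }
})

test_that("a planted cohesive module is detected as significant on all metrics", {
  g <- simulate_interactome(2000, 3, seed = 14)
  mod <- plant_module(g, 30, cohesion = 1, seed = 15)
  expect_equal(module_metrics(g, mod$members)$lcc_size, 30) # construction guarantee
  fit <- localize_module(g, mod$members, n_perm = 500, seed = 16)
  expect_true(all(fit$result$p_value < 0.05))
  expect_true(all(fit$result$z > 0))
})

test_that("localize_modules shares bins and derives per-set sub-seeds", {
  g <- simulate_interactome(500, 2, seed = 21)
  mods <- map_gene_sets(g, list(
    m1 = plant_module(g, 12, 1, seed = 1)$members,
    m2 = plant_module(g, 12, 0, seed = 2)$members
  ))
  t1 <- localize_modules(g, mods, n_perm = 200, min_occupancy = 50, seed = 31)
  t2 <- localize_modules(g, mods, n_perm = 200, min_occupancy = 50, seed = 31)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 6)
  expect_true(all(t1$p_value >= 0 & t1$p_value <= 1))
})
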