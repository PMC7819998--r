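make_pairwise <- function(g, sets, n_perm = 200, seed = 7, ...) {
  mods <- suppressMessages(map_gene_sets(g, sets))
  pairwise_separation(g, mods, n_perm = n_perm, min_occupancy = 50, seed = seed, ...)
}

test_that("pairwise matrices are symmetric with the diagonal convention", {
  g <- simulate_interactome(400, 2, seed = 1)
  sets <- list(
    a = plant_module(g, 10, 1, seed = 2)$members,
    b = plant_module(g, 10, 1, seed = 3)$members,
    c = plant_module(g, 10, 0, seed = 4)$members
  )
  pw <- make_pairwise(g, sets)
  expect_equal(nrow(pw$pairs), 3)
  for (which in c("s", "p_value", "s_tilde")) {
    M <- pairwise_matrix(pw, which)
    expect_equal(M, t(M))
    expect_equal(dimnames(M), list(names(sets), names(sets)))
  }
  expect_equal(diag(pairwise_matrix(pw, "s")), c(a = 0, b = 0, c = 0))
  # fixed seed -> identical result, independent of module order
  pw2 <- make_pairwise(g, rev(sets))
  expect_equal(pairwise_matrix(pw2, "s"), pairwise_matrix(pw, "s")[names(rev(sets)), names(rev(sets))])
})

test_that("a duplicated module gives zero off-diagonal separation", {
  g <- simulate_interactome(400, 2, seed = 5)
  m <- plant_module(g, 10, 1, seed = 6)$members
  pw <- make_pairwise(g, list(d1 = m, d2 = m), n_perm = 100)
  expect_equal(pairwise_matrix(pw, "s")["d1", "d2"], 0)
})

test_that("failing pairs are recorded and clustering refuses missing entries", {
  g <- simulate_interactome(400, 2, seed = 8)
  sets <- list(
    ok1 = plant_module(g, 10, 1, seed = 9)$members,
    ok2 = plant_module(g, 10, 0, seed = 10)$members,
    solo = plant_module(g, 10, 1, seed = 11)$members[1]
  )
  mods <- suppressMessages(map_gene_sets(g, sets))
  pw <- pairwise_separation(g, mods, n_perm = 100, min_occupancy = 50, seed = 12)
  expect_equal(nrow(pw$failed), 2)
  expect_true(anyNA(pairwise_matrix(pw, "s")["solo", c("ok1", "ok2")]))
  expect_error(cluster_diseases(pw), "missing")
})

test_that("complete-linkage clustering merges the closest pair first", {
  S <- matrix(c(
    0, -1, 2,
    -1, 0, 2,
    2, 2, 0
  ), 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- cluster_diseases(S)
  expect_equal(sort(cl$merge[1, ]), c(-2, -1)) # A and B first
  expect_equal(length(cl$order), 3)
  expect_false(is.unsorted(cl$height))
  # all-equal distances: merges break ties lexicographically ("a","b" first),
  # then the remaining singleton leads the display order (smaller first)
  S2 <- matrix(1, 3, 3, dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  diag(S2) <- 0
  cl2 <- cluster_diseases(S2)
  expect_setequal(cl2$labels[-cl2$merge[1, ]], c("a", "b"))
  expect_equal(cl2$labels[cl2$order], c("c", "a", "b"))
})

test_that("merge order is invariant under additive shifts of s", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    v <- rnorm(n * (n - 1) / 2)
    S <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    S[upper.tri(S)] <- v
    S <- S + t(S)
    base <- cluster_diseases(S)
    for (shift in c(-5, 0.7, 123)) {
      shifted <- cluster_diseases(S + shift * (1 - diag(n)))
      expect_identical(shifted$merge, base$merge)
      expect_identical(shifted$order, base$order)
    }
  }
})

test_that("percentile thresholds follow linear interpolation", {
  # one disease with negatives {-0.4,-0.3,-0.2,-0.1}: t = -0.175, so the
  # -0.4, -0.3 and -0.2 partners are admitted
  lab <- c("D", "p1", "p2", "p3", "p4")
  St <- matrix(0.2, 5, 5, dimnames = list(lab, lab))
  diag(St) <- 0
  St["D", c("p1", "p2", "p3", "p4")] <- c(-0.4, -0.3, -0.2, -0.1)
  St[, "D"] <- St["D", ]
  dz <- build_diseasome(St, rule = "intersection")
  expect_equal(dz$thresholds$threshold[dz$thresholds$set == "D"], -0.175)
  d_edges <- dz$edges[dz$edges$from == "D" | dz$edges$to == "D", ]
  partners <- setdiff(c(d_edges$from, d_edges$to), "D")
  expect_setequal(partners, c("p1", "p2", "p3"))
})

test_that("a disease with no negative scores admits no edges of its own", {
  lab <- c("x", "y", "z")
  St <- matrix(c(0, 0.3, 0.2, 0.3, 0, -0.2, 0.2, -0.2, 0), 3, 3,
    dimnames = list(lab, lab)
  )
  dz_union <- build_diseasome(St, rule = "union")
  dz_inter <- build_diseasome(St, rule = "intersection")
  # x has no negative partner: isolated under both rules here
  expect_false("x" %in% c(dz_union$edges$from, dz_union$edges$to))
  # y~z admitted from both sides (single negative each)
  expect_equal(nrow(dz_union$edges), 1)
  expect_equal(nrow(dz_inter$edges), 1)
  expect_error(build_diseasome(St[1, 1, drop = FALSE]), "at least 2")
})

test_that("planted class structure yields clade, triangle and isolate", {
  spec <- benchmark_spec(within_class_overlap = 0.6, seed = 2)
  b <- generate_benchmark(spec)
  mods <- suppressMessages(map_gene_sets(b$graph, b$sets))
  pw <- pairwise_separation(b$graph, mods, n_perm = 400, seed = 2)
  within <- grepl("tumor", pw$pairs$module_a) & grepl("tumor", pw$pairs$module_b)
  expect_true(all(pw$pairs$label[within] == "cognate"))
  expect_true(all(pw$pairs$label[!within] == "non_cognate"))
  cl <- cluster_diseases(pw)
  first_two <- unique(unlist(lapply(1:2, function(i) {
    ids <- cl$merge[i, ]
    cl$labels[-ids[ids < 0]]
  })))
  expect_true(all(grepl("tumor", first_two))) # tumor trio forms one clade
  dz <- build_diseasome(pw)
  expect_equal(nrow(dz$edges), 3)
  expect_true(all(grepl("tumor", c(dz$edges$from, dz$edges$to))))
  expect_equal(unname(igraph::degree(dz$graph)["neuro_1"]), 0)
})

test_that("cross-collection comparison enumerates pairs and assigns stars", {
  g <- simulate_interactome(400, 2, seed = 13)
  coll_a <- suppressMessages(map_gene_sets(g, list(
    a1 = plant_module(g, 10, 1, seed = 14)$members,
    a2 = plant_module(g, 10, 1, seed = 15)$members
  )))
  coll_b <- suppressMessages(map_gene_sets(g, list(
    b1 = plant_module(g, 10, 0, seed = 16)$members,
    b2 = plant_module(g, 10, 0, seed = 17)$members,
    b3 = plant_module(g, 10, 0, seed = 18)$members
  )))
  res <- cross_collection_separation(g, coll_a, coll_b,
    n_perm = 100, min_occupancy = 50, seed = 19
  )
  expect_equal(sum(res$comparison == "cross"), 6)
  expect_equal(sum(res$comparison == "within_b"), 3)
  expect_true(all(res$stars %in% c("", "*", "**", "***")))
  expect_true(all((res$p_value < 0.05) == (res$stars != "")))
  # a module compared with itself across collections has s = 0
  res2 <- cross_collection_separation(
    g, coll_a[1, ], coll_a[1, ],
    n_perm = 100, min_occupancy = 50, seed = 20
  )
  expect_equal(res2$s[res2$comparison == "cross"], 0)
})

test_that("diseasome export writes parseable, reloadable artifacts", {
  g <- simulate_interactome(400, 2, seed = 21)
  sets <- list(
    d1 = plant_module(g, 10, 1, seed = 22)$members,
    d2 = plant_module(g, 10, 1, seed = 23)$members,
    d3 = plant_module(g, 10, 0, seed = 24)$members
  )
  pw <- make_pairwise(g, sets, n_perm = 100)
  cl <- cluster_diseases(pw)
  dz <- build_diseasome(pw, metadata = tibble::tibble(
    set = names(sets), class = c("k1", "k1", "k2")
  ))
  out <- withr::local_tempdir()
  files <- export_diseasome(dz, cl, pw, out)
  g2 <- igraph::read_graph(files[["graphml"]], format = "graphml")
  expect_setequal(igraph::V(g2)$name, names(sets))
  expect_equal(igraph::ecount(g2), nrow(dz$edges))
  expect_true("class" %in% igraph::vertex_attr_names(g2))
  tree <- ape::read.tree(files[["newick"]])
  expect_equal(sort(tree$tip.label), sort(names(sets)))
  M <- readr::read_tsv(files[["s_matrix"]], show_col_types = FALSE)
  expect_equal(dim(M), c(3, 4))
  manifest <- jsonlite::read_json(files[["manifest"]])
  expect_equal(manifest$rule, "union")
  expect_equal(manifest$alpha, 0.3)
  # rerun is byte-identical (determinism of the whole chain)
  out2 <- withr::local_tempdir()
  pw_b <- make_pairwise(g, sets, n_perm = 100)
  files2 <- export_diseasome(build_diseasome(pw_b, metadata = tibble::tibble(
    set = names(sets), class = c("k1", "k1", "k2")
  )), cluster_diseases(pw_b), pw_b, out2)
  expect_identical(
    readLines(files[["graphml"]]), readLines(files2[["graphml"]])
  )
})
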