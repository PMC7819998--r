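#' Pairwise separation analysis of a module collection
#'
#' Runs [separation_test()] for every unordered pair of modules, sharing one
#' degree binning and one distance cache. Pairs are processed in sorted
#' label order, each with a sub-seed derived from `seed`, so results are
#' reproducible regardless of input order. Pairs that fail (e.g. singleton
#' modules) are recorded and their matrix entries left missing.
#'
#' @param g Interactome graph (connected).
#' @param modules Tibble as returned by [map_gene_sets()] (columns `set`,
#'   `mapped`); at least 2 modules with >= 2 mapped members each.
#' @param n_perm,alpha,level,min_occupancy,seed As in [separation_test()].
#' @return An object of class `netsep_pairwise`: the long pair table
#'   (`$pairs`), the failed pairs (`$failed`), module labels and sizes, and
#'   run metadata. Use [pairwise_matrix()] or `as.matrix()` for the square
#'   `s`, `p_value` and `s_tilde` matrices (diagonal convention: `s = 0`,
#'   `s_tilde = 0`, `p_value = NA`).
#' @export
pairwise_separation <- function(g, modules, n_perm = 1000, alpha = 0.3,
                                level = 0.05, min_occupancy = 100, seed = NULL) {
  if (nrow(modules) < 2) abort("Need at least 2 modules for pairwise separation.")
  labels <- modules$set
  if (anyDuplicated(labels)) abort("Module labels must be unique.")
  bins <- degree_bins(g, min_occupancy = min_occupancy)
  dist_cache <- if (igraph::vcount(g) <= 5000) distance_cache(g) else NULL
  pair_idx <- utils::combn(order(labels), 2)
  rows <- list()
  failed <- list()
  for (k in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1, k]
    j <- pair_idx[2, k]
    key <- paste(sort(c(labels[[i]], labels[[j]])), collapse = "|")
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("separate:", key))
    fit <- tryCatch(
      separation_test(
        g, modules$mapped[[i]], modules$mapped[[j]],
        name_a = labels[[i]], name_b = labels[[j]],
        n_perm = n_perm, alpha = alpha, level = level,
        bins = bins, seed = sub_seed, dist_cache = dist_cache
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failed[[key]] <- tibble::tibble(
        module_a = labels[[i]], module_b = labels[[j]],
        error = conditionMessage(fit)
      )
    } else {
      rows[[key]] <- dplyr::mutate(fit$result, seed = sub_seed %||% NA_integer_)
    }
  }
  structure(
    list(
      pairs = dplyr::bind_rows(rows),
      failed = dplyr::bind_rows(failed),
      labels = labels,
      module_sizes = setNames(vapply(modules$mapped, length, integer(1)), labels),
      n_perm = n_perm, alpha = alpha, level = level, seed = seed
    ),
    class = "netsep_pairwise"
  )
}

#' Extract a square matrix from a pairwise separation result
#'
#' @param x A `netsep_pairwise` object.
#' @param which One of `"s"`, `"p_value"`, `"s_tilde"`, `"z"`.
#' @return A symmetric matrix over the module labels. Diagonal is 0 for `s`
#'   and `s_tilde`, `NA` otherwise; entries of failed pairs are `NA`.
#' @export
pairwise_matrix <- function(x, which = c("s", "p_value", "s_tilde", "z")) {
  which <- match.arg(which)
  n <- length(x$labels)
  M <- matrix(NA_real_, n, n, dimnames = list(x$labels, x$labels))
  if (nrow(x$pairs) > 0) {
    for (r in seq_len(nrow(x$pairs))) {
      a <- x$pairs$module_a[[r]]
      b <- x$pairs$module_b[[r]]
      M[a, b] <- M[b, a] <- x$pairs[[which]][[r]]
    }
  }
  if (which %in% c("s", "s_tilde")) diag(M) <- 0
  M
}

#' @export
as.matrix.netsep_pairwise <- function(x, which = "s", ...) pairwise_matrix(x, which)

#' @export
print.netsep_pairwise <- function(x, ...) {
  cat(sprintf(
    "Pairwise separation: %d modules, %d pair(s) computed, %d failed (n_perm = %d, alpha = %g)\n",
    length(x$labels), nrow(x$pairs), nrow(x$failed), x$n_perm, x$alpha
  ))
  print(dplyr::select(
    x$pairs,
    dplyr::all_of(c("module_a", "module_b", "s", "z", "p_value", "s_tilde", "label"))
  ))
  invisible(x)
}

#' Complete-linkage clustering of diseases by module separation
#'
#' Clusters diseases with the pairwise separation statistic as the distance.
#' Because `s` can be negative, the matrix is shifted by `-min(s)` before
#' agglomeration; a uniform shift leaves the complete-linkage merge order
#' unchanged, and the shift is recorded so heights can be mapped back. The
#' leaf order is canonical: at every merge the smaller cluster is placed
#' first, ties broken by the lexicographically smallest member label.
#'
#' @param x A `netsep_pairwise` object, or a symmetric numeric matrix of
#'   separation values with dimnames.
#' @return An object of class `netsep_clustering`: `$merge` and `$height`
#'   (as in [stats::hclust()], heights on the shifted scale), `$order`,
#'   `$labels`, `$shift`, and `$hclust` (base object with the canonical
#'   order applied).
#' @export
cluster_diseases <- function(x) {
  S <- if (inherits(x, "netsep_pairwise")) pairwise_matrix(x, "s") else as.matrix(x)
  # lexicographic label order makes equal-distance merges break ties
  # deterministically, independent of input order
  S <- S[order(rownames(S)), order(colnames(S))]
  lab <- rownames(S)
  off <- S[upper.tri(S)]
  if (anyNA(off)) {
    idx <- which(is.na(S) & upper.tri(S), arr.ind = TRUE)
    bad <- paste(lab[idx[, 1]], lab[idx[, 2]], sep = "~", collapse = ", ")
    abort(paste0("Separation matrix has missing entries: ", bad))
  }
  shift <- -min(off, 0)
  hc <- hclust(as.dist(S + shift), method = "complete")
  ord <- .canonical_leaf_order(hc$merge, hc$labels)
  hc$order <- ord
  structure(
    list(
      merge = hc$merge, height = hc$height, order = ord,
      labels = hc$labels, shift = shift, hclust = hc
    ),
    class = "netsep_clustering"
  )
}

# Recursive display order: smaller cluster first, ties by smallest label.
.canonical_leaf_order <- function(merge, labels) {
  n <- nrow(merge) + 1L
  node <- vector("list", nrow(merge))
  get_info <- function(id) {
    if (id < 0) {
      list(leaves = -id, size = 1L, minlab = labels[[-id]])
    } else {
      node[[id]]
    }
  }
  for (i in seq_len(nrow(merge))) {
    a <- get_info(merge[i, 1])
    b <- get_info(merge[i, 2])
    first_a <- a$size < b$size || (a$size == b$size && a$minlab <= b$minlab)
    node[[i]] <- list(
      leaves = if (first_a) c(a$leaves, b$leaves) else c(b$leaves, a$leaves),
      size = a$size + b$size,
      minlab = min(a$minlab, b$minlab)
    )
  }
  node[[nrow(merge)]]$leaves
}

#' @export
print.netsep_clustering <- function(x, ...) {
  cat(sprintf(
    "Complete-linkage disease clustering: %d leaves (distance shift %.4f)\nLeaf order: %s\n",
    length(x$labels), x$shift, paste(x$labels[x$order], collapse = ", ")
  ))
  invisible(x)
}

#' @export
as.hclust.netsep_clustering <- function(x, ...) x$hclust

#' Build the disease-disease network by the percentile edge rule
#'
#' Nodes are diseases; a candidate edge (D, E) is admitted from D's side
#' when the generalized separation `s_tilde(D, E)` does not exceed the 75th
#' percentile (linear interpolation on the sorted values) of the *negative*
#' `s_tilde` values between D and all other diseases — i.e. E is among D's
#' most strongly overlapping partners. A disease with no negative value
#' admits no edges of its own. The final edge set is, by default, the union
#' of both endpoints' admissions (the `"intersection"` variant requires
#' both).
#'
#' @param x A `netsep_pairwise` object, or a symmetric `s_tilde` matrix with
#'   dimnames.
#' @param metadata Optional tibble with columns `set` and any of `class`,
#'   `module_size`, attached as node attributes.
#' @param rule `"union"` (default) or `"intersection"` of the per-endpoint
#'   admissions.
#' @param percentile Percentile of the negative-value distribution used as
#'   the per-disease threshold (default 0.75).
#' @return An object of class `netsep_diseasome`: `$graph` (igraph; edge
#'   attribute `s_tilde`, node attributes `module_size`, `class` when
#'   available), `$edges` (tibble), `$thresholds` (per-disease tibble) and
#'   the rule parameters.
#' @export
build_diseasome <- function(x, metadata = NULL, rule = c("union", "intersection"),
                            percentile = 0.75) {
  rule <- match.arg(rule)
  St <- if (inherits(x, "netsep_pairwise")) pairwise_matrix(x, "s_tilde") else as.matrix(x)
  lab <- rownames(St)
  n <- length(lab)
  if (n < 2) abort("Need at least 2 diseases to build a diseasome.")
  if (anyNA(St[upper.tri(St)])) abort("s_tilde matrix has missing entries; compute all pairs first.")
  thr <- rep(NA_real_, n)
  admit <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    neg <- St[i, -i]
    neg <- neg[neg < 0]
    if (length(neg) == 0) next
    thr[[i]] <- unname(quantile(neg, percentile, type = 7))
    admit[i, ] <- St[i, ] <= thr[[i]]
    admit[i, i] <- FALSE
  }
  keep <- if (rule == "union") admit | t(admit) else admit & t(admit)
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- tibble::tibble(
    from = lab[idx[, 1]], to = lab[idx[, 2]],
    s_tilde = St[cbind(idx[, 1], idx[, 2])]
  )
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = lab))
  if (inherits(x, "netsep_pairwise")) {
    igraph::V(g)$module_size <- unname(x$module_sizes[lab])
  }
  if (!is.null(metadata)) {
    pos <- match(lab, metadata$set)
    for (col in setdiff(names(metadata), "set")) {
      g <- igraph::set_vertex_attr(g, col, value = metadata[[col]][pos])
    }
  }
  structure(
    list(
      graph = g, edges = edges,
      thresholds = tibble::tibble(set = lab, threshold = thr),
      rule = rule, percentile = percentile
    ),
    class = "netsep_diseasome"
  )
}

#' @export
print.netsep_diseasome <- function(x, ...) {
  cat(sprintf(
    "Diseasome: %d disease(s), %d edge(s) (%s rule, %g percentile)\n",
    igraph::vcount(x$graph), nrow(x$edges), x$rule, x$percentile
  ))
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Compare one module collection against another
#'
#' Computes [separation_test()] for every pair of one module from collection
#' A and one from collection B, plus every within-B pair — the design used
#' to contrast discovery-based disease modules with externally curated ones.
#' Significance stars follow the usual convention: `*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001.
#'
#' @param g Interactome graph.
#' @param collection_a,collection_b Module tibbles as from [map_gene_sets()].
#' @param n_perm,alpha,level,min_occupancy,seed As in [separation_test()].
#' @return A long tibble with one row per pair: the [separation_test()]
#'   columns plus `comparison` (`"cross"` or `"within_b"`) and `stars`.
#' @export
cross_collection_separation <- function(g, collection_a, collection_b,
                                        n_perm = 1000, alpha = 0.3, level = 0.05,
                                        min_occupancy = 100, seed = NULL) {
  if (nrow(collection_a) == 0 || nrow(collection_b) == 0) {
    abort("Both collections must contain at least one module.")
  }
  bins <- degree_bins(g, min_occupancy = min_occupancy)
  dist_cache <- if (igraph::vcount(g) <= 5000) distance_cache(g) else NULL
  run_pair <- function(na, ma, nb, mb, type) {
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("cross:", na, "|", nb))
    fit <- separation_test(
      g, ma, mb,
      name_a = na, name_b = nb, n_perm = n_perm, alpha = alpha,
      level = level, bins = bins, seed = sub_seed, dist_cache = dist_cache
    )
    dplyr::mutate(fit$result, comparison = type)
  }
  cross <- purrr::map(seq_len(nrow(collection_a)), function(i) {
    purrr::map(seq_len(nrow(collection_b)), function(j) {
      run_pair(
        collection_a$set[[i]], collection_a$mapped[[i]],
        collection_b$set[[j]], collection_b$mapped[[j]], "cross"
      )
    })
  })
  within_b <- if (nrow(collection_b) >= 2) {
    cmb <- utils::combn(seq_len(nrow(collection_b)), 2)
    purrr::map(seq_len(ncol(cmb)), function(k) {
      i <- cmb[1, k]
      j <- cmb[2, k]
      run_pair(
        collection_b$set[[i]], collection_b$mapped[[i]],
        collection_b$set[[j]], collection_b$mapped[[j]], "within_b"
      )
    })
  } else {
    list()
  }
  out <- dplyr::bind_rows(purrr::flatten(cross), within_b)
  dplyr::mutate(out, stars = dplyr::case_when(
    .data$p_value < 0.001 ~ "***",
    .data$p_value < 0.01 ~ "**",
    .data$p_value < 0.05 ~ "*",
    .default = ""
  ))
}

#' Export diseasome results to standard formats
#'
#' Writes the disease network as GraphML, the `s` and `s_tilde` matrices as
#' TSV, the dendrogram as Newick (with complete-linkage merge heights on the
#' shifted scale), and a JSON run manifest recording parameters and
#' thresholds.
#'
#' @param diseasome A `netsep_diseasome` object.
#' @param clustering A `netsep_clustering` object (optional; skips the
#'   Newick export when `NULL`).
#' @param pairwise A `netsep_pairwise` object (optional; skips the matrix
#'   TSVs when `NULL`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
export_diseasome <- function(diseasome, clustering = NULL, pairwise = NULL, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- c()
  gpath <- file.path(out_dir, "diseasome.graphml")
  igraph::write_graph(diseasome$graph, gpath, format = "graphml")
  files["graphml"] <- gpath
  if (!is.null(pairwise)) {
    for (which in c("s", "s_tilde")) {
      M <- pairwise_matrix(pairwise, which)
      mpath <- file.path(out_dir, paste0(which, "_matrix.tsv"))
      readr::write_tsv(
        tibble::as_tibble(as.data.frame(M), rownames = "set"), mpath
      )
      files[paste0(which, "_matrix")] <- mpath
    }
  }
  if (!is.null(clustering)) {
    npath <- file.path(out_dir, "dendrogram.nwk")
    ape::write.tree(ape::as.phylo(as.hclust(clustering)), file = npath)
    files["newick"] <- npath
  }
  manifest <- list(
    rule = diseasome$rule,
    percentile = diseasome$percentile,
    thresholds = diseasome$thresholds,
    n_edges = nrow(diseasome$edges),
    shift = if (!is.null(clustering)) clustering$shift else NULL,
    n_perm = if (!is.null(pairwise)) pairwise$n_perm else NULL,
    alpha = if (!is.null(pairwise)) pairwise$alpha else NULL,
    level = if (!is.null(pairwise)) pairwise$level else NULL,
    seed = if (!is.null(pairwise)) pairwise$seed else NULL
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files["manifest"] <- mpath
  invisible(files)
}
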