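#' Simulate a heavy-tailed synthetic interactome
#'
#' Generates a connected, simple, undirected graph by preferential
#' attachment: starting from `m` unconnected seed nodes, each of the
#' remaining `n - m` nodes attaches to `m` distinct existing nodes chosen
#' with probability proportional to degree + 1. The result has exactly
#' `m * (n - m)` edges and a heavy-tailed degree distribution — the features
#' of a real interactome that the degree-binned null model and the
#' distance-based statistics exercise.
#'
#' @param n Number of nodes (`n >= m + 1`).
#' @param m Attachment parameter: edges added per new node (`m >= 1`).
#' @param seed Optional integer seed; identical seeds give identical graphs.
#' @return An interactome igraph with node names `g000001`-style.
#' @export
#' @examples
#' g <- simulate_interactome(100, 2, seed = 1)
#' igraph::ecount(g) # 2 * 98
simulate_interactome <- function(n, m, seed = NULL) {
  if (m < 1 || n < m + 1) abort("Need n >= m + 1 >= 2.")
  n <- as.integer(n)
  m <- as.integer(m)
  edges <- .with_seed(seed, {
    deg <- integer(n)
    from <- integer(m * (n - m))
    to <- integer(m * (n - m))
    k <- 0L
    for (i in seq.int(m + 1L, n)) {
      targets <- sample.int(i - 1L, m, prob = deg[seq_len(i - 1L)] + 1)
      idx <- k + seq_len(m)
      from[idx] <- i
      to[idx] <- targets
      deg[targets] <- deg[targets] + 1L
      deg[[i]] <- deg[[i]] + m
      k <- k + m
    }
    cbind(from, to)
  })
  width <- nchar(as.character(n))
  nm <- sprintf(paste0("g%0", width, "d"), seq_len(n))
  as_interactome(tibble::tibble(from = nm[edges[, 1]], to = nm[edges[, 2]]))
}

# Start node for a non-overlapping module of an existing class: the class
# anchor when still free, else an unused node bordering the class region so
# same-class modules stay in one neighborhood without sharing members.
.pick_start <- function(idx, anchor, region, used) {
  if (!used[[anchor]]) return(anchor)
  cand <- unique(unlist(idx$adj[region]))
  cand <- cand[!used[cand]]
  if (length(cand) == 0) cand <- which(!used)
  cand[[sample.int(length(cand), 1)]]
}

# Randomized breadth-first ball: starting from `start` (vertex ids,
# themselves connected), add whole shells of new neighbors (each shell in
# random order) until the next shell would overshoot `size`, then fill up
# with a uniform sample of that boundary shell. `blocked` nodes are never
# entered. Returns ids in grown order; every prefix is connected and the
# set is as compact around `start` as the graph allows.
.grow_connected <- function(idx, start, size, blocked = NULL) {
  in_set <- logical(idx$n)
  banned <- logical(idx$n)
  if (!is.null(blocked)) banned[blocked] <- TRUE
  members <- start
  in_set[start] <- TRUE
  ring <- start
  while (length(members) < size) {
    shell <- unique(unlist(idx$adj[ring]))
    shell <- shell[!in_set[shell] & !banned[shell]]
    if (length(shell) == 0) {
      abort("Connected growth exhausted its neighborhood; module size is infeasible here.")
    }
    need <- size - length(members)
    shell <- if (length(shell) > 1) shell[sample.int(length(shell))] else shell
    if (length(shell) > need) shell <- shell[seq_len(need)]
    in_set[shell] <- TRUE
    members <- c(members, shell)
    ring <- shell
  }
  members
}

#' Plant a gene module with controlled localization
#'
#' Constructs a gene set of the requested size whose connected fraction
#' (`cohesion`) is grown as a connected subgraph by randomized
#' breadth-first expansion from a random (or given) anchor node; the
#' remaining members are drawn uniformly from the rest of the graph. With
#' `cohesion = 1` the induced subgraph is connected by construction; with
#' `cohesion = 0` the set is a uniform random draw — the two poles of the
#' localization null and alternative.
#'
#' @param g Interactome graph.
#' @param size Module size (>= 1, <= number of nodes).
#' @param cohesion Fraction of members grown connectedly, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param anchor Optional anchor node identifier for the connected core.
#' @param name Module label.
#' @return A list with `name`, `members` (character), `core` (the
#'   connectedly grown members), and `cohesion_realized`.
#' @export
plant_module <- function(g, size, cohesion = 1, seed = NULL, anchor = NULL,
                         name = "planted") {
  idx <- .net_index(g)
  if (size < 1 || size > idx$n) abort("Module size must be between 1 and the number of nodes.")
  if (cohesion < 0 || cohesion > 1) abort("`cohesion` must lie in [0, 1].")
  .with_seed(seed, {
    n_core <- ceiling(cohesion * size)
    core <- integer(0)
    if (n_core >= 1) {
      start <- if (is.null(anchor)) sample.int(idx$n, 1) else match(anchor, idx$names)
      if (anyNA(start)) abort("`anchor` must be a node of the interactome.")
      core <- .grow_connected(idx, start, n_core)
    }
    rest <- setdiff(seq_len(idx$n), core)
    uniform <- if (size - n_core > 0) rest[sample.int(length(rest), size - n_core)] else integer(0)
    members <- c(core, uniform)
    list(
      name = name,
      members = idx$names[members],
      core = idx$names[core],
      cohesion_realized = n_core / size
    )
  })
}

#' Specification of a synthetic ground-truth benchmark
#'
#' Describes the study conditions a benchmark emulates: a heavy-tailed
#' interactome and a family of planted disease modules with controlled
#' cohesion and within-class member overlap. The defaults plant a
#' three-module "tumor-like" class (fully cohesive modules of 30 genes
#' sharing 40% of their members) plus one distant cohesive isolate in a
#' 2000-node, attachment-3 network — module sizes and localization strength
#' in the range reported for real switch-gene lists, at a network scale
#' where a full distance matrix stays cheap.
#'
#' @param n_nodes Interactome size.
#' @param attachment Preferential-attachment parameter `m`.
#' @param modules Tibble with columns `module`, `class`, `size`, `cohesion`.
#' @param within_class_overlap Fraction of each module's members shared
#'   with every other module of the same class, in `[0, 1]`; across-class
#'   overlap is always 0.
#' @param seed Integer run seed; all stage randomness derives from it.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_nodes = 2000, attachment = 3,
                           modules = tibble::tibble(
                             module = c("tumor_1", "tumor_2", "tumor_3", "neuro_1"),
                             class = c("tumor", "tumor", "tumor", "neuro"),
                             size = 30,
                             cohesion = 1
                           ),
                           within_class_overlap = 0.4,
                           seed = 1) {
  stopifnot(all(c("module", "class", "size", "cohesion") %in% names(modules)))
  if (within_class_overlap < 0 || within_class_overlap > 1) {
    abort("`within_class_overlap` must lie in [0, 1].")
  }
  if (any(modules$size < 3)) abort("Planted module sizes must be at least 3.")
  if (n_nodes < 10 * max(modules$size)) {
    abort("`n_nodes` must be at least 10 times the largest module size.")
  }
  structure(
    list(
      n_nodes = as.integer(n_nodes), attachment = as.integer(attachment),
      modules = modules, within_class_overlap = within_class_overlap,
      seed = as.integer(seed)
    ),
    class = "benchmark_spec"
  )
}

#' Plant a family of modules with class structure and controlled overlap
#'
#' Realizes the ground truth of a benchmark: one anchor per class, chosen
#' mutually distant (greedy farthest-point selection on hop distances); per
#' class, one connected ball grown by randomized breadth-first expansion
#' from the anchor. The first `round(overlap * size)` ball nodes form the
#' shared core contained in every module of the class; the remaining ball
#' nodes are dealt round-robin in grown order, interleaving the modules'
#' private members through the ball's shells so that same-class modules
#' truly occupy one neighborhood. Realized within-class pairwise overlap
#' therefore equals the core size exactly and across-class overlap is 0.
#' A module's `cohesion` sets the fraction of its members drawn from the
#' class ball (the rest are uniform random nodes); with several modules per
#' class the ball is connected as a whole, while each single-module class
#' is itself a connected subgraph when `cohesion = 1`.
#'
#' @param g Interactome graph.
#' @param modules Module tibble (columns `module`, `class`, `size`,
#'   `cohesion`).
#' @param within_class_overlap Shared fraction within each class.
#' @param seed Optional integer seed.
#' @return A list with `sets` (tibble: `set`, `class`, `genes` list-column,
#'   `n_genes`) and `truth` (list: `anchors`, `overlap_counts` matrix,
#'   `cores`, `cohesion_realized`).
#' @export
plant_module_family <- function(g, modules, within_class_overlap = 0.4, seed = NULL) {
  idx <- .net_index(g)
  .with_seed(seed, {
    classes <- unique(modules$class)
    # greedy farthest-point anchors, one per class
    anchors <- integer(0)
    first <- sample.int(idx$n, 1)
    anchors[1] <- first
    while (length(anchors) < length(classes)) {
      D <- igraph::distances(g, v = anchors, algorithm = "unweighted")
      dmin <- apply(D, 2, min)
      dmin[anchors] <- -1
      cand <- which(dmin == max(dmin))
      anchors <- c(anchors, cand[[sample.int(length(cand), 1)]])
    }
    names(anchors) <- classes
    used <- logical(idx$n)
    sets <- list()
    cores <- list()
    realized <- numeric(0)
    for (cl in classes) {
      rows <- which(modules$class == cl)
      sizes <- modules$size[rows]
      o <- if (length(rows) > 1) round(within_class_overlap * min(sizes)) else 0L
      # members drawn from the class ball, per module (shared core + private)
      n_ball <- pmax(o, pmin(sizes, ceiling(modules$cohesion[rows] * sizes)))
      ball_size <- o + sum(n_ball - o)
      start <- .pick_start(idx, anchors[[cl]], integer(0), used)
      ball <- .grow_connected(idx, start, ball_size, blocked = which(used & seq_len(idx$n) != start))
      used[ball] <- TRUE
      core_shared <- if (o > 0) ball[seq_len(o)] else integer(0)
      pool <- if (ball_size > o) ball[(o + 1):ball_size] else integer(0)
      # round-robin assignment in grown order interleaves the modules'
      # private members through the ball's breadth-first shells, so
      # same-class modules occupy one shared neighborhood
      need <- n_ball - o
      assign <- integer(length(pool))
      turn <- 1L
      for (p in seq_along(pool)) {
        while (need[[turn]] == 0L) turn <- turn %% length(rows) + 1L
        assign[[p]] <- turn
        need[[turn]] <- need[[turn]] - 1L
        turn <- turn %% length(rows) + 1L
      }
      for (ri in seq_along(rows)) {
        r <- rows[[ri]]
        sz <- modules$size[[r]]
        ball_part <- c(core_shared, pool[assign == ri])
        rand_part <- integer(0)
        if (sz - length(ball_part) > 0) {
          avail <- which(!used)
          rand_part <- avail[sample.int(length(avail), sz - length(ball_part))]
          used[rand_part] <- TRUE
        }
        sets[[modules$module[[r]]]] <- c(ball_part, rand_part)
        cores[[modules$module[[r]]]] <- ball_part
        realized[modules$module[[r]]] <- length(ball_part) / sz
      }
    }
    nms <- modules$module
    ov <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
    for (i in seq_along(nms)) {
      for (j in seq_along(nms)) {
        ov[i, j] <- length(intersect(sets[[nms[[i]]]], sets[[nms[[j]]]]))
      }
    }
    list(
      sets = tibble::tibble(
        set = nms,
        class = modules$class,
        genes = unname(lapply(sets[nms], function(v) idx$names[v])),
        n_genes = lengths(sets[nms])
      ),
      truth = list(
        anchors = setNames(idx$names[anchors], classes),
        overlap_counts = ov,
        cores = lapply(cores[nms], function(v) idx$names[v]),
        cohesion_realized = realized[nms]
      )
    )
  })
}

#' Generate a full benchmark in memory
#'
#' Builds the interactome and the planted module family described by a
#' [benchmark_spec()]. All randomness derives from the spec seed via
#' [derive_seed()], so regeneration is exact.
#'
#' @param spec A [benchmark_spec()].
#' @return A list with `graph`, `sets` (gene-set tibble), and `truth`.
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  g <- simulate_interactome(spec$n_nodes, spec$attachment,
                            seed = derive_seed(spec$seed, "graph"))
  fam <- plant_module_family(g, spec$modules, spec$within_class_overlap,
                             seed = derive_seed(spec$seed, "modules"))
  list(graph = g, sets = fam$sets, truth = fam$truth)
}

#' Write a benchmark to disk
#'
#' Emits the edge-list TSV, the GMT of planted modules, the ground-truth
#' JSON (anchors, overlap counts, realized cohesion, members) and a
#' manifest recording the spec and seed. Identical spec + seed give
#' byte-identical files.
#'
#' @param spec A [benchmark_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects (`graph`, `sets`,
#'   `truth`) and the file paths.
#' @export
write_benchmark <- function(spec, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  bench <- generate_benchmark(spec)
  paths <- list(
    interactome = file.path(out_dir, "interactome.tsv"),
    gmt = file.path(out_dir, "modules.gmt"),
    truth = file.path(out_dir, "truth.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_interactome(bench$graph, paths$interactome)
  write_gmt(
    dplyr::mutate(bench$sets, description = paste0("class:", .data$class)),
    paths$gmt
  )
  jsonlite::write_json(
    list(
      anchors = as.list(bench$truth$anchors),
      overlap_counts = bench$truth$overlap_counts,
      cohesion_realized = as.list(bench$truth$cohesion_realized),
      members = setNames(bench$sets$genes, bench$sets$set)
    ),
    paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(
      n_nodes = spec$n_nodes, attachment = spec$attachment,
      modules = spec$modules,
      within_class_overlap = spec$within_class_overlap, seed = spec$seed
    ),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(c(bench, list(paths = paths)))
}
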