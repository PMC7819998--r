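#' Read an interactome from an edge-list or SIF file
#'
#' Loads an undirected protein-protein interaction network. Self-loops and
#' duplicate edges are dropped (with a message reporting how many), lines
#' starting with `#` are skipped, and fields are split on any whitespace.
#' In SIF dialect each line is `node relation target [target ...]` and one
#' edge is created per target.
#'
#' @param path Path to the network file.
#' @param format `"edgelist"` (two whitespace-separated identifier columns)
#'   or `"sif"` (Simple Interaction Format).
#' @return An undirected, simple [igraph][igraph::igraph-package] graph whose
#'   vertices are named by gene identifier and sorted lexicographically, so
#'   the same edge set always yields an identical object.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("A B", "B C", "A B"), tf)
#' g <- read_interactome(tf)
#' igraph::vcount(g) # 3
#' igraph::ecount(g) # 2
read_interactome <- function(path, format = c("edgelist", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Cannot read interactome file '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  pairs_from <- character(0)
  pairs_to <- character(0)
  for (i in idx) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (format == "edgelist") {
      if (length(fields) < 2) {
        abort(sprintf("Malformed edge-list line %d in '%s': need 2 identifiers.", i, path))
      }
      pairs_from <- c(pairs_from, fields[[1]])
      pairs_to <- c(pairs_to, fields[[2]])
    } else {
      if (length(fields) < 3) {
        abort(sprintf("Malformed SIF line %d in '%s': need node, relation, target.", i, path))
      }
      tg <- fields[3:length(fields)]
      pairs_from <- c(pairs_from, rep(fields[[1]], length(tg)))
      pairs_to <- c(pairs_to, tg)
    }
  }
  as_interactome(tibble::tibble(from = pairs_from, to = pairs_to))
}

#' Coerce an edge table or igraph to a canonical interactome
#'
#' @param x A data frame whose first two columns are gene identifiers of the
#'   two endpoints of each interaction, or an igraph object with named
#'   vertices.
#' @return An undirected simple igraph graph with lexicographically sorted,
#'   named vertices. Self-loops and duplicate (unordered) edges are removed;
#'   a message reports the counts dropped.
#' @export
as_interactome <- function(x) {
  if (igraph::is_igraph(x)) {
    nm <- igraph::vertex_attr(x, "name")
    if (is.null(nm)) abort("Interactome graphs must have named vertices.")
    el <- igraph::as_edgelist(x, names = TRUE)
    x <- tibble::tibble(from = el[, 1], to = el[, 2])
  }
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort("`x` must be an igraph object or a data frame with two identifier columns.")
  }
  from <- as.character(x[[1]])
  to <- as.character(x[[2]])
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]
  to <- to[!self]
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_self > 0 || n_dup > 0) {
    inform(sprintf("Dropped %d self-loop(s) and %d duplicate edge(s).", n_self, n_dup))
  }
  nodes <- sort(unique(c(from, to, x[[1]][self])))
  ord <- order(a[!dup], b[!dup])
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[!dup][ord], to = b[!dup][ord]),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  g
}

#' Write an interactome to a two-column TSV edge list or GraphML
#'
#' @param g Interactome graph.
#' @param path Output file.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  g <- as_interactome(g)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(g, names = TRUE)
    readr::write_tsv(tibble::tibble(from = el[, 1], to = el[, 2]), path, col_names = FALSE)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Restrict a graph to its largest connected component
#'
#' All distance-based statistics in the package are computed on the largest
#' connected component (LCC) so that every shortest-path distance is finite.
#' Ties in component size are broken by the lexicographically smallest member
#' identifier.
#'
#' @param g Interactome graph.
#' @return The subgraph induced by the LCC, in canonical form.
#' @export
restrict_to_lcc <- function(g) {
  if (igraph::vcount(g) == 0) abort("Cannot take the LCC of an empty graph.")
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    nm <- igraph::V(g)$name
    first_member <- vapply(best, function(k) min(nm[comp$membership == k]), character(1))
    best <- best[order(first_member)][1]
  }
  n_drop <- igraph::vcount(g) - sizes[best]
  if (n_drop > 0) {
    warn(sprintf("Restricting to largest connected component: %d node(s) dropped.", n_drop))
  }
  as_interactome(igraph::induced_subgraph(g, which(comp$membership == best)))
}

#' Read gene-set collections in GMT format
#'
#' One set per line: name, description, then tab-separated member
#' identifiers. Duplicate members within a line are collapsed with a warning;
#' empty lines are skipped.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set` (name), `description`, `genes`
#'   (list-column of unique identifiers) and `n_genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read GMT file '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      set = character(0), description = character(0),
      genes = list(), n_genes = integer(0)
    ))
  }
  rows <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("Malformed GMT line %d in '%s': need name, description and >= 1 member.", i, path))
    }
    members <- fields[3:length(fields)]
    members <- members[members != ""]
    uniq <- unique(members)
    if (length(uniq) < length(members)) {
      warn(sprintf("Gene set '%s': %d duplicate member(s) collapsed.", fields[[1]], length(members) - length(uniq)))
    }
    tibble::tibble(set = fields[[1]], description = fields[[2]], genes = list(uniq))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, n_genes = lengths(.data$genes))
}

#' Write gene sets to a GMT file
#'
#' @param sets Tibble with columns `set`, `genes` and optionally
#'   `description` (defaults to `"na"`), as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- if ("description" %in% names(sets)) sets$description else rep("na", nrow(sets))
  lines <- purrr::map_chr(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set[[i]], desc[[i]], sets$genes[[i]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Map a gene set onto the interactome
#'
#' Intersects a gene set with the interactome's node set (exact,
#' case-sensitive identifier matching) and records how many members were
#' lost to interactome incompleteness.
#'
#' @param g Interactome graph.
#' @param genes Character vector of member identifiers.
#' @param name Optional module label.
#' @return A list with elements `name`, `mapped` (identifiers present in
#'   `g`), and `unmapped_count`.
#' @export
map_gene_set <- function(g, genes, name = "module") {
  genes <- unique(as.character(genes))
  mapped <- genes[genes %in% igraph::V(g)$name]
  if (length(mapped) == 0) {
    abort(sprintf("Gene set '%s' has no members in the interactome.", name))
  }
  n_un <- length(genes) - length(mapped)
  if (n_un > 0) {
    inform(sprintf("Gene set '%s': %d of %d member(s) not in the interactome.", name, n_un, length(genes)))
  }
  list(name = name, mapped = mapped, unmapped_count = n_un)
}

#' Map a collection of gene sets onto the interactome
#'
#' @param g Interactome graph.
#' @param sets Gene-set tibble as returned by [read_gmt()] (columns `set`,
#'   `genes`), or a named list of character vectors.
#' @param drop_failed If `TRUE` (default) sets with no member in the
#'   interactome are dropped with a warning rather than raising an error.
#' @return A tibble with columns `set`, `n_members`, `n_mapped`,
#'   `n_unmapped`, and `mapped` (list-column of mapped identifiers).
#' @export
map_gene_sets <- function(g, sets, drop_failed = TRUE) {
  if (is.list(sets) && !is.data.frame(sets)) {
    sets <- tibble::tibble(set = names(sets), genes = unname(sets))
  }
  rows <- purrr::map(seq_len(nrow(sets)), function(i) {
    res <- tryCatch(
      map_gene_set(g, sets$genes[[i]], name = sets$set[[i]]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (!drop_failed) abort(conditionMessage(res))
      warn(sprintf("Dropping gene set '%s': %s", sets$set[[i]], conditionMessage(res)))
      return(NULL)
    }
    tibble::tibble(
      set = res$name,
      n_members = length(sets$genes[[i]]),
      n_mapped = length(res$mapped),
      n_unmapped = res$unmapped_count,
      mapped = list(res$mapped)
    )
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Minimum hop distances from a set of source nodes to a target set
#'
#' For each source node `a`, the minimum unweighted shortest-path (hop)
#' distance to any node of the target set. With `exclude_self = TRUE` the
#' target `b = a` is skipped, which is the convention used for a module's
#' self-proximity.
#'
#' @param g Interactome graph (connected).
#' @param sources,targets Character vectors of node identifiers present in
#'   `g`.
#' @param exclude_self Exclude each source node from its own target set.
#' @return A tibble with columns `node` and `distance` (non-negative
#'   integer), one row per source, in the order given.
#' @export
min_set_distances <- function(g, sources, targets, exclude_self = FALSE) {
  nm <- igraph::V(g)$name
  if (!all(sources %in% nm) || !all(targets %in% nm)) {
    abort("All source and target identifiers must be nodes of the interactome.")
  }
  D <- igraph::distances(g, v = sources, to = targets, algorithm = "unweighted")
  if (exclude_self) {
    for (a in intersect(sources, targets)) D[a, a] <- Inf
  }
  d <- apply(D, 1, min)
  if (any(!is.finite(d))) {
    bad <- sources[!is.finite(d)]
    if (exclude_self && any(bad %in% targets) && length(targets) == 1) {
      abort("Self-comparison of a singleton set: no other target to measure against.")
    }
    abort("Some sources cannot reach the target set; restrict to the LCC first.")
  }
  tibble::tibble(node = sources, distance = as.numeric(d))
}

# Fast adjacency-list index used by the permutation machinery: repeated
# induced-subgraph metrics through igraph would dominate run time.
.net_index <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  list(n = n, names = igraph::V(g)$name, adj = adj, deg = lengths(adj))
}
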