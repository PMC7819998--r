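# Small fixture graphs and independent brute-force oracles used across the
# suite. The oracles deliberately avoid the package's own code paths (and
# igraph's distance routines) so they can certify them.

path_graph <- function(n) {
  as_interactome(data.frame(
    from = as.character(seq_len(n - 1)),
    to = as.character(seq_len(n - 1) + 1)
  ))
}

cycle_graph <- function(n) {
  as_interactome(data.frame(
    from = as.character(seq_len(n)),
    to = as.character(c(seq_len(n - 1) + 1, 1))
  ))
}

star_graph <- function(n_leaves) {
  as_interactome(data.frame(
    from = rep("hub", n_leaves),
    to = paste0("leaf", seq_len(n_leaves))
  ))
}

triangle_graph <- function() {
  as_interactome(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")))
}

# A random connected graph on `n` nodes: a random spanning path plus extra
# random edges. Node names are letters.
random_connected_graph <- function(n, extra = n) {
  stopifnot(n <= 26)
  nm <- letters[seq_len(n)]
  perm <- sample(nm)
  from <- perm[-n]
  to <- perm[-1]
  if (extra > 0) {
    pairs <- t(combn(nm, 2))
    pick <- pairs[sample.int(nrow(pairs), min(extra, nrow(pairs))), , drop = FALSE]
    from <- c(from, pick[, 1])
    to <- c(to, pick[, 2])
  }
  suppressMessages(as_interactome(data.frame(from = from, to = to)))
}

# Floyd-Warshall all-pairs hop distances; independent of igraph.
fw_distances <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  D <- matrix(Inf, n, n, dimnames = list(nm, nm))
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = TRUE)
  for (r in seq_len(nrow(el))) {
    D[el[r, 1], el[r, 2]] <- 1
    D[el[r, 2], el[r, 1]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Brute-force proximity straight from the defining sum, on an fw_distances
# matrix. Self-proximity excludes the node itself from the inner minimum.
brute_proximity <- function(D, a, b) {
  self <- setequal(a, b)
  inner_min <- function(x, targets) {
    t2 <- if (self) setdiff(targets, x) else targets
    min(D[x, t2])
  }
  (sum(vapply(a, inner_min, numeric(1), targets = b)) +
    sum(vapply(b, inner_min, numeric(1), targets = a))) / (length(a) + length(b))
}

brute_separation <- function(D, a, b) {
  if (setequal(a, b)) return(0)
  brute_proximity(D, a, b) -
    (brute_proximity(D, a, a) + brute_proximity(D, b, b)) / 2
}

# Exhaustively enumerated localization null on a small graph: metrics of
# every k-subset of nodes (valid because a regular graph has one degree bin).
enumerate_null <- function(g, k) {
  nm <- igraph::V(g)$name
  subs <- combn(nm, k)
  vapply(seq_len(ncol(subs)), function(i) {
    unlist(module_metrics(g, subs[, i])[, c("total_edges", "lcc_size", "lcc_edges")])
  }, numeric(3))
}
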