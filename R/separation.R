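#' Generalized (significance-weighted) module separation
#'
#' Blends the separation statistic `s` and its p-value into one bounded,
#' dimensionless score via a sigmoid:
#' `s_tilde = 1 / (1 + exp(-alpha * s / pval)) - 0.5`.
#' It is strictly increasing in `s`, odd in `s`, shrinks toward 0 as the
#' p-value grows (insignificant pairs land near 0), and approaches +/-0.5 as
#' the p-value approaches 0.
#'
#' p-values are floored at `1e-308` to avoid overflow; where the sigmoid
#' saturates to exactly +/-0.5 in floating point the value is nudged to
#' +/-(0.5 - 1e-9), preserving the open bound `|s_tilde| < 0.5`.
#'
#' @param s Separation value(s), in hops.
#' @param pval Corresponding p-value(s), in `(0, 1]` (0 allowed only with
#'   `saturate = TRUE`).
#' @param alpha Smoothing parameter (> 0). The default 0.3 keeps the score
#'   inside roughly `[-0.1, 0.1]` for insignificant p-values while spreading
#'   significant pairs toward the bounds.
#' @param saturate If `TRUE`, a zero p-value is treated as the floor value
#'   and the score saturates; if `FALSE` (default) a zero p-value is an
#'   error.
#' @return Numeric vector of scores in `(-0.5, 0.5)`.
#' @export
#' @examples
#' generalized_separation(0, 0.5)          # 0: sigmoid midpoint
#' generalized_separation(-2/3, 0.01)      # ~ -0.5: strongly overlapping
#' generalized_separation(1, 0.8)          # near 0: insignificant
generalized_separation <- function(s, pval, alpha = 0.3, saturate = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) abort("`alpha` must be a positive number.")
  if (any(pval < 0 | pval > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  if (!saturate && any(pval == 0, na.rm = TRUE)) {
    abort("p-value of 0 is outside the domain; use `saturate = TRUE` to report the limiting value.")
  }
  p <- pmax(pval, 1e-308)
  st <- 1 / (1 + exp(-alpha * s / p)) - 0.5
  pmin(pmax(st, -0.5 + 1e-9), 0.5 - 1e-9)
}

#' Classify a disease pair from its separation and significance
#'
#' Pairs with significantly negative separation occupy the same interactome
#' neighborhood (`cognate`); significantly positive separation means
#' topologically distinct modules (`non_cognate`); anything else — including
#' degenerate nulls — is `uncertain`.
#'
#' @param s Separation value(s).
#' @param pval Two-tailed p-value(s).
#' @param level Significance level (default 0.05).
#' @return Character vector in `{"cognate", "non_cognate", "uncertain"}`.
#' @export
classify_separation <- function(s, pval, level = 0.05) {
  dplyr::case_when(
    !is.na(pval) & pval < level & s < 0 ~ "cognate",
    !is.na(pval) & pval < level & s > 0 ~ "non_cognate",
    .default = "uncertain"
  )
}

# Distance accessor: full cached matrix for small graphs, on-demand BFS
# otherwise. Both return hop-count matrices indexed by integer vertex id.
.make_getD <- function(g, dist_cache = NULL, cache_max = 5000) {
  if (!is.null(dist_cache)) {
    force(dist_cache)
    return(function(i, j) dist_cache[i, j, drop = FALSE])
  }
  if (igraph::vcount(g) <= cache_max) {
    D <- igraph::distances(g, algorithm = "unweighted")
    return(function(i, j) D[i, j, drop = FALSE])
  }
  function(i, j) igraph::distances(g, v = i, to = j, algorithm = "unweighted")
}

#' Precompute the full hop-distance matrix of an interactome
#'
#' Useful to share across many [separation_test()] calls on the same graph;
#' requires `8 * n^2` bytes of memory.
#'
#' @param g Interactome graph.
#' @return A dense numeric matrix of hop counts, in vertex-id order.
#' @export
distance_cache <- function(g) {
  igraph::distances(g, algorithm = "unweighted")
}

# Proximity on integer ids. `self = TRUE` applies the self-excluding inner
# minimum used for a module's proximity to itself.
.proximity_ids <- function(getD, a, b, self = FALSE) {
  D <- getD(a, b)
  if (self) diag(D) <- Inf
  ra <- apply(D, 1, min)
  cb <- apply(D, 2, min)
  if (any(!is.finite(ra)) || any(!is.finite(cb))) {
    abort("Infinite distances in proximity; restrict the interactome to its LCC first.")
  }
  (sum(ra) + sum(cb)) / (length(a) + length(b))
}

# Proximity/separation preamble shared by the public wrappers.
.resolve_ids <- function(g, nodes, what) {
  nodes <- unique(as.character(nodes))
  ids <- match(nodes, igraph::V(g)$name)
  if (anyNA(ids)) abort(sprintf("All members of %s must be nodes of the interactome.", what))
  if (length(ids) == 0) abort(sprintf("%s is empty.", what))
  ids
}

#' Module proximity
#'
#' Mean nearest-member hop distance between two modules:
#' `p(A,B) = (sum_a min_b d(a,b) + sum_b min_a d(b,a)) / (|A| + |B|)`.
#' When `a` and `b` contain the same members the self-proximity convention
#' applies: each node's nearest *other* member is used (so a singleton has
#' no self-proximity). When two distinct modules share members, a shared
#' node contributes distance 0, pulling the proximity down.
#'
#' @param g Interactome graph (connected).
#' @param a,b Character vectors of module members.
#' @param dist_cache Optional matrix from [distance_cache()].
#' @return The mean hop distance (a single number).
#' @export
module_proximity <- function(g, a, b, dist_cache = NULL) {
  ia <- .resolve_ids(g, a, "module A")
  ib <- .resolve_ids(g, b, "module B")
  self <- setequal(ia, ib)
  if (self && length(ia) < 2) abort("Self-proximity of a singleton module is undefined.")
  getD <- .make_getD(g, dist_cache)
  if (self) ib <- ia
  .proximity_ids(getD, ia, ib, self = self)
}

#' Module separation statistic
#'
#' `s(A,B) = p_AB - (p_AA + p_BB) / 2`: the mean nearest-member distance
#' between the two modules, relative to the modules' own internal
#' nearest-member distances. Positive values mean topological separation;
#' negative values mean the modules occupy overlapping neighborhoods.
#' Symmetric in its two arguments.
#'
#' @inheritParams module_proximity
#' @return The separation, in hops.
#' @export
module_separation <- function(g, a, b, dist_cache = NULL) {
  ia <- .resolve_ids(g, a, "module A")
  ib <- .resolve_ids(g, b, "module B")
  if (length(ia) < 2 || length(ib) < 2) abort("Separation requires at least 2 mapped members per module.")
  getD <- .make_getD(g, dist_cache)
  .sep_ids(getD, ia, ib)
}

.sep_ids <- function(getD, ia, ib) {
  if (setequal(ia, ib)) return(0)
  p_ab <- .proximity_ids(getD, ia, ib, self = FALSE)
  p_aa <- .proximity_ids(getD, ia, ia, self = TRUE)
  p_bb <- .proximity_ids(getD, ib, ib, self = TRUE)
  p_ab - (p_aa + p_bb) / 2
}

#' Permutation significance of module separation
#'
#' Builds the null distribution of `s(A,B)` by replacing *both* modules with
#' independent degree-matched random node sets `n_perm` times, z-scores the
#' observed separation against it, and reports a two-tailed normal p-value.
#' The result carries the generalized score `s_tilde` and the
#' cognate / non_cognate / uncertain label at the chosen `level`. A
#' degenerate null (zero standard deviation) forces the label to
#' `uncertain`.
#'
#' @param g Interactome graph (connected; use [restrict_to_lcc()]).
#' @param a,b Character vectors of mapped module members (>= 2 each).
#' @param name_a,name_b Labels for the output.
#' @param n_perm Null replicates (default 1000).
#' @param alpha Smoothing parameter of [generalized_separation()].
#' @param level Significance level for the pair label.
#' @param bins Optional shared [degree_bins()].
#' @param min_occupancy Passed to [degree_bins()] when `bins` is `NULL`.
#' @param seed Optional integer seed.
#' @param dist_cache Optional matrix from [distance_cache()]; computed
#'   internally for graphs up to 5000 nodes otherwise.
#' @return An object of class `netsep_separation`; see [tidy()][generics::tidy]
#'   for the one-row summary (p_ab, p_aa, p_bb, s, null_mean, null_sd, z,
#'   p_value, s_tilde, label).
#' @export
separation_test <- function(g, a, b, name_a = "A", name_b = "B", n_perm = 1000,
                            alpha = 0.3, level = 0.05, bins = NULL,
                            min_occupancy = 100, seed = NULL, dist_cache = NULL) {
  if (n_perm < 2) abort("`n_perm` must be at least 2.")
  .assert_scalar_prob(level, "level")
  ia <- .resolve_ids(g, a, "module A")
  ib <- .resolve_ids(g, b, "module B")
  if (length(ia) < 2 || length(ib) < 2) abort("Separation requires at least 2 mapped members per module.")
  getD <- .make_getD(g, dist_cache)
  if (is.null(bins)) bins <- degree_bins(g, min_occupancy = min_occupancy)
  need_a <- tabulate(bins$bin_of[ia], nbins = length(bins$bin_nodes))
  need_b <- tabulate(bins$bin_of[ib], nbins = length(bins$bin_nodes))

  p_ab <- .proximity_ids(getD, ia, ib, self = FALSE)
  p_aa <- .proximity_ids(getD, ia, ia, self = TRUE)
  p_bb <- .proximity_ids(getD, ib, ib, self = TRUE)
  s_obs <- if (setequal(ia, ib)) 0 else p_ab - (p_aa + p_bb) / 2

  null_s <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      a2 <- .sample_matched_ids(bins, need_a)
      b2 <- .sample_matched_ids(bins, need_b)
      .sep_ids(getD, a2, b2)
    }, numeric(1))
  })
  null_mean <- mean(null_s)
  null_sd <- sd(null_s)
  degenerate <- null_sd == 0
  if (degenerate) {
    z <- NA_real_
    p <- NA_real_
    label <- "uncertain"
    s_tilde <- NA_real_
  } else {
    z <- (s_obs - null_mean) / null_sd
    p <- max(2 * pnorm(-abs(z)), 1e-308)
    s_tilde <- generalized_separation(s_obs, p, alpha = alpha, saturate = TRUE)
    label <- classify_separation(s_obs, p, level = level)
  }
  structure(
    list(
      name_a = name_a, name_b = name_b,
      result = tibble::tibble(
        module_a = name_a, module_b = name_b,
        p_ab = p_ab, p_aa = p_aa, p_bb = p_bb, s = s_obs,
        null_mean = null_mean, null_sd = null_sd, z = z, p_value = p,
        s_tilde = s_tilde, label = label, degenerate = degenerate
      ),
      null_samples = null_s,
      n_perm = n_perm, alpha = alpha, level = level, seed = seed
    ),
    class = "netsep_separation"
  )
}

#' @export
print.netsep_separation <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "Separation s(%s, %s) = %.4f  [z = %.2f, p = %.3g, s_tilde = %.4f] -> %s\n",
    r$module_a, r$module_b, r$s, r$z, r$p_value, r$s_tilde, r$label
  ))
  invisible(x)
}
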