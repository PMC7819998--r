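#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn localize_module Tidy per-metric table (one row per metric).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.netsep_localization <- function(x, ...) x$result

#' @describeIn localize_module One-row summary: the smallest metric p-value
#'   and whether all three metrics are significant at 0.05.
#' @export
glance.netsep_localization <- function(x, ...) {
  tibble::tibble(
    set = x$set, n_nodes = x$n_nodes, n_perm = x$n_perm,
    min_p_value = min(x$result$p_value),
    all_significant = all(x$result$p_value < 0.05)
  )
}

#' @describeIn separation_test Tidy one-row result table.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.netsep_separation <- function(x, ...) x$result

#' @describeIn separation_test One-row run summary.
#' @export
glance.netsep_separation <- function(x, ...) {
  tibble::tibble(
    module_a = x$name_a, module_b = x$name_b, n_perm = x$n_perm,
    alpha = x$alpha, level = x$level, label = x$result$label
  )
}

#' @describeIn pairwise_separation Long pair table (one row per unordered
#'   pair).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.netsep_pairwise <- function(x, ...) x$pairs

#' @describeIn pairwise_separation One-row summary with label counts.
#' @export
glance.netsep_pairwise <- function(x, ...) {
  tibble::tibble(
    n_modules = length(x$labels),
    n_pairs = nrow(x$pairs),
    n_failed = nrow(x$failed),
    n_cognate = sum(x$pairs$label == "cognate"),
    n_non_cognate = sum(x$pairs$label == "non_cognate"),
    n_uncertain = sum(x$pairs$label == "uncertain"),
    n_perm = x$n_perm, alpha = x$alpha, level = x$level
  )
}

#' @describeIn cluster_diseases Tidy merge history: one row per
#'   agglomeration step. Negative `node_*` values are leaves (`-i` is the
#'   i-th label), positive values earlier merge steps.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.netsep_clustering <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$height),
    node_a = x$merge[, 1], node_b = x$merge[, 2],
    height = x$height
  )
}

#' @describeIn cluster_diseases One-row summary.
#' @export
glance.netsep_clustering <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(x$labels), shift = x$shift,
    max_height = max(x$height)
  )
}

#' @describeIn build_diseasome Tidy edge table.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.netsep_diseasome <- function(x, ...) x$edges

#' @describeIn build_diseasome One-row summary.
#' @export
glance.netsep_diseasome <- function(x, ...) {
  tibble::tibble(
    n_diseases = igraph::vcount(x$graph),
    n_edges = nrow(x$edges),
    n_isolated = sum(igraph::degree(x$graph) == 0),
    rule = x$rule, percentile = x$percentile
  )
}
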