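# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom stats quantile sd pnorm hclust as.dist as.hclust setNames
#' @importFrom utils head
NULL

# Stable 31-bit hash of a string, used to derive stage- and pair-level
# sub-seeds from one run seed so that stages are decoupled but reproducible.
.hash_string <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647L
  as.integer(h)
}

#' Derive a reproducible sub-seed
#'
#' Combines a run-level seed with a stage label so that independent pipeline
#' stages (or disease pairs) consume decoupled random streams while the whole
#' run stays reproducible from a single seed.
#'
#' @param seed Integer run seed.
#' @param stage Character label of the stage or unit of work.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(42L, "localize:AD")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + .hash_string(stage)) %% 2147483647)
}

# Run `expr` under `seed` when given, restoring the caller's RNG state;
# with seed = NULL the global stream is consumed as-is.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

.assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single number in (0, 1).", name))
  }
}
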