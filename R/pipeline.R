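#' Assemble a pipeline run configuration
#'
#' Collects all knobs of the analysis pipeline with the study defaults:
#' 1000 permutation replicates, smoothing `alpha = 0.3`, significance level
#' 0.05, degree-bin occupancy 100, and the union variant of the diseasome
#' edge rule.
#'
#' @param interactome Path to the interactome file.
#' @param gene_sets Path to the GMT gene-set file.
#' @param format Interactome dialect, `"edgelist"` or `"sif"`.
#' @param n_perm Permutation replicates.
#' @param alpha Sigmoid smoothing parameter.
#' @param level Significance level.
#' @param min_occupancy Degree-bin occupancy floor.
#' @param seed Integer run seed.
#' @param out_dir Output directory.
#' @param edge_rule `"union"` or `"intersection"` diseasome admission.
#' @return A `netsep_config` list.
#' @export
netsep_config <- function(interactome = NULL, gene_sets = NULL,
                          format = "edgelist", n_perm = 1000, alpha = 0.3,
                          level = 0.05, min_occupancy = 100, seed = 1,
                          out_dir = ".", edge_rule = "union") {
  cfg <- list(
    interactome = interactome, gene_sets = gene_sets, format = format,
    n_perm = as.integer(n_perm), alpha = alpha, level = level,
    min_occupancy = as.integer(min_occupancy), seed = as.integer(seed),
    out_dir = out_dir, edge_rule = edge_rule
  )
  .assert_scalar_prob(cfg$level, "level")
  if (cfg$alpha <= 0) abort("`alpha` must be positive.")
  if (!cfg$edge_rule %in% c("union", "intersection")) {
    abort("`edge_rule` must be 'union' or 'intersection'.")
  }
  structure(cfg, class = "netsep_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [netsep_config()]; `overrides` (e.g. parsed
#' command-line flags) take precedence over the file, which takes precedence
#' over the defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults/overrides.
#' @param overrides Named list of values overriding the file.
#' @return A `netsep_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  do.call(netsep_config, vals)
}

# Load, LCC-restrict, and map the inputs shared by the run_* commands.
.load_inputs <- function(config) {
  g <- read_interactome(config$interactome, format = config$format)
  g <- restrict_to_lcc(g)
  sets <- read_gmt(config$gene_sets)
  modules <- map_gene_sets(g, sets)
  failed <- setdiff(sets$set, modules$set)
  list(graph = g, sets = sets, modules = modules, failed = failed)
}

.write_manifest <- function(config, path, extra = list()) {
  payload <- c(unclass(config), extra, list(netsep_version = as.character(utils::packageVersion("netsep"))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the localization stage
#'
#' Maps every gene set onto the interactome's LCC and computes module
#' significance for each. Writes `localization.tsv` (one row per module and
#' metric; gene sets with no mapped member appear as `status = "failed"`
#' rows) and `localization_manifest.json` into the configured output
#' directory.
#'
#' @param config A `netsep_config`.
#' @return The localization tibble, invisibly.
#' @export
run_localize <- function(config) {
  inp <- .load_inputs(config)
  tab <- localize_modules(
    inp$graph, inp$modules,
    n_perm = config$n_perm,
    min_occupancy = config$min_occupancy, seed = config$seed
  )
  tab$status <- "ok"
  if (length(inp$failed) > 0) {
    tab <- dplyr::bind_rows(tab, tibble::tibble(set = inp$failed, status = "failed"))
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  readr::write_tsv(tab, file.path(config$out_dir, "localization.tsv"))
  .write_manifest(config, file.path(config$out_dir, "localization_manifest.json"),
                  list(stage = "localize", failed_sets = inp$failed))
  invisible(tab)
}

#' Run the pairwise separation stage
#'
#' Computes the separation z-test, generalized score and pair label for
#' every unordered pair of mapped modules. Writes `separation.tsv` and
#' `separation_manifest.json`.
#'
#' @param config A `netsep_config`.
#' @return The `netsep_pairwise` object, invisibly.
#' @export
run_separate <- function(config) {
  inp <- .load_inputs(config)
  pw <- pairwise_separation(
    inp$graph, inp$modules,
    n_perm = config$n_perm, alpha = config$alpha, level = config$level,
    min_occupancy = config$min_occupancy, seed = config$seed
  )
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  out <- dplyr::mutate(pw$pairs, n_perm = config$n_perm, alpha = config$alpha)
  readr::write_tsv(out, file.path(config$out_dir, "separation.tsv"))
  .write_manifest(config, file.path(config$out_dir, "separation_manifest.json"),
                  list(stage = "separate", failed_pairs = pw$failed))
  invisible(pw)
}

#' Run the diseasome stage
#'
#' Composes pairwise separation, complete-linkage clustering and the
#' percentile edge rule, then exports GraphML, matrix TSVs, a Newick
#' dendrogram and a JSON manifest.
#'
#' @param config A `netsep_config`.
#' @return A list with `pairwise`, `clustering` and `diseasome`, invisibly.
#' @export
run_diseasome <- function(config) {
  inp <- .load_inputs(config)
  pw <- pairwise_separation(
    inp$graph, inp$modules,
    n_perm = config$n_perm, alpha = config$alpha, level = config$level,
    min_occupancy = config$min_occupancy, seed = config$seed
  )
  cl <- cluster_diseases(pw)
  meta <- tibble::tibble(set = inp$modules$set)
  if ("description" %in% names(inp$sets)) {
    meta$class <- sub("^class:", "", inp$sets$description[match(meta$set, inp$sets$set)])
  }
  dz <- build_diseasome(pw, metadata = meta, rule = config$edge_rule)
  export_diseasome(dz, cl, pw, config$out_dir)
  .write_manifest(config, file.path(config$out_dir, "diseasome_manifest.json"),
                  list(stage = "diseasome", shift = cl$shift))
  invisible(list(pairwise = pw, clustering = cl, diseasome = dz))
}

#' Run the benchmark simulation stage
#'
#' Generates the synthetic ground-truth benchmark (interactome, planted
#' modules, truth and manifest files) described by a [benchmark_spec()],
#' or by a YAML file with the same fields.
#'
#' @param spec A [benchmark_spec()] or a path to a YAML spec.
#' @param out_dir Output directory.
#' @return Invisibly, the [write_benchmark()] result.
#' @export
run_simulate <- function(spec, out_dir) {
  if (is.character(spec)) {
    vals <- yaml::read_yaml(spec)
    if (!is.null(vals$modules)) {
      vals$modules <- dplyr::bind_rows(lapply(vals$modules, tibble::as_tibble))
    }
    spec <- do.call(benchmark_spec, vals)
  }
  write_benchmark(spec, out_dir)
}
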