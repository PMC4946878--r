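#' Pipeline configuration
#'
#' A pipeline config bundles input paths (or a simulation block replacing
#' them), the hit-calling parameters, an output directory and a seed; it
#' round-trips losslessly through YAML so an analysis can be re-run
#' byte-identically from its config file.
#'
#' @param out_dir Output directory (created if absent).
#' @param library Path to a library TSV, or `NULL` when simulating.
#' @param counts Path to a counts TSV, or `NULL` when simulating.
#' @param simulate A list of [simulation_params()] arguments, or `NULL`
#'   when reading counts from disk.
#' @param hit_call A list of [hit_call_params()] arguments.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "screenvote_out", library = NULL,
                            counts = NULL, simulate = NULL,
                            hit_call = list(), seed = 1L) {
  if (is.null(simulate) && (is.null(library) || is.null(counts)))
    stop("config needs either a 'simulate' block or both ",
         "'library' and 'counts' paths")
  structure(list(out_dir = out_dir, library = library, counts = counts,
                 simulate = simulate, hit_call = hit_call,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @param path YAML file path.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @param config A `pipeline_config`.
#' @rdname pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the screen analysis pipeline
#'
#' End-to-end driver: load (or simulate) the library and count tables,
#' compute per-sgRNA enrichment, call and rank candidate genes, score
#' against ground truth when available, and write all primary outputs
#' (`candidates.tsv`, `enrichment.tsv`, and `recovery.tsv` when truth is
#' known) into the configured output directory. Every threshold in force is
#' echoed to the log; outputs are deterministic given the config and seed.
#'
#' @param config A [pipeline_config()] or the path to its YAML file.
#' @param quiet Suppress log messages.
#' @return Invisibly, a list with `candidates`, `report` (or `NULL`) and
#'   `paths` of the written files.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- function(...) if (!quiet) message(...)
  params <- stage("params", do.call(hit_call_params, config$hit_call))
  if (!quiet) {
    log("screenvote pipeline (seed ", config$seed, ")")
    print(params)
  }
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sp <- stage("simulate", do.call(simulation_params, sim_args))
    sim <- stage("simulate", simulate_screen(sp))
    library <- sim$library
    counts <- sim$counts
    truth <- sim$truth
    log("simulated ", sp$n_screens, " screens, ", nrow(library), " guides, ",
        sp$n_resistance, " planted resistance genes")
  } else {
    library <- stage("read library", read_library(config$library))
    counts <- stage("read counts", read_counts(config$counts, library))
    log("loaded ", nrow(library), " guides, ",
        length(unique(counts$screen_id)), " screens")
  }
  fit <- stage("call candidates", call_candidates(counts, library, params))
  log(sum(fit$candidate), " candidate genes from ", nrow(fit),
      " genes with enriched sgRNAs")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    candidates = file.path(config$out_dir, "candidates.tsv"),
    enrichment = file.path(config$out_dir, "enrichment.tsv"))
  stage("write outputs", {
    write_candidates(fit, paths$candidates)
    write_enrichment(attr(fit, "records"), paths$enrichment)
  })
  report <- NULL
  if (!is.null(truth)) {
    report <- stage("evaluate", recovery_metrics(fit, truth))
    paths$recovery <- file.path(config$out_dir, "recovery.tsv")
    stage("write outputs", write_recovery(report, paths$recovery))
    if (!quiet) print(report)
  }
  invisible(list(candidates = fit, report = report, paths = paths))
}
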