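#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> search -> null -> rank -> report as
#' one reproducible run. A single [match_params()] object is shared by the
#' forward and reversed-peptide searches; inputs are validated before any
#' stage runs; every stage's outputs plus a machine-readable manifest land in
#' the run directory. Re-running with an identical configuration reproduces
#' byte-identical reports.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one. Recognized sections:
#'   \describe{
#'     \item{`simulate`}{Arguments for [sim_config()] (with `panels` given as
#'       lists of [panel_spec()] arguments) — used when no input files are
#'       named.}
#'     \item{`panels`, `proteome`}{Input file paths (TSV/FASTA) when not
#'       simulating.}
#'     \item{`match`}{Arguments for [match_params()].}
#'     \item{`null`}{`min_matches_threshold` (default 1 at desk scale) and
#'       optional `exclude_panels` for the reversed search.}
#'     \item{`rank`}{Options passed to [rank_candidates()]
#'       (`exclude_panels`, `alternative`, `weight_by_copies`).}
#'   }
#' @param out_dir Run directory (created if needed).
#' @param seed Overrides `simulate$seed` when given.
#' @return Invisibly, a list with `panels`, `proteome`, `hits`, `null`,
#'   `candidates` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  # fail-fast validation before any stage runs
  simulating <- !is.null(config$simulate)
  if (!simulating) {
    for (key in c("panels", "proteome")) {
      if (is.null(config[[key]]))
        abort(sprintf("Config must name '%s' (or provide a 'simulate' block).", key))
      if (!file.exists(config[[key]]))
        abort(sprintf("Input file for '%s' not found: %s", key, config[[key]]))
    }
  }
  params <- do.call(match_params, config$match %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- character(0)
  if (simulating) {
    sim_args <- config$simulate
    if (!is.null(seed)) sim_args$seed <- seed
    if (!is.null(sim_args$panels))
      sim_args$panels <- lapply(sim_args$panels, function(p) do.call(panel_spec, p))
    sim <- simulate_screen(do.call(sim_config, sim_args), out_dir = out_dir)
    panels <- sim$panels; proteome <- sim$proteome
    inputs <- file.path(out_dir, c("proteome.fasta", "panels.tsv"))
  } else {
    panels <- read_panels(config$panels)
    proteome <- read_proteome(config$proteome)
    inputs <- c(config$panels, config$proteome)
  }

  message(sprintf("search: %d peptides in %d panel(s) vs %d proteins",
                  nrow(panels), dplyr::n_distinct(panels$panel_id),
                  nrow(proteome)))
  hits <- search_panels(panels, proteome, params)
  write_hits(hits, file.path(out_dir, "hits.tsv"))

  null_cfg <- config$null %||% list()
  null_panels <- panels
  if (!is.null(null_cfg$exclude_panels))
    null_panels <- panels[!panels$panel_id %in% null_cfg$exclude_panels, ]
  threshold <- null_cfg$min_matches_threshold %||% 1L
  message(sprintf("null: reversing %d peptides (threshold %d)",
                  dplyr::n_distinct(null_panels$sequence), threshold))
  null <- estimate_null(null_panels, proteome, params,
                        min_matches_threshold = threshold)
  jsonlite::write_json(
    list(f_mean = null$f_mean, f_sd = null$f_sd,
         n_peptides_used = null$n_peptides_used,
         min_matches_threshold = null$min_matches_threshold,
         proteins_used = null$proteins_used,
         match_params = unclass(null$params)),
    file.path(out_dir, "null.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  rank_cfg <- config$rank %||% list()
  candidates <- rank_candidates(
    hits, panels, proteome, null,
    exclude_panels = rank_cfg$exclude_panels,
    alternative = rank_cfg$alternative %||% "greater",
    weight_by_copies = isTRUE(rank_cfg$weight_by_copies))
  write_report(candidates, file.path(out_dir, "candidates.tsv"),
               hits = dedupe_hits(hits))

  outputs <- file.path(out_dir, c("hits.tsv", "null.json", "candidates.tsv",
                                  "candidates.json"))
  manifest <- list(
    tool = "mimoscan",
    version = as.character(utils::packageVersion("mimoscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (simulating) (if (!is.null(seed)) seed else (config$simulate$seed %||% 1L)) else NULL,
    config = config,
    match_params = unclass(params),
    null = list(f_mean = null$f_mean, f_sd = null$f_sd,
                n_peptides_used = null$n_peptides_used,
                min_matches_threshold = null$min_matches_threshold),
    input_digests = as.list(tools::md5sum(inputs)),
    output_digests = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panels = panels, proteome = proteome, hits = hits,
                 null = null, candidates = candidates, manifest = manifest))
}
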