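# End-to-end orchestration: screen -> filter -> build -> project ->
# partition -> score -> select, with a machine-readable run report.

#' Pipeline configuration
#'
#' @param seed integer seed used for module detection (and synthetic
#'   generation when `synth` is given).
#' @param criteria ADMET screening rules (default
#'   [default_screen_criteria()]).
#' @param probability_threshold strict cutoff for compound-target predictions
#'   (default 0.1).
#' @param resolution Louvain resolution (default 1.0).
#' @param weighted use shared-pathway weights in module detection.
#' @param scope centrality scope, `"module_subgraph"` (default) or
#'   `"whole_graph"`.
#' @param weighted_ec weighted eigenvector centrality (default `TRUE`).
#' @param degenerate degenerate min-max range rule, `"zero"` or `"half"`.
#' @param ic_threshold strict integrated-centrality cutoff for key targets
#'   (default 0.8).
#' @param key_modules module ids eligible for key-target selection
#'   (default all).
#' @param synth optional [synth_config()]; when given, inputs are generated
#'   rather than read (its seed is overridden by `seed`).
#' @param delim input table delimiter.
#' @param columns per-table column mappings (see [read_tables()]).
#' @param export_formats graph export formats (subset of
#'   `c("pajek", "graphml", "sif", "edgelist_csv")`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42L,
                            criteria = default_screen_criteria(),
                            probability_threshold = 0.1,
                            resolution = 1.0,
                            weighted = TRUE,
                            scope = c("module_subgraph", "whole_graph"),
                            weighted_ec = TRUE,
                            degenerate = c("zero", "half"),
                            ic_threshold = 0.8,
                            key_modules = NULL,
                            synth = NULL,
                            delim = ",",
                            columns = list(),
                            export_formats = c("pajek", "graphml")) {
  structure(
    list(
      seed = as.integer(seed), criteria = screen_criteria(criteria),
      probability_threshold = probability_threshold,
      resolution = resolution, weighted = weighted,
      scope = match.arg(scope), weighted_ec = weighted_ec,
      degenerate = match.arg(degenerate),
      ic_threshold = ic_threshold, key_modules = key_modules,
      synth = synth, delim = delim, columns = columns,
      export_formats = export_formats
    ),
    class = "pipeline_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    np_abort(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "netpharm_stage_error",
      parent = e
    )
  })
}

#' Run the full network-pharmacology pipeline
#'
#' Reads (or generates) the five input tables, screens compounds on ADMET
#' rules, filters predicted targets by probability, builds the
#' target-pathway-disease network, projects it to the weighted target-target
#' graph, detects functional modules, computes contribution scores and
#' integrated centralities, selects key targets, and writes all artifacts:
#' `targets.csv` (per-target centralities and module), `cs_matrix.csv`
#' (module x disease contribution scores), graph exports
#' (`tpd.<ext>` / `tt.<ext>`), `report.json`, and — for synthetic runs — the
#' generated input tables. The run is deterministic for a fixed seed; on any
#' stage error partial outputs are removed.
#'
#' @param output_dir directory for artifacts (created if needed).
#' @param input_dir directory holding `compounds.csv`, `admet.csv`,
#'   `predictions.csv`, `annotations.csv`, `diseases.csv`; ignored when
#'   `config$synth` is set.
#' @param config a [pipeline_config()].
#' @return the run report (named list, class `netpharm_report`), invisibly.
#' @export
run_pipeline <- function(output_dir, input_dir = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  note <- function(path) {
    written <<- c(written, path)
    path
  }
  on_failure_cleanup <- function(expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(e)
    })
  }

  on_failure_cleanup({
    tables <- with_stage("load", {
      if (!is.null(config$synth)) {
        syn_cfg <- config$synth
        syn_cfg$seed <- config$seed
        synth <- generate_synthetic_data(syn_cfg)
        for (p in write_synthetic_data(synth, output_dir)) note(p)
        synth$tables
      } else {
        if (is.null(input_dir)) {
          np_abort("input_dir is required unless config$synth is set",
            class = "netpharm_usage_error"
          )
        }
        read_tables(
          list(
            compounds = file.path(input_dir, "compounds.csv"),
            admet = file.path(input_dir, "admet.csv"),
            predictions = file.path(input_dir, "predictions.csv"),
            annotations = file.path(input_dir, "annotations.csv"),
            diseases = file.path(input_dir, "diseases.csv")
          ),
          delim = config$delim, columns = config$columns
        )
      }
    })

    screen <- with_stage(
      "screen",
      apply_admet_screen(tables$admet, config$criteria)
    )
    preds_in <- tables$predictions
    preds_screened <- preds_in[preds_in$compound_id %in% screen$passing, ,
      drop = FALSE
    ]
    filt <- with_stage(
      "filter_targets",
      filter_targets(preds_screened, config$probability_threshold)
    )
    tpd <- with_stage(
      "build_tpd",
      build_tpd(filt$targets, tables$annotations, tables$diseases)
    )
    tt <- with_stage("project_tt", project_tt(tpd))
    partition <- with_stage(
      "detect_modules",
      detect_modules(tt,
        resolution = config$resolution, seed = config$seed,
        weighted = config$weighted
      )
    )
    cs <- with_stage("contribution_scores", contribution_scores(partition, tpd))
    records <- with_stage(
      "score_targets",
      score_targets(tt, partition,
        scope = config$scope,
        weighted_ec = config$weighted_ec, degenerate = config$degenerate
      )
    )
    selected <- with_stage(
      "select_key_targets",
      select_key_targets(records, config$key_modules, config$ic_threshold)
    )

    with_stage("write_artifacts", {
      readr::write_csv(records, note(file.path(output_dir, "targets.csv")),
        progress = FALSE
      )
      cs_df <- as_tibble(as.data.frame(unclass(cs)), rownames = "module")
      readr::write_csv(cs_df, note(file.path(output_dir, "cs_matrix.csv")),
        progress = FALSE
      )
      ext <- c(
        pajek = "net", graphml = "graphml", sif = "sif", edgelist_csv = "csv"
      )
      for (fmt in config$export_formats) {
        export_graph(tpd, fmt, note(file.path(
          output_dir, paste0("tpd.", ext[[fmt]])
        )))
        export_graph(tt, fmt, note(file.path(
          output_dir, paste0("tt.", ext[[fmt]])
        )))
        if (fmt == "pajek") {
          note(file.path(output_dir, "tpd.net.map.csv"))
          note(file.path(output_dir, "tt.net.map.csv"))
        }
      }
    })

    type <- igraph::vertex_attr(tpd, "type")
    report <- list(
      tool = "netpharm",
      version = as.character(utils::packageVersion("netpharm")),
      seed = config$seed,
      counts = list(
        compounds_in = nrow(tables$compounds),
        compounds_passing = length(screen$passing),
        predictions_in = nrow(preds_in),
        predictions_retained = nrow(filt$support),
        targets_filtered = length(filt$targets),
        tpd_targets = sum(type == "target"),
        tpd_pathways = sum(type == "pathway"),
        tpd_diseases = sum(type == "disease"),
        tpd_nodes = igraph::vcount(tpd),
        tpd_edges = igraph::ecount(tpd),
        tt_nodes = igraph::vcount(tt),
        tt_edges = igraph::ecount(tt),
        n_modules = length(partition$sizes),
        scored_diseases = ncol(cs)
      ),
      modularity = partition$modularity,
      modules = module_size_table(partition),
      selected_key_targets = selected[c("target_symbol", "module", "ic")],
      config = list(
        probability_threshold = config$probability_threshold,
        resolution = config$resolution,
        weighted = config$weighted,
        scope = config$scope,
        weighted_ec = config$weighted_ec,
        degenerate = config$degenerate,
        ic_threshold = config$ic_threshold,
        key_modules = config$key_modules,
        criteria = as.data.frame(config$criteria),
        synthetic = !is.null(config$synth)
      )
    )
    with_stage("write_report", {
      jsonlite::write_json(
        report, note(file.path(output_dir, "report.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
      )
    })
    class(report) <- "netpharm_report"
    invisible(report)
  })
}

#' @export
print.netpharm_report <- function(x, ...) {
  c_ <- x$counts
  cat(sprintf(
    paste0(
      "netpharm run (seed %d)\n",
      "  compounds: %d in, %d passing screen\n",
      "  predictions: %d in, %d retained (threshold %s)\n",
      "  T-P-D: %d nodes (%d targets, %d pathways, %d diseases), %d edges\n",
      "  T-T: %d targets, %d edges; %d module(s), modularity %.4f\n",
      "  key targets (IC > %s): %s\n"
    ),
    x$seed, c_$compounds_in, c_$compounds_passing,
    c_$predictions_in, c_$predictions_retained,
    format(x$config$probability_threshold),
    c_$tpd_nodes, c_$tpd_targets, c_$tpd_pathways, c_$tpd_diseases,
    c_$tpd_edges, c_$tt_nodes, c_$tt_edges,
    c_$n_modules, x$modularity,
    format(x$config$ic_threshold),
    if (nrow(x$selected_key_targets) == 0) {
      "none"
    } else {
      paste(x$selected_key_targets$target_symbol, collapse = ", ")
    }
  ))
  invisible(x)
}
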