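# Graph exporters: Pajek .net, GraphML, SIF and edge-list CSV.
#
# All writers are deterministic: vertices are sorted lexicographically before
# writing, and edges follow vertex order. Pajek and GraphML exports are
# round-trip safe (node set, edge set and integer weights are preserved
# exactly by `import_graph()`).

sort_vertices <- function(graph) {
  igraph::permute(graph, order(order(igraph::V(graph)$name)))
}

#' Export a network to an interchange format
#'
#' Supported formats:
#' * `pajek` — Pajek .net with 1-based vertex numbering and quoted labels;
#'   an explicit id-to-label map is written alongside as `<path>.map.csv`.
#' * `graphml` — GraphML via igraph; vertex `name`, `type` and edge `weight`
#'   attributes are preserved.
#' * `sif` — Cytoscape simple-interaction format (tab-separated). For a
#'   T-P-D network the relation labels are `participates_in`
#'   (target-pathway) and `implicated_in` (pathway-disease); for a
#'   target-target graph the label is `shares_pathways`.
#' * `edgelist_csv` — CSV with `from`, `to` and any edge attributes.
#'
#' @param graph an igraph from [build_tpd()] or [project_tt()].
#' @param format one of `"pajek"`, `"graphml"`, `"sif"`, `"edgelist_csv"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, format, path) {
  if (igraph::vcount(graph) == 0) {
    np_abort("cannot export an empty graph", "netpharm_usage_error")
  }
  g <- sort_vertices(graph)
  switch(format,
    pajek = export_pajek(g, path),
    graphml = {
      if ("id" %in% igraph::vertex_attr_names(g)) {
        g <- igraph::delete_vertex_attr(g, "id")
      }
      igraph::write_graph(g, path, format = "graphml")
    },
    sif = export_sif(g, path),
    edgelist_csv = {
      el <- igraph::as_data_frame(g, what = "edges")
      readr::write_csv(as_tibble(el), path, progress = FALSE)
    },
    np_abort(
      sprintf("unknown export format '%s' (use pajek, graphml, sif or edgelist_csv)", format),
      class = "netpharm_usage_error"
    )
  )
  invisible(path)
}

export_pajek <- function(g, path) {
  igraph::V(g)$id <- igraph::V(g)$name # Pajek labels
  igraph::write_graph(g, path, format = "pajek")
  readr::write_csv(
    tibble(vertex = seq_len(igraph::vcount(g)), label = igraph::V(g)$name),
    paste0(path, ".map.csv"),
    progress = FALSE
  )
}

sif_relation <- function(g) {
  if (identical(igraph::graph_attr(g, "netpharm"), "tpd")) {
    type <- setNames(igraph::vertex_attr(g, "type"), igraph::V(g)$name)
    function(from, to) {
      ifelse(type[from] == "target" | type[to] == "target",
        "participates_in", "implicated_in"
      )
    }
  } else {
    function(from, to) rep("shares_pathways", length(from))
  }
}

export_sif <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  rel <- sif_relation(g)
  type <- igraph::vertex_attr(g, "type")
  if (!is.null(type)) {
    # orient edges source-layer first (target->pathway, pathway->disease)
    tmap <- setNames(type, igraph::V(g)$name)
    rank <- c(target = 1, pathway = 2, disease = 3)
    flip <- rank[tmap[el$from]] > rank[tmap[el$to]]
    tmp <- el$from[flip]
    el$from[flip] <- el$to[flip]
    el$to[flip] <- tmp
  }
  lines <- paste(el$from, rel(el$from, el$to), el$to, sep = "\t")
  writeLines(lines, path)
}

#' Re-import an exported graph
#'
#' Reads back `pajek` or `graphml` files written by [export_graph()],
#' normalizing vertex names so that round-trips preserve the node set, edge
#' set and weights.
#'
#' @param path file path.
#' @param format `"pajek"` or `"graphml"`.
#' @return an undirected igraph.
#' @export
import_graph <- function(path, format) {
  if (!format %in% c("pajek", "graphml")) {
    np_abort(
      sprintf("import supports pajek and graphml, not '%s'", format),
      class = "netpharm_usage_error"
    )
  }
  g <- igraph::read_graph(path, format = format)
  if (!"name" %in% igraph::vertex_attr_names(g) &&
    "id" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$name <- igraph::V(g)$id
  }
  igraph::as_undirected(g, mode = "each")
}
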