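# Tripartite target-pathway-disease (T-P-D) network construction and its
# one-mode projection to a weighted target-target (T-T) graph.
#
# Both graphs are igraph objects:
#   T-P-D: vertex attribute `type` in {"target", "pathway", "disease"};
#          edges only target-pathway and pathway-disease.
#   T-T:   vertex names are target symbols; edge attributes `weight`
#          (= number of shared pathways) and `shared_pathways`
#          ("|"-separated sorted pathway ids).

#' Build the target-pathway-disease network
#'
#' Keeps only targets with at least one pathway edge, pathways with at least
#' one target edge *and* at least one disease edge, and diseases with at least
#' one pathway edge; annotations for targets outside `targets` are dropped
#' with a warning. The edge count of the result equals the number of retained
#' target-pathway pairs plus retained pathway-disease pairs.
#'
#' @param targets character vector of target symbols that survived the
#'   probability filter (see [filter_targets()]).
#' @param annotations pathway-annotation tibble (`target_symbol`,
#'   `pathway_id`, optionally `pathway_name`).
#' @param diseases disease-mapping tibble (`pathway_id`, `disease_category`).
#' @return an undirected igraph with vertex attributes `type` and (for
#'   pathways) `pathway_name`, and graph attribute `netpharm` = `"tpd"`.
#' @examples
#' ann <- tibble::tibble(
#'   target_symbol = c("A", "B", "B", "C"),
#'   pathway_id = c("p1", "p1", "p2", "p2")
#' )
#' dis <- tibble::tibble(pathway_id = c("p1", "p2"), disease_category = "d1")
#' g <- build_tpd(c("A", "B", "C"), ann, dis)
#' igraph::vcount(g) # 6
#' igraph::ecount(g) # 5
#' @export
build_tpd <- function(targets, annotations, diseases) {
  targets <- unique(trimws(targets))
  ann <- distinct(annotations, .data$target_symbol, .data$pathway_id,
    .keep_all = TRUE
  )
  dropped <- setdiff(unique(ann$target_symbol), targets)
  if (length(dropped) > 0) {
    warn(sprintf(
      "build_tpd: dropping %d annotated target(s) absent from the filtered set: %s",
      length(dropped), paste(head(sort(dropped), 5), collapse = ", ")
    ))
    ann <- ann[ann$target_symbol %in% targets, , drop = FALSE]
  }
  dis <- distinct(diseases, .data$pathway_id, .data$disease_category)

  # a pathway is retained iff it carries both a target and a disease edge
  pathways_ok <- intersect(unique(ann$pathway_id), unique(dis$pathway_id))
  if (length(pathways_ok) == 0) {
    np_abort("no disease-linked pathways: target annotations and disease mappings share no pathway",
      class = "netpharm_network_error"
    )
  }
  tp <- ann[ann$pathway_id %in% pathways_ok, , drop = FALSE]
  pd <- dis[dis$pathway_id %in% pathways_ok, , drop = FALSE]

  t_nodes <- sort(unique(tp$target_symbol))
  p_nodes <- sort(pathways_ok)
  d_nodes <- sort(unique(pd$disease_category))
  clash <- c(
    intersect(t_nodes, p_nodes), intersect(p_nodes, d_nodes),
    intersect(t_nodes, d_nodes)
  )
  if (length(clash) > 0) {
    np_abort(
      sprintf(
        "node labels must be unique across layers; shared label(s): %s",
        paste(unique(clash), collapse = ", ")
      ),
      class = "netpharm_validation_error"
    )
  }

  vertices <- tibble(
    name = c(t_nodes, p_nodes, d_nodes),
    type = rep(c("target", "pathway", "disease"),
      c(length(t_nodes), length(p_nodes), length(d_nodes))
    )
  )
  if ("pathway_name" %in% names(tp)) {
    pn <- tp[!duplicated(tp$pathway_id), c("pathway_id", "pathway_name")]
    vertices$pathway_name <- pn$pathway_name[match(vertices$name, pn$pathway_id)]
  }
  edges <- rbind(
    data.frame(from = tp$target_symbol, to = tp$pathway_id),
    data.frame(from = pd$pathway_id, to = pd$disease_category)
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  g <- igraph::set_graph_attr(g, "netpharm", "tpd")
  g
}

# target -> pathway incidence of a T-P-D network, as a named list
tpd_target_pathways <- function(network) {
  stopifnot(igraph::graph_attr(network, "netpharm") == "tpd")
  el <- igraph::as_data_frame(network, what = "edges")
  type <- setNames(
    igraph::vertex_attr(network, "type"),
    igraph::V(network)$name
  )
  tp <- el[type[el$from] == "target" | type[el$to] == "target", , drop = FALSE]
  tgt <- ifelse(type[tp$from] == "target", tp$from, tp$to)
  pw <- ifelse(type[tp$from] == "target", tp$to, tp$from)
  split(pw, tgt)
}

#' Project the T-P-D network onto a one-mode target-target graph
#'
#' Two targets are connected iff they share at least one pathway; the edge
#' weight is the number of shared pathways and the shared pathway set is kept
#' on the edge (`shared_pathways`, "|"-separated, sorted). Targets that share
#' no pathway with anyone remain as isolated vertices.
#'
#' @param network a T-P-D igraph from [build_tpd()].
#' @return an undirected simple weighted igraph with graph attribute
#'   `netpharm` = `"tt"`.
#' @export
project_tt <- function(network) {
  by_target <- tpd_target_pathways(network)
  t_nodes <- sort(names(by_target))
  if (length(t_nodes) < 2) {
    np_abort("projection needs at least 2 targets", "netpharm_network_error")
  }
  # accumulate shared pathways via per-pathway target lists
  by_pathway <- split(
    rep(names(by_target), lengths(by_target)),
    unlist(by_target, use.names = FALSE)
  )
  pair_rows <- lapply(names(by_pathway), function(p) {
    ts <- sort(by_pathway[[p]])
    if (length(ts) < 2) {
      return(NULL)
    }
    pairs <- t(combn(ts, 2))
    data.frame(from = pairs[, 1], to = pairs[, 2], pathway = p)
  })
  pair_rows <- do.call(rbind, pair_rows)
  if (is.null(pair_rows)) {
    edges <- data.frame(
      from = character(), to = character(),
      weight = integer(), shared_pathways = character()
    )
  } else {
    edges <- pair_rows |>
      group_by(.data$from, .data$to) |>
      summarise(
        weight = dplyr::n(),
        shared_pathways = paste(sort(.data$pathway), collapse = "|"),
        .groups = "drop"
      ) |>
      arrange(.data$from, .data$to)
  }
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = t_nodes)
  )
  g <- igraph::set_graph_attr(g, "netpharm", "tt")
  g
}
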