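# Module-to-disease contribution scores, the four node centralities, the
# integrated centrality (IC) and key-target selection.
#
# IC of target i within its functional module:
#
#   IC_i = 1/4 * [ (DC_i - DC_min)/(DC_max - DC_min)
#                + (BC_i - BC_min)/(BC_max - BC_min)
#                + (CC_i - CC_min)/(CC_max - CC_min)
#                + (EC_i - EC_min)/(EC_max - EC_min) ]
#
# where min/max are taken over the targets of the module. IC lies in [0, 1];
# it reaches 1 exactly when a target attains the module maximum of all four
# centralities (with non-degenerate ranges). A degenerate range
# (max == min) contributes 0 by default, so clique-like modules in which a
# centrality carries no information cannot push targets over the selection
# cutoff.

#' Module-to-disease contribution scores
#'
#' The weight of module m for disease category d is the number of distinct
#' (target in m, pathway) edges whose pathway maps to d; contribution scores
#' normalize each disease column to sum to 1:
#' `cs(m, d) = w(m, d) / sum_m' w(m', d)`.
#'
#' @param partition a `module_partition` covering every target of `network`.
#' @param network the T-P-D igraph the partition was derived from.
#' @return a `modules x diseases` numeric matrix of class
#'   `contribution_matrix` (rows named by module id, columns by disease
#'   category); diseases whose total weight is zero are omitted and listed in
#'   the `"unscored"` attribute.
#' @export
contribution_scores <- function(partition, network) {
  by_target <- tpd_target_pathways(network)
  missing <- setdiff(names(by_target), names(partition$assignment))
  if (length(missing) > 0) {
    np_abort(
      sprintf(
        "partition does not cover %d network target(s): %s",
        length(missing), paste(head(sort(missing), 5), collapse = ", ")
      ),
      class = "netpharm_usage_error"
    )
  }
  el <- igraph::as_data_frame(network, what = "edges")
  type <- setNames(igraph::vertex_attr(network, "type"), igraph::V(network)$name)
  pd <- el[type[el$from] == "disease" | type[el$to] == "disease", , drop = FALSE]
  pw <- ifelse(type[pd$from] == "pathway", pd$from, pd$to)
  ds <- ifelse(type[pd$from] == "pathway", pd$to, pd$from)
  disease_of_pathway <- split(ds, pw)

  modules <- sort(unique(partition$assignment[names(by_target)]))
  diseases <- sort(unique(ds))
  w <- matrix(0,
    nrow = length(modules), ncol = length(diseases),
    dimnames = list(as.character(modules), diseases)
  )
  for (t in names(by_target)) {
    m <- as.character(partition$assignment[[t]])
    for (p in by_target[[t]]) {
      for (d in disease_of_pathway[[p]]) {
        w[m, d] <- w[m, d] + 1
      }
    }
  }
  totals <- colSums(w)
  unscored <- diseases[totals == 0]
  scored <- totals > 0
  cs <- sweep(w[, scored, drop = FALSE], 2, totals[scored], "/")
  structure(cs, class = c("contribution_matrix", class(cs)), unscored = unscored)
}

#' Highest-contributing module for a disease category
#'
#' @param cs a `contribution_matrix` from [contribution_scores()].
#' @param disease disease-category label (must be scored).
#' @return the module id (integer) with the largest contribution score; ties
#'   are broken toward the smaller module id with a warning.
#' @export
top_module_by_disease <- function(cs, disease) {
  if (!disease %in% colnames(cs)) {
    np_abort(sprintf("disease '%s' is not scored", disease), "netpharm_usage_error")
  }
  col <- cs[, disease]
  best <- which(col == max(col))
  if (length(best) > 1) {
    warn(sprintf(
      "top_module_by_disease: tie between modules %s for '%s'; returning the smallest id",
      paste(rownames(cs)[best], collapse = ", "), disease
    ))
  }
  as.integer(rownames(cs)[min(best)])
}

# ---- centralities ---------------------------------------------------------

# Degree, betweenness, closeness and eigenvector centrality of one graph.
# Shortest-path measures (BC, CC) treat edges as unweighted: shared-pathway
# weights express evidence strength, not distance. EC uses the weighted
# adjacency unless weighted_ec = FALSE.
compute_centralities <- function(g, weighted_ec = TRUE) {
  n <- igraph::vcount(g)
  name <- igraph::V(g)$name
  if (n == 1) {
    return(tibble(target_symbol = name, dc = 0, bc = 0, cc = 0, ec = 0))
  }
  dc <- igraph::degree(g) / (n - 1)
  bc_raw <- igraph::betweenness(g, weights = NA, normalized = FALSE)
  bc <- if (n > 2) bc_raw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  cc <- closeness_wf(g)
  ec <- eigen_centrality_power(g, weighted = weighted_ec)
  tibble(target_symbol = name, dc = unname(dc), bc = unname(bc), cc = cc, ec = ec)
}

# Wasserman-Faust closeness with component scaling:
#   cc(i) = (r_i / (n - 1)) * (r_i / sum of distances from i),
# r_i = number of vertices reachable from i (self excluded); isolates get 0.
closeness_wf <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g, weights = NA)
  diag(d) <- Inf
  vapply(seq_len(n), function(i) {
    reach <- is.finite(d[i, ])
    r <- sum(reach)
    if (r == 0) {
      return(0)
    }
    (r / (n - 1)) * (r / sum(d[i, reach]))
  }, numeric(1))
}

# Eigenvector centrality by shifted power iteration. The dominant connected
# component (largest leading eigenvalue; ties broken toward the component
# holding the lexicographically smallest vertex) carries the L2-normalized
# Perron vector; all other vertices score 0.
eigen_centrality_power <- function(g, weighted = TRUE, tol = 1e-8,
                                   max_iter = 100000L) {
  n <- igraph::vcount(g)
  scores <- rep(0, n)
  if (igraph::ecount(g) == 0) {
    return(scores)
  }
  comp <- igraph::components(g)
  A <- igraph::as_adjacency_matrix(
    g,
    attr = if (weighted && "weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
    sparse = TRUE
  )
  best <- NULL
  for (k in seq_len(comp$no)) {
    idx <- which(comp$membership == k)
    if (length(idx) < 2) next # no edges -> eigenvalue 0
    Ak <- A[idx, idx, drop = FALSE]
    shift <- max(Matrix::rowSums(abs(Ak))) + 1 # same eigenvectors, all eigenvalues > 0
    x <- rep(1 / sqrt(length(idx)), length(idx))
    for (it in seq_len(max_iter)) {
      y <- as.numeric(Ak %*% x) + shift * x
      y <- y / sqrt(sum(y^2))
      if (sqrt(sum((y - x)^2)) < tol) {
        x <- y
        break
      }
      x <- y
    }
    lambda <- as.numeric(x %*% (Ak %*% x)) # Rayleigh quotient, shift removed
    cand <- list(lambda = lambda, idx = idx, vec = abs(x))
    if (is.null(best) || lambda > best$lambda + 1e-9 ||
      (abs(lambda - best$lambda) <= 1e-9 &&
        min(igraph::V(g)$name[idx]) < min(igraph::V(g)$name[best$idx]))) {
      best <- cand
    }
  }
  if (!is.null(best)) scores[best$idx] <- best$vec
  scores
}

#' Node centralities per functional module
#'
#' Computes degree (`dc`, degree/(n-1)), betweenness (`bc`, shortest-path
#' betweenness normalized by (n-1)(n-2)/2, unweighted paths), closeness
#' (`cc`, Wasserman-Faust component-scaled) and eigenvector centrality
#' (`ec`, power iteration to 1e-8, L2-normalized, zeros off the dominant
#' component). With `scope = "module_subgraph"` (default) each module's
#' induced subgraph is analyzed separately; `"whole_graph"` computes the four
#' centralities once on the full target-target graph and only the min-max
#' normalization of [integrated_centrality()] is per module.
#'
#' @param graph target-target igraph from [project_tt()].
#' @param partition a `module_partition` on the same targets.
#' @param scope `"module_subgraph"` or `"whole_graph"`.
#' @param weighted_ec use shared-pathway weights in the eigenvector
#'   centrality (default `TRUE`); `dc`, `bc`, `cc` are always unweighted.
#' @return tibble (`target_symbol`, `module`, `dc`, `bc`, `cc`, `ec`).
#' @export
centralities <- function(graph, partition,
                         scope = c("module_subgraph", "whole_graph"),
                         weighted_ec = TRUE) {
  scope <- match.arg(scope)
  if (igraph::vcount(graph) == 0) {
    np_abort("graph is empty", "netpharm_usage_error")
  }
  assignment <- partition$assignment
  missing <- setdiff(igraph::V(graph)$name, names(assignment))
  if (length(missing) > 0) {
    np_abort(
      sprintf("partition does not cover target(s): %s",
        paste(head(missing, 5), collapse = ", ")
      ),
      class = "netpharm_usage_error"
    )
  }
  if (scope == "whole_graph") {
    rec <- compute_centralities(graph, weighted_ec)
    rec$module <- as.integer(assignment[rec$target_symbol])
  } else {
    rec <- bind_rows(lapply(sort(unique(assignment)), function(m) {
      members <- names(assignment)[assignment == m]
      sub <- igraph::induced_subgraph(graph, members)
      out <- compute_centralities(sub, weighted_ec)
      out$module <- m
      out
    }))
  }
  arrange(
    rec[c("target_symbol", "module", "dc", "bc", "cc", "ec")],
    .data$module, .data$target_symbol
  )
}

#' Per-module centrality minima and maxima
#'
#' @param records centrality tibble from [centralities()].
#' @return tibble with one row per module and `<centrality>_min` /
#'   `<centrality>_max` columns.
#' @export
module_stats <- function(records) {
  records |>
    group_by(module = .data$module) |>
    summarise(
      dc_min = min(.data$dc), dc_max = max(.data$dc),
      bc_min = min(.data$bc), bc_max = max(.data$bc),
      cc_min = min(.data$cc), cc_max = max(.data$cc),
      ec_min = min(.data$ec), ec_max = max(.data$ec),
      .groups = "drop"
    )
}

#' Integrated centrality within functional modules
#'
#' Fills the `ic` column: the mean of the four min-max normalized
#' centralities over the target's module. A centrality whose range is
#' degenerate within a module (max == min, as in a clique where every node is
#' equivalent) contributes 0 under `degenerate = "zero"` (default) or 0.5
#' under `degenerate = "half"`.
#'
#' @param records centrality tibble from [centralities()].
#' @param stats optional precomputed [module_stats()]; must cover exactly the
#'   modules present in `records`.
#' @param degenerate value a degenerate-range centrality contributes:
#'   `"zero"` or `"half"`.
#' @return `records` with an `ic` column in \[0, 1\], sorted by module and
#'   target symbol.
#' @export
integrated_centrality <- function(records, stats = NULL,
                                  degenerate = c("zero", "half")) {
  degenerate <- match.arg(degenerate)
  if (is.null(stats)) stats <- module_stats(records)
  if (!setequal(stats$module, unique(records$module))) {
    np_abort("module_stats do not match the modules present in records",
      class = "netpharm_usage_error"
    )
  }
  fill <- if (degenerate == "zero") 0 else 0.5
  df <- left_join(records, stats, by = "module")
  norm_term <- function(x, lo, hi) {
    ifelse(hi > lo, (x - lo) / (hi - lo), fill)
  }
  df$ic <- (norm_term(df$dc, df$dc_min, df$dc_max) +
    norm_term(df$bc, df$bc_min, df$bc_max) +
    norm_term(df$cc, df$cc_min, df$cc_max) +
    norm_term(df$ec, df$ec_min, df$ec_max)) / 4
  arrange(
    df[c("target_symbol", "module", "dc", "bc", "cc", "ec", "ic")],
    .data$module, .data$target_symbol
  )
}

#' Rank and select key targets by integrated centrality
#'
#' @param records centrality tibble with an `ic` column
#'   (see [integrated_centrality()]).
#' @param modules module ids to draw from; default all.
#' @param threshold strict IC cutoff in \[0, 1\]; default 0.8, i.e. a target
#'   is selected iff `ic > 0.8`.
#' @return tibble of selected rows sorted by decreasing `ic`, ties broken
#'   alphabetically by target symbol; may be empty.
#' @export
select_key_targets <- function(records, modules = NULL, threshold = 0.8) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    np_abort("threshold must lie in [0, 1]", "netpharm_usage_error")
  }
  if (!"ic" %in% names(records)) {
    np_abort("records lack an 'ic' column; run integrated_centrality() first",
      class = "netpharm_usage_error"
    )
  }
  keep <- records
  if (!is.null(modules)) keep <- keep[keep$module %in% modules, , drop = FALSE]
  keep <- keep[keep$ic > threshold, , drop = FALSE]
  arrange(keep, desc(.data$ic), .data$target_symbol)
}

#' One-call target scoring
#'
#' Convenience wrapper: [centralities()] then [integrated_centrality()].
#'
#' @inheritParams centralities
#' @inheritParams integrated_centrality
#' @return centrality tibble with `ic` filled.
#' @export
score_targets <- function(graph, partition,
                          scope = c("module_subgraph", "whole_graph"),
                          weighted_ec = TRUE,
                          degenerate = c("zero", "half")) {
  integrated_centrality(
    centralities(graph, partition, scope, weighted_ec),
    degenerate = degenerate
  )
}
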