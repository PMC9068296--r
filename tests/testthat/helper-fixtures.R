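# Fixture builders shared across test files. Everything is generated in code.

# an ADMET profile sitting exactly on the passing side of every default rule
boundary_profile <- function(compound_id = "c1", ...) {
  base <- tibble::tibble(
    compound_id = compound_id,
    qed = 0.67, lipinski_violations = 1, caco2 = -5.0, hia = 0.3,
    ppb = 90, fu = 5, cl = 5, h_ht = 0.3, herg = 0.3, f20 = 0.3,
    f30 = 0.3, ames = 0.3, fsp3 = 0.42, mce18 = 46,
    pains_alerts = 0, golden_triangle_violations = 0
  )
  overrides <- list(...)
  for (f in names(overrides)) base[[f]] <- overrides[[f]]
  base
}

# minimal T-P-D input: 3 targets, pathways p1:(A,B) p2:(B,C), one disease on both
toy_tpd_tables <- function() {
  list(
    targets = c("A", "B", "C"),
    annotations = tibble::tibble(
      target_symbol = c("A", "B", "B", "C"),
      pathway_id = c("p1", "p1", "p2", "p2"),
      pathway_name = c("P one", "P one", "P two", "P two")
    ),
    diseases = tibble::tibble(
      pathway_id = c("p1", "p2"),
      disease_category = c("d1", "d1")
    )
  )
}

toy_tpd <- function() {
  tabs <- toy_tpd_tables()
  build_tpd(tabs$targets, tabs$annotations, tabs$diseases)
}

# unweighted target-target igraph from a 0/1 adjacency matrix
tt_from_adj <- function(adj, names = NULL) {
  n <- nrow(adj)
  names <- names %||% sprintf("T%02d", seq_len(n))
  dimnames(adj) <- list(names, names)
  g <- igraph::graph_from_adjacency_matrix(adj, "undirected")
  igraph::set_graph_attr(g, "netpharm", "tt")
}

# a module_partition placing every vertex of g in one module
single_module_partition <- function(g) {
  nm <- igraph::V(g)$name
  structure(
    list(
      assignment = stats::setNames(rep(1L, length(nm)), nm),
      sizes = length(nm), modularity = 0, resolution = 1, seed = 0L,
      weighted = TRUE
    ),
    class = "module_partition"
  )
}

manual_partition <- function(assignment) {
  structure(
    list(
      assignment = assignment, sizes = as.integer(table(assignment)),
      modularity = NA_real_, resolution = 1, seed = 0L, weighted = TRUE
    ),
    class = "module_partition"
  )
}

# planted-block fixture at the standard recovery conditions; 25 pathways per
# block keep the hub's annotation profile unique with overwhelming probability
planted_fixture <- function(seed, n_blocks = 4L, targets_per_block = 20L,
                            pathways_per_block = 25L, p_in = 0.6,
                            p_out = 0.02, hub_boost = 3) {
  synth_config(
    seed = seed,
    n_targets = n_blocks * targets_per_block,
    n_pathways = n_blocks * pathways_per_block,
    n_blocks = n_blocks, n_diseases = 2L * n_blocks,
    p_in = p_in, p_out = p_out, hub_boost = hub_boost
  )
}

# generate + build + project + partition + score one small synthetic fixture;
# memoised so several test files can share the same 100 runs
small_fixture_cache <- new.env(parent = emptyenv())
run_small_fixture <- function(seed) {
  key <- as.character(seed)
  if (!is.null(small_fixture_cache[[key]])) {
    return(small_fixture_cache[[key]])
  }
  cfg <- synth_config(
    seed = seed, n_compounds = 20L, n_targets = 30L, n_pathways = 15L,
    n_diseases = 5L, n_blocks = 3L
  )
  syn <- generate_synthetic_data(cfg)
  tpd <- suppressWarnings(build_tpd(
    names(syn$truth$block_of_target), syn$tables$annotations,
    syn$tables$diseases
  ))
  tt <- project_tt(tpd)
  part <- detect_modules(tt, seed = seed)
  out <- list(
    syn = syn, tpd = tpd, tt = tt, partition = part,
    cs = contribution_scores(part, tpd),
    records = score_targets(tt, part)
  )
  small_fixture_cache[[key]] <- out
  out
}

write_toy_tables <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::tibble(
    compound_id = c("c1", "c2", "c3"),
    name = paste("cmp", 1:3),
    chem_class = c("alkaloid", "lipid", "alkaloid"),
    StR = c(10, 0, 3), StS = c(0, 2, 5), StF = c(1, 1, 0)
  ), file.path(dir, "compounds.csv"), progress = FALSE)
  readr::write_csv(
    dplyr::bind_rows(
      boundary_profile("c1"),
      boundary_profile("c2", qed = 0.5),
      boundary_profile("c3")
    ),
    file.path(dir, "admet.csv"),
    progress = FALSE
  )
  readr::write_csv(tibble::tibble(
    compound_id = c("c1", "c1", "c3"),
    target_symbol = c("A", "B", "C"),
    probability = c(0.5, 0.2, 0.9)
  ), file.path(dir, "predictions.csv"), progress = FALSE)
  tabs <- toy_tpd_tables()
  readr::write_csv(tabs$annotations, file.path(dir, "annotations.csv"),
    progress = FALSE
  )
  readr::write_csv(tabs$diseases, file.path(dir, "diseases.csv"),
    progress = FALSE
  )
  dir
}

`%||%` <- function(x, y) if (is.null(x)) y else x
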