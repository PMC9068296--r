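test_that("contribution scores normalize, concentrate and match the triple-loop oracle", {
  # two modules structurally identical w.r.t. one disease: cs = 1/2 each
  ann <- tibble::tibble(
    target_symbol = c("A", "B"), pathway_id = c("p1", "p2")
  )
  dis <- tibble::tibble(pathway_id = c("p1", "p2"), disease_category = "d1")
  tpd <- build_tpd(c("A", "B"), ann, dis)
  part <- manual_partition(c(A = 1L, B = 2L))
  cs <- contribution_scores(part, tpd)
  expect_equal(unname(cs[, "d1"]), c(0.5, 0.5))

  # disease linked only to module-2 pathways: full concentration
  ann2 <- tibble::tibble(
    target_symbol = c("A", "B", "B"), pathway_id = c("p1", "p2", "p3")
  )
  dis2 <- tibble::tibble(
    pathway_id = c("p1", "p2", "p3"),
    disease_category = c("d1", "d2", "d2")
  )
  cs2 <- contribution_scores(
    manual_partition(c(A = 1L, B = 2L)),
    build_tpd(c("A", "B"), ann2, dis2)
  )
  expect_equal(unname(cs2[, "d2"]), c(0, 1))
  expect_equal(unname(cs2[, "d1"]), c(1, 0))

  # random fixtures vs brute-force tally over all (t, p, d) triples
  for (s in 1:8) {
    fx <- run_small_fixture(340 + s)
    want <- oracle_contributions(
      fx$partition$assignment,
      fx$syn$tables$annotations, fx$syn$tables$diseases
    )
    expect_equal(dim(fx$cs), dim(want))
    expect_equal(unclass(fx$cs)[rownames(want), colnames(want)],
      want,
      tolerance = 1e-12, ignore_attr = TRUE
    )
    expect_true(all(abs(colSums(fx$cs) - 1) < 1e-9))
    expect_true(all(fx$cs >= 0 & fx$cs <= 1))
  }

  # partition must cover the network's targets
  expect_error(
    contribution_scores(manual_partition(c(A = 1L)), tpd),
    class = "netpharm_usage_error"
  )
})

test_that("top module selection takes the argmax with a deterministic tie rule", {
  cs <- matrix(c(0.7, 0.2, 0.1), 3, 1, dimnames = list(1:3, "d1"))
  class(cs) <- c("contribution_matrix", class(cs))
  expect_equal(top_module_by_disease(cs, "d1"), 1L)

  tied <- matrix(c(0.5, 0.5), 2, 1, dimnames = list(1:2, "d1"))
  class(tied) <- c("contribution_matrix", class(tied))
  expect_warning(m <- top_module_by_disease(tied, "d1"), "tie")
  expect_equal(m, 1L)

  expect_error(top_module_by_disease(cs, "nope"), class = "netpharm_usage_error")

  for (s in 1:5) {
    fx <- run_small_fixture(350 + s)
    for (d in colnames(fx$cs)) {
      got <- suppressWarnings(top_module_by_disease(fx$cs, d))
      col <- fx$cs[, d]
      expect_equal(got, as.integer(names(col)[min(which(col == max(col)))]))
    }
  }
})

test_that("hand-computed centralities on the 3-node path and the 4-star", {
  path3 <- tt_from_adj(
    matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3),
    names = c("A", "B", "C")
  )
  rec <- centralities(path3, single_module_partition(path3))
  rec <- rec[match(c("A", "B", "C"), rec$target_symbol), ]
  expect_equal(rec$dc, c(0.5, 1, 0.5))
  expect_equal(rec$bc, c(0, 1, 0))
  # B is the unique maximum of all four centralities
  for (col in c("dc", "bc", "cc", "ec")) {
    expect_equal(which.max(rec[[col]]), 2L, label = col)
    expect_true(rec[[col]][2] > max(rec[[col]][c(1, 3)]), label = col)
  }

  # star K1,4: center lies on all 6 leaf pairs' shortest paths -> BC = 1
  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1L
  star_g <- tt_from_adj(star, names = c("hub", "l1", "l2", "l3", "l4"))
  recs <- centralities(star_g, single_module_partition(star_g))
  expect_equal(recs$bc[recs$target_symbol == "hub"], 1)
  expect_equal(recs$dc[recs$target_symbol == "hub"], 1)

  # single-node module: all four centralities are 0
  one <- tt_from_adj(matrix(0L, 1, 1), names = "X")
  rec1 <- centralities(one, single_module_partition(one))
  expect_equal(unlist(rec1[c("dc", "bc", "cc", "ec")]),
    c(dc = 0, bc = 0, cc = 0, ec = 0))
})

test_that("centralities match the exhaustive oracle on assorted small graphs", {
  withr::local_seed(21)
  graphs <- c(
    all_connected_graphs(4),
    lapply(1:10, function(i) random_connected_adj(7, 0.4))
  )
  # include a disconnected case: triangle + path, only the dominant
  # component carries eigenvector mass
  dis <- matrix(0L, 6, 6)
  dis[1, 2] <- dis[2, 1] <- dis[2, 3] <- dis[3, 2] <- dis[1, 3] <- dis[3, 1] <- 1L
  dis[4, 5] <- dis[5, 4] <- dis[5, 6] <- dis[6, 5] <- 1L
  graphs <- c(graphs, list(dis))
  for (adj in graphs) {
    got <- package_centralities(adj)
    want <- oracle_centralities(adj)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("integrated centrality is the mean of min-max normalized centralities", {
  path3 <- tt_from_adj(
    matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3),
    names = c("A", "B", "C")
  )
  rec <- score_targets(path3, single_module_partition(path3))
  expect_equal(
    stats::setNames(rec$ic, rec$target_symbol),
    c(A = 0, B = 1, C = 0)
  )

  # manual records: target at module max of all four -> 1; at min -> 0
  recs <- tibble::tibble(
    target_symbol = c("t1", "t2", "t3"), module = 1L,
    dc = c(1, 0.2, 0.5), bc = c(0.8, 0.1, 0.3),
    cc = c(0.9, 0.4, 0.6), ec = c(0.7, 0.2, 0.5)
  )
  ic <- integrated_centrality(recs)
  expect_equal(ic$ic[ic$target_symbol == "t1"], 1)
  expect_equal(ic$ic[ic$target_symbol == "t2"], 0)
  expect_true(ic$ic[ic$target_symbol == "t3"] > 0 &&
    ic$ic[ic$target_symbol == "t3"] < 1)

  # explicit stats must cover the same modules
  expect_error(
    integrated_centrality(recs, stats = module_stats(dplyr::mutate(recs, module = 2L))),
    class = "netpharm_usage_error"
  )
})

test_that("cliques are fully degenerate: every IC is 0 (or 0.5 under the half rule)", {
  k4 <- tt_from_adj(matrix(1L, 4, 4) - diag(1L, 4))
  rec <- score_targets(k4, single_module_partition(k4))
  expect_equal(rec$ic, rep(0, 4))
  rec_half <- score_targets(k4, single_module_partition(k4), degenerate = "half")
  expect_equal(rec_half$ic, rep(0.5, 4))
})

test_that("IC is scale invariant and independent of record order", {
  withr::local_seed(22)
  recs <- tibble::tibble(
    target_symbol = sprintf("t%02d", 1:12),
    module = rep(1:2, each = 6),
    dc = runif(12), bc = runif(12), cc = runif(12), ec = runif(12)
  )
  base <- integrated_centrality(recs)
  # multiply all four centralities within a module by c > 0
  scaled <- recs
  for (col in c("dc", "bc", "cc", "ec")) {
    scaled[[col]] <- scaled[[col]] * ifelse(scaled$module == 1, 7.3, 0.02)
  }
  expect_equal(integrated_centrality(scaled)$ic, base$ic, tolerance = 1e-12)
  # permuted row order yields identical values
  perm <- integrated_centrality(recs[sample(12), ])
  expect_equal(perm, base)
})

test_that("key-target selection is strict, sorted, and module-scoped", {
  recs <- tibble::tibble(
    target_symbol = c("ZZZ", "AAA", "MMM", "BBB"),
    module = c(1L, 1L, 2L, 2L),
    dc = 0, bc = 0, cc = 0, ec = 0,
    ic = c(0.95, 0.8, 0.79, 0.95)
  )
  sel <- select_key_targets(recs, threshold = 0.8)
  expect_equal(sel$target_symbol, c("BBB", "ZZZ")) # 0.8 excluded; ties alphabetical
  expect_equal(select_key_targets(recs, modules = 1L, threshold = 0.8)$target_symbol, "ZZZ")
  expect_equal(nrow(select_key_targets(recs, threshold = 0)), 4)
  expect_error(select_key_targets(recs, threshold = 2), class = "netpharm_usage_error")
  expect_error(select_key_targets(recs[, -7]), class = "netpharm_usage_error")
})

test_that("planted per-module hubs are selected as key targets", {
  # three modules, each a star with a few extra leaf-leaf edges; the star
  # center maximizes all four centralities in its module by construction
  adj <- matrix(0L, 15, 15)
  for (b in 0:2) {
    hub <- b * 5 + 1
    leaves <- (b * 5 + 2):(b * 5 + 5)
    adj[hub, leaves] <- adj[leaves, hub] <- 1L
    adj[leaves[1], leaves[2]] <- adj[leaves[2], leaves[1]] <- 1L
  }
  # weak inter-module bridges so the graph is connected
  adj[5, 6] <- adj[6, 5] <- 1L
  adj[10, 11] <- adj[11, 10] <- 1L
  g <- tt_from_adj(adj, names = sprintf("N%02d", 1:15))
  part <- manual_partition(stats::setNames(rep(1:3, each = 5L), sprintf("N%02d", 1:15)))
  rec <- score_targets(g, part)
  sel <- select_key_targets(rec, threshold = 0.8)
  expect_setequal(sel$target_symbol, c("N01", "N06", "N11"))
})
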