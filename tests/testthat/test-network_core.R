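test_that("build_tpd keeps exactly the disease-linked structure", {
  g <- toy_tpd()
  expect_equal(igraph::vcount(g), 6) # A B C p1 p2 d1
  # annotations (A,p1) (B,p1) (B,p2) (C,p2) and diseases (p1,d1) (p2,d1)
  expect_equal(igraph::ecount(g), 6) # 4 t-p + 2 p-d
  type <- igraph::vertex_attr(g, "type")
  expect_equal(sum(type == "target"), 3)
  expect_equal(sum(type == "pathway"), 2)
  expect_equal(sum(type == "disease"), 1)
})

test_that("edge count equals retained t-p pairs plus retained p-d pairs", {
  tabs <- toy_tpd_tables()
  g <- build_tpd(tabs$targets, tabs$annotations, tabs$diseases)
  expect_equal(igraph::ecount(g), nrow(tabs$annotations) + nrow(tabs$diseases))
  # and on random fixtures, after recounting retained pairs independently
  for (s in 1:5) {
    fx <- run_small_fixture(310 + s)
    ann <- unique(fx$syn$tables$annotations[c("target_symbol", "pathway_id")])
    dis <- unique(fx$syn$tables$diseases[c("pathway_id", "disease_category")])
    ok_pw <- intersect(unique(ann$pathway_id), unique(dis$pathway_id))
    expect_equal(
      igraph::ecount(fx$tpd),
      sum(ann$pathway_id %in% ok_pw) + sum(dis$pathway_id %in% ok_pw)
    )
    type <- igraph::vertex_attr(fx$tpd, "type")
    expect_equal(sum(type == "target"), length(unique(
      ann$target_symbol[ann$pathway_id %in% ok_pw]
    )))
  }
})

test_that("pathways without diseases are excluded along with dangling targets", {
  ann <- tibble::tibble(
    target_symbol = c("A", "B", "D"),
    pathway_id = c("p1", "p1", "p3") # p3 has no disease mapping
  )
  dis <- tibble::tibble(pathway_id = "p1", disease_category = "d1")
  g <- build_tpd(c("A", "B", "D"), ann, dis)
  expect_false("p3" %in% igraph::V(g)$name)
  expect_false("D" %in% igraph::V(g)$name) # lost its only edge
  expect_equal(igraph::vcount(g), 4)

  # single chain: one target, one pathway, one disease
  chain <- build_tpd(
    "A",
    tibble::tibble(target_symbol = "A", pathway_id = "p1"),
    tibble::tibble(pathway_id = "p1", disease_category = "d1")
  )
  expect_equal(igraph::vcount(chain), 3)
  expect_equal(igraph::ecount(chain), 2)

  # no overlap between annotated and disease-linked pathways
  expect_error(
    build_tpd(
      "A",
      tibble::tibble(target_symbol = "A", pathway_id = "p1"),
      tibble::tibble(pathway_id = "p9", disease_category = "d1")
    ),
    class = "netpharm_network_error"
  )

  # annotations outside the filtered target set are dropped with a warning
  expect_warning(
    build_tpd(
      c("A", "B"),
      tibble::tibble(target_symbol = c("A", "B", "Z"), pathway_id = "p1"),
      dis
    ),
    "Z"
  )
})

test_that("one-mode projection matches the pairwise set-intersection oracle", {
  # two targets sharing two pathways: one edge of weight 2
  ann <- tibble::tibble(
    target_symbol = c("A", "A", "B", "B"),
    pathway_id = c("p1", "p2", "p1", "p2")
  )
  dis <- tibble::tibble(pathway_id = c("p1", "p2"), disease_category = "d1")
  tt <- project_tt(build_tpd(c("A", "B"), ann, dis))
  expect_equal(igraph::ecount(tt), 1)
  expect_equal(igraph::E(tt)$weight, 2)
  expect_equal(igraph::E(tt)$shared_pathways, "p1|p2")

  # disjoint pathway sets: no edge, targets stay as isolates
  ann2 <- tibble::tibble(
    target_symbol = c("A", "B"), pathway_id = c("p1", "p2")
  )
  tt2 <- project_tt(build_tpd(c("A", "B"), ann2, dis))
  expect_equal(igraph::ecount(tt2), 0)
  expect_equal(igraph::vcount(tt2), 2)

  # random memberships vs brute-force all-pairs intersection
  for (s in 1:10) {
    withr::with_seed(700 + s, {
      ann3 <- tibble::tibble(
        target_symbol = sample(paste0("T", 1:5), 12, replace = TRUE),
        pathway_id = sample(paste0("p", 1:3), 12, replace = TRUE)
      ) |> dplyr::distinct()
    })
    dis3 <- tibble::tibble(
      pathway_id = paste0("p", 1:3), disease_category = "d1"
    )
    tt3 <- project_tt(suppressWarnings(
      build_tpd(unique(ann3$target_symbol), ann3, dis3)
    ))
    got <- igraph::as_data_frame(tt3, what = "edges")
    got <- got[order(got$from, got$to), ]
    want <- oracle_projection(ann3)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$from, want$from)
      expect_equal(got$to, want$to)
      expect_equal(got$weight, want$weight)
      expect_equal(got$shared_pathways, want$shared_pathways)
    }
  }
})

test_that("projection weight never exceeds either pathway degree", {
  for (s in 1:5) {
    fx <- run_small_fixture(320 + s)
    deg <- table(igraph::as_data_frame(fx$tpd, what = "edges") |>
      (\(el) {
        type <- stats::setNames(
          igraph::vertex_attr(fx$tpd, "type"), igraph::V(fx$tpd)$name
        )
        tp <- el[type[el$from] == "target" | type[el$to] == "target", ]
        ifelse(type[tp$from] == "target", tp$from, tp$to)
      })())
    el <- igraph::as_data_frame(fx$tt, what = "edges")
    expect_true(all(el$weight <= pmin(deg[el$from], deg[el$to])))
  }
})

test_that("Louvain recovers obvious community structure", {
  # two 5-cliques joined by a single bridge edge
  adj <- matrix(0L, 10, 10)
  adj[1:5, 1:5] <- 1L
  adj[6:10, 6:10] <- 1L
  diag(adj) <- 0L
  adj[5, 6] <- adj[6, 5] <- 1L
  g <- tt_from_adj(adj)
  part <- detect_modules(g, seed = 1)
  expect_equal(length(part$sizes), 2)
  a <- part$assignment[igraph::V(g)$name]
  expect_equal(length(unique(a[1:5])), 1)
  expect_equal(length(unique(a[6:10])), 1)
  expect_false(a[[1]] == a[[10]])

  # the clique split maximizes modularity: exhaustive check on a smaller
  # two-triangle graph (all 203 partitions of 6 nodes)
  adj6 <- matrix(0L, 6, 6)
  adj6[1:3, 1:3] <- 1L
  adj6[4:6, 4:6] <- 1L
  diag(adj6) <- 0L
  adj6[3, 4] <- adj6[4, 3] <- 1L
  g6 <- tt_from_adj(adj6)
  all_partitions <- function(n) {
    if (n == 1) {
      return(list(1L))
    }
    out <- list()
    for (p in all_partitions(n - 1)) {
      for (b in seq_len(max(p) + 1)) out[[length(out) + 1]] <- c(p, b)
    }
    out
  }
  qs <- vapply(
    all_partitions(6),
    function(p) igraph::modularity(g6, p), numeric(1)
  )
  best <- all_partitions(6)[[which.max(qs)]]
  part6 <- detect_modules(g6, seed = 1)
  expect_equal(
    mclust::adjustedRandIndex(part6$assignment[igraph::V(g6)$name], best), 1
  )
  expect_equal(part6$modularity, max(qs), tolerance = 1e-12)
})

test_that("partition bookkeeping: totality, renumbering, isolates, determinism", {
  fx <- run_small_fixture(331)
  part <- fx$partition
  expect_setequal(names(part$assignment), igraph::V(fx$tt)$name)
  expect_equal(sum(part$sizes), igraph::vcount(fx$tt))
  # ids 1..k by decreasing size
  expect_equal(sort(unique(part$assignment)), seq_along(part$sizes))
  expect_equal(part$sizes, sort(part$sizes, decreasing = TRUE))
  # better than the all-singletons partition
  singles <- seq_len(igraph::vcount(fx$tt))
  expect_gte(part$modularity, igraph::modularity(
    fx$tt, singles,
    weights = igraph::E(fx$tt)$weight
  ))
  # determinism under a fixed seed
  again <- detect_modules(fx$tt, seed = 331)
  expect_identical(part$assignment, again$assignment)

  # complete graph: a single module
  k5 <- tt_from_adj(matrix(1L, 5, 5) - diag(1L, 5))
  expect_equal(length(detect_modules(k5, seed = 1)$sizes), 1)

  # isolates become singleton modules
  adj <- matrix(0L, 4, 4)
  adj[1, 2] <- adj[2, 1] <- 1L
  gi <- tt_from_adj(adj)
  pi_ <- detect_modules(gi, seed = 1)
  expect_equal(length(pi_$sizes), 3)
  expect_equal(sum(pi_$sizes == 1), 2)

  expect_error(
    detect_modules(igraph::make_empty_graph(0, directed = FALSE)),
    class = "netpharm_usage_error"
  )
  expect_error(detect_modules(fx$tt, resolution = 0), class = "netpharm_usage_error")
})

test_that("module numbering is stable under relabeling of target symbols", {
  adj <- matrix(0L, 10, 10)
  adj[1:6, 1:6] <- 1L # size-6 clique -> module 1
  adj[7:10, 7:10] <- 1L # size-4 clique -> module 2
  diag(adj) <- 0L
  adj[6, 7] <- adj[7, 6] <- 1L
  g1 <- tt_from_adj(adj, names = sprintf("A%02d", 1:10))
  g2 <- tt_from_adj(adj, names = sprintf("Z%02d", 10:1)) # reversed name order
  p1 <- detect_modules(g1, seed = 5)
  p2 <- detect_modules(g2, seed = 5)
  expect_equal(unname(p1$assignment[sprintf("A%02d", 1:10)]),
    unname(p2$assignment[sprintf("Z%02d", 10:1)]))
  expect_equal(p1$sizes, c(6, 4))
})
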