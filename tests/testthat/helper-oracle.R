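# Independent brute-force oracles. These never call the package's centrality
# code: shortest paths are enumerated exhaustively over simple paths, and the
# eigenvector oracle uses base R's eigen() decomposition.

# all shortest s-t paths by depth-first enumeration of simple paths
oracle_shortest_paths <- function(adj, s, t) {
  best <- Inf
  found <- list()
  rec <- function(path, v) {
    if (v == t) {
      len <- length(path) - 1
      if (len < best) {
        best <<- len
        found <<- list(path)
      } else if (len == best) {
        found[[length(found) + 1]] <<- path
      }
      return()
    }
    if (length(path) - 1 >= best) {
      return()
    }
    for (w in which(adj[v, ] > 0)) {
      if (!(w %in% path)) rec(c(path, w), w)
    }
  }
  rec(s, s)
  list(dist = best, paths = found)
}

# degree, betweenness, closeness (Wasserman-Faust), eigenvector centrality
# of an unweighted simple graph given as a 0/1 adjacency matrix
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  if (n == 1) {
    return(data.frame(dc = 0, bc = 0, cc = 0, ec = 0))
  }
  dc <- rowSums(adj > 0) / (n - 1)
  bc_raw <- numeric(n)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      sp <- oracle_shortest_paths(adj, s, t)
      dist[s, t] <- dist[t, s] <- sp$dist
      if (is.finite(sp$dist)) {
        interior <- unlist(lapply(sp$paths, function(p) p[-c(1, length(p))]))
        if (length(interior) > 0) {
          tab <- table(interior)
          idx <- as.integer(names(tab))
          bc_raw[idx] <- bc_raw[idx] + as.numeric(tab) / length(sp$paths)
        }
      }
    }
  }
  bc <- if (n > 2) bc_raw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  cc <- vapply(seq_len(n), function(i) {
    d <- dist[i, -i]
    r <- sum(is.finite(d))
    if (r == 0) 0 else (r / (n - 1)) * (r / sum(d[is.finite(d)]))
  }, numeric(1))
  # eigenvector centrality: eigen() per component, dominant component only
  membership <- integer(n)
  k <- 0
  for (i in seq_len(n)) {
    if (membership[i] == 0) {
      k <- k + 1
      membership[is.finite(dist[i, ])] <- k
    }
  }
  ec <- numeric(n)
  best_lambda <- -Inf
  best <- NULL
  for (c_ in seq_len(k)) {
    idx <- which(membership == c_)
    if (length(idx) < 2) next
    e <- eigen(adj[idx, idx, drop = FALSE], symmetric = TRUE)
    lambda <- e$values[1]
    if (lambda > best_lambda + 1e-9) {
      best_lambda <- lambda
      best <- list(idx = idx, vec = abs(e$vectors[, 1]))
    }
  }
  if (!is.null(best)) {
    ec[best$idx] <- best$vec / sqrt(sum(best$vec^2))
  }
  data.frame(dc = dc, bc = bc, cc = cc, ec = ec)
}

# run the package's centrality code on a bare adjacency matrix
package_centralities <- function(adj) {
  g <- tt_from_adj(adj)
  rec <- centralities(g, single_module_partition(g))
  rec <- rec[match(igraph::V(g)$name, rec$target_symbol), ]
  data.frame(dc = rec$dc, bc = rec$bc, cc = rec$cc, ec = rec$ec)
}

adj_from_mask <- function(mask, n, pairs) {
  np <- nrow(pairs)
  bits <- bitwAnd(bitwShiftR(mask, 0:(np - 1)), 1L) == 1L
  adj <- matrix(0L, n, n)
  sel <- pairs[bits, , drop = FALSE]
  adj[sel] <- 1L
  adj[sel[, 2:1, drop = FALSE]] <- 1L
  adj
}

is_connected_adj <- function(adj) {
  n <- nrow(adj)
  r <- diag(n) + adj
  for (k in seq_len(ceiling(log2(max(n, 2))))) r <- (r %*% r > 0) + 0
  all(r[1, ] > 0)
}

# all connected labeled graphs on n vertices (adjacency matrices)
all_connected_graphs <- function(n) {
  if (n == 1) {
    return(list(matrix(0L, 1, 1)))
  }
  pairs <- t(combn(n, 2))
  out <- list()
  for (mask in 0:(2^nrow(pairs) - 1)) {
    adj <- adj_from_mask(mask, n, pairs)
    if (is_connected_adj(adj)) out[[length(out) + 1]] <- adj
  }
  out
}

# one representative per isomorphism class of connected n-vertex graphs
connected_graph_classes <- function(n) {
  pairs <- t(combn(n, 2))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (mask in 0:(2^nrow(pairs) - 1)) {
    adj <- adj_from_mask(mask, n, pairs)
    if (!is_connected_adj(adj)) next
    g <- igraph::graph_from_adjacency_matrix(adj, "undirected")
    cp <- igraph::canonical_permutation(g)$labeling
    el <- igraph::as_edgelist(igraph::permute(g, cp))
    el <- t(apply(el, 1, sort))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    key <- paste(t(el), collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1]] <- adj
    }
  }
  out
}

random_connected_adj <- function(n, p) {
  repeat {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        adj[i, j] <- adj[j, i] <- as.integer(runif(1) < p)
      }
    }
    if (is_connected_adj(adj)) {
      return(adj)
    }
  }
}

# brute-force one-mode projection: all-pairs pathway-set intersections
oracle_projection <- function(annotations) {
  by_target <- split(annotations$pathway_id, annotations$target_symbol)
  ts <- sort(names(by_target))
  rows <- list()
  if (length(ts) >= 2) {
    for (i in seq_len(length(ts) - 1)) {
      for (j in seq(i + 1, length(ts))) {
        shared <- intersect(by_target[[ts[i]]], by_target[[ts[j]]])
        if (length(shared) > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            from = ts[i], to = ts[j], weight = length(shared),
            shared_pathways = paste(sort(shared), collapse = "|")
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      from = character(), to = character(),
      weight = integer(), shared_pathways = character()
    ))
  }
  do.call(rbind, rows)
}

# brute-force contribution tally over all (target, pathway, disease) triples
oracle_contributions <- function(assignment, annotations, diseases) {
  ann <- unique(annotations[c("target_symbol", "pathway_id")])
  dis <- unique(diseases[c("pathway_id", "disease_category")])
  mods <- sort(unique(assignment))
  ds <- sort(unique(dis$disease_category))
  w <- matrix(0,
    nrow = length(mods), ncol = length(ds),
    dimnames = list(as.character(mods), ds)
  )
  for (r in seq_len(nrow(ann))) {
    t <- ann$target_symbol[r]
    p <- ann$pathway_id[r]
    if (!t %in% names(assignment)) next
    for (d in dis$disease_category[dis$pathway_id == p]) {
      w[as.character(assignment[[t]]), d] <- w[as.character(assignment[[t]]), d] + 1
    }
  }
  keep <- colSums(w) > 0
  sweep(w[, keep, drop = FALSE], 2, colSums(w)[keep], "/")
}
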