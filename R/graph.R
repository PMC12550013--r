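#' Build a Jaccard-weighted k-nearest-neighbour graph
#'
#' PhenoGraph-style graph construction: directed Euclidean kNN lists (ties
#' broken by node index), symmetrised by union, with each edge weighted by
#' the Jaccard overlap of the two endpoints' kNN sets,
#' `|N(i) ∩ N(j)| / |N(i) ∪ N(j)|`. Zero-weight edges are dropped.
#'
#' @param emb numeric matrix (patients x dimensions).
#' @param k neighbourhood size, `1 <= k < n`.
#' @return An object of class `jip_graph`: list with `n`, `k`, `edges`
#'   (data.frame `i`, `j`, `w` with `i < j`), and `nn` (the n x k directed
#'   neighbour index matrix).
#' @export
build_knn_graph <- function(emb, k = 30L) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  if (k < 1L || k >= n) stop("parameter error: need 1 <= k < n")
  d <- as.matrix(stats::dist(emb))
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    nn[i, ] <- order(di, seq_len(n))[seq_len(k)]
  }
  # candidate edges: union-symmetrised directed kNN
  ei <- rep(seq_len(n), each = k)
  ej <- as.vector(t(nn))
  a <- pmin(ei, ej); b <- pmax(ei, ej)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  w <- vapply(seq_along(a), function(e) {
    ni <- nn[a[e], ]; nj <- nn[b[e], ]
    inter <- sum(ni %in% nj)
    inter / (2L * k - inter)
  }, numeric(1))
  pos <- w > 0
  g <- list(n = n, k = k,
            edges = data.frame(i = a[pos], j = b[pos], w = w[pos]),
            nn = nn)
  class(g) <- "jip_graph"
  g
}

#' @export
print.jip_graph <- function(x, ...) {
  cat("kNN-Jaccard graph:", x$n, "nodes,", nrow(x$edges),
      "edges (k =", x$k, ")\n")
  invisible(x)
}

#' Export a graph as an edge list
#' @param graph a `jip_graph`.
#' @param path CSV path (columns node1, node2, weight).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.csv(stats::setNames(graph$edges, c("node1", "node2", "weight")),
                   path, row.names = FALSE)
  invisible(path)
}

# adjacency list representation used by louvain/modularity
adjacency <- function(n, edges) {
  nb <- vector("list", n)
  wt <- vector("list", n)
  for (v in seq_len(n)) { nb[[v]] <- integer(0); wt[[v]] <- numeric(0) }
  if (nrow(edges) > 0L) {
    sp_i <- split(seq_len(nrow(edges)), edges$i)
    for (v in names(sp_i)) {
      vi <- as.integer(v)
      nb[[vi]] <- c(nb[[vi]], edges$j[sp_i[[v]]])
      wt[[vi]] <- c(wt[[vi]], edges$w[sp_i[[v]]])
    }
    sp_j <- split(seq_len(nrow(edges)), edges$j)
    for (v in names(sp_j)) {
      vi <- as.integer(v)
      nb[[vi]] <- c(nb[[vi]], edges$i[sp_j[[v]]])
      wt[[vi]] <- c(wt[[vi]], edges$w[sp_j[[v]]])
    }
  }
  list(nb = nb, wt = wt)
}

#' Weighted modularity of a partition
#'
#' \deqn{Q = \sum_c \left( w_c/W - (s_c/2W)^2 \right)} with `w_c` the
#' intra-community edge weight, `s_c` the community strength (sum of node
#' strengths) and `W` the total edge weight.
#'
#' @param graph a `jip_graph` (or any list with `n` and `edges`).
#' @param labels integer community label per node.
#' @return Scalar Q.
#' @export
modularity <- function(graph, labels) {
  if (length(labels) != graph$n) stop("labels must cover every node")
  e <- graph$edges
  W <- sum(e$w)
  if (W == 0) return(0)
  same <- labels[e$i] == labels[e$j]
  w_c <- tapply(e$w[same], labels[e$i][same], sum)
  strength <- numeric(graph$n)
  for (idx in seq_len(nrow(e))) {
    strength[e$i[idx]] <- strength[e$i[idx]] + e$w[idx]
    strength[e$j[idx]] <- strength[e$j[idx]] + e$w[idx]
  }
  s_c <- tapply(strength, labels, sum)
  sum(w_c) / W - sum((s_c / (2 * W))^2)
}

#' Louvain community detection
#'
#' Greedy modularity maximisation: repeated local-moving passes over nodes in
#' a seed-shuffled order, followed by graph aggregation, iterated until no
#' pass improves modularity by more than `1e-9`. Disconnected components are
#' handled naturally (no moves across zero-weight boundaries).
#'
#' @param graph a `jip_graph`.
#' @param seed integer seed for the node-order shuffles.
#' @return An object of class `jip_partition`: list with `labels` (contiguous
#'   integers starting at 1), `n_communities`, `modularity` and `trace`
#'   (modularity after each aggregation level, non-decreasing).
#' @export
louvain <- function(graph, seed = 1L) {
  if (graph$n == 0L) stop("empty graph")
  set.seed(seed)
  n0 <- graph$n
  node_comm <- seq_len(n0)        # mapping original node -> current community
  edges <- graph$edges
  n <- n0
  trace <- numeric(0)
  repeat {
    adj <- adjacency(n, edges)
    strength <- numeric(n)
    loops <- numeric(n)           # self-loop weight (aggregated graphs)
    if (nrow(edges) > 0L) {
      is_loop <- edges$i == edges$j
      for (idx in which(!is_loop)) {
        strength[edges$i[idx]] <- strength[edges$i[idx]] + edges$w[idx]
        strength[edges$j[idx]] <- strength[edges$j[idx]] + edges$w[idx]
      }
      for (idx in which(is_loop)) {
        loops[edges$i[idx]] <- loops[edges$i[idx]] + edges$w[idx]
        strength[edges$i[idx]] <- strength[edges$i[idx]] + 2 * edges$w[idx]
      }
    }
    two_m <- sum(strength)
    if (two_m == 0) break
    comm <- seq_len(n)
    sigma_tot <- strength
    improved_any <- FALSE
    repeat {
      moved <- FALSE
      for (v in sample.int(n)) {
        cv <- comm[v]
        nbv <- adj$nb[[v]]
        wtv <- adj$wt[[v]]
        keep <- nbv != v
        nbv <- nbv[keep]; wtv <- wtv[keep]
        if (length(nbv) == 0L) next
        # weight from v to each neighbouring community
        cn <- comm[nbv]
        cand <- unique(cn)
        wc <- rowsum(wtv, match(cn, cand), reorder = FALSE)[, 1L]
        sigma_tot[cv] <- sigma_tot[cv] - strength[v]
        k_v <- strength[v]
        pos_cv <- match(cv, cand)
        base <- if (is.na(pos_cv)) 0 else wc[pos_cv]
        gain_stay <- base - sigma_tot[cv] * k_v / two_m
        gains <- wc - sigma_tot[cand] * k_v / two_m
        best_i <- which.max(gains)
        if (gains[best_i] > gain_stay + 1e-12 && cand[best_i] != cv) {
          comm[v] <- cand[best_i]
          sigma_tot[cand[best_i]] <- sigma_tot[cand[best_i]] + k_v
          moved <- TRUE
          improved_any <- TRUE
        } else {
          sigma_tot[cv] <- sigma_tot[cv] + k_v
        }
      }
      if (!moved) break
    }
    labels_now <- match(comm, sort(unique(comm)))
    q_now <- modularity_from_edges(n, edges, labels_now)
    if (length(trace) > 0L && q_now <= trace[length(trace)] + 1e-9) {
      trace <- c(trace, max(q_now, trace[length(trace)]))
      break
    }
    trace <- c(trace, q_now)
    node_comm <- labels_now[node_comm]
    if (!improved_any) break
    # aggregate: communities become nodes
    nc <- max(labels_now)
    if (nc == n) break
    li <- labels_now[edges$i]
    lj <- labels_now[edges$j]
    a <- pmin(li, lj); b <- pmax(li, lj)
    key <- (a - 1) * nc + b
    agg <- rowsum(edges$w, key)          # sorted by key
    ks <- as.numeric(rownames(agg))
    edges <- data.frame(i = as.integer((ks - 1) %/% nc + 1),
                        j = as.integer((ks - 1) %% nc + 1),
                        w = agg[, 1L])
    n <- nc
  }
  labels <- match(node_comm, sort(unique(node_comm)))
  part <- list(labels = labels, n_communities = max(labels),
               modularity = modularity(graph, labels), trace = trace)
  class(part) <- "jip_partition"
  part
}

# modularity allowing self-loop edges (aggregated graphs)
modularity_from_edges <- function(n, edges, labels) {
  if (nrow(edges) == 0L) return(0)
  is_loop <- edges$i == edges$j
  W <- sum(edges$w[!is_loop]) + sum(edges$w[is_loop])
  strength <- numeric(n)
  for (idx in seq_len(nrow(edges))) {
    if (is_loop[idx]) {
      strength[edges$i[idx]] <- strength[edges$i[idx]] + 2 * edges$w[idx]
    } else {
      strength[edges$i[idx]] <- strength[edges$i[idx]] + edges$w[idx]
      strength[edges$j[idx]] <- strength[edges$j[idx]] + edges$w[idx]
    }
  }
  same <- labels[edges$i] == labels[edges$j]
  intra <- sum(edges$w[same])
  s_c <- tapply(strength, labels, sum)
  intra / W - sum((s_c / (2 * W))^2)
}

#' @export
print.jip_partition <- function(x, ...) {
  cat("Partition:", x$n_communities, "communities, modularity Q =",
      round(x$modularity, 4), "\n")
  print(table(x$labels))
  invisible(x)
}
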