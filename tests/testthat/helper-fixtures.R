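# Shared fixtures: built in code, deterministic seeds.

small_cohort <- function(n = 60L, seed = 42L, outcomes = FALSE,
                         synovium = FALSE) {
  cfg <- default_calibration(n_patients = as.integer(n))
  co <- generate_cohort(cfg, seed = seed)
  if (outcomes) co <- generate_outcomes(co, cfg, seed = seed + 1L)
  if (synovium) co <- generate_synovium(co, cfg, seed = seed + 2L)
  co
}

# single-phenotype calibration (degenerate mixing)
one_cluster_config <- function(cluster, n) {
  cfg <- default_calibration(n_patients = as.integer(n))
  cfg$mixing[] <- 0
  cfg$mixing[cluster] <- 1
  cfg
}

# a minimal jip_model around a given embedding, bypassing the autoencoder,
# for exercising the graph/stability machinery in isolation
embedding_model <- function(emb, k = 10L, seed = 1L) {
  g <- build_knn_graph(emb, k = k)
  part <- louvain(g, seed = seed)
  centroids <- do.call(rbind, lapply(seq_len(part$n_communities), function(c) {
    colMeans(emb[part$labels == c, , drop = FALSE])
  }))
  structure(list(embedding = emb, graph = g, partition = part,
                 centroids = centroids, k = k, projection_k = k,
                 row_ids = as.character(seq_len(nrow(emb)))),
            class = "jip_model")
}

# exhaustive maximum-modularity partition of a small graph (restricted
# growth string enumeration); oracle for louvain
best_partition_bruteforce <- function(graph) {
  n <- graph$n
  stopifnot(n <= 9L)
  best_q <- -Inf
  best <- NULL
  a <- integer(n)
  recurse <- function(i, maxl) {
    if (i > n) {
      q <- modularity(graph, a[seq_len(n)] + 1L)
      if (q > best_q) { best_q <<- q; best <<- a[seq_len(n)] + 1L }
      return(invisible(NULL))
    }
    for (v in 0:(maxl + 1L)) {
      a[i] <<- v
      recurse(i + 1L, max(maxl, v))
    }
  }
  recurse(1L, -1L)
  list(labels = best, modularity = best_q)
}

# independent Cox partial log-likelihood for tie-free data, one covariate
cox_pl_bruteforce <- function(time, event, x, beta) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}
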