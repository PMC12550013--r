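#' Bootstrap co-clustering stability of a fitted cluster model
#'
#' Repeatedly subsamples the cohort without replacement, re-runs the
#' clustering on the subsample (by default re-clustering the frozen
#' embedding; optionally retraining the autoencoder), matches the resulting
#' communities to the reference partition by a maximum-overlap (Hungarian)
#' assignment on the contingency table, and records:
#' per-patient stability (the fraction of a patient's inclusions in which it
#' was assigned to its reference-matched cluster), the pairwise
#' co-clustering matrix (fraction of co-inclusions clustered together), the
#' per-iteration adjusted Rand index against the reference, and the mean
#' per-patient stability, which is the headline "fraction of patients
#' grouping together".
#'
#' @param model a fitted `jip_model`.
#' @param iterations number of random subsets (>= 2).
#' @param subsample_fraction fraction of patients per subset, in (0, 1).
#' @param seed integer seed.
#' @param refit `"embedding"` (re-cluster the frozen embedding, default) or
#'   `"mmae"` (retrain the autoencoder per subsample; slow).
#' @param features the `jip_features` used to fit the model; required for
#'   `refit = "mmae"`.
#' @return An object of class `jip_stability`: list with `iterations`,
#'   `subsample_fraction`, `per_patient` (named vector in `[0, 1]`),
#'   `cocluster` (symmetric matrix, unit diagonal), `mean_stability`, `ari`
#'   (per iteration).
#' @export
stability_analysis <- function(model, iterations = 200L,
                               subsample_fraction = 0.8, seed = 1L,
                               refit = c("embedding", "mmae"),
                               features = NULL) {
  stopifnot(inherits(model, "jip_model"))
  refit <- match.arg(refit)
  if (iterations < 2L) stop("parameter error: iterations must be >= 2")
  if (subsample_fraction <= 0 || subsample_fraction >= 1) {
    stop("parameter error: subsample_fraction must be in (0, 1)")
  }
  n <- nrow(model$embedding)
  m <- round(subsample_fraction * n)
  if (m <= model$k) stop("parameter error: subsample smaller than k + 1")
  if (refit == "mmae" && is.null(features)) {
    stop("refit = 'mmae' requires the fitted feature matrix")
  }
  ref <- model$partition$labels
  set.seed(seed)
  it_seeds <- sample.int(.Machine$integer.max, iterations)
  incl <- numeric(n)
  correct <- numeric(n)
  co_incl <- matrix(0, n, n)
  co_same <- matrix(0, n, n)
  ari <- numeric(iterations)
  for (it in seq_len(iterations)) {
    set.seed(it_seeds[it])
    idx <- sort(sample.int(n, m))
    if (refit == "embedding") {
      emb_s <- model$embedding[idx, , drop = FALSE]
    } else {
      feat_s <- features
      feat_s$x <- features$x[idx, , drop = FALSE]
      feat_s$row_ids <- features$row_ids[idx]
      cfg <- model$mmae$config
      cfg$seed <- it_seeds[it]
      emb_s <- encode(train_mmae(feat_s, cfg), feat_s)
    }
    g <- build_knn_graph(emb_s, k = model$k)
    part <- louvain(g, seed = it_seeds[it])
    li <- part$labels
    map <- match_communities(li, ref[idx])
    matched <- map[li]
    ok <- !is.na(matched) & matched == ref[idx]
    incl[idx] <- incl[idx] + 1
    correct[idx[ok]] <- correct[idx[ok]] + 1
    same <- outer(li, li, `==`) * 1
    co_incl[idx, idx] <- co_incl[idx, idx] + 1
    co_same[idx, idx] <- co_same[idx, idx] + same
    ari[it] <- adjusted_rand_index(li, ref[idx])
  }
  per_patient <- ifelse(incl > 0, correct / incl, NA_real_)
  names(per_patient) <- model$row_ids
  cocluster <- ifelse(co_incl > 0, co_same / co_incl, NA_real_)
  diag(cocluster) <- 1
  out <- list(iterations = iterations, subsample_fraction = subsample_fraction,
              per_patient = per_patient, cocluster = cocluster,
              mean_stability = mean(per_patient, na.rm = TRUE), ari = ari)
  class(out) <- "jip_stability"
  out
}

#' @export
print.jip_stability <- function(x, ...) {
  cat(sprintf("Stability over %d subsets (%.0f%% subsampling):\n",
              x$iterations, 100 * x$subsample_fraction))
  cat(sprintf("  mean per-patient stability %.3f, mean ARI vs reference %.3f\n",
              x$mean_stability, mean(x$ari)))
  invisible(x)
}

# Map subsample community labels to reference cluster labels by
# maximum-overlap assignment (Hungarian on the negated contingency table).
# Returns, for each subsample community 1..r, the matched reference cluster
# (NA when there are more communities than reference clusters).
match_communities <- function(sub_labels, ref_labels) {
  tab <- table(factor(sub_labels, levels = sort(unique(sub_labels))),
               factor(ref_labels, levels = sort(unique(ref_labels))))
  r <- nrow(tab); c <- ncol(tab)
  size <- max(r, c)
  cost <- matrix(0, size, size)
  cost[seq_len(r), seq_len(c)] <- max(tab) - tab
  assign <- solve_assignment(cost)
  map <- rep(NA_integer_, r)
  ref_values <- as.integer(colnames(tab))
  for (i in seq_len(r)) {
    j <- assign[i]
    if (j <= c && tab[i, j] > 0) map[i] <- ref_values[j]
  }
  map
}

# Hungarian algorithm (Jonker-style potentials, O(n^3)) for a square cost
# matrix; returns for each row the assigned column, minimising total cost.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}
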