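#' Fit the joint-involvement-pattern cluster model
#'
#' The end-to-end phenotyping pipeline: preprocess the cohort
#' ([fit_transform()]), train the multimodal autoencoder ([train_mmae()]),
#' encode patients into the 8-dimensional embedding, build the kNN-Jaccard
#' graph and partition it with Louvain. The returned model freezes the
#' transform parameters, the encoder, the reference embedding and the
#' reference partition, so external cohorts can be projected without any
#' refitting (see [predict.jip_model()]).
#'
#' @param cohort a complete-case `jip_cohort`.
#' @param mmae a [mmae_config()]; its seed is overridden by `seed`.
#' @param k kNN neighbourhood size (PhenoGraph's published default, 30).
#' @param projection_k neighbours used for the majority vote when projecting
#'   new patients.
#' @param seed one seed governing the whole chain.
#' @return An object of class `jip_model` with elements `params` (frozen
#'   transform), `mmae`, `embedding`, `graph`, `partition`, `centroids`
#'   (per-community embedding means), `k`, `projection_k`, `row_ids`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(default_calibration(n_patients = 300L))
#' fit <- jip_fit(cohort, mmae = mmae_config(max_epochs = 50L), seed = 1L)
#' print(fit)
#' }
#' @export
jip_fit <- function(cohort, mmae = mmae_config(), k = 30L,
                    projection_k = 30L, seed = 1L) {
  stopifnot(inherits(cohort, "jip_cohort"))
  features <- fit_transform(cohort)
  fit_cluster_model(features, mmae_cfg = mmae, k = k,
                    projection_k = projection_k, seed = seed)
}

#' @rdname jip_fit
#' @param features a `jip_features` matrix (complete-case).
#' @param mmae_cfg a [mmae_config()].
#' @export
fit_cluster_model <- function(features, mmae_cfg = mmae_config(), k = 30L,
                              projection_k = 30L, seed = 1L) {
  stopifnot(inherits(features, "jip_features"))
  mmae_cfg$seed <- as.integer(seed)
  model <- train_mmae(features, mmae_cfg)
  emb <- encode(model, features)
  graph <- build_knn_graph(emb, k = k)
  part <- louvain(graph, seed = seed)
  centroids <- do.call(rbind, lapply(seq_len(part$n_communities), function(c) {
    colMeans(emb[part$labels == c, , drop = FALSE])
  }))
  fit <- list(params = features$params, mmae = model, embedding = emb,
              graph = graph, partition = part, centroids = centroids,
              k = k, projection_k = projection_k, seed = seed,
              row_ids = features$row_ids)
  class(fit) <- "jip_model"
  fit
}

#' @export
print.jip_model <- function(x, ...) {
  cat("Joint-involvement-pattern cluster model\n")
  cat(sprintf("  %d patients, embedding dim %d, kNN k = %d\n",
              nrow(x$embedding), ncol(x$embedding), x$k))
  cat(sprintf("  %d communities, modularity Q = %.4f\n",
              x$partition$n_communities, x$partition$modularity))
  print(table(cluster = x$partition$labels))
  invisible(x)
}

#' @export
summary.jip_model <- function(object, ...) {
  sizes <- table(object$partition$labels)
  out <- list(n = nrow(object$embedding),
              n_communities = object$partition$n_communities,
              sizes = sizes,
              proportions = as.numeric(sizes) / nrow(object$embedding),
              modularity = object$partition$modularity,
              best_epoch = object$mmae$best_epoch)
  class(out) <- "summary.jip_model"
  out
}

#' @export
print.summary.jip_model <- function(x, ...) {
  cat("Cluster model:", x$n, "patients in", x$n_communities,
      "communities (Q =", round(x$modularity, 4), ")\n")
  df <- data.frame(cluster = names(x$sizes), n = as.integer(x$sizes),
                   fraction = round(x$proportions, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Project new patients onto a fitted cluster model
#'
#' Applies the frozen transform parameters and the frozen encoder to the new
#' cohort, then assigns each patient by majority vote among its
#' `projection_k` nearest reference embeddings (Euclidean); ties are broken
#' by the nearest cluster centroid. Nothing is refitted: no statistic of the
#' new cohort enters the transform or the encoder.
#'
#' @param object a fitted `jip_model`.
#' @param newdata a complete-case `jip_cohort`.
#' @param ... unused.
#' @return Integer vector of cluster labels for the new patients.
#' @export
predict.jip_model <- function(object, newdata, ...) {
  project_patients(object, newdata)
}

#' @rdname predict.jip_model
#' @param model a fitted `jip_model`.
#' @param new_cohort a complete-case `jip_cohort`.
#' @export
project_patients <- function(model, new_cohort) {
  stopifnot(inherits(model, "jip_model"), inherits(new_cohort, "jip_cohort"))
  features <- apply_transform(new_cohort, model$params)
  emb_new <- encode(model$mmae, features)
  ref <- model$embedding
  labs <- model$partition$labels
  kp <- min(model$projection_k, nrow(ref))
  out <- integer(nrow(emb_new))
  # squared Euclidean distances to reference points, row-blockwise
  ref_sq <- rowSums(ref^2)
  for (i in seq_len(nrow(emb_new))) {
    d2 <- ref_sq - 2 * as.vector(ref %*% emb_new[i, ])
    nnk <- order(d2, seq_along(d2))[seq_len(kp)]
    votes <- table(labs[nnk])
    winners <- as.integer(names(votes)[votes == max(votes)])
    if (length(winners) == 1L) {
      out[i] <- winners
    } else {
      cd <- rowSums(sweep(model$centroids[winners, , drop = FALSE], 2L,
                          emb_new[i, ])^2)
      out[i] <- winners[which.min(cd)]
    }
  }
  out
}
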