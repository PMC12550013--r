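#' Fit a surrogate classifier for cluster assignment
#'
#' Trains a gradient-boosted tree multiclass classifier mapping the input
#' feature matrix to the cluster labels, for post-hoc explanation of what
#' drives each cluster (via [shapley_attributions()]).
#'
#' @param features a `jip_features` (or plain numeric matrix).
#' @param labels cluster labels (>= 2 distinct values), one per row.
#' @param nrounds boosting rounds.
#' @param seed seed.
#' @return An object of class `jip_surrogate`: list with the fitted booster,
#'   `accuracy` (training accuracy), `classes`, `layout`.
#' @export
fit_surrogate <- function(features, labels, nrounds = 100L, seed = 1L) {
  x <- if (inherits(features, "jip_features")) features$x else as.matrix(features)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 clusters for a surrogate")
  if (nrow(x) != length(labels)) stop("labels must match feature rows")
  set.seed(seed)
  y <- as.integer(labels) - 1L
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = nlevels(labels),
                  max_depth = 4, eta = 0.3, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  pred <- predict_surrogate_matrix(booster, x, nlevels(labels))
  acc <- mean(max.col(pred) == as.integer(labels))
  out <- list(booster = booster, accuracy = acc,
              classes = levels(labels), layout = colnames(x))
  class(out) <- "jip_surrogate"
  out
}

predict_surrogate_matrix <- function(booster, x, nclass) {
  dm <- xgboost::xgb.DMatrix(as.matrix(x), nthread = 1)
  p <- stats::predict(booster, dm)
  if (is.matrix(p)) unname(p) else matrix(p, ncol = nclass, byrow = TRUE)
}

# class-probability matrix for rows, honouring function-backed surrogates
# (a jip_surrogate may carry predict_fun(rows) instead of a booster)
surrogate_eval <- function(model, rows) {
  if (!is.null(model$predict_fun)) {
    out <- model$predict_fun(as.matrix(rows))
    return(as.matrix(out))
  }
  predict_surrogate_matrix(model$booster, rows, length(model$classes))
}

#' Predicted class probabilities from a surrogate
#' @param model a `jip_surrogate`.
#' @param x matrix of rows in the training layout.
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
surrogate_prob <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$layout) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$layout)) {
    stop("feature layout mismatch")
  }
  surrogate_eval(model, x)
}

#' @export
print.jip_surrogate <- function(x, ...) {
  cat("Surrogate classifier:", length(x$classes), "classes,",
      length(x$layout), "features, training accuracy",
      round(x$accuracy, 3), "\n")
  invisible(x)
}

#' Monte-Carlo Shapley attributions for a surrogate prediction
#'
#' Permutation-sampling estimator of Shapley values: for `m` random feature
#' orderings, features are switched one at a time from a background-imputed
#' value to the explained patient's value, and the marginal change in each
#' cluster's predicted probability is accredited to the switched feature.
#' The estimator is unbiased in `m`; by the efficiency property the
#' attributions per cluster sum to the prediction minus the background base
#' rate, up to Monte-Carlo error (the residual is reported).
#'
#' @param model a `jip_surrogate`.
#' @param x a single feature row (named vector or 1-row matrix) in the
#'   training layout.
#' @param background matrix of background rows used to impute absent
#'   features.
#' @param m number of sampled orderings (>= 1).
#' @param seed seed.
#' @return An object of class `jip_shapley`: list with `phi` (features x
#'   clusters matrix), `base` (background mean prediction per cluster),
#'   `prediction`, `residual` (local-accuracy gap per cluster) and
#'   `se` (per-feature-per-cluster Monte-Carlo standard errors).
#' @export
shapley_attributions <- function(model, x, background, m = 200L, seed = 1L) {
  stopifnot(inherits(model, "jip_surrogate"), m >= 1L)
  x <- as.numeric(as.matrix(x))
  p <- length(model$layout)
  if (length(x) != p) stop("feature layout mismatch: expected ", p, " features")
  background <- as.matrix(background)
  if (nrow(background) < 1L) stop("background must be non-empty")
  if (ncol(background) != p) stop("feature layout mismatch in background")
  set.seed(seed)
  nc <- length(model$classes)
  contrib <- array(0, dim = c(p, nc, m))
  for (t in seq_len(m)) {
    ord <- sample.int(p)
    b <- background[sample.int(nrow(background), 1L), ]
    # rows: background row, then one feature switched in at a time
    rows <- matrix(b, p + 1L, p, byrow = TRUE)
    cur <- b
    for (s in seq_len(p)) {
      cur[ord[s]] <- x[ord[s]]
      rows[s + 1L, ] <- cur
    }
    colnames(rows) <- model$layout
    preds <- surrogate_eval(model, rows)
    diffs <- preds[-1L, , drop = FALSE] - preds[-(p + 1L), , drop = FALSE]
    contrib[ord, , t] <- diffs
  }
  phi <- apply(contrib, c(1, 2), mean)
  se <- apply(contrib, c(1, 2), stats::sd) / sqrt(dim(contrib)[3])
  rownames(phi) <- rownames(se) <- model$layout
  colnames(phi) <- colnames(se) <- model$classes
  base <- colMeans(surrogate_prob(model, background))
  pred <- as.vector(surrogate_prob(model, matrix(x, 1L, p,
                                                 dimnames = list(NULL, model$layout))))
  out <- list(phi = phi, base = base, prediction = pred,
              residual = pred - base - colSums(phi), se = se)
  class(out) <- "jip_shapley"
  out
}

#' Exact Shapley values by coalition enumeration
#'
#' Exhaustive computation over all feature coalitions, feasible for small
#' feature counts; used as an independent check of the Monte-Carlo
#' estimator. Absent features are imputed per background row and averaged.
#'
#' @inheritParams shapley_attributions
#' @return Matrix of Shapley values (features x clusters).
#' @export
shapley_exact <- function(model, x, background) {
  x <- as.numeric(as.matrix(x))
  p <- length(model$layout)
  if (p > 16L) stop("exact enumeration limited to 16 features")
  background <- as.matrix(background)
  nc <- length(model$classes)
  nb <- nrow(background)
  # value of each coalition: mean prediction with coalition features from x
  nsub <- 2L^p
  vals <- matrix(0, nsub, nc)
  for (s in 0:(nsub - 1L)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    rows <- background
    if (length(members) > 0L) {
      rows[, members] <- matrix(x[members], nb, length(members), byrow = TRUE)
    }
    colnames(rows) <- model$layout
    vals[s + 1L, ] <- colMeans(surrogate_eval(model, rows))
  }
  phi <- matrix(0, p, nc, dimnames = list(model$layout, model$classes))
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (s in 0:(nsub - 1L)) {
      if (bitwAnd(s, bit) == 0L) {
        size <- sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L)
        wgt <- factorial(size) * factorial(p - size - 1L) / factorial(p)
        phi[i, ] <- phi[i, ] + wgt * (vals[s + bit + 1L, ] - vals[s + 1L, ])
      }
    }
  }
  phi
}

#' Per-cluster baseline profile table
#'
#' Summarises each cluster the way baseline characteristics tables do:
#' size, percent female, age mean (SD), RF/ACPA positivity, ESR median
#' (IQR), SJC/TJC medians (IQR), DAS44(3) and DAS28(3) medians.
#'
#' @param cohort a `jip_cohort`.
#' @param labels cluster label per patient.
#' @return data.frame with one row per non-empty cluster.
#' @export
cluster_profile <- function(cohort, labels) {
  stopifnot(inherits(cohort, "jip_cohort"))
  d <- cohort$data
  if (length(labels) != nrow(d)) stop("labels must match cohort size")
  jc <- joint_counts(cohort)
  das44 <- compute_das(jc$tjc44, jc$sjc44, d$esr, "das44_3")
  das28 <- compute_das(jc$tjc28, jc$sjc28, d$esr, "das28_3")
  all_levels <- if (is.factor(labels)) levels(labels) else unique(labels)
  rows <- lapply(all_levels, function(cl) {
    i <- which(labels == cl)
    if (length(i) == 0L) return(NULL)
    iqr <- function(x) sprintf("%.3g (%.3g-%.3g)", stats::median(x),
                               stats::quantile(x, 0.25), stats::quantile(x, 0.75))
    data.frame(
      cluster = as.character(cl), n = length(i),
      female_pct = 100 * mean(d$sex[i] == "female"),
      age_mean = mean(d$age[i]), age_sd = stats::sd(d$age[i]),
      rf_pct = 100 * mean(d$rf[i]), acpa_pct = 100 * mean(d$acpa[i]),
      esr = iqr(d$esr[i]), sjc = iqr(jc$sjc44[i]), tjc = iqr(jc$tjc44[i]),
      das44_3 = iqr(das44[i]), das28_3 = iqr(das28[i]),
      stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) warning("empty cluster(s) omitted: ",
                          paste(all_levels[empty], collapse = ", "))
  do.call(rbind, rows[!empty])
}

#' Per-cluster joint involvement prevalence
#'
#' For each cluster and atlas joint, the fraction of patients with the joint
#' involved (tender OR swollen) — the matrix behind pictorial mannequin
#' displays.
#'
#' @param cohort a `jip_cohort`.
#' @param labels cluster label per patient.
#' @return Matrix (clusters x 44 joints) of prevalences in `[0, 1]`.
#' @export
joint_prevalence <- function(cohort, labels) {
  stopifnot(inherits(cohort, "jip_cohort"))
  d <- cohort$data
  atlas <- cohort$atlas
  inv <- (as.matrix(d[, tender_cols(atlas)]) |
            as.matrix(d[, swollen_cols(atlas)])) * 1
  colnames(inv) <- atlas$joint_id
  lv <- sort(unique(labels))
  out <- do.call(rbind, lapply(lv, function(cl) {
    colMeans(inv[labels == cl, , drop = FALSE])
  }))
  rownames(out) <- as.character(lv)
  out
}
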