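#' Merge the sparse lowest synovitis grade
#'
#' Krenn component grades run 0 (none) to 3 (severe); in treatment-naive
#' active synovitis the 'none' grade is rare, so it is combined with the
#' 'low' grade before ordinal modelling.
#'
#' @param y integer grades in `{0, 1, 2, 3}`.
#' @return Grades with 0 mapped to 1; warns if the merge collapses the data
#'   to a single category.
#' @export
merge_sparse_levels <- function(y) {
  stopifnot(all(y %in% 0:3))
  out <- ifelse(y == 0L, 1L, y)
  if (length(unique(out)) == 1L) {
    warning("single-category collapse after merging grade 0 into 1")
  }
  out
}

#' Proportional-odds ordinal regression with Wald tests
#'
#' Cumulative-logit model `logit P(Y <= j) = theta_j - x beta` with strictly
#' increasing thresholds and common slopes, fitted by maximum likelihood via
#' [MASS::polr()]. Reports the global Wald test on the cluster coefficient
#' block and all pairwise cluster contrasts (post-hoc Wald).
#'
#' @param y ordinal response (integer grades or ordered factor).
#' @param cluster cluster label per observation.
#' @param covariate optional additional covariate (e.g. DAS category),
#'   entered as a factor.
#' @return An object of class `jip_ordinal`: list with `thresholds`,
#'   `coef`, `vcov`, `global_wald` (`statistic`, `df`, `p` for the cluster
#'   block), `pairwise` (data.frame of cluster contrasts with z and p),
#'   `fitted_probs` and the underlying `polr` fit.
#' @export
ordinal_fit <- function(y, cluster, covariate = NULL) {
  yf <- if (is.ordered(y)) droplevels(y) else factor(y, ordered = TRUE)
  yf <- droplevels(yf)
  if (nlevels(yf) < 2L) stop("need at least 2 observed categories")
  cluster <- factor(cluster)
  df <- data.frame(y = yf, cluster = cluster)
  form <- y ~ cluster
  if (!is.null(covariate)) {
    df$covariate <- factor(covariate)
    form <- y ~ cluster + covariate
  }
  mm <- stats::model.matrix(form, df)
  if (qr(mm)$rank < ncol(mm)) stop("design matrix is rank deficient")
  fit <- MASS::polr(form, data = df, Hess = TRUE)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)[names(beta), names(beta), drop = FALSE]
  cl_idx <- grep("^cluster", names(beta))
  b <- beta[cl_idx]
  Vb <- V[cl_idx, cl_idx, drop = FALSE]
  w <- as.numeric(t(b) %*% solve(Vb) %*% b)
  global <- list(statistic = w, df = length(cl_idx),
                 p = stats::pchisq(w, length(cl_idx), lower.tail = FALSE))
  # pairwise contrasts on the cluster latent shifts (reference shift = 0)
  lev <- levels(cluster)
  shift <- c(0, b)
  names(shift) <- lev
  Vfull <- matrix(0, length(lev), length(lev),
                  dimnames = list(lev, lev))
  Vfull[-1, -1] <- Vb
  pairs <- utils::combn(lev, 2)
  pw <- data.frame(
    a = pairs[1, ], b = pairs[2, ],
    estimate = shift[pairs[2, ]] - shift[pairs[1, ]],
    se = sqrt(Vfull[cbind(pairs[1, ], pairs[1, ])] +
                Vfull[cbind(pairs[2, ], pairs[2, ])] -
                2 * Vfull[cbind(pairs[1, ], pairs[2, ])]),
    stringsAsFactors = FALSE, row.names = NULL)
  pw$z <- pw$estimate / pw$se
  pw$p <- 2 * stats::pnorm(-abs(pw$z))
  probs <- fit$fitted.values
  out <- list(thresholds = fit$zeta, coef = beta, vcov = V,
              global_wald = global, pairwise = pw,
              fitted_probs = probs, polr = fit)
  class(out) <- "jip_ordinal"
  out
}

#' @export
print.jip_ordinal <- function(x, ...) {
  cat("Proportional-odds fit: thresholds",
      paste(round(x$thresholds, 3), collapse = ", "), "\n")
  cat(sprintf("global cluster Wald: chi2 = %.3f, df = %d, p = %.4g\n",
              x$global_wald$statistic, x$global_wald$df, x$global_wald$p))
  invisible(x)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H via [stats::kruskal.test()], followed by
#' Dunn's pairwise z statistics with tie-corrected variance. Pairwise
#' p-values are unadjusted by default; Holm adjustment available.
#'
#' @param values numeric vector.
#' @param group group label per value (>= 2 groups).
#' @param adjust `"none"` or `"holm"` for the pairwise p-values.
#' @return list with `H`, `df`, `p` and `pairwise` (data.frame with groups,
#'   z, p, p_adj).
#' @export
kruskal_dunn <- function(values, group, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  kt <- stats::kruskal.test(values, group)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, group, mean)
  ng <- tapply(r, group, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_corr
  pairs <- utils::combn(levels(group), 2)
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) /
    sqrt(v0 * (1 / ng[pairs[1, ]] + 1 / ng[pairs[2, ]]))
  p <- 2 * stats::pnorm(-abs(z))
  pw <- data.frame(a = pairs[1, ], b = pairs[2, ], z = as.numeric(z),
                   p = as.numeric(p),
                   p_adj = if (adjust == "holm") stats::p.adjust(p, "holm")
                           else as.numeric(p),
                   stringsAsFactors = FALSE, row.names = NULL)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value), pairwise = pw)
}

#' Categorise baseline DAS44 into ordered strata
#'
#' Low/moderate/high disease-activity strata used as the adjustment
#' covariate in the synovitis models. Cutpoints follow the conventional
#' DAS44 bands: low < 2.4, moderate < 3.7, high otherwise.
#'
#' @param das44 baseline DAS44 values.
#' @param cuts the two cutpoints.
#' @return Ordered factor with levels low/moderate/high.
#' @export
das_category <- function(das44, cuts = c(2.4, 3.7)) {
  cut(das44, breaks = c(-Inf, cuts, Inf),
      labels = c("low", "moderate", "high"), ordered_result = TRUE)
}
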