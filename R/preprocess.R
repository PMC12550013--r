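#' Yeo-Johnson power transformation
#'
#' Applies the Yeo-Johnson transform, a power transform defined on the whole
#' real line:
#' \deqn{\psi(y,\lambda) = ((y+1)^\lambda - 1)/\lambda}{psi = ((y+1)^l - 1)/l}
#' for \eqn{y \ge 0, \lambda \ne 0}; \eqn{\log(y+1)} for \eqn{\lambda = 0};
#' \eqn{-((-y+1)^{2-\lambda} - 1)/(2-\lambda)} for \eqn{y < 0,
#' \lambda \ne 2}; and \eqn{-\log(-y+1)} for \eqn{\lambda = 2}.
#'
#' @param y numeric vector.
#' @param lambda transformation parameter.
#' @return Transformed vector.
#' @export
apply_yeo_johnson <- function(y, lambda) {
  stopifnot(is.finite(lambda))
  out <- numeric(length(y))
  pos <- !is.na(y) & y >= 0
  neg <- !is.na(y) & y < 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((y[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(y[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    out[neg] <- -(((-y[neg] + 1)^(2 - lambda) - 1) / (2 - lambda))
  } else {
    out[neg] <- -log1p(-y[neg])
  }
  out[is.na(y)] <- NA_real_
  out
}

# Profile log-likelihood of lambda under the normal model for psi(y, lambda)
yj_loglik <- function(lambda, y) {
  psi <- apply_yeo_johnson(y, lambda)
  n <- length(y)
  s2 <- stats::var(psi) * (n - 1) / n
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(y) * log1p(abs(y)))
}

#' Estimate the Yeo-Johnson lambda by maximum likelihood
#'
#' Maximises the Yeo-Johnson profile log-likelihood by bounded scalar (Brent)
#' optimisation on \eqn{[-5, 5]} with tolerance `1e-5`.
#'
#' @param values numeric vector with at least 10 finite values and nonzero
#'   variance.
#' @return The estimated lambda.
#' @export
fit_yeo_johnson <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 10L) stop("degenerate input: fewer than 10 finite values")
  if (stats::var(v) == 0) stop("degenerate input: constant vector")
  stats::optimize(yj_loglik, c(-5, 5), y = v, maximum = TRUE,
                  tol = 1e-5)$maximum
}

#' One-hot encode a categorical vector against a frozen level list
#'
#' @param value vector of category values.
#' @param levels ordered character vector of allowed levels.
#' @return A binary matrix with `length(levels)` columns; exactly one 1 per
#'   row. A value outside `levels` raises an unseen-level error (levels are
#'   never silently extended).
#' @export
one_hot <- function(value, levels) {
  stopifnot(length(levels) > 0L)
  idx <- match(as.character(value), levels)
  if (anyNA(idx)) {
    stop("unseen-level error: ",
         paste(unique(setdiff(as.character(value), levels)), collapse = ", "))
  }
  out <- matrix(0, length(value), length(levels),
                dimnames = list(NULL, levels))
  out[cbind(seq_along(idx), idx)] <- 1
  out
}

numeric_vars <- c("age", "hb", "ht", "leuko", "thrombo", "esr")
categorical_vars <- list(sex = c("female", "male"),
                         rf = c("TRUE", "FALSE"),
                         acpa = c("TRUE", "FALSE"))

#' Fit the preprocessing transform and build the feature matrix
#'
#' Numeric variables (age and blood labs) are Yeo-Johnson transformed with a
#' per-variable maximum-likelihood lambda and standardised; ESR is
#' log-transformed (`log(esr + 1)`, reflecting its log-normal distribution)
#' and then standardised on the same footing. Categorical variables (sex, RF,
#' ACPA) are one-hot encoded with both yes/no columns, and the 88 per-joint
#' tender/swollen flags enter as binary columns of the categorical modality.
#' All fitted parameters (lambdas, means, SDs, level lists) are frozen in the
#' returned object so external cohorts can be projected with
#' [apply_transform()] without refitting.
#'
#' @param cohort a complete-case `jip_cohort`.
#' @return An object of class `jip_features`: list with `x` (full matrix),
#'   `numeric_cols`, `categorical_cols` (column name vectors), `row_ids` and
#'   `params` (class `jip_transform_params`).
#' @export
fit_transform <- function(cohort) {
  stopifnot(inherits(cohort, "jip_cohort"))
  d <- cohort$data
  params <- list(numeric = list(), categorical = categorical_vars,
                 atlas_ids = cohort$atlas$joint_id)
  for (v in numeric_vars) {
    raw <- d[[v]]
    if (anyNA(raw)) stop("fit_transform requires a complete-case cohort (", v, ")")
    if (v == "esr") {
      if (any(raw < 0)) stop("domain error: negative ESR")
      psi <- log1p(raw)
      lam <- NA_real_
    } else {
      lam <- fit_yeo_johnson(raw)
      psi <- apply_yeo_johnson(raw, lam)
    }
    params$numeric[[v]] <- list(lambda = lam, mean = mean(psi),
                                sd = stats::sd(psi), esr_log = (v == "esr"))
    if (params$numeric[[v]]$sd <= 0) stop("degenerate input: constant ", v)
  }
  class(params) <- "jip_transform_params"
  apply_transform(cohort, params)
}

#' Apply a frozen preprocessing transform
#'
#' Uses only the frozen parameters: no statistic of the new cohort enters.
#' Applying it to the cohort the parameters were fitted on reproduces the
#' fitted matrix exactly.
#'
#' @param cohort a complete-case `jip_cohort`.
#' @param params a `jip_transform_params` object.
#' @return A `jip_features` object.
#' @export
apply_transform <- function(cohort, params) {
  stopifnot(inherits(cohort, "jip_cohort"),
            inherits(params, "jip_transform_params"))
  d <- cohort$data
  num <- matrix(NA_real_, nrow(d), length(numeric_vars),
                dimnames = list(NULL, numeric_vars))
  for (v in numeric_vars) {
    p <- params$numeric[[v]]
    raw <- d[[v]]
    if (anyNA(raw)) stop("apply_transform requires a complete-case cohort (", v, ")")
    psi <- if (isTRUE(p$esr_log)) {
      if (any(raw < 0)) stop("domain error: negative ESR")
      log1p(raw)
    } else {
      apply_yeo_johnson(raw, p$lambda)
    }
    num[, v] <- (psi - p$mean) / p$sd
  }
  cat_blocks <- lapply(names(params$categorical), function(v) {
    m <- one_hot(d[[v]], params$categorical[[v]])
    colnames(m) <- paste0(v, "_", tolower(params$categorical[[v]]))
    m
  })
  tcols <- paste0("tender_", params$atlas_ids)
  scols <- paste0("swollen_", params$atlas_ids)
  joints <- as.matrix(d[, c(tcols, scols), drop = FALSE]) * 1
  if (anyNA(joints)) stop("apply_transform requires complete joint vectors")
  cat_mat <- do.call(cbind, c(cat_blocks, list(joints)))
  x <- cbind(num, cat_mat)
  rownames(x) <- d$patient_id
  obj <- list(x = x,
              numeric_cols = colnames(num),
              categorical_cols = colnames(cat_mat),
              row_ids = d$patient_id,
              params = params)
  class(obj) <- "jip_features"
  obj
}

#' @export
print.jip_features <- function(x, ...) {
  cat("Feature matrix: ", nrow(x$x), " patients x ", ncol(x$x), " columns (",
      length(x$numeric_cols), " numeric, ", length(x$categorical_cols),
      " categorical/binary)\n", sep = "")
  invisible(x)
}

#' Serialize / read frozen transform parameters as JSON
#'
#' @param params a `jip_transform_params` object.
#' @param path JSON file path.
#' @return `write_transform_params` returns `path` invisibly;
#'   `read_transform_params` returns the parameters.
#' @export
write_transform_params <- function(params, path) {
  stopifnot(inherits(params, "jip_transform_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_transform_params
#' @export
read_transform_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$numeric <- lapply(p$numeric, function(q) {
    q$lambda <- if (is.null(q$lambda) || is.na(q$lambda)) NA_real_ else q$lambda
    q
  })
  p$categorical <- lapply(p$categorical, as.character)
  class(p) <- "jip_transform_params"
  p
}

#' Log-transform ESR
#'
#' `log(esr + 1)`, optionally standardised with frozen mean/SD. This is the
#' transform applied to ESR instead of Yeo-Johnson, reflecting its log-normal
#' distribution.
#'
#' @param esr ESR values (mm/hr), non-negative.
#' @param mean,sd frozen standardisation parameters (defaults leave the value
#'   on the log scale).
#' @return Transformed values.
#' @export
transform_esr <- function(esr, mean = 0, sd = 1) {
  if (any(esr < 0, na.rm = TRUE)) stop("domain error: negative ESR")
  (log1p(esr) - mean) / sd
}
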