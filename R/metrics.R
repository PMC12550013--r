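#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement from the contingency table of the
#' two labelings; 1 for identical partitions (up to label permutation), about
#' 0 for independent ones.
#'
#' @param p1,p2 label vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("partitions differ in length")
  tab <- table(p1, p2)
  n <- length(p1)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Local Inverse Simpson's Index (LISI)
#'
#' For each point, neighbourhood weights are a Gaussian kernel whose
#' bandwidth is tuned by binary search so the weight distribution has the
#' target perplexity; the label proportions \eqn{p_c} under those weights
#' give \eqn{LISI = 1/\sum_c p_c^2}, the effective number of label
#' categories in the local neighbourhood. Values range from 1 (locally pure)
#' to the number of categories (perfect local mixing). Used to check whether
#' treating physicians are evenly distributed across the embedding.
#'
#' @param emb numeric matrix (points x dimensions).
#' @param labels categorical label per point.
#' @param perplexity target perplexity (< number of points).
#' @return Numeric vector of per-point LISI values.
#' @export
lisi <- function(emb, labels, perplexity = 30) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  if (length(labels) != n) stop("labels must cover every point")
  if (perplexity >= n) stop("parameter error: perplexity must be < n")
  labels <- as.factor(labels)
  if (nlevels(labels) == 1L) return(rep(1, n))
  d2 <- as.matrix(stats::dist(emb))^2
  target_h <- log(perplexity)
  out <- numeric(n)
  lab_int <- as.integer(labels)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    li <- lab_int[-i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:60) {
      w <- exp(-beta * di)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target_h) < 1e-5) break
      if (h > target_h) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-beta * di)
    p <- w / sum(w)
    pc <- tapply(p, li, sum)
    pc[is.na(pc)] <- 0
    out[i] <- 1 / sum(pc^2)
  }
  out
}
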