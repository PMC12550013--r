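test_that("Kaplan-Meier estimates match the product-limit by hand", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  # S(1) = 3/4; S(3) = 3/4 * 1/2 = 0.375
  expect_equal(km$estimate(1), 0.75)
  expect_equal(km$estimate(3), 0.375)
  expect_equal(km$estimate(0.5), 1)
  # all censored: S identically 1
  km0 <- km_estimate(c(2, 5, 7), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # all events at t = 1
  km1 <- km_estimate(rep(1, 4), rep(1, 4))
  expect_equal(km1$estimate(1), 0)
  # Greenwood SE at the first event of the toy: S(1)*sqrt(1/(4*3))
  expect_equal(km$se[km$time == 1], 0.75 * sqrt(1 / 12))
  expect_error(km_estimate(c(0, 1), c(1, 1)), "non-positive")
})

test_that("log-rank matches hand tabulation and is label-invariant", {
  t <- c(1, 3, 2, 4); e <- c(1, 1, 1, 0); g <- c("A", "A", "B", "B")
  lr <- logrank_test(t, e, g)
  # O_A = 2, E_A = 1/2 + 1/3 + 1/2, V = 1/4 + 2/9 + 1/4
  expect_equal(lr$statistic, (2 - 4 / 3)^2 / (1 / 4 + 2 / 9 + 1 / 4),
               tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  g2 <- c("B", "B", "A", "A")
  expect_equal(logrank_test(t, e, g2)$statistic, lr$statistic)
  # identical groups: statistic 0
  expect_equal(logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1),
                            c("A", "A", "B", "B"))$statistic, 0)
  expect_error(logrank_test(t, c(0, 0, 0, 0), g), "no events")
})

test_that("log-rank equals the squared Cox score test on tie-free data", {
  set.seed(71)
  n <- 60
  d <- data.frame(time = sort(rexp(n)) + seq_len(n) * 1e-6,
                  event = rbinom(n, 1, 0.8),
                  group = sample(c("A", "B"), n, TRUE))
  lr <- logrank_test(d$time, d$event, d$group)
  fit <- survival::coxph(survival::Surv(time, event) ~ group, data = d)
  expect_equal(lr$statistic, unname(summary(fit)$sctest["test"]),
               tolerance = 1e-6)
})

test_that("Cox fits maximise the partial likelihood (grid oracle)", {
  d <- data.frame(time = c(1, 2.5, 3, 4.2, 5, 6.1, 7, 8.3),
                  event = c(1, 1, 0, 1, 1, 0, 1, 1),
                  group = c(0, 1, 0, 1, 0, 1, 0, 1))
  fit <- cox_fit(d, ~ group)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b) {
    cox_pl_bruteforce(d$time, d$event, d$group, b)
  }, numeric(1))
  expect_equal(unname(fit$coef), grid[which.max(ll)], tolerance = 1e-4)
  expect_equal(unname(fit$hr), exp(unname(fit$coef)))
  expect_true(fit$ci_lower < fit$hr & fit$hr < fit$ci_upper)
  expect_gte(fit$loglik[2], fit$loglik[1])
})

test_that("Cox edge cases: null effect, separation, no events", {
  d <- data.frame(time = rep(c(1, 2, 3, 4), 2), event = rep(c(1, 1, 0, 1), 2),
                  group = rep(c("A", "B"), each = 4))
  fit <- cox_fit(d, ~ group)
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)
  expect_equal(unname(fit$hr), 1, tolerance = 1e-8)
  sep <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                    event = c(1, 1, 1, 1, 1, 1),
                    group = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_fit(sep, ~ group), "divergence|separation")
  expect_error(cox_fit(data.frame(time = 1:3, event = c(0, 0, 0),
                                  group = c(1, 0, 1)), ~ group), "no events")
})

test_that("nested Cox models compare by likelihood ratio", {
  set.seed(72)
  n <- 150
  d <- data.frame(age = rnorm(n), group = sample(c("A", "B"), n, TRUE))
  d$time <- rexp(n, exp(0.8 * (d$group == "B")))
  d$event <- rbinom(n, 1, 0.9)
  f0 <- cox_fit(d, ~ age)
  f1 <- cox_fit(d, ~ age + group)
  lrt <- cox_lrt(f0, f1)
  expect_equal(lrt$df, 1L)
  expect_gt(lrt$statistic, 0)
  same <- cox_lrt(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(cox_lrt(f1, f0), "not nested")
})

test_that("Schoenfeld residuals equal covariate minus risk-set mean", {
  d <- data.frame(time = c(2, 4, 5, 7, 9), event = c(1, 1, 0, 1, 1),
                  x = c(0.3, -1.2, 0.8, 1.5, -0.4))
  fit <- cox_fit(d, ~ x)
  beta <- unname(fit$coef)
  res <- residuals(fit$coxph, type = "schoenfeld")
  for (tt in names(res)) {
    risk <- d$x[d$time >= as.numeric(tt)]
    wmean <- sum(risk * exp(beta * risk)) / sum(exp(beta * risk))
    xev <- d$x[d$time == as.numeric(tt)]
    expect_equal(unname(res[tt]), xev - wmean, tolerance = 1e-10)
  }
  ph <- schoenfeld_ph_test(fit)
  expect_true(all(c("x", "GLOBAL") %in% ph$covariate))
  expect_true(all(ph$p >= 0 & ph$p <= 1))
  expect_error(schoenfeld_ph_test(cox_fit(data.frame(
    time = c(1, 2, 3), event = c(1, 1, 0), x = c(0.5, -0.5, 1)), ~ x)),
    "3 events")
})

test_that("LOCF remission follows the carried-forward rule", {
  r1 <- locf_remission(c(120, 240), c(2.0, 1.4), horizon = 365)
  expect_true(r1$remission)
  expect_equal(r1$time, 240)
  r2 <- locf_remission(120, 1.7, horizon = 365)
  expect_false(r2$remission)
  expect_true(is.na(r2$time))
  # dip below threshold then relapse: not in remission at the horizon,
  # but the first-remission time is still reported
  r3 <- locf_remission(c(120, 300), c(1.4, 2.1), horizon = 365)
  expect_false(r3$remission)
  expect_equal(r3$time, 120)
  r4 <- locf_remission(numeric(0), numeric(0))
  expect_true(is.na(r4$remission))
  expect_error(locf_remission(c(200, 100), c(1, 2)), "sorted")
})

test_that("chi-square cross-tabulation matches hand computation", {
  expect_equal(chi2_crosstab(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chi2_crosstab(matrix(c(10, 10, 10, 10), 2))$p, 1)
  ct <- chi2_crosstab(matrix(c(20, 10, 10, 20), 2))
  expect_equal(ct$statistic, 100 / 15, tolerance = 1e-10)
  expect_equal(ct$df, 1L)
  m <- matrix(c(5, 9, 12, 4, 7, 3), 2)
  expect_equal(chi2_crosstab(t(m))$statistic, chi2_crosstab(m)$statistic)
  expect_error(chi2_crosstab(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
})

test_that("Kruskal-Wallis and Dunn match hand rank computations", {
  kd <- kruskal_dunn(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(kd$H, 2.4, tolerance = 1e-10)
  # Dunn z: (1.5 - 3.5) / sqrt(5/3 * (1/2 + 1/2))
  expect_equal(kd$pairwise$z, -2 / sqrt(5 / 3), tolerance = 1e-10)
  # identical distributions by permutation: tiny H
  set.seed(73)
  v <- rnorm(90)
  kd0 <- kruskal_dunn(v, sample(rep(c("A", "B", "C"), 30)))
  expect_lt(kd0$H, qchisq(0.99, 2))
  # one shifted group dominates the smallest pairwise p-values
  g <- rep(c("A", "B", "C"), each = 40)
  x <- rnorm(120) + ifelse(g == "C", 2, 0)
  kd1 <- kruskal_dunn(x, g, adjust = "holm")
  pw <- kd1$pairwise
  involved <- pw$a == "C" | pw$b == "C"
  expect_lt(max(pw$p[involved]), min(pw$p[!involved]))
  expect_true(all(pw$p_adj >= pw$p))
})

test_that("proportional-odds fit recovers thresholds and planted shifts", {
  # no covariate effect: thresholds equal the marginal cumulative logits
  set.seed(74)
  y <- rep(c(0, 1, 2), times = c(500, 300, 200))
  cl <- sample(c("A", "B"), 1000, TRUE)
  fit <- ordinal_fit(y, cl)
  expect_equal(unname(fit$thresholds[1]), 0, tolerance = 0.15)
  expect_equal(unname(fit$thresholds[2]), log(0.8 / 0.2), tolerance = 0.15)
  expect_lt(abs(fit$coef[["clusterB"]]), 0.25)
  expect_true(all(diff(fit$thresholds) > 0))
  expect_true(all(abs(rowSums(fit$fitted_probs) - 1) < 1e-8))

  # planted two-group shift beta = 1 recovered within 2 SE at n = 2000
  set.seed(75)
  n <- 2000
  grp <- rep(c(0, 1), each = n / 2)
  theta <- c(-1, 0.5, 2)
  u <- runif(n)
  cum <- plogis(outer(grp, theta, function(g, t) t - 1 * g))
  yy <- rowSums(u > cum)
  fit2 <- ordinal_fit(yy, factor(grp))
  beta_hat <- fit2$coef[[1]]
  se <- sqrt(diag(fit2$vcov))[[1]]
  expect_lt(abs(beta_hat - 1), 2 * se)
  expect_equal(fit2$global_wald$df, 1L)
  expect_lt(fit2$global_wald$p, 0.001)
})

test_that("sparse grade-0 levels merge into grade 1", {
  expect_equal(merge_sparse_levels(c(0, 1, 2, 3)), c(1, 1, 2, 3))
  expect_equal(merge_sparse_levels(c(1, 2, 3)), c(1, 2, 3))
  expect_warning(out <- merge_sparse_levels(c(0, 0, 0)), "collapse")
  expect_equal(out, c(1, 1, 1))
  expect_error(merge_sparse_levels(c(0, 4)))
})
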