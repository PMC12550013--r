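test_that("the default calibration carries the published marginals", {
  cfg <- default_calibration()
  expect_equal(unname(cfg$mixing),
               c(596, 761, 450, 402) / 2209, tolerance = 1e-12)
  expect_equal(unname(cfg$outcome$failure_1yr["JIP-hand"]), 0.16)
  expect_equal(unname(cfg$outcome$remission_1yr["JIP-hand"]), 0.557)
  expect_equal(unname(cfg$age_mean["JIP-hand"]), 66.4)
  # implied hand-vs-poly hazard ratio: closed form -log(1-F)/T ratio
  lam <- failure_rates(cfg)
  expect_equal(unname(lam["JIP-hand"] / lam["JIP-poly"]),
               log(0.84) / log(0.70), tolerance = 1e-12)
  expect_equal(unname(lam["JIP-hand"] / lam["JIP-poly"]), 0.489,
               tolerance = 0.001)
})

test_that("generation is reproducible and respects degenerate mixing", {
  cfg <- default_calibration(n_patients = 40L)
  expect_identical(generate_cohort(cfg, seed = 5)$data,
                   generate_cohort(cfg, seed = 5)$data)
  co <- generate_cohort(one_cluster_config("JIP-foot", 30L), seed = 5)
  expect_true(all(co$data$true_label == "JIP-foot"))
  expect_warning(generate_cohort(default_calibration(n_patients = 3L), seed = 1),
                 "fewer patients")
})

test_that("symmetry coupling controls left-right dependence", {
  cfg1 <- one_cluster_config("JIP-poly", 300L)
  cfg1$joints$rho[] <- 1
  co <- generate_cohort(cfg1, seed = 2)
  pairs <- unique(co$atlas$name)
  for (pref in c("tender_", "swollen_")) {
    l <- as.matrix(co$data[, paste0(pref, "L_", pairs)])
    r <- as.matrix(co$data[, paste0(pref, "R_", pairs)])
    expect_true(all(l == r))
  }
  cfg0 <- one_cluster_config("JIP-poly", 4000L)
  cfg0$joints$rho[] <- 0
  co0 <- generate_cohort(cfg0, seed = 2)
  l <- as.matrix(co0$data[, paste0("tender_L_", pairs)]) * 1
  r <- as.matrix(co0$data[, paste0("tender_R_", pairs)]) * 1
  expect_lt(mean(abs(diag(cor(l, r)))), 0.05)
})

test_that("involvement structure and marginal rates match the field", {
  cfg <- one_cluster_config("JIP-foot", 4000L)
  co <- generate_cohort(cfg, seed = 6)
  tm <- as.matrix(co$data[, grep("^tender_", names(co$data))])
  sm <- as.matrix(co$data[, grep("^swollen_", names(co$data))])
  inv <- tm | sm
  # every involved joint that is not swollen must be tender
  expect_true(all(tm[inv & !sm]))
  # tenderness conditional on swelling matches its configured probability
  expect_lt(abs(mean(tm[sm]) - cfg$joints$p_tender_given_swollen), 0.02)
  # per-region involvement rates match the configured field
  rates <- cfg$joints$region_rate[["JIP-foot"]]
  for (reg in names(rates)) {
    cols <- co$atlas$region == reg
    expect_lt(abs(mean(inv[, cols]) - rates[reg]), 0.02)
  }
  # tenderness is more likely than swelling (TJC >= SJC in median)
  jc <- joint_counts(co)
  expect_gte(median(jc$tjc44), median(jc$sjc44))
  # conditional swelling rate
  expect_lt(abs(mean(sm[inv]) -
                 cfg$joints$p_swollen_given_involved["JIP-foot"]), 0.02)
})

test_that("generated cohorts are complete-case by construction", {
  co <- small_cohort(n = 150L, seed = 13L, outcomes = TRUE, synovium = TRUE)
  res <- filter_complete_cases(co)
  expect_equal(nrow(res$cohort$data), 150L)
  expect_length(res$report, 0L)
})

test_that("joint count medians reproduce the per-phenotype calibration", {
  co <- small_cohort(n = 4000L, seed = 21L)
  jc <- joint_counts(co)
  med <- sapply(split(jc$sjc44, co$data$true_label), median)
  expect_lte(abs(med[["JIP-poly"]] - 15), 1)
  expect_lte(abs(med[["JIP-oligo"]] - 2), 1)
  medt <- sapply(split(jc$tjc44, co$data$true_label), median)
  expect_lte(abs(medt[["JIP-poly"]] - 22), 1.5)
})

test_that("outcome simulation matches the planted rates", {
  cfg0 <- one_cluster_config("JIP-hand", 300L)
  cfg0$outcome$failure_1yr[] <- 0
  co0 <- generate_outcomes(generate_cohort(cfg0, seed = 3), cfg0, seed = 4)
  expect_true(all(is.na(co0$data$switch_day)))

  cfg <- one_cluster_config("JIP-hand", 4000L)
  co <- generate_outcomes(generate_cohort(cfg, seed = 3), cfg, seed = 4)
  fail1yr <- mean(!is.na(co$data$switch_day) & co$data$switch_day <= 365)
  expect_lt(abs(fail1yr - 0.16), 0.02)
  expect_true(all(co$data$followup_days >= 365))
  sv <- mtx_survival(co)
  expect_true(all(sv$time > 0))
  expect_true(all(sv$event %in% 0:1))
  # remission by LOCF at one year matches the planted fraction
  rem <- cohort_remission(co)
  expect_lt(abs(mean(rem$remission) - 0.557), 0.025)
  expect_error(generate_outcomes(jip_cohort(co$data[, setdiff(names(co$data),
                                                              "true_label")]),
                                 cfg), "true_label")
})

test_that("synovium grades follow the planted proportional-odds shifts", {
  # equal severe fractions -> identical grade distributions across clusters
  cfg <- default_calibration(n_patients = 4000L)
  for (comp in names(cfg$synovium$severe)) cfg$synovium$severe[[comp]][] <- 0.2
  co <- generate_synovium(generate_cohort(cfg, seed = 7), cfg, seed = 8)
  tab <- prop.table(table(co$data$true_label, co$data$krenn_lining), 1)
  expect_lt(max(abs(sweep(tab, 2, colMeans(tab)))), 0.05)

  cfgp <- one_cluster_config("JIP-poly", 4000L)
  cop <- generate_synovium(generate_cohort(cfgp, seed = 7), cfgp, seed = 8)
  expect_lt(abs(mean(cop$data$krenn_lining == 3) - 0.438), 0.025)
  expect_true(all(cop$data$krenn_total ==
                    cop$data$krenn_lining + cop$data$krenn_stromal +
                    cop$data$krenn_infiltrate))
  expect_true(all(cop$data$krenn_total >= 0 & cop$data$krenn_total <= 9))
})
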