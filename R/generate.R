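#' Generate a synthetic early-arthritis cohort with planted phenotypes
#'
#' Draws a labelled baseline cohort from the four-component mixture described
#' by a [default_calibration()] configuration. Each patient first receives a
#' phenotype label, then demographics, serology (via a correlated bivariate
#' latent for RF/ACPA), truncated-Gaussian blood labs, log-normal ESR, and
#' per-joint involvement. Joint involvement uses a per-region probability
#' field with left-right symmetry: each joint pair shares a Gaussian latent
#' with loading `sqrt(rho)`, so `rho = 1` forces identical sides and
#' `rho = 0` makes them independent. Swollen status is drawn conditionally on
#' involvement and tenderness conditionally on swelling, so that every
#' involved joint is tender or swollen and tender counts exceed swollen
#' counts in median.
#'
#' @param config a `jip_calibration`.
#' @param seed integer seed; defaults to the seed stored in `config`.
#' @return A `jip_cohort` whose table carries a `true_label` column.
#' @export
generate_cohort <- function(config = default_calibration(), seed = config$seed) {
  stopifnot(inherits(config, "jip_calibration"))
  n <- config$n_patients
  if (n < length(config$clusters) && all(config$mixing > 0)) {
    warning("fewer patients than mixture components; some phenotypes absent")
  }
  set.seed(seed)
  atlas <- joint_atlas()
  labels <- sample(config$clusters, n, replace = TRUE, prob = config$mixing)

  d <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                  stringsAsFactors = FALSE)
  d$age <- d$sex <- d$rf <- d$acpa <- NA
  d$hb <- d$ht <- d$leuko <- d$thrombo <- d$esr <- NA_real_
  for (cl in tender_cols(atlas)) d[[cl]] <- NA
  for (cl in swollen_cols(atlas)) d[[cl]] <- NA

  pair_names <- unique(atlas$name)              # 22 bilateral pairs
  pair_region <- vapply(pair_names, function(nm) {
    atlas$region[match(nm, atlas$name)]
  }, character(1))

  for (cl in config$clusters) {
    idx <- which(labels == cl)
    m <- length(idx)
    if (m == 0L) next
    d$age[idx] <- rtruncnorm(m, config$age_mean[cl], config$age_sd[cl], 18, 100)
    d$sex[idx] <- ifelse(stats::runif(m) < config$female[cl], "female", "male")
    # RF/ACPA share a Gaussian latent with the configured association
    r <- config$rf_acpa_assoc
    z1 <- stats::rnorm(m)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(m)
    d$rf[idx] <- z1 < stats::qnorm(config$rf[cl])
    d$acpa[idx] <- z2 < stats::qnorm(config$acpa[cl])
    for (lab in names(config$labs)) {
      lb <- config$labs[[lab]]
      d[[lab]][idx] <- rtruncnorm(m, lb$mean[cl], lb$sd, lb$lower, lb$upper)
    }
    d$esr[idx] <- exp(stats::rnorm(m, config$esr$log_median[cl],
                                   config$esr$log_sd[cl]))
    # joint involvement field with left-right symmetry coupling
    rho <- config$joints$rho[cl]
    rates <- config$joints$region_rate[[cl]]
    p_pair <- pmin(1, pmax(0, rates[pair_region] *
                             config$joints$joint_modifier[pair_names]))
    thr <- stats::qnorm(p_pair)                  # length 22
    # shared pair latents: involvement, swelling and tenderness each mix a
    # pair-shared and a side-specific Gaussian, so rho = 1 makes all flags
    # of a pair identical across sides and rho = 0 makes sides independent
    u_inv <- matrix(stats::rnorm(m * 22L), m, 22L)
    u_sw <- matrix(stats::rnorm(m * 22L), m, 22L)
    u_tn <- matrix(stats::rnorm(m * 22L), m, 22L)
    thr_sw <- stats::qnorm(config$joints$p_swollen_given_involved[cl])
    thr_tn <- stats::qnorm(config$joints$p_tender_given_swollen)
    for (side in c("L", "R")) {
      mix <- function(u) sqrt(rho) * u +
        sqrt(1 - rho) * matrix(stats::rnorm(m * 22L), m, 22L)
      involved <- sweep(mix(u_inv), 2L, thr, `<`)
      swollen <- involved & (mix(u_sw) < thr_sw)
      tender <- involved & (!swollen | (mix(u_tn) < thr_tn))
      cols_t <- paste0("tender_", side, "_", pair_names)
      cols_s <- paste0("swollen_", side, "_", pair_names)
      d[idx, cols_t] <- tender
      d[idx, cols_s] <- swollen
    }
  }
  d$physician_id <- sprintf("MD%02d",
                            sample.int(config$n_physicians, n, replace = TRUE))
  d$symptom_duration <- round(exp(stats::rnorm(
    n, log(c(`JIP-foot` = 143, `JIP-oligo` = 186, `JIP-hand` = 101,
             `JIP-poly` = 147))[labels], 1.2)))
  d$true_label <- labels
  jip_cohort(d, atlas = atlas,
             provenance = sprintf("synthetic (seed %d)", seed))
}

# truncated normal via inverse-CDF sampling
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

#' Simulate treatment and remission outcomes for a labelled cohort
#'
#' Fills the longitudinal outcome columns of a synthetic cohort. Methotrexate
#' failure times are exponential with per-cluster daily rate
#' `-log(1 - F_c)/365`, so the one-year failure fraction equals the
#' configured `F_c`; administrative censoring uses a log-normal follow-up
#' (floored at 365 days, matching the one-year ascertainment requirement).
#' DAS44 series are simulated on a quarterly visit grid so that the one-year
#' last-observation-carried-forward remission probability equals the
#' configured `R_c`. Failure and remission processes are drawn independently.
#'
#' @param cohort a labelled `jip_cohort` (from [generate_cohort()]).
#' @param config the calibration used; defaults to [default_calibration()].
#' @param seed integer seed.
#' @return The cohort with `drug`, `switch_day`, `followup_days` and
#'   `das_day_*`/`das_val_*` columns filled.
#' @export
generate_outcomes <- function(cohort, config = default_calibration(),
                              seed = config$seed + 1L) {
  stopifnot(inherits(cohort, "jip_cohort"))
  if (is.null(cohort$data$true_label)) {
    stop("precondition error: cohort has no true_label column")
  }
  set.seed(seed)
  d <- cohort$data
  n <- nrow(d)
  lab <- d$true_label
  lambda <- failure_rates(config)[lab]
  t_fail <- -log(stats::runif(n)) / lambda   # Inf when the rate is 0
  followup <- pmax(config$outcome$followup_min,
                   exp(stats::rnorm(n, config$outcome$followup_log_median[lab],
                                    config$outcome$followup_log_sd[lab])))
  followup <- round(followup)
  event <- t_fail <= followup
  d$drug <- "MTX"
  d$switch_day <- ifelse(event, pmax(1, pmin(round(t_fail), followup)), NA)
  d$followup_days <- followup

  # DAS44 series: day-0 baseline from the generated joint counts and ESR,
  # then quarterly visits; remitters cross 1.6 at a random visit >= 180 d.
  jc <- joint_counts(cohort)
  das0 <- compute_das(jc$tjc44, jc$sjc44, d$esr, "das44_3")
  remit <- stats::runif(n) < config$outcome$remission_1yr[lab]
  visits <- config$outcome$visit_days
  nv <- length(visits)
  onset <- sample(2:nv, n, replace = TRUE)      # remission visit index
  vals <- matrix(NA_real_, n, nv)
  for (j in seq_len(nv)) {
    frac <- j / nv
    # declining trajectory toward a non-remission plateau
    target <- das0 * (1 - 0.35 * frac) + stats::rnorm(n, 0, 0.25)
    target <- pmax(1.62, target)
    vals[, j] <- target
    rem_now <- remit & (j >= onset)
    vals[rem_now, j] <- stats::runif(sum(rem_now), 0.6, 1.55)
  }
  d$das_day_1 <- 0
  d$das_val_1 <- das0
  for (j in seq_len(nv)) {
    d[[paste0("das_day_", j + 1L)]] <- visits[j]
    d[[paste0("das_val_", j + 1L)]] <- vals[, j]
  }
  cohort$data <- d
  cohort
}

#' Simulate Krenn synovitis grades for a labelled cohort
#'
#' Draws each Krenn component (lining-layer hyperplasia, stromal density,
#' inflammatory infiltrate) from a proportional-odds model over grades 0-3
#' with shared cutpoints and per-cluster latent shifts pinned by the severe
#' (grade 3) fractions in the calibration, e.g. severe lining hyperplasia in
#' 43.8% of JIP-poly vs 14.3% of JIP-oligo patients. The total Krenn score
#' is the component sum on the 0-9 scale.
#'
#' @inheritParams generate_outcomes
#' @return The cohort with `krenn_lining`, `krenn_stromal`,
#'   `krenn_infiltrate` and `krenn_total` columns filled.
#' @export
generate_synovium <- function(cohort, config = default_calibration(),
                              seed = config$seed + 2L) {
  stopifnot(inherits(cohort, "jip_cohort"))
  if (is.null(cohort$data$true_label)) {
    stop("precondition error: cohort has no true_label column")
  }
  set.seed(seed)
  d <- cohort$data
  lab <- d$true_label
  th <- config$synovium$thresholds
  for (comp in names(config$synovium$severe)) {
    sev <- config$synovium$severe[[comp]][lab]
    eta <- th[3] + stats::qlogis(sev)            # P(grade 3) = sev exactly
    cum <- outer(eta, th, function(e, t) stats::plogis(t - e)) # n x 3
    u <- stats::runif(nrow(d))
    d[[paste0("krenn_", comp)]] <- rowSums(u > cum)
  }
  d$krenn_total <- d$krenn_lining + d$krenn_stromal + d$krenn_infiltrate
  cohort$data <- d
  cohort
}

#' Survival-format view of methotrexate outcomes
#'
#' Extracts a tidy time/event table for survival analysis from a cohort with
#' filled outcome columns: `time` is the switch day for failures, otherwise
#' the follow-up day; `event` marks MTX failure. Baseline covariates and the
#' grouping label (planted `true_label` unless a fitted `cluster_label` is
#' present and `use` says otherwise) are attached.
#'
#' @param cohort a `jip_cohort` with outcome columns.
#' @param use which label column to group by: `"true_label"` or
#'   `"cluster_label"`.
#' @param horizon optional administrative cut at this many days (events after
#'   it are censored); `NULL` for none.
#' @return data.frame with `time`, `event`, `group` and covariates.
#' @export
mtx_survival <- function(cohort, use = c("true_label", "cluster_label"),
                         horizon = NULL) {
  use <- match.arg(use)
  d <- cohort$data
  if (is.null(d$followup_days)) stop("cohort has no outcome columns")
  event <- !is.na(d$switch_day)
  time <- ifelse(event, d$switch_day, d$followup_days)
  if (!is.null(horizon)) {
    over <- time > horizon
    event[over] <- FALSE
    time[over] <- horizon
  }
  jc <- joint_counts(cohort)
  data.frame(
    patient_id = d$patient_id,
    time = pmax(time, 0.5),
    event = as.integer(event),
    group = d[[use]],
    age = d$age, sex = d$sex, rf = d$rf, acpa = d$acpa,
    sjc = jc$sjc44, tjc = jc$tjc44,
    das_baseline = compute_das(jc$tjc44, jc$sjc44, d$esr, "das44_3"),
    stringsAsFactors = FALSE
  )
}
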