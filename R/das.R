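#' Tender and swollen joint counts per patient
#'
#' Computes, for every patient of a cohort, joint counts over the full
#' 44-joint atlas and its 28-joint DAS subset, plus the number of *involved*
#' joints (tender OR swollen) in the hand region (wrists, MCPs, PIPs; max 22)
#' and the foot region (ankles, MTPs; max 12).
#'
#' @param cohort a `jip_cohort` (joint flags must be complete).
#' @return data.frame with columns `patient_id`, `tjc44`, `sjc44`, `tjc28`,
#'   `sjc28`, `hand_count`, `foot_count`.
#' @export
joint_counts <- function(cohort) {
  stopifnot(inherits(cohort, "jip_cohort"))
  atlas <- cohort$atlas
  tj <- as.matrix(cohort$data[, tender_cols(atlas), drop = FALSE]) * 1
  sw <- as.matrix(cohort$data[, swollen_cols(atlas), drop = FALSE]) * 1
  inv <- (tj | sw) * 1
  d28 <- atlas$das28
  data.frame(
    patient_id = cohort$data$patient_id,
    tjc44 = rowSums(tj),
    sjc44 = rowSums(sw),
    tjc28 = rowSums(tj[, d28, drop = FALSE]),
    sjc28 = rowSums(sw[, d28, drop = FALSE]),
    hand_count = rowSums(inv[, atlas$region == "hand", drop = FALSE]),
    foot_count = rowSums(inv[, atlas$region == "foot", drop = FALSE]),
    stringsAsFactors = FALSE
  )
}

#' Three-component disease activity scores
#'
#' Evaluates the ESR-based three-component DAS formulas:
#' \deqn{DAS28(3) = 1.08 (0.56 \sqrt{TJC28} + 0.28 \sqrt{SJC28} +
#'   0.70 \ln ESR) + 0.16}
#' \deqn{DAS44(3) = 0.54 \sqrt{RAI} + 0.065\, SJC44 + 0.33 \ln ESR + 0.22}
#' With binary tenderness data the Ritchie articular index (RAI) is
#' approximated by the 44-joint tender count (one grade per tender joint).
#' ESR is clamped below at 1 mm/hr (lab floor) before taking the log.
#' Remission is defined as DAS44 below 1.6 (strict inequality).
#'
#' @param tjc tender joint count for the scheme (TJC44 or TJC28).
#' @param sjc swollen joint count for the scheme.
#' @param esr erythrocyte sedimentation rate, mm/hr.
#' @param scheme `"das44_3"` or `"das28_3"`.
#' @return Numeric DAS value(s); vectorised over the inputs.
#' @examples
#' compute_das(0, 0, 1, "das28_3")    # 0.16
#' compute_das(11, 10, 28, "das28_3") # about 5.64
#' @export
compute_das <- function(tjc, sjc, esr, scheme = c("das44_3", "das28_3")) {
  scheme <- match.arg(scheme)
  if (any(tjc < 0) || any(sjc < 0)) stop("domain error: negative joint counts")
  if (any(esr < 0)) stop("domain error: negative ESR")
  maxc <- if (scheme == "das44_3") 44 else 28
  if (any(tjc > maxc) || any(sjc > maxc)) {
    stop("domain error: joint count exceeds ", maxc, " for scheme ", scheme)
  }
  le <- log(pmax(esr, 1))
  if (scheme == "das28_3") {
    1.08 * (0.56 * sqrt(tjc) + 0.28 * sqrt(sjc) + 0.70 * le) + 0.16
  } else {
    0.54 * sqrt(tjc) + 0.065 * sjc + 0.33 * le + 0.22
  }
}

#' DAS44 remission flag
#' @param das44 DAS44(3) value(s).
#' @return Logical: `das44 < 1.6`.
#' @export
das44_remission <- function(das44) das44 < 1.6
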