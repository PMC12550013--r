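#' The 44-joint atlas used for joint involvement assessment
#'
#' Defines the bilateral 44-joint scheme underlying the DAS44: for each side,
#' the sternoclavicular, acromioclavicular, shoulder, elbow, wrist, MCP 1-5,
#' PIP 1-5, knee, ankle and MTP 1-5 joints. The 28-joint DAS subset (shoulders,
#' elbows, wrists, MCPs, PIPs, knees) is flagged, and each joint carries a
#' region tag used by the synthetic generator and prevalence summaries:
#' `hand` (wrist + MCP + PIP, 22 joints), `foot` (ankle + MTP, 12 joints),
#' `large` (shoulder, elbow, knee) and `other` (sterno-/acromioclavicular).
#'
#' @return A data.frame with one row per joint and columns `joint_id`
#'   (e.g. `"L_MTP1"`), `side` (`"L"`/`"R"`), `name`, `region` and `das28`
#'   (logical, membership in the 28-joint subset).
#' @examples
#' atlas <- joint_atlas()
#' nrow(atlas)          # 44
#' sum(atlas$das28)     # 28
#' table(atlas$region)
#' @export
joint_atlas <- function() {
  names_one_side <- c("SC", "AC", "shoulder", "elbow", "wrist",
                      paste0("MCP", 1:5), paste0("PIP", 1:5),
                      "knee", "ankle", paste0("MTP", 1:5))
  region_of <- function(nm) {
    if (nm %in% c("wrist", paste0("MCP", 1:5), paste0("PIP", 1:5))) "hand"
    else if (nm %in% c("ankle", paste0("MTP", 1:5))) "foot"
    else if (nm %in% c("shoulder", "elbow", "knee")) "large"
    else "other"
  }
  das28_of <- function(nm) {
    nm %in% c("shoulder", "elbow", "wrist", paste0("MCP", 1:5),
              paste0("PIP", 1:5), "knee")
  }
  side <- rep(c("L", "R"), each = length(names_one_side))
  name <- rep(names_one_side, times = 2)
  atlas <- data.frame(
    joint_id = paste(side, name, sep = "_"),
    side = side,
    name = name,
    region = vapply(name, region_of, character(1)),
    das28 = vapply(name, das28_of, logical(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  stopifnot(nrow(atlas) == 44L, sum(atlas$das28) == 28L,
            sum(atlas$region == "hand") == 22L,
            sum(atlas$region == "foot") == 12L,
            !anyDuplicated(atlas$joint_id))
  atlas
}

#' @keywords internal
tender_cols <- function(atlas) paste0("tender_", atlas$joint_id)

#' @keywords internal
swollen_cols <- function(atlas) paste0("swollen_", atlas$joint_id)
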