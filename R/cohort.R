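#' Construct a patient cohort
#'
#' A cohort bundles a patient-level baseline table with the joint atlas that
#' defines its tender/swollen columns. The table holds one row per patient
#' with mandatory baseline fields (demographics, serology, blood labs, ESR,
#' 88 per-joint indicator columns) and optional longitudinal outcome columns
#' (treatment, switch day, follow-up, DAS series, Krenn synovitis grades).
#'
#' @param data data.frame with one row per patient (see [cohort_schema()]).
#' @param atlas joint atlas, default [joint_atlas()].
#' @param provenance free-text label recording where the table came from.
#' @return An object of class `jip_cohort`: a list with elements `data`,
#'   `atlas` and `provenance`.
#' @seealso [load_cohort()], [write_cohort()], [filter_complete_cases()]
#' @export
jip_cohort <- function(data, atlas = joint_atlas(), provenance = "") {
  stopifnot(is.data.frame(data))
  mand <- mandatory_columns(atlas)
  missing_cols <- setdiff(mand, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- unique(data$patient_id[duplicated(data$patient_id)])
  if (length(dup) > 0L) {
    stop("cohort validation error: duplicated patient_id(s): ",
         paste(dup, collapse = ", "))
  }
  validate_ranges(data)
  obj <- list(data = data, atlas = atlas, provenance = provenance)
  class(obj) <- "jip_cohort"
  obj
}

#' Mandatory baseline columns for a cohort table
#' @param atlas joint atlas.
#' @return Character vector of column names.
#' @export
mandatory_columns <- function(atlas = joint_atlas()) {
  c("patient_id", "age", "sex", "rf", "acpa",
    "hb", "ht", "leuko", "thrombo", "esr",
    tender_cols(atlas), swollen_cols(atlas))
}

# Range invariants on non-missing entries; NAs are tolerated here and
# handled by filter_complete_cases().
validate_ranges <- function(data) {
  chk <- function(ok, what) {
    bad <- which(!ok & !is.na(ok))
    if (length(bad) > 0L) {
      stop("cohort validation error: ", what, " violated for patient(s): ",
           paste(utils::head(data$patient_id[bad], 5L), collapse = ", "))
    }
  }
  chk(data$esr >= 0, "esr >= 0")
  for (lab in c("hb", "ht", "leuko", "thrombo")) chk(data[[lab]] > 0, paste(lab, "> 0"))
  chk(data$age >= 18 & data$age <= 100, "18 <= age <= 100")
  if ("followup_days" %in% names(data)) chk(data$followup_days >= 0, "followup_days >= 0")
  if (all(c("switch_day", "followup_days") %in% names(data))) {
    chk(is.na(data$switch_day) | (data$switch_day >= 0 &
        data$switch_day <= data$followup_days), "0 <= switch_day <= followup_days")
  }
  sx <- data$sex[!is.na(data$sex)]
  if (!all(sx %in% c("female", "male"))) {
    stop("cohort validation error: sex must be 'female' or 'male'")
  }
  invisible(TRUE)
}

#' @export
print.jip_cohort <- function(x, ...) {
  cat("Patient cohort (", nrow(x$data), " patients, ",
      nrow(x$atlas), "-joint atlas)\n", sep = "")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  if ("true_label" %in% names(x$data)) {
    cat("planted labels:\n")
    print(table(x$data$true_label))
  }
  invisible(x)
}

#' Write a cohort to CSV
#'
#' Writes the patient table as comma-separated UTF-8 text. Numeric fields are
#' written with 17 significant digits so that a write/load round trip
#' reproduces every double bit-exactly.
#'
#' @param cohort a `jip_cohort`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "jip_cohort"))
  d <- cohort$data
  for (j in seq_along(d)) {
    if (is.double(d[[j]])) d[[j]] <- sprintf("%.17g", d[[j]])
    d[[j]][d[[j]] %in% c("NA", NA)] <- ""
  }
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Load a cohort from CSV
#'
#' Reads a baseline table in the package's cohort schema. Rows whose mandatory
#' fields contain unparseable text (non-numeric entries in numeric columns,
#' unknown sex/logical codes) are rejected with row-level diagnostics; empty
#' cells become `NA` and are left to [filter_complete_cases()]. A missing
#' mandatory column is a schema error; duplicated patient ids are a
#' validation error.
#'
#' @param path CSV file path.
#' @param atlas joint atlas the joint columns must match.
#' @return A `jip_cohort`.
#' @export
load_cohort <- function(path, atlas = joint_atlas()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "")
  mand <- mandatory_columns(atlas)
  missing_cols <- setdiff(mand, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  numeric_mand <- c("age", "hb", "ht", "leuko", "thrombo", "esr")
  logical_mand <- c("rf", "acpa", tender_cols(atlas), swollen_cols(atlas))
  bad <- rep(FALSE, nrow(raw))
  why <- rep("", nrow(raw))
  mark <- function(rows, msg) {
    bad[rows] <<- TRUE
    why[rows] <<- ifelse(nzchar(why[rows]), why[rows], msg)
  }
  parsed <- raw
  for (col in numeric_mand) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    mark(which(is.na(v) & !is.na(raw[[col]])), paste("unparseable", col))
    parsed[[col]] <- v
  }
  for (col in logical_mand) {
    v <- parse_flag(raw[[col]])
    mark(which(is.na(v) & !is.na(raw[[col]])), paste("unparseable", col))
    parsed[[col]] <- v
  }
  sx <- tolower(raw$sex)
  mark(which(!is.na(sx) & !(sx %in% c("female", "male"))), "unparseable sex")
  parsed$sex <- sx
  # optional numeric columns, parsed leniently (unparseable -> NA)
  opt_num <- intersect(c("symptom_duration", "switch_day", "followup_days",
                         "krenn_lining", "krenn_stromal", "krenn_infiltrate",
                         "krenn_total",
                         grep("^das_(day|val)_", names(raw), value = TRUE)),
                       names(raw))
  for (col in opt_num) parsed[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected: ",
            paste(sprintf("row %d (%s): %s", which(bad),
                          raw$patient_id[bad], why[bad]), collapse = "; "))
    parsed <- parsed[!bad, , drop = FALSE]
  }
  jip_cohort(parsed, atlas = atlas, provenance = path)
}

parse_flag <- function(x) {
  v <- rep(NA, length(x))
  v[x %in% c("TRUE", "true", "T", "1")] <- TRUE
  v[x %in% c("FALSE", "false", "F", "0")] <- FALSE
  v
}

#' Drop patients with incomplete baseline data
#'
#' Retains only patients with all labs, ESR, serology, age, sex and the full
#' tender/swollen joint vectors present, mirroring the complete-case rule of
#' the clustering pipeline. Incomplete longitudinal/outcome fields do not
#' cause exclusion.
#'
#' @param cohort a `jip_cohort`.
#' @return A list with `cohort` (the filtered cohort) and `report`, a named
#'   integer vector counting dropped patients per missing field (a patient
#'   missing several fields is counted under each).
#' @export
filter_complete_cases <- function(cohort) {
  stopifnot(inherits(cohort, "jip_cohort"))
  d <- cohort$data
  fields <- list(
    age = "age", sex = "sex", rf = "rf", acpa = "acpa",
    hb = "hb", ht = "ht", leuko = "leuko", thrombo = "thrombo", esr = "esr"
  )
  miss <- lapply(fields, function(col) is.na(d[[col]]))
  jt <- as.matrix(d[, tender_cols(cohort$atlas), drop = FALSE])
  js <- as.matrix(d[, swollen_cols(cohort$atlas), drop = FALSE])
  miss$joints <- apply(is.na(jt) | is.na(js), 1L, any)
  any_missing <- Reduce(`|`, miss)
  report <- vapply(miss, function(m) sum(m), integer(1))
  report <- report[report > 0L]
  out <- cohort
  out$data <- d[!any_missing, , drop = FALSE]
  if (nrow(out$data) == 0L) warning("complete-case filter removed every patient")
  list(cohort = out, report = report)
}
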