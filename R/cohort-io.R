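## Biometry cohort data model and CSV I/O.
##
## A cohort is a data.frame (class "biometry_cohort") with one validated row
## per eye. Internal column names drop the unit suffixes used on disk:
##   patient_id, eye, al, acd, lt, cct, k1, k2, wtw, pupil,
##   iol_model, iol_power, postop_se
## Units: mm for distances except cct (micrometres); diopters for k1/k2,
## iol_power and postop_se. The preoperative ACD is measured from the corneal
## epithelium to the crystalline lens front (optical-biometer convention);
## functions that need an endothelium-referenced depth subtract cct/1000
## internally. Missing optional values are NA, never 0.

# on-disk schema: disk name -> internal name
.cohort_schema <- c(
  patient_id = "patient_id", eye = "eye",
  al_mm = "al", acd_mm = "acd", lt_mm = "lt", cct_um = "cct",
  k1_d = "k1", k2_d = "k2", wtw_mm = "wtw", pupil_mm = "pupil",
  iol_model = "iol_model", iol_power_d = "iol_power", postop_se_d = "postop_se"
)
.cohort_required_values <- c("patient_id", "eye", "al", "acd", "lt", "k1", "k2")

#' Validate a biometry cohort
#'
#' Checks every row against the physiologic invariants: axial length in
#' \[15, 40\] mm, keratometry in \[30, 60\] D, ACD in \[1.5, 5.5\] mm, lens
#' thickness in \[2.5, 6.5\] mm, `acd + lt < al`, and CCT in \[400, 700\] um
#' when present. Validation is total: each row either passes all checks or
#' produces an error naming the offending patient.
#'
#' @param cohort data.frame with the internal cohort columns
#' @return the cohort, invisibly classed as `biometry_cohort`
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(unname(.cohort_schema), names(cohort))
  if (length(missing_cols)) {
    iolray_stop("iolray_schema_error",
                paste0("missing cohort column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  fail <- function(bad, what) {
    i <- which(bad)[1]
    if (is.na(i)) return(invisible())
    iolray_stop("iolray_validation_error",
                sprintf("row %d (patient %s): %s", i,
                        as.character(cohort$patient_id[i]), what),
                patient_id = as.character(cohort$patient_id[i]))
  }
  if (nrow(cohort)) {
    for (f in .cohort_required_values) {
      fail(is.na(cohort[[f]]), paste0("mandatory field '", f, "' is missing"))
    }
    fail(!cohort$eye %in% c("OD", "OS"), "eye must be OD or OS")
    fail(cohort$al < 15 | cohort$al > 40, "al outside [15, 40] mm")
    fail(cohort$acd < 1.5 | cohort$acd > 5.5, "acd outside [1.5, 5.5] mm")
    fail(cohort$lt < 2.5 | cohort$lt > 6.5, "lt outside [2.5, 6.5] mm")
    fail(cohort$acd + cohort$lt >= cohort$al, "acd + lt must be smaller than al")
    fail(cohort$k1 < 30 | cohort$k1 > 60, "k1 outside [30, 60] D")
    fail(cohort$k2 < 30 | cohort$k2 > 60, "k2 outside [30, 60] D")
    fail(!is.na(cohort$cct) & (cohort$cct < 400 | cohort$cct > 700),
         "cct outside [400, 700] um")
  }
  class(cohort) <- unique(c("biometry_cohort", class(cohort)))
  invisible(cohort)
}

#' Read a biometry cohort from CSV
#'
#' Expects a comma-separated, period-decimal, UTF-8 file with a mandatory
#' header row using the declared column names `patient_id, eye, al_mm,
#' acd_mm, lt_mm, cct_um, k1_d, k2_d, wtw_mm, pupil_mm, iol_model,
#' iol_power_d, postop_se_d`. Row order is preserved and every row is
#' validated (see [validate_cohort()]).
#'
#' @param path path to the CSV file
#' @return a `biometry_cohort` data.frame (possibly 0 rows)
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    iolray_stop("iolray_io_error", paste0("file not found: ", path))
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(.cohort_schema), names(raw))
  if (length(missing_cols)) {
    iolray_stop("iolray_schema_error",
                paste0("missing mandatory column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[, names(.cohort_schema), drop = FALSE]
  names(raw) <- unname(.cohort_schema)
  num_cols <- setdiff(names(raw), c("patient_id", "eye", "iol_model"))
  for (cl in num_cols) {
    x <- trimws(raw[[cl]])
    x[x == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(x))
    if (any(!is.na(x) & is.na(val))) {
      iolray_stop("iolray_validation_error",
                  sprintf("column %s contains non-numeric values", cl))
    }
    raw[[cl]] <- val
  }
  raw$iol_model[trimws(raw$iol_model) == ""] <- NA_character_
  if (nrow(raw) == 0) {
    class(raw) <- c("biometry_cohort", class(raw))
    return(raw)
  }
  validate_cohort(raw)
  class(raw) <- unique(c("biometry_cohort", class(raw)))
  raw
}

#' Write a biometry cohort to CSV
#'
#' Numeric fields are written with four decimals, so any value representable
#' at that precision round-trips bit-identically through
#' [read_cohort_csv()].
#'
#' @param cohort a `biometry_cohort` data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)[, unname(.cohort_schema), drop = FALSE]
  for (cl in setdiff(names(out), c("patient_id", "eye", "iol_model"))) {
    x <- sprintf("%.4f", out[[cl]])
    x[is.na(out[[cl]])] <- ""
    out[[cl]] <- x
  }
  out$iol_model[is.na(out$iol_model)] <- ""
  names(out) <- names(.cohort_schema)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.biometry_cohort <- function(x, ...) {
  cat(sprintf("<biometry_cohort> %d eyes, %d patients\n",
              nrow(x), length(unique(x$patient_id))))
  if (nrow(x)) {
    cat(sprintf("  AL %.2f-%.2f mm (mean %.2f), mean K %.2f D\n",
                min(x$al), max(x$al), mean(x$al), mean((x$k1 + x$k2) / 2)))
  }
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5))
  invisible(x)
}
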