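#' Read a calibration table of paired D/L values and calibrated ages
#'
#' Reads and validates a CSV of radiocarbon-dated (or live-collected)
#' calibration shells. Required columns: `specimen_id`, `dl_asp`, `dl_glu`,
#' `cal_age`, `cal_age_lo`, `cal_age_hi`, `live_collected`; optional:
#' `species`, `depth_top_cm`, `depth_bottom_cm`, `dl_ser`, `dl_ala`. Ages are
#' calendar years before the collection year (the reference core was
#' collected in 2013 AD, so its ages are years before 2013). D/L ratios may
#' be `NA` (e.g. shells dated by radiocarbon only) but where present must lie
#' in `[0, 1)`; the 95% bounds must bracket the age; live-collected shells
#' must have `cal_age <= liveAgeMax`.
#'
#' Validation failures report the offending data rows by line number.
#'
#' @param path CSV file path.
#' @param liveAgeMax maximum admissible age (years) for a live-collected
#'   shell.
#' @return data.frame of validated calibration specimens.
#' @seealso [brijuniCalibration()] for the bundled reference table.
#' @export
readCalibrationTable <- function(path, liveAgeMax = 5) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(x) == 0L) {
    warning("calibration table ", path, " is empty")
    return(x)
  }
  required <- c("specimen_id", "dl_asp", "dl_glu", "cal_age",
                "cal_age_lo", "cal_age_hi", "live_collected")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("calibration table is missing columns: ", paste(missing, collapse = ", "))
  x$live_collected <- as.logical(x$live_collected)
  .failRows <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      stop(sprintf("%s in calibration table rows %s", what,
                   paste(which(bad), collapse = ", ")))
    }
  }
  for (col in intersect(c("dl_asp", "dl_glu", "dl_ser", "dl_ala"), names(x))) {
    v <- x[[col]]
    .failRows(!is.na(v) & (v < 0 | v >= 1),
              sprintf("%s outside [0, 1)", col))
  }
  .failRows(x$cal_age < 0, "negative calibrated age")
  .failRows(x$cal_age_lo > x$cal_age | x$cal_age > x$cal_age_hi,
            "95% bounds do not bracket cal_age")
  .failRows(x$live_collected & x$cal_age > liveAgeMax,
            sprintf("live-collected shell older than %g yr", liveAgeMax))
  x
}

#' Bundled AMS-AAR calibration table for the Brijuni core
#'
#' The shipped calibration fixture: 13 dead-collected and 3 live-collected
#' *Timoclea ovata* with Asp and Glu D/L ratios and calibrated ages (years
#' before 2013 AD), plus 4 radiocarbon-only shells of large bivalves from the
#' mid-core shell bed. Live-collected shells are listed at age 1.
#'
#' @param onlyTimoclea drop the four radiocarbon-only shells of other species
#'   (default TRUE: they carry no D/L and cannot enter a kinetic fit).
#' @return data.frame of calibration specimens.
#' @examples
#' nrow(brijuniCalibration(onlyTimoclea = FALSE))  # 20
#' @export
brijuniCalibration <- function(onlyTimoclea = TRUE) {
  path <- system.file("extdata", "calibration_brijuni.csv",
                      package = "aarchron", mustWork = TRUE)
  x <- readCalibrationTable(path)
  if (onlyTimoclea) x <- x[!is.na(x$dl_asp), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Screening rules for calibration specimens
#'
#' Thresholds for flagging aberrant amino-acid measurements before
#' calibration. The defaults are conventions, not fitted values: serine
#' racemizes so fast that high Ser D/L in a young shell indicates
#' contamination or diagenetic alteration, and Asp racemizes faster than Glu
#' so their ratio should fall in a concordance band.
#'
#' @param serMax ceiling on `dl_ser` (NA disables).
#' @param aspGluRatio length-2 admissible band for `dl_asp / dl_glu`
#'   (NA disables).
#' @param dlCeiling ceiling on any D/L ratio (saturation guard).
#' @return named list of rules, as consumed by [screenOutliers()].
#' @export
screeningRules <- function(serMax = 0.8, aspGluRatio = c(1, 8),
                           dlCeiling = 1 - 1e-6) {
  list(serMax = serMax, aspGluRatio = aspGluRatio, dlCeiling = dlCeiling)
}

#' Screen calibration specimens for aberrant amino-acid values
#'
#' Partitions a calibration table into kept and flagged specimens under a
#' configurable rule set; each flagged record carries the name of the rule it
#' violated. Screening is idempotent: re-running on the kept set flags
#' nothing new. An empty rule set (`rules = list()`) keeps everything.
#'
#' @param points calibration data.frame (see [readCalibrationTable()]).
#' @param rules named list of thresholds, see [screeningRules()].
#' @return list with elements `kept` (data.frame) and `flagged` (data.frame
#'   with an extra `rule` column).
#' @export
screenOutliers <- function(points, rules = screeningRules()) {
  stopifnot(is.data.frame(points))
  rule <- rep(NA_character_, nrow(points))
  .flag <- function(bad, name) {
    bad <- !is.na(bad) & bad
    rule[is.na(rule) & bad] <<- name
  }
  if (!is.null(rules$dlCeiling) && !is.na(rules$dlCeiling)) {
    for (col in intersect(c("dl_asp", "dl_glu", "dl_ser", "dl_ala"),
                          names(points))) {
      .flag(points[[col]] > rules$dlCeiling, paste0(col, "_ceiling"))
    }
  }
  if (!is.null(rules$serMax) && !is.na(rules$serMax) && "dl_ser" %in% names(points)) {
    .flag(points$dl_ser > rules$serMax, "ser_max")
  }
  if (!is.null(rules$aspGluRatio) && !any(is.na(rules$aspGluRatio)) &&
      all(c("dl_asp", "dl_glu") %in% names(points))) {
    r <- points$dl_asp / points$dl_glu
    .flag(r < rules$aspGluRatio[1] | r > rules$aspGluRatio[2], "asp_glu_concordance")
  }
  flagged <- points[!is.na(rule), , drop = FALSE]
  if (nrow(flagged)) flagged$rule <- rule[!is.na(rule)] else flagged$rule <- character(0)
  list(kept = points[is.na(rule), , drop = FALSE], flagged = flagged)
}
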