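#' @import methods
#' @importFrom stats dlnorm dgamma qnorm qgamma quantile median var optim
#'   setNames rnorm rpois rlnorm wilcox.test complete.cases
#' @importFrom utils read.csv write.csv head
NULL

AMINO_ACIDS <- c("Asp", "Glu")
KINETIC_FAMILIES <- c("SPK", "CPK", "TDK", "APK")
UNCERTAINTY_MODELS <- c("lognormal", "gamma")

#' Fitted AAR calibration model
#'
#' Holds one point of the kinetic-model grid together with its
#' maximum-likelihood parameters on a set of paired D/L-radiocarbon
#' calibration shells.
#'
#' Parameter vector: `a` (rate scale, years), `b` (exponent, dimensionless;
#' fixed at 2 for the APK family), `dl0` (initial D/L at age zero), `d`
#' (dispersion of the age-uncertainty model: variance on the log-age scale
#' for lognormal, inverse shape for gamma). The `c` slot stores a
#' family-specific shape value where one exists; it is not a free parameter
#' of any fitted family here and defaults to `NA`.
#'
#' @slot amino "Asp" or "Glu".
#' @slot family one of "SPK", "CPK", "TDK", "APK".
#' @slot estimateInitial logical; was the initial D/L estimated (TRUE) or
#'   fixed at zero (FALSE)?
#' @slot uncertainty "lognormal" or "gamma".
#' @slot params named numeric vector (a, b, dl0, d).
#' @slot c family-specific shape value (NA when unused).
#' @slot logLik fitted log-likelihood.
#' @slot nobs number of calibration observations.
#' @slot df number of free parameters.
#' @slot converged logical.
#' @slot data the calibration points used (data.frame: specimen_id, dl, age,
#'   live_collected).
#' @export
setClass("AarCalibration",
  representation(
    amino = "character",
    family = "character",
    estimateInitial = "logical",
    uncertainty = "character",
    params = "numeric",
    c = "numeric",
    logLik = "numeric",
    nobs = "integer",
    df = "integer",
    converged = "logical",
    data = "data.frame"
  ),
  prototype(c = NA_real_, converged = TRUE)
)

setValidity("AarCalibration", function(object) {
  msg <- character()
  if (!object@amino %in% AMINO_ACIDS) msg <- c(msg, "amino must be 'Asp' or 'Glu'")
  if (!object@family %in% KINETIC_FAMILIES)
    msg <- c(msg, "family must be one of SPK, CPK, TDK, APK")
  if (!object@uncertainty %in% UNCERTAINTY_MODELS)
    msg <- c(msg, "uncertainty must be 'lognormal' or 'gamma'")
  p <- object@params
  if (!all(c("a", "b", "dl0", "d") %in% names(p)))
    msg <- c(msg, "params must contain a, b, dl0, d")
  else {
    if (!is.na(p["a"]) && p["a"] <= 0) msg <- c(msg, "a must be > 0")
    if (!is.na(p["b"]) && p["b"] <= 0) msg <- c(msg, "b must be > 0")
    if (!is.na(p["dl0"]) && (p["dl0"] < 0 || p["dl0"] >= 1))
      msg <- c(msg, "dl0 must lie in [0, 1)")
    if (!is.na(p["d"]) && p["d"] <= 0) msg <- c(msg, "d must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Ranked BIC comparison of AAR kinetic models
#'
#' @slot table data.frame, one row per attempted model, sorted ascending by
#'   BIC, with a `dBIC` column relative to the best model and a `status`
#'   column ("ok" or the failure message).
#' @slot fits list of `AarCalibration` objects (NULL where a fit failed),
#'   in the order of `table`.
#' @export
setClass("AarModelSelection",
  representation(table = "data.frame", fits = "list")
)

setValidity("AarModelSelection", function(object) {
  if (nrow(object@table) != length(object@fits))
    return("table rows and fits must align")
  TRUE
})

#' Depth-resolved molluscan death assemblage
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are taxa and
#' whose columns are depth increments ordered shallow to deep. The `counts`
#' assay holds individuals per taxon and increment (non-negative, possibly
#' fractional for plate-derived polyplacophoran counts); `colData` carries
#' `depth_top` and `depth_bottom` (cm, half-open `[top, bottom)`), and
#' `rowData` optionally carries the functional-trait table.
#'
#' @export
#' @import SummarizedExperiment
setClass("CoreAssemblage", contains = "SummarizedExperiment")

setValidity("CoreAssemblage", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  cts <- assay(object, "counts")
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  cd <- colData(object)
  if (!all(c("depth_top", "depth_bottom") %in% colnames(cd)))
    msg <- c(msg, "colData must contain depth_top and depth_bottom")
  else {
    if (any(cd$depth_top >= cd$depth_bottom))
      msg <- c(msg, "depth_top must be < depth_bottom")
    if (is.unsorted(cd$depth_top))
      msg <- c(msg, "increments must be ordered shallow to deep")
  }
  if (length(msg)) msg else TRUE
})
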