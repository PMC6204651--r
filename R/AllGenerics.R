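#' @include AllClasses.R
NULL

#' Convert D/L ratios to calendar ages
#'
#' @param object a fitted calibration (see [fitAarModel()]).
#' @param dl numeric vector of D/L ratios.
#' @param ... further arguments passed to methods.
#' @return A data.frame with columns `dl`, `age`, `pi_lo`, `pi_hi` (years
#'   before collection; 95% prediction interval).
#' @export
setGeneric("predictAge", function(object, dl, ...) standardGeneric("predictAge"))

#' Kinetic parameters of a fitted calibration
#' @param object an `AarCalibration`.
#' @return Named numeric vector with elements `a`, `b`, `dl0`, `d`.
#' @export
setGeneric("kineticParams", function(object) standardGeneric("kineticParams"))

#' Model label (e.g. "Asp TDK1 lognormal")
#' @param object an `AarCalibration`.
#' @export
setGeneric("modelLabel", function(object) standardGeneric("modelLabel"))

#' Increments-by-taxa abundance matrix
#'
#' Returns the community matrix with depth increments as rows (shallow to
#' deep) and taxa as columns, the orientation expected by vegan.
#' @param x a `CoreAssemblage`.
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))

#' Depth intervals of the increments of an assemblage
#' @param x a `CoreAssemblage`.
#' @return data.frame with columns `depth_top`, `depth_bottom` (cm below the
#'   sediment-water interface; half-open `[top, bottom)` intervals).
#' @export
setGeneric("depthIntervals", function(x) standardGeneric("depthIntervals"))

#' Best model of a model-selection run
#' @param object an `AarModelSelection`.
#' @export
setGeneric("bestModel", function(object) standardGeneric("bestModel"))

#' Ranked model-comparison table
#' @param object an `AarModelSelection`.
#' @export
setGeneric("selectionTable", function(object) standardGeneric("selectionTable"))
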