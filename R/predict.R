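#' @describeIn predictAge convert D/L ratios to calendar ages under a fitted
#'   calibration.
#'
#' The point age is the kinetic model age at `dl` (for the TDK family this
#' is `a * arctanh((dl - dl0)/(1 - dl*dl0))^b`); ages are years before the
#' collection year (2013 AD for the reference core). The 95% prediction
#' interval follows the fitted uncertainty model: for lognormal uncertainty
#' `exp(log(age) +/- 1.96 * sqrt(d))`, for gamma uncertainty the 2.5% and
#' 97.5% quantiles of a gamma with mean `age` and shape `1/d`. At
#' `dl = dl0` the age and both bounds are 0. D/L values within `1e-6` of
#' racemic equilibrium are rejected rather than extrapolated.
#'
#' @param specimen optional labels used in error messages.
#' @export
setMethod("predictAge", "AarCalibration", function(object, dl, specimen = NULL,
                                                   ...) {
  stopifnot(is.numeric(dl))
  p <- object@params
  sat <- which(dl > 1 - 1e-6)
  if (length(sat)) {
    stop("D/L within 1e-6 of racemic equilibrium; age saturates and cannot ",
         "be estimated", .specimenSuffix(specimen, sat))
  }
  bad <- which(dl < p[["dl0"]])
  if (length(bad)) {
    stop(sprintf("D/L ratio below the fitted initial value dl0 = %g",
                 p[["dl0"]]), .specimenSuffix(specimen, bad))
  }
  age <- .kineticAge(dl, object@family, p[["a"]], p[["b"]], p[["dl0"]],
                     specimen = specimen)
  if (object@uncertainty == "lognormal") {
    z <- qnorm(0.975)
    lo <- age * exp(-z * sqrt(p[["d"]]))
    hi <- age * exp(z * sqrt(p[["d"]]))
  } else {
    shape <- 1 / p[["d"]]
    lo <- ifelse(age > 0, qgamma(0.025, shape = shape, rate = shape / age), 0)
    hi <- ifelse(age > 0, qgamma(0.975, shape = shape, rate = shape / age), 0)
  }
  zero <- age == 0
  lo[zero] <- hi[zero] <- 0
  data.frame(dl = dl, age = age, pi_lo = lo, pi_hi = hi)
})
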