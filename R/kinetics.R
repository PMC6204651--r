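#' Initial-value (Mobius) rescaling of a D/L ratio
#'
#' Racemization of an amino acid with racemic equilibrium at D/L = 1 follows
#' first-order reversible kinetics in the arctanh-transformed ratio. A shell
#' that starts life at a non-zero D/L value `dl0` is brought back to a common
#' origin by the Mobius rescaling
#' \deqn{u = \frac{DL - DL_0}{1 - DL \cdot DL_0},}
#' the subtraction rule of the tanh group: `u` is the racemization extent
#' accumulated since age zero. `mobiusTransform()` returns
#' `arctanh(u)`, the transformed extent on which the kinetic families
#' operate; it is 0 at `dl = dl0`, strictly increasing in `dl`, and diverges
#' as `dl` approaches equilibrium.
#'
#' @param dl numeric vector of observed D/L ratios, in `[dl0, 1)`.
#' @param dl0 initial D/L at age zero, in `[0, 1)`.
#' @param specimen optional vector of specimen labels used in error messages.
#' @return `arctanh((dl - dl0) / (1 - dl * dl0))`.
#' @examples
#' mobiusTransform(0.110, 0.02071817)
#' @export
mobiusTransform <- function(dl, dl0, specimen = NULL) {
  stopifnot(is.numeric(dl), is.numeric(dl0), length(dl0) == 1L)
  if (dl0 < 0 || dl0 >= 1) stop("dl0 must lie in [0, 1)")
  bad <- which(dl >= 1)
  if (length(bad)) {
    stop("D/L ratio at or beyond racemic equilibrium (>= 1)",
         .specimenSuffix(specimen, bad))
  }
  bad <- which(dl < dl0)
  if (length(bad)) {
    stop(sprintf("D/L ratio below the initial value dl0 = %g", dl0),
         .specimenSuffix(specimen, bad))
  }
  atanh((dl - dl0) / (1 - dl * dl0))
}

.specimenSuffix <- function(specimen, idx) {
  if (is.null(specimen)) {
    sprintf(" (element %s)", paste(idx, collapse = ", "))
  } else {
    sprintf(" (specimen %s)", paste(specimen[idx], collapse = ", "))
  }
}

# Kinetic family ladder, all defined on the Mobius-rescaled extent
# u = (dl - dl0) / (1 - dl * dl0):
#   APK  t = a * u^2                  (apparent parabolic; exponent fixed)
#   SPK  t = a * u^b                  (simple power law)
#   CPK  t = a * (-log(1 - u))^b      (first-order irreversible approach)
#   TDK  t = a * arctanh(u)^b         (first-order reversible, time-dependent
#                                      apparent rate)
# TDK is the family of the printed calibration equation
# t = a * arctanh((DL - DL0)/(1 - DL*DL0))^b.
.extentTransform <- function(family) {
  switch(family,
    SPK = function(u) u,
    APK = function(u) u,
    CPK = function(u) -log1p(-u),
    TDK = function(u) atanh(u),
    stop("unknown kinetic family: ", family)
  )
}

.extentInverse <- function(family) {
  switch(family,
    SPK = function(x) x,
    APK = function(x) x,
    CPK = function(x) -expm1(-x),
    TDK = function(x) tanh(x),
    stop("unknown kinetic family: ", family)
  )
}

#' Forward kinetic age of a D/L value (inverse calibration curve)
#'
#' Internal work-horse: model age in years at D/L `dl` for a given family
#' and parameter set. Vectorized over `dl`.
#' @noRd
.kineticAge <- function(dl, family, a, b, dl0, specimen = NULL) {
  u <- (dl - dl0) / (1 - dl * dl0)
  if (any(dl < dl0)) {
    stop(sprintf("D/L ratio below the initial value dl0 = %g", dl0),
         .specimenSuffix(specimen, which(dl < dl0)))
  }
  x <- .extentTransform(family)(u)
  if (family == "APK") a * x^2 else a * x^b
}

#' D/L value at a given true age (forward racemization curve)
#' @noRd
.kineticDl <- function(age, family, a, b, dl0) {
  x <- if (family == "APK") sqrt(age / a) else (age / a)^(1 / b)
  u <- .extentInverse(family)(x)
  (dl0 + u) / (1 + dl0 * u)
}

#' The default kinetic-model grid
#'
#' Enumerates the full model grid: 2 amino acids (Asp, Glu) x 4 kinetic
#' families (SPK, CPK, TDK, APK) x initial D/L fixed at zero (0) or
#' estimated from data (1) x 2 age-uncertainty models (lognormal, gamma) =
#' 32 models. Subsets can be selected with the arguments.
#'
#' @param amino amino acids to include.
#' @param family kinetic families to include.
#' @param uncertainty uncertainty models to include.
#' @param estimateInitial logical vector; `FALSE` = initial D/L fixed at 0,
#'   `TRUE` = estimated.
#' @return data.frame with columns `amino`, `family`, `estimate_initial`,
#'   `uncertainty`, `label` (e.g. "Asp TDK1 lognormal").
#' @examples
#' nrow(kineticModelGrid())  # 32
#' @export
kineticModelGrid <- function(amino = AMINO_ACIDS,
                             family = KINETIC_FAMILIES,
                             uncertainty = UNCERTAINTY_MODELS,
                             estimateInitial = c(FALSE, TRUE)) {
  amino <- match.arg(amino, AMINO_ACIDS, several.ok = TRUE)
  family <- match.arg(family, KINETIC_FAMILIES, several.ok = TRUE)
  uncertainty <- match.arg(uncertainty, UNCERTAINTY_MODELS, several.ok = TRUE)
  g <- expand.grid(
    amino = amino, family = family, estimate_initial = estimateInitial,
    uncertainty = uncertainty,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g$label <- sprintf("%s %s%d %s", g$amino, g$family,
                     as.integer(g$estimate_initial), g$uncertainty)
  g
}
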