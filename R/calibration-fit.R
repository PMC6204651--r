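#' Log-likelihood of a calibration model on paired D/L-age data
#'
#' Sum over calibration shells of the log-density of the observed calibrated
#' age under the fitted age-uncertainty model. For `lognormal` uncertainty
#' the observed age is lognormal with median equal to the kinetic model age
#' at the shell's D/L and variance `d` on the log-age scale; for `gamma`
#' uncertainty it is gamma with mean equal to the model age and shape `1/d`,
#' so `d` plays a comparable dispersion role in both modes. Live-collected
#' shells enter with their listed near-zero ages.
#'
#' @param fit an `AarCalibration`.
#' @param points calibration data.frame; defaults to the points the model
#'   was fitted to.
#' @return the summed log-likelihood (scalar). A dead-collected point at
#'   which the model age is not positive contributes `-Inf` and raises a
#'   warning.
#' @export
aarLogLik <- function(fit, points = fit@data) {
  stopifnot(is(fit, "AarCalibration"))
  obs <- .calibrationObservations(points, fit@amino)
  p <- fit@params
  .aarNegLogLik(
    mu = .kineticAge(obs$dl, fit@family, p[["a"]], p[["b"]], p[["dl0"]],
                     specimen = obs$specimen_id),
    age = obs$age, d = p[["d"]], uncertainty = fit@uncertainty,
    live = obs$live_collected, warnNonPositive = TRUE
  ) * -1
}

# Extract (specimen_id, dl, age, live_collected) for one amino acid.
.calibrationObservations <- function(points, amino) {
  col <- paste0("dl_", tolower(amino))
  if (!col %in% names(points))
    stop("calibration points carry no ", col, " column")
  keep <- !is.na(points[[col]]) & !is.na(points$cal_age)
  out <- data.frame(
    specimen_id = if ("specimen_id" %in% names(points)) points$specimen_id[keep]
                  else as.character(which(keep)),
    dl = points[[col]][keep],
    age = points$cal_age[keep],
    live_collected = if ("live_collected" %in% names(points))
      as.logical(points$live_collected[keep]) else rep(FALSE, sum(keep)),
    stringsAsFactors = FALSE
  )
  if (any(out$dl < 0 | out$dl >= 1))
    stop("D/L values must lie in [0, 1)")
  out
}

.aarNegLogLik <- function(mu, age, d, uncertainty, live = NULL,
                          warnNonPositive = FALSE) {
  bad <- mu <= 0 & age > 0
  if (!is.null(live)) bad <- bad & !live
  if (any(bad)) {
    if (warnNonPositive)
      warning("model age <= 0 at ", sum(bad), " dead-collected point(s); ",
              "-Inf log-likelihood contribution")
    return(Inf)
  }
  ll <- if (uncertainty == "lognormal") {
    dlnorm(age, meanlog = log(mu), sdlog = sqrt(d), log = TRUE)
  } else {
    dgamma(age, shape = 1 / d, rate = 1 / (d * mu), log = TRUE)
  }
  -sum(ll)
}

# Free-parameter packing. theta lives on an unconstrained scale:
#   log(a), [log(b)], [qlogis(dl0 / dl0Max)], log(d)
.unpackTheta <- function(theta, family, estimateInitial, dl0Max) {
  i <- 1L
  a <- exp(theta[i]); i <- i + 1L
  if (family == "APK") b <- 2 else { b <- exp(theta[i]); i <- i + 1L }
  if (estimateInitial) { dl0 <- stats::plogis(theta[i]) * dl0Max; i <- i + 1L }
  else dl0 <- 0
  d <- exp(theta[i])
  c(a = a, b = b, dl0 = dl0, d = d)
}

#' Fit one AAR kinetic calibration model by seeded multi-start ML
#'
#' Maximizes the age likelihood of [aarLogLik()] over the free parameters of
#' the chosen kinetic family (`a`, `b` unless APK, `dl0` if
#' `estimateInitial`, and the dispersion `d`) with Nelder-Mead started from a
#' deterministic coarse grid (log-spaced `a`, `b` in `[0.5, 6]`, `dl0` in
#' `[0, min D/L)`) plus `nStarts` seeded random starts. Refitting with the
#' same seed reproduces the result bit for bit.
#'
#' @param points calibration data.frame (see [readCalibrationTable()]).
#' @param amino "Asp" or "Glu".
#' @param family kinetic family: "SPK", "CPK", "TDK" or "APK".
#' @param estimateInitial estimate the initial D/L (TRUE) or fix it at 0.
#' @param uncertainty "lognormal" or "gamma".
#' @param seed integer seed for the random extra starts.
#' @param nStarts number of seeded random starts added to the grid.
#' @param minPoints minimum number of usable calibration points.
#' @return an [AarCalibration-class] object.
#' @examples
#' fit <- fitAarModel(brijuniCalibration(), "Asp", "TDK",
#'                    estimateInitial = TRUE, uncertainty = "lognormal")
#' kineticParams(fit)
#' @export
fitAarModel <- function(points, amino = c("Asp", "Glu"),
                        family = c("TDK", "SPK", "CPK", "APK"),
                        estimateInitial = TRUE,
                        uncertainty = c("lognormal", "gamma"),
                        seed = 1L, nStarts = 8L, minPoints = 5L) {
  amino <- match.arg(amino)
  family <- match.arg(family)
  uncertainty <- match.arg(uncertainty)
  obs <- .calibrationObservations(points, amino)
  if (nrow(obs) < minPoints)
    stop("need at least ", minPoints, " usable calibration points, got ", nrow(obs))
  if (length(unique(obs$dl)) < 2L || diff(range(obs$dl)) < 1e-8)
    stop("degenerate calibration data: no spread in D/L values")
  dl0Max <- min(obs$dl)
  if (estimateInitial && dl0Max <= 0)
    stop("cannot estimate initial D/L: minimum observed D/L is 0")

  negll <- function(theta) {
    p <- .unpackTheta(theta, family, estimateInitial, dl0Max)
    mu <- tryCatch(
      .kineticAge(obs$dl, family, p[["a"]], p[["b"]], p[["dl0"]]),
      error = function(e) NULL
    )
    if (is.null(mu) || any(!is.finite(mu))) return(1e10)
    v <- .aarNegLogLik(mu, obs$age, p[["d"]], uncertainty, live = NULL)
    if (!is.finite(v)) 1e10 else v
  }

  # deterministic start grid
  la <- seq(6, 16, by = 2.5)
  lb <- log(c(0.5, 1.5, 3, 6))
  q0 <- c(-2, 0, 2)
  starts <- expand.grid(
    la = la,
    lb = if (family == "APK") 0 else lb,
    q = if (estimateInitial) q0 else 0,
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- lapply(seq_len(nrow(starts)), function(i) {
    th <- starts$la[i]
    if (family != "APK") th <- c(th, starts$lb[i])
    if (estimateInitial) th <- c(th, starts$q[i])
    c(th, log(0.1))
  })
  # seeded random starts
  if (nStarts > 0L) {
    rng <- .seededRng(seed)
    rand <- lapply(seq_len(nStarts), function(i) {
      th <- rng(1, 4, 18)
      if (family != "APK") th <- c(th, rng(1, log(0.5), log(6)))
      if (estimateInitial) th <- c(th, rng(1, -3, 3))
      c(th, rng(1, log(0.01), log(1)))
    })
    grid <- c(grid, rand)
  }

  best <- NULL
  for (th in grid) {
    r <- tryCatch(
      optim(th, negll, method = "Nelder-Mead",
            control = list(maxit = 3000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("AAR model fit failed to converge for ", amino, " ", family,
         as.integer(estimateInitial), " ", uncertainty,
         if (!is.null(best)) sprintf(" (best objective %.4g)", best$value))
  }
  best <- optim(best$par, negll, method = "Nelder-Mead",
                control = list(maxit = 20000, reltol = 1e-14))
  p <- .unpackTheta(best$par, family, estimateInitial, dl0Max)
  k <- 2L + as.integer(family != "APK") + as.integer(estimateInitial)
  new("AarCalibration",
      amino = amino, family = family, estimateInitial = estimateInitial,
      uncertainty = uncertainty, params = p, c = NA_real_,
      logLik = -best$value, nobs = nrow(obs), df = k,
      converged = best$convergence == 0L,
      data = points)
}

# Deterministic uniform draws independent of the global RNG state
# (Lehmer minstd generator; exact in double arithmetic).
.seededRng <- function(seed) {
  env <- new.env()
  env$state <- (abs(as.numeric(seed)) %% 2147483646) + 1
  function(n, lo, hi) {
    u <- numeric(n)
    for (i in seq_len(n)) {
      env$state <- (48271 * env$state) %% 2147483647
      u[i] <- env$state / 2147483647
    }
    lo + u * (hi - lo)
  }
}

#' @describeIn fitAarModel number of free parameters of a fitted model.
#' @param object,fit an `AarCalibration`.
#' @export
setMethod("kineticParams", "AarCalibration", function(object) object@params)

#' @export
setMethod("modelLabel", "AarCalibration", function(object) {
  sprintf("%s %s%d %s", object@amino, object@family,
          as.integer(object@estimateInitial), object@uncertainty)
})

#' @export
setMethod("show", "AarCalibration", function(object) {
  p <- object@params
  cat("AAR calibration model ", modelLabel(object), "\n", sep = "")
  cat(sprintf("  a = %.4g yr, b = %.4g, dl0 = %.6g, d = %.4g\n",
              p[["a"]], p[["b"]], p[["dl0"]], p[["d"]]))
  cat(sprintf("  logLik = %.3f on %d points (%d free parameters), BIC = %.2f\n",
              object@logLik, object@nobs, object@df, BIC(object)))
  if (!object@converged) cat("  WARNING: optimizer did not report convergence\n")
})

#' @importFrom stats logLik BIC coef
NULL

setGeneric("logLik")
setGeneric("BIC")
setGeneric("coef")

#' Log-likelihood of a fitted calibration
#' @param object an `AarCalibration`.
#' @export
setMethod("logLik", "AarCalibration", function(object) {
  structure(object@logLik, df = object@df, nobs = object@nobs,
            class = "logLik")
})

#' Bayesian information criterion, `k ln(n) - 2 logLik`
#'
#' `k` counts the free parameters of the model specification: `a` and `d`
#' always, `b` unless the family is APK, and `dl0` only when the initial D/L
#' is estimated.
#' @param object an `AarCalibration`.
#' @export
setMethod("BIC", "AarCalibration", function(object) {
  object@df * log(object@nobs) - 2 * object@logLik
})

#' @export
setMethod("coef", "AarCalibration", function(object) object@params)

#' Fit and rank a grid of AAR kinetic models by BIC
#'
#' Fits every model of `grid` (default: the full 32-model grid of
#' [kineticModelGrid()]) to the calibration points and returns them ranked
#' by ascending BIC with `dBIC = BIC - min(BIC)`. Models whose fit fails are
#' kept in the table with their error message in `status` and excluded from
#' ranking.
#'
#' @inheritParams fitAarModel
#' @param grid data.frame as produced by [kineticModelGrid()].
#' @return an [AarModelSelection-class]; the selected model is the first row
#'   (see [bestModel()]).
#' @export
selectAarModel <- function(points, grid = kineticModelGrid(), seed = 1L,
                           nStarts = 8L) {
  stopifnot(nrow(grid) > 0L)
  fits <- vector("list", nrow(grid))
  status <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- tryCatch(
      fitAarModel(points, amino = grid$amino[i], family = grid$family[i],
                  estimateInitial = grid$estimate_initial[i],
                  uncertainty = grid$uncertainty[i],
                  seed = seed + i, nStarts = nStarts),
      error = function(e) conditionMessage(e)
    )
    status[i] <- if (is.character(fits[[i]])) fits[[i]] else "ok"
    if (is.character(fits[[i]])) fits[i] <- list(NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("every model fit failed; diagnostics: ",
         paste(unique(status), collapse = "; "))
  tab <- grid
  tab$a <- tab$b <- tab$dl0 <- tab$d <- tab$logLik <- tab$BIC <- NA_real_
  tab$k <- tab$n <- NA_integer_
  for (i in which(ok)) {
    f <- fits[[i]]
    tab$a[i] <- f@params[["a"]]; tab$b[i] <- f@params[["b"]]
    tab$dl0[i] <- f@params[["dl0"]]; tab$d[i] <- f@params[["d"]]
    tab$logLik[i] <- f@logLik; tab$BIC[i] <- BIC(f)
    tab$k[i] <- f@df; tab$n[i] <- f@nobs
  }
  tab$status <- status
  ord <- order(tab$BIC)  # NAs (failed fits) sort last
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$dBIC <- tab$BIC - min(tab$BIC, na.rm = TRUE)
  rownames(tab) <- NULL
  new("AarModelSelection", table = tab, fits = fits)
}

#' @export
setMethod("bestModel", "AarModelSelection", function(object) object@fits[[1L]])

#' @export
setMethod("selectionTable", "AarModelSelection", function(object) object@table)

#' @export
setMethod("show", "AarModelSelection", function(object) {
  tab <- object@table
  cat("AAR model selection across", nrow(tab), "candidate models\n")
  cols <- c("label", "a", "b", "dl0", "d", "BIC", "dBIC", "status")
  print(head(tab[, cols], 10), digits = 5)
  if (nrow(tab) > 10) cat("  ... and", nrow(tab) - 10, "more rows\n")
})
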