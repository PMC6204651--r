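#' Configuration of a synthetic sediment core
#'
#' Parameterizes a simulated death-assemblage core with known ground truth:
#' the slicing plan, stratigraphic units with their true median ages,
#' log-age dispersions, expected sample sizes and taxon-pool compositions,
#' the racemization kinetics, taphonomic element-loss probabilities, and
#' monotone covariate depth profiles. The defaults imitate the scale of the
#' Brijuni reference core: 160 cm, ten 2-cm top slices plus twenty-eight
#' 5-cm slices (38 subsamples), six units with median ages from ~150 to
#' ~6000 years and centennial-to-millennial age dispersion, TDK kinetics
#' with the published parameter values, and unit 6 left below the minimum-N
#' analysis threshold. Units 1 and 2 share an identical generating
#' composition so that a no-difference PERMANOVA contrast exists by
#' construction.
#'
#' All randomness downstream flows from `seed` via fixed offsets (+101 ages,
#' +102 D/L noise, +103 assemblage, +104 covariates), so each sub-generator
#' is independently reproducible.
#'
#' @param seed master seed.
#' @param coreLength core length in cm.
#' @param nTaxa number of taxa in the pool.
#' @param nDatedPerIncrement dated (age-carrying) shells per slice.
#' @param fractionC14 fraction of dated shells flagged as radiocarbon-dated
#'   ("known" ages).
#' @param kinetics list with `family`, `a`, `b`, `dl0`, `d`.
#' @param taphonomy list with `pDouble`, `pValveKeep`, `pApex`, `pPlateKeep`.
#' @param units data.frame overriding the default unit table (columns
#'   `unit`, `depth_top`, `depth_bottom`, `median_age`, `log_age_sd`,
#'   `n_expected`).
#' @return an object of class `SyntheticCoreConfig`.
#' @export
syntheticCoreConfig <- function(seed = 1L, coreLength = 160, nTaxa = 30L,
                                nDatedPerIncrement = 8L, fractionC14 = 0.05,
                                kinetics = list(family = "TDK", a = 257268.1,
                                                b = 2.9614, dl0 = 0.02071817,
                                                d = 0.0605),
                                taphonomy = list(pDouble = 0.3,
                                                 pValveKeep = 0.75,
                                                 pApex = 0.85,
                                                 pPlateKeep = 0.6),
                                units = NULL) {
  if (is.null(units)) {
    units <- brijuniUnits()
    units <- units[order(units$unit), ]
    units$median_age <- c(6000, 5050, 3700, 2500, 1000, 150)
    units$log_age_sd <- c(0.25, 0.25, 0.35, 0.45, 0.70, 1.10)
    # expected individuals per 5-cm analysis increment; thin slices scale
    # proportionally. Gives per-unit totals of ~40 (unit 6, below the
    # minimum-N analysis threshold) up to ~1500 (unit 1).
    units$n_expected <- c(190, 135, 75, 75, 125, 25)
  }
  topSlices <- data.frame(depth_top = seq(0, 18, by = 2),
                          depth_bottom = seq(2, 20, by = 2))
  deepSlices <- data.frame(depth_top = seq(20, coreLength - 5, by = 5),
                           depth_bottom = seq(25, coreLength, by = 5))
  slices <- rbind(topSlices, deepSlices)

  groups <- rep(c("bivalve", "gastropod", "polyplacophoran", "scaphopod"),
                times = ceiling(nTaxa * c(0.4, 0.4, 0.1, 0.1)))[seq_len(nTaxa)]
  voc <- traitVocabulary()
  taxa <- data.frame(
    taxon = sprintf("taxon_%02d", seq_len(nTaxa)),
    higher_group = groups,
    feeding_guild = voc$feeding_guild[(seq_len(nTaxa) - 1L) %%
                                        length(voc$feeding_guild) + 1L],
    substrate_relation = voc$substrate_relation[(seq_len(nTaxa) - 1L) %%
                                        length(voc$substrate_relation) + 1L],
    host_association = voc$host_association[(seq_len(nTaxa) - 1L) %% 2L + 1L],
    weed_association = voc$weed_association[(seq_len(nTaxa) - 1L) %%
                                        length(voc$weed_association) + 1L],
    stringsAsFactors = FALSE
  )

  # Unit-specific multinomial weights: each taxon prefers a position on the
  # unit axis; units 1 and 2 share one composition (computed at their mean
  # position) so they are replicate-identical by construction.
  pref <- seq(1, 6, length.out = nTaxa)
  pos <- c(1.5, 1.5, 3, 4, 5, 6)  # effective axis position of units 1..6
  comp <- sapply(pos, function(p) exp(-(pref - p)^2 / (2 * 1.2^2)) + 0.03)
  comp <- sweep(comp, 2, colSums(comp), "/")
  dimnames(comp) <- list(taxa$taxon, paste0("unit", 1:6))

  covariates <- list(
    clay = list(profile = function(z) 75 - 0.45 * z, noise_sd = 3),
    gravel = list(profile = function(z) 10 + 55 * exp(-(z - 105)^2 / 450),
                  noise_sd = 3),
    water_depth = list(profile = function(z) 44 - 0.08 * z, noise_sd = 0.5),
    TN = list(profile = function(z) 0.15 - 8e-4 * z, noise_sd = 0.005),
    TOC = list(profile = function(z) 1.2 - 5e-3 * z, noise_sd = 0.05),
    Hg = list(profile = function(z) 0.1 + 1.0 * exp(-z / 12), noise_sd = 0.02),
    Pb = list(profile = function(z) 15 + 40 * exp(-z / 15), noise_sd = 2),
    As = list(profile = function(z) 8 + 2 * exp(-z / 40), noise_sd = 0.5),
    Cd = list(profile = function(z) 0.1 + 0.25 * exp(-(z - 50)^2 / 288),
              noise_sd = 0.01)
  )
  structure(list(
    seed = as.integer(seed), coreLength = coreLength, slices = slices,
    units = units, taxa = taxa, composition = comp, kinetics = kinetics,
    taphonomy = taphonomy, nDatedPerIncrement = nDatedPerIncrement,
    fractionC14 = fractionC14, covariates = covariates,
    covariateLayers = c(1, 5, 9, 24, 46, 69, 85, 105, 126, 151)
  ), class = "SyntheticCoreConfig")
}

# True median age at a depth: log-linear interpolation through the unit
# midpoints, flat beyond the outermost midpoints.
.ageDepthTrend <- function(depth, units) {
  u <- units[order(units$depth_top), ]
  mid <- (u$depth_top + u$depth_bottom) / 2
  stats::approx(mid, log(u$median_age), xout = depth, rule = 2)$y |> exp()
}

.unitAt <- function(depth, units) {
  i <- findInterval(depth, sort(units$depth_top))
  units[order(units$depth_top), ][i, ]
}

#' Draw true depositional ages for a synthetic core
#'
#' Per slice, `nDatedPerIncrement` shells receive true ages drawn from a
#' lognormal centred on the unit age-depth trend with the unit's log-age
#' dispersion. Stratigraphic order holds in expectation; individual ages may
#' invert, emulating sediment mixing. With zero dispersion every age equals
#' the trend value.
#'
#' @param config a [syntheticCoreConfig()].
#' @return data.frame: `specimen_id`, `depth_top`, `depth_bottom`,
#'   `true_age`, `age_source` ("AAR" or "14C").
#' @export
generateAges <- function(config) {
  stopifnot(inherits(config, "SyntheticCoreConfig"))
  withr_seed(config$seed + 101L, {
    rows <- lapply(seq_len(nrow(config$slices)), function(i) {
      top <- config$slices$depth_top[i]; bot <- config$slices$depth_bottom[i]
      uu <- .unitAt(top, config$units)
      n <- config$nDatedPerIncrement
      trend <- .ageDepthTrend((top + bot) / 2, config$units)
      age <- if (uu$log_age_sd > 0)
        rlnorm(n, meanlog = log(trend), sdlog = uu$log_age_sd)
      else rep(trend, n)
      data.frame(
        specimen_id = sprintf("SYN-%02d-%03d", i, seq_len(n)),
        depth_top = top, depth_bottom = bot, true_age = age,
        age_source = "AAR", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    nC14 <- round(config$fractionC14 * nrow(out))
    if (nC14 > 0)
      out$age_source[sample(nrow(out), nC14)] <- "14C"
    out
  })
}

#' Forward-model D/L values from true ages
#'
#' Applies the forward racemization curve (the exact algebraic inverse of
#' the calibration equation; for TDK,
#' `DL(t) = (dl0 + tanh((t/a)^(1/b))) / (1 + dl0 * tanh((t/a)^(1/b)))`),
#' then multiplicative lognormal age-equivalent noise of variance `d`: the
#' true age is perturbed on the log scale before the forward map, so
#' `predictAge()` under the generating parameters recovers the true age
#' exactly when `d = 0`.
#'
#' @param trueAges numeric vector of true ages (years).
#' @param kinetics list with `family`, `a`, `b`, `dl0`, `d`.
#' @param seed RNG seed.
#' @return numeric vector of D/L values.
#' @export
generateDL <- function(trueAges, kinetics, seed = 1L) {
  stopifnot(all(trueAges >= 0))
  k <- kinetics
  withr_seed(seed, {
    tNoisy <- if (k$d > 0)
      trueAges * exp(rnorm(length(trueAges), 0, sqrt(k$d)))
    else trueAges
    .kineticDl(tNoisy, k$family, k$a, k$b, k$dl0)
  })
}

#' Generate raw shell-element records for a synthetic core
#'
#' Per slice, the number of individuals is Poisson around the unit
#' expectation and taxa are drawn from the unit's multinomial pool; bivalve
#' individuals are split into double-valved specimens and loose valves with
#' configured articulation/loss probabilities, gastropods keep their apex
#' with probability `pApex`, polyplacophorans are emitted as surviving
#' plates (8 per individual), and scaphopods as whole shells.
#'
#' @param config a [syntheticCoreConfig()].
#' @return list with `records` (element records, see [buildAssemblage()])
#'   and `trueIndividuals` (data.frame of true deposited individuals per
#'   taxon and slice).
#' @export
generateAssemblage <- function(config) {
  stopifnot(inherits(config, "SyntheticCoreConfig"))
  tp <- config$taphonomy
  withr_seed(config$seed + 103L, {
    recs <- list(); truth <- list()
    for (i in seq_len(nrow(config$slices))) {
      top <- config$slices$depth_top[i]; bot <- config$slices$depth_bottom[i]
      uu <- .unitAt(top, config$units)
      n <- rpois(1, uu$n_expected * (bot - top) / 5)
      if (n == 0) next
      w <- config$composition[, paste0("unit", uu$unit)]
      counts <- as.vector(stats::rmultinom(1, n, w))
      for (j in which(counts > 0)) {
        tx <- config$taxa$taxon[j]; grp <- config$taxa$higher_group[j]
        nj <- counts[j]
        truth[[length(truth) + 1L]] <- data.frame(
          taxon = tx, depth_top = top, depth_bottom = bot, individuals = nj)
        add <- function(element, count) {
          if (count > 0)
            recs[[length(recs) + 1L]] <<- data.frame(
              taxon = tx, higher_group = grp, element = element,
              count = count, depth_top = top, depth_bottom = bot)
        }
        if (grp == "bivalve") {
          nDouble <- stats::rbinom(1, nj, tp$pDouble)
          nLoose <- nj - nDouble
          add("double_valved", nDouble)
          add("left_valve", stats::rbinom(1, nLoose, tp$pValveKeep))
          add("right_valve", stats::rbinom(1, nLoose, tp$pValveKeep))
        } else if (grp == "gastropod") {
          nApex <- stats::rbinom(1, nj, tp$pApex)
          add("shell_with_apex", nApex)
          add("shell_without_apex", nj - nApex)
        } else if (grp == "polyplacophoran") {
          add("plate", stats::rbinom(1, 8L * nj, tp$pPlateKeep))
        } else {
          add("whole", nj)
        }
      }
    }
    records <- do.call(rbind, recs)
    records$record_id <- sprintf("REC-%05d", seq_len(nrow(records)))
    list(records = records, trueIndividuals = do.call(rbind, truth))
  })
}

#' Generate layered environmental covariates for a synthetic core
#'
#' Evaluates each configured covariate profile at the discrete sampling
#' layers and adds seeded Gaussian noise. With zero noise the output equals
#' the configured profile exactly.
#'
#' @param config a [syntheticCoreConfig()].
#' @return long data.frame: `depth_cm`, `variable`, `value`.
#' @export
generateCovariates <- function(config) {
  stopifnot(inherits(config, "SyntheticCoreConfig"))
  layers <- config$covariateLayers
  withr_seed(config$seed + 104L, {
    rows <- lapply(names(config$covariates), function(v) {
      spec <- config$covariates[[v]]
      data.frame(depth_cm = layers, variable = v,
                 value = spec$profile(layers) +
                   rnorm(length(layers), 0, spec$noise_sd))
    })
    do.call(rbind, rows)
  })
}

#' Map layered covariates onto depth increments
#'
#' Environmental covariates measured at discrete core layers are assigned to
#' analysis increments either by nearest layer (default) or by linear
#' interpolation at the increment midpoint.
#'
#' @param covariates long data.frame from [generateCovariates()] (or read
#'   with [readCovariateTable()]).
#' @param increments data.frame with `depth_top`, `depth_bottom`.
#' @param method "nearest" or "interpolate".
#' @return data.frame of increments x covariate columns.
#' @export
mapCovariatesToIncrements <- function(covariates, increments,
                                      method = c("nearest", "interpolate")) {
  method <- match.arg(method)
  mid <- (increments$depth_top + increments$depth_bottom) / 2
  out <- data.frame(row.names = seq_along(mid))
  for (v in unique(covariates$variable)) {
    sub <- covariates[covariates$variable == v, ]
    sub <- sub[order(sub$depth_cm), ]
    out[[v]] <- if (method == "nearest") {
      sub$value[vapply(mid, function(m) which.min(abs(sub$depth_cm - m)),
                       integer(1))]
    } else {
      stats::approx(sub$depth_cm, sub$value, xout = mid, rule = 2)$y
    }
  }
  out
}

#' Simulate a complete synthetic core
#'
#' Runs all sub-generators and bundles their output with the ground truth.
#' The truth component is emitted alongside the data for validation only;
#' no pipeline stage consumes it.
#'
#' @param config a [syntheticCoreConfig()].
#' @return object of class `SyntheticCore`: list with `datedSpecimens`
#'   (dated shells with observed `dl` and, for the 14C fraction, known
#'   ages), `records` (shell-element records), `covariates` (long layer
#'   table), and `truth` (true ages, true per-increment population IQR,
#'   generating composition and kinetics, config).
#' @export
simulateCore <- function(config = syntheticCoreConfig()) {
  ages <- generateAges(config)
  dl <- generateDL(ages$true_age, config$kinetics, seed = config$seed + 102L)
  assem <- generateAssemblage(config)
  cov <- generateCovariates(config)
  dated <- data.frame(
    specimen_id = ages$specimen_id, depth_top = ages$depth_top,
    depth_bottom = ages$depth_bottom, dl_asp = dl,
    age_source = ages$age_source,
    cal_age = ifelse(ages$age_source == "14C", ages$true_age, NA_real_),
    stringsAsFactors = FALSE)
  u <- config$units
  z <- qnorm(0.75)
  trueIqr <- data.frame(
    depth_top = config$slices$depth_top,
    depth_bottom = config$slices$depth_bottom)
  trend <- .ageDepthTrend((trueIqr$depth_top + trueIqr$depth_bottom) / 2,
                          config$units)
  sdv <- vapply(trueIqr$depth_top,
                function(d) .unitAt(d, config$units)$log_age_sd, numeric(1))
  trueIqr$iqr_true <- 2 * trend * sinh(z * sdv)
  structure(list(
    datedSpecimens = dated,
    records = assem$records,
    covariates = cov,
    truth = list(trueAges = ages, trueIndividuals = assem$trueIndividuals,
                 trueIqr = trueIqr, composition = config$composition,
                 kinetics = config$kinetics, config = config)
  ), class = "SyntheticCore")
}

#' @export
print.SyntheticCore <- function(x, ...) {
  cat("SyntheticCore:", nrow(x$datedSpecimens), "dated shells,",
      nrow(x$records), "element records,",
      length(unique(x$covariates$variable)), "covariates\n")
  invisible(x)
}
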