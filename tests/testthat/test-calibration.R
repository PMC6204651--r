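test_that("lognormal age log-likelihood matches a brute-force density sum", {
  fit <- publishedTdkFit()
  obs <- aarchron:::.calibrationObservations(fit@data, "Asp")
  mu <- publishedCurve(obs$dl)
  expect_equal(aarLogLik(fit), bruteForceLogLik(mu, obs$age, 0.0605),
               tolerance = 1e-9)
  # frozen value of the brute-force oracle on the bundled table
  expect_equal(aarLogLik(fit), -100.321039441, tolerance = 1e-9)
})

test_that("log-likelihood is additive and reduces to the closed single-point form", {
  fit <- publishedTdkFit()
  cal <- fit@data
  doubled <- rbind(cal, cal)
  expect_equal(aarLogLik(fit, doubled), 2 * aarLogLik(fit, cal),
               tolerance = 1e-12)
  # one point observed exactly at the model median age
  mu <- publishedCurve(0.110)
  pt <- data.frame(specimen_id = "x", dl_asp = 0.110, cal_age = mu,
                   live_collected = FALSE)
  expect_equal(aarLogLik(fit, pt), -log(mu) - 0.5 * log(2 * pi * 0.0605),
               tolerance = 1e-9)
})

test_that("gamma log-likelihood matches an independent dgamma summation", {
  fit <- publishedTdkFit()
  gfit <- new("AarCalibration", amino = "Asp", family = "TDK",
              estimateInitial = TRUE, uncertainty = "gamma",
              params = fit@params, logLik = 0, nobs = 16L, df = 4L,
              converged = TRUE, data = fit@data)
  obs <- aarchron:::.calibrationObservations(fit@data, "Asp")
  mu <- publishedCurve(obs$dl)
  d <- 0.0605
  oracle <- sum(dgamma(obs$age, shape = 1 / d, scale = d * mu, log = TRUE))
  expect_equal(aarLogLik(gfit), oracle, tolerance = 1e-9)
})

test_that("BIC counts free parameters and penalizes by log(n)", {
  f <- publishedTdkFit()
  f@logLik <- -100; f@df <- 3L; f@nobs <- 16L
  expect_equal(BIC(f), 208.317766167, tolerance = 1e-8)
  f@logLik <- 0; f@df <- 0L
  expect_equal(BIC(f), 0)
  # published parameter values reproduce the published BIC
  expect_equal(BIC(publishedTdkFit()), 211.73, tolerance = 0.005)
})

test_that("TDK refit of the bundled calibration recovers the published parameters", {
  fit <- fitAarModel(brijuniCalibration(), "Asp", "TDK",
                     estimateInitial = TRUE, uncertainty = "lognormal",
                     seed = 1)
  p <- kineticParams(fit)
  expect_lt(abs(p[["a"]] - 257268.1) / 257268.1, 0.20)
  expect_lt(abs(p[["b"]] - 2.9614) / 2.9614, 0.10)
  expect_lt(abs(p[["dl0"]] - 0.02071817) / 0.02071817, 0.10)
  expect_lt(abs(p[["d"]] - 0.0605) / 0.0605, 0.10)
  expect_true(fit@converged)
  expect_identical(fit@nobs, 16L)
  # bit-reproducible under the same seed
  refit <- fitAarModel(brijuniCalibration(), "Asp", "TDK",
                       estimateInitial = TRUE, uncertainty = "lognormal",
                       seed = 1)
  expect_identical(kineticParams(refit), p)
})

test_that("fitting rejects degenerate and undersized calibration data", {
  cal <- brijuniCalibration()
  degenerate <- cal[1:6, ]
  degenerate$dl_asp <- 0.2
  expect_error(fitAarModel(degenerate, "Asp", "TDK"), "degenerate")
  expect_error(fitAarModel(cal[1:3, ], "Asp", "TDK"), "at least 5")
})

test_that("estimating the initial D/L never worsens the fitted log-likelihood", {
  cal <- brijuniCalibration()
  for (fam in c("TDK", "SPK")) {
    f0 <- fitAarModel(cal, "Asp", fam, estimateInitial = FALSE,
                      uncertainty = "lognormal", seed = 2)
    f1 <- fitAarModel(cal, "Asp", fam, estimateInitial = TRUE,
                      uncertainty = "lognormal", seed = 2)
    expect_gte(f1@logLik, f0@logLik - 1e-6)
    expect_identical(f1@df, f0@df + 1L)
  }
})

test_that("parameters are recovered from data simulated under known kinetics", {
  kin <- list(family = "TDK", a = 257268.1, b = 2.9614, dl0 = 0.02071817,
              d = 0.0605)
  set.seed(7)
  age <- c(rep(1, 10), exp(runif(190, log(50), log(9500))))
  dl <- generateDL(age, kin, seed = 11)
  pts <- data.frame(specimen_id = seq_along(age), dl_asp = dl, cal_age = age,
                    live_collected = age <= 1)
  fit <- fitAarModel(pts, "Asp", "TDK", TRUE, "lognormal", seed = 3)
  p <- kineticParams(fit)
  expect_lt(abs(log(p[["a"]] / kin$a)), log(1.6))
  expect_lt(abs(p[["b"]] - kin$b) / kin$b, 0.12)
  expect_lt(abs(p[["dl0"]] - kin$dl0), 0.01)
  expect_lt(abs(p[["d"]] - kin$d) / kin$d, 0.30)
})

test_that("model selection ranks by BIC with dBIC = 0 for the first row", {
  sel <- selectAarModel(brijuniCalibration(),
                        grid = kineticModelGrid(amino = "Asp",
                                                family = c("TDK", "APK"),
                                                uncertainty = "lognormal"),
                        seed = 1)
  tab <- selectionTable(sel)
  expect_identical(nrow(tab), 4L)
  expect_equal(tab$dBIC[1], 0)
  expect_true(!is.unsorted(tab$BIC))
  expect_s4_class(bestModel(sel), "AarCalibration")
  expect_equal(BIC(bestModel(sel)), tab$BIC[1], tolerance = 1e-9)
})

test_that("outlier screening applies named rules and is idempotent", {
  cal <- brijuniCalibration()
  # empty rule set keeps everything
  r0 <- screenOutliers(cal, rules = list())
  expect_identical(nrow(r0$kept), nrow(cal))
  expect_identical(nrow(r0$flagged), 0L)
  # a serine ceiling flags the offending specimen with the rule name
  cal$dl_ser[3] <- 0.95
  r1 <- screenOutliers(cal, rules = screeningRules(serMax = 0.8))
  expect_identical(r1$flagged$specimen_id, cal$specimen_id[3])
  expect_identical(r1$flagged$rule, "ser_max")
  # idempotent on the kept set
  r2 <- screenOutliers(r1$kept, rules = screeningRules(serMax = 0.8))
  expect_identical(nrow(r2$flagged), 0L)
  expect_identical(r2$kept, r1$kept)
})

test_that("asp/glu concordance screening flags discordant shells", {
  cal <- brijuniCalibration()
  cal$dl_glu[5] <- cal$dl_asp[5] * 2  # ratio 0.5, below any plausible band
  r <- screenOutliers(cal, rules = screeningRules(aspGluRatio = c(1, 8)))
  expect_true(cal$specimen_id[5] %in% r$flagged$specimen_id)
  expect_true(all(r$flagged$rule == "asp_glu_concordance"))
})
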