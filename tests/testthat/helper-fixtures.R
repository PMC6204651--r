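# Shared fixtures, built in code.

# AarCalibration with the published best-fit TDK1 parameter values,
# constructed directly (not fitted).
publishedTdkFit <- function() {
  cal <- brijuniCalibration()
  new("AarCalibration",
      amino = "Asp", family = "TDK", estimateInitial = TRUE,
      uncertainty = "lognormal",
      params = c(a = 257268.1, b = 2.9614, dl0 = 0.02071817, d = 0.0605),
      logLik = -100.321039441, nobs = 16L, df = 4L, converged = TRUE,
      data = cal)
}

# Independent brute-force lognormal age log-likelihood: per-point density
# formula summed in a plain loop (no dlnorm).
bruteForceLogLik <- function(mu, age, d) {
  total <- 0
  for (i in seq_along(age)) {
    total <- total - log(age[i]) - 0.5 * log(2 * pi * d) -
      (log(age[i]) - log(mu[i]))^2 / (2 * d)
  }
  total
}

# Published inverse TDK calibration curve, written out directly.
publishedCurve <- function(dl) {
  257268.1 * atanh((dl - 0.02071817) / (1 - dl * 0.02071817))^2.9614
}

# Random bivalve element multiset for MNI property tests.
randomBivalveRecords <- function() {
  n <- sample(0:4, 3)
  data.frame(element = c("double_valved", "left_valve", "right_valve"),
             count = n)[n > 0, , drop = FALSE]
}

# Small deterministic assemblage: 4 taxa x 3 increments.
smallRecords <- function() {
  data.frame(
    taxon = c("biv_a", "biv_a", "biv_a", "gas_b", "gas_b", "chi_c", "sca_d"),
    higher_group = c("bivalve", "bivalve", "bivalve", "gastropod",
                     "gastropod", "polyplacophoran", "scaphopod"),
    element = c("double_valved", "left_valve", "right_valve",
                "shell_with_apex", "shell_without_apex", "plate", "whole"),
    count = c(3, 5, 4, 4, 7, 12, 2),
    depth_top = c(0, 0, 0, 0, 0, 5, 10),
    depth_bottom = c(5, 5, 5, 5, 5, 10, 15)
  )
}

smallTraits <- function() {
  data.frame(
    taxon = c("biv_a", "gas_b", "chi_c", "sca_d"),
    feeding_guild = c("filter-feeding", "carnivore", "grazing", "carnivore"),
    substrate_relation = c("infauna", "epifauna", "epifauna", "infauna"),
    host_association = c("free_living", "free_living", "free_living",
                         "free_living"),
    weed_association = c("none", "none", "seagrass_and_algae", "none")
  )
}
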