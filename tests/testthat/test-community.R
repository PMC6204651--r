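test_that("effective species richness matches hand-computed Shannon values", {
  m <- rbind(even = c(25, 25, 25, 25))
  d <- incrementDiversity(m, iterations = 50, seed = 1)
  expect_equal(d$effective_richness, 4, tolerance = 1e-12)
  single <- rbind(x = c(10, 0, 0))
  expect_equal(incrementDiversity(single, iterations = 10)$effective_richness, 1)
  # counts {2,1,1}: H = -(0.5 ln 0.5 + 2 * 0.25 ln 0.25)
  mix <- rbind(x = c(2, 1, 1))
  d3 <- incrementDiversity(mix, iterations = 10, seed = 1)
  expect_equal(d3$shannon_h, 1.03972077084, tolerance = 1e-9)
  expect_equal(d3$effective_richness, 2.82842712475, tolerance = 1e-9)
})

test_that("exp(H) is invariant to rescaling all counts in a row", {
  set.seed(2)
  row <- runif(12, 0, 20)
  m <- rbind(a = row, b = row * 7.3)
  d <- incrementDiversity(m, iterations = 10, seed = 1)
  expect_equal(d$effective_richness[1], d$effective_richness[2],
               tolerance = 1e-12)
})

test_that("resampling CIs bracket the resampled mean and respect bounds", {
  set.seed(3)
  m <- matrix(rpois(60, 8), nrow = 5,
              dimnames = list(paste0("i", 1:5), paste0("sp", 1:12)))
  d <- incrementDiversity(m, iterations = 300, seed = 4)
  expect_true(all(d$ci_lo <= d$mean_resampled & d$mean_resampled <= d$ci_hi))
  expect_true(all(d$ci_lo >= 1 - 1e-9))
  expect_true(all(d$effective_richness <= d$richness_raw + 1e-9))
  # identical seeds reproduce the CIs exactly
  d2 <- incrementDiversity(m, iterations = 300, seed = 4)
  expect_identical(d$ci_lo, d2$ci_lo)
})

test_that("fractional (plate-derived) counts are resampled by weight", {
  m <- rbind(inc = c(chiton = 2.5, snail = 40, clam = 12.25))
  d <- incrementDiversity(m, iterations = 100, seed = 5, minN = 20)
  expect_true(is.finite(d$mean_resampled))
  expect_true(d$ci_lo >= 1)
})

test_that("Wilcoxon unit contrasts reproduce exact rank-sum p-values", {
  same <- diversityContrast(c(1, 2, 3, 1, 2, 3), rep(c("u1", "u2"), each = 3))
  expect_equal(same$p_value, 1)
  sep <- diversityContrast(c(1:5, 101:105), rep(c("u1", "u2"), each = 5))
  expect_equal(sep$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  # permuting values within a unit changes nothing
  perm <- diversityContrast(c(5:1, 101:105), rep(c("u1", "u2"), each = 5))
  expect_equal(perm$p_value, sep$p_value)
})

test_that("Bray-Curtis distances match the hand formula", {
  m <- rbind(r1 = c(1, 3), r2 = c(2, 2), r3 = c(1, 3))
  d0 <- as.matrix(brayCurtisDist(m, transform = "none"))
  expect_equal(d0["r1", "r2"], 0.25)          # (|1-2|+|3-2|) / 8
  expect_equal(d0["r1", "r3"], 0)
  disjoint <- rbind(a = c(5, 0), b = c(0, 9))
  expect_equal(as.numeric(brayCurtisDist(disjoint, transform = "none")), 1)
  # sqrt of relative abundances applied before the distance
  s1 <- sqrt(c(0.25, 0.75)); s2 <- sqrt(c(0.5, 0.5))
  expected <- sum(abs(s1 - s2)) / sum(s1 + s2)
  expect_equal(as.matrix(brayCurtisDist(m))["r1", "r2"], expected,
               tolerance = 1e-12)
  d <- brayCurtisDist(m)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PERMANOVA separates disjoint groups at the minimum attainable p", {
  m <- rbind(matrix(rep(c(10, 0, 2, 0), 4), 4, byrow = TRUE) + runif(16),
             matrix(rep(c(0, 9, 0, 3), 4), 4, byrow = TRUE) + runif(16))
  rownames(m) <- paste0("i", 1:8)
  d <- brayCurtisDist(m)
  grp <- rep(c("A", "B"), each = 4)
  res <- permanovaTest(d, grp, nPermutations = 199, seed = 1)
  # the attainable floor is set by partition-preserving label permutations
  # (4! * 4! * 2 of the 8! relabelings, ~2.9%), so p must sit at or near it
  expect_gte(res$p_value, 1 / 200)
  expect_lte(res$p_value, 0.05)
  expect_gt(res$pseudo_f, 1)
  # refusal below minimum group size
  expect_error(permanovaTest(d, c("A", rep("B", 7)), 99), "at least 2")
  # p-values live on the 1/(nPermutations + 1) grid
  res2 <- permanovaTest(d, grp, nPermutations = 399, seed = 1)
  expect_equal(res$p_value * 200, round(res$p_value * 200))
  expect_equal(res2$p_value * 400, round(res2$p_value * 400))
})

test_that("NMDS recovers an exactly embeddable 2-D configuration", {
  pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1.3))
  d <- dist(pts)
  fit <- suppressWarnings(nmdsOrdination(d, dims = 2, starts = 10, seed = 2))
  expect_lt(fit$stress, 0.01)
  expect_equal(dim(fit$scores), c(4L, 2L))
})

test_that("identical community rows collapse to coincident NMDS scores", {
  m <- rbind(a = c(4, 1, 3), b = c(4, 1, 3), c = c(0, 9, 1), d = c(2, 2, 2),
             e = c(7, 0, 1))
  fit <- suppressWarnings(nmdsOrdination(brayCurtisDist(m), starts = 10, seed = 3))
  expect_lt(sqrt(sum((fit$scores["a", ] - fit$scores["b", ])^2)), 1e-4)
})

test_that("forward RDA selects the generating covariate and stops on collinearity", {
  set.seed(6)
  n <- 20
  x <- seq(-1, 1, length.out = n)
  noise1 <- rnorm(n); noise2 <- rnorm(n)
  resp <- sapply(1:8, function(j) 5 + x * (j - 4) + rnorm(n, 0, 0.2))
  resp <- resp - min(resp) + 0.1
  rownames(resp) <- paste0("i", 1:n)
  cov <- data.frame(driver = x, dup = x, n1 = noise1, n2 = noise2)
  sel <- rdaForwardSelect(resp, cov, nPermutations = 199, seed = 7,
                          transform = "none")
  expect_true(sel$selected$variable[1] %in% c("driver", "dup"))
  # the duplicated covariate adds no second-step gain
  expect_false(all(c("driver", "dup") %in% sel$selected$variable))
  # variance partition: constrained + unconstrained = total
  expect_equal(sel$varianceFractions[["constrained"]] +
                 sel$varianceFractions[["unconstrained"]],
               sel$varianceFractions[["total"]], tolerance = 1e-9)
  expect_true(all(diff(sel$selected$gain) <= 1e-9))  # gains decrease
})

test_that("forward RDA admits nothing for pure-noise responses (single run)", {
  set.seed(17)
  resp <- matrix(runif(20 * 6, 1, 5), nrow = 20)
  cov <- data.frame(a = rnorm(20), b = rnorm(20))
  sel <- rdaForwardSelect(resp, cov, nPermutations = 199, seed = 8,
                          transform = "none", alpha = 0.01)
  expect_lte(nrow(sel$selected), 1L)
})
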