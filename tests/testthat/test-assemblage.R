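test_that("bivalve MNI is doubles plus the larger loose-valve count", {
  r <- data.frame(element = c("double_valved", "left_valve", "right_valve"),
                  count = c(3, 5, 4))
  expect_equal(countBivalveMni(r), 8)
  expect_equal(countBivalveMni(r[0, ]), 0)
  expect_error(countBivalveMni(data.frame(element = "plate", count = 1)),
               "non-bivalve")
})

test_that("bivalve MNI equals a brute-force rule oracle on random multisets", {
  set.seed(8)
  for (i in 1:200) {
    r <- randomBivalveRecords()
    if (nrow(r) == 0) next
    # oracle: expand to individual elements and recount from scratch
    el <- rep(r$element, r$count)
    oracle <- sum(el == "double_valved") +
      max(sum(el == "left_valve"), sum(el == "right_valve"))
    expect_equal(countBivalveMni(r), oracle)
  }
})

test_that("counting operators are additive except the subadditive bivalve MNI", {
  set.seed(9)
  for (i in 1:50) {
    a <- randomBivalveRecords(); b <- randomBivalveRecords()
    both <- rbind(a, b)
    if (nrow(both) == 0) next
    expect_lte(countBivalveMni(both),
               countBivalveMni(a) + countBivalveMni(b))
  }
  g1 <- data.frame(element = "shell_with_apex", count = 3)
  g2 <- data.frame(element = c("shell_with_apex", "shell_without_apex"),
                   count = c(2, 5))
  expect_equal(countGastropods(rbind(g1, g2)),
               countGastropods(g1) + countGastropods(g2))
})

test_that("gastropods count only apex-bearing shells", {
  r <- data.frame(element = c("shell_with_apex", "shell_without_apex"),
                  count = c(4, 7))
  expect_equal(countGastropods(r), 4)
  expect_equal(countGastropods(
    data.frame(element = "shell_without_apex", count = 9)), 0)
})

test_that("polyplacophorans are plates divided by eight, kept fractional", {
  expect_equal(countPolyplacophorans(data.frame(element = "plate", count = 16)), 2)
  expect_equal(countPolyplacophorans(data.frame(element = "plate", count = 4)), 0.5)
  expect_equal(countPolyplacophorans(data.frame(element = "plate", count = 0)[0, ]), 0)
})

test_that("buildAssemblage applies the counting protocol per taxon and increment", {
  a <- buildAssemblage(smallRecords(), traits = smallTraits())
  m <- abundanceMatrix(a)
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(unname(m["0-5cm", "biv_a"]), 8)   # 3 + max(5, 4)
  expect_equal(unname(m["0-5cm", "gas_b"]), 4)   # apex-bearing only
  expect_equal(unname(m["5-10cm", "chi_c"]), 1.5)  # 12 plates / 8
  expect_equal(unname(m["10-15cm", "sca_d"]), 2)
  expect_equal(depthIntervals(a)$depth_top, c(0, 5, 10))
  expect_true("feeding_guild" %in%
                colnames(SummarizedExperiment::rowData(a)))
})

test_that("element types not permitted for a higher group are rejected", {
  bad <- smallRecords()
  bad$element[4] <- "left_valve"  # a valve on a gastropod
  expect_error(buildAssemblage(bad), "not permitted.*4")
  bad2 <- smallRecords()
  bad2$count[1] <- 0
  expect_error(buildAssemblage(bad2), "non-positive")
})

test_that("merging 2-cm top slices pairwise conserves individuals (38 -> 33)", {
  set.seed(12)
  top <- expand.grid(taxon = c("g1", "g2"), i = 1:10)
  recs <- data.frame(
    taxon = as.character(top$taxon), higher_group = "gastropod",
    element = "shell_with_apex", count = sample(1:9, 20, TRUE),
    depth_top = (top$i - 1) * 2, depth_bottom = top$i * 2)
  deep <- data.frame(
    taxon = "g1", higher_group = "gastropod", element = "shell_with_apex",
    count = sample(1:9, 28, TRUE),
    depth_top = seq(20, 155, by = 5), depth_bottom = seq(25, 160, by = 5))
  a <- buildAssemblage(rbind(recs, deep))
  expect_equal(ncol(a), 38L)
  m <- mergeTopSlices(a)
  expect_equal(ncol(m), 33L)
  expect_equal(sum(abundanceMatrix(m)), sum(abundanceMatrix(a)))
  # merged pair equals the per-taxon sum of its two slices
  expect_equal(abundanceMatrix(m)["0-4cm", ],
               abundanceMatrix(a)["0-2cm", ] + abundanceMatrix(a)["2-4cm", ])
  # deeper 5-cm slices untouched
  expect_equal(abundanceMatrix(m)["20-25cm", ], abundanceMatrix(a)["20-25cm", ])
})

test_that("an unpaired 2-cm slice is an error", {
  recs <- data.frame(
    taxon = "g1", higher_group = "gastropod", element = "shell_with_apex",
    count = c(1, 1, 1), depth_top = c(0, 2, 10), depth_bottom = c(2, 4, 12))
  expect_error(mergeTopSlices(buildAssemblage(recs)), "odd|adjacent")
})

test_that("trait aggregation conserves totals and normalizes relatives", {
  a <- buildAssemblage(smallRecords(), traits = smallTraits())
  ag <- aggregateByTrait(a, "feeding_guild")
  expect_equal(sum(ag$absolute), sum(abundanceMatrix(a)))
  rs <- rowSums(ag$relative)
  expect_equal(unname(rs), rep(1, 3))
  # single-category increment has relative 1
  expect_equal(unname(ag$relative["10-15cm", "carnivore"]), 1)
})

test_that("taxa without traits either error or pool into 'unclassified'", {
  tr <- smallTraits()[-2, ]  # drop gas_b
  a <- buildAssemblage(smallRecords(), traits = tr)
  expect_error(aggregateByTrait(a, "feeding_guild"), "gas_b")
  ag <- aggregateByTrait(a, "feeding_guild", missing = "unclassified")
  expect_true("unclassified" %in% colnames(ag$absolute))
  expect_equal(sum(ag$absolute), sum(abundanceMatrix(a)))
})

test_that("minimum-N filter is boundary-inclusive and logs exclusions", {
  recs <- data.frame(
    taxon = rep(c("a", "b"), each = 2), higher_group = "gastropod",
    element = "shell_with_apex", count = c(24, 25, 25, 25),
    depth_top = c(0, 5, 0, 5), depth_bottom = c(5, 10, 5, 10))
  a <- buildAssemblage(recs)
  expect_equal(unname(rowSums(abundanceMatrix(a))), c(49, 50))
  f <- filterMinN(a, threshold = 50)
  expect_equal(ncol(f), 1L)
  expect_equal(colnames(f), "5-10cm")
  expect_equal(S4Vectors::metadata(f)$excluded$increment, "0-5cm")
  expect_warning(filterMinN(a, threshold = 1000), "below the minimum")
})
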