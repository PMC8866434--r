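test_that("field validity catches bad values and bad grids", {
  expect_error(ConcentrationField(matrix(c(1, -2), 1)), ">= 0")
  expect_error(ConcentrationField(matrix(c(1, NA), 1)), "finite")
  expect_error(ConcentrationField(matrix(1, 2, 2), latEdges = c(0, 1, 1)),
               "strictly increasing")
  expect_error(ConcentrationField(matrix(1, 2, 2), latEdges = c(0, 1)),
               "length")
  expect_error(PopulationField(array(-1, c(1, 2, 2)), "a"), ">= 0")
  expect_error(PopulationField(array(1, c(2, 2, 2)), c("a", "a")), "unique")
})

test_that("registration demands identical edges in identical order", {
  conc <- fxConc(matrix(10, 3, 4))
  pop <- fxPop(matrix(1, 3, 4))
  expect_true(checkRegistration(conc, pop))

  shifted <- PopulationField(array(1, c(1, 3, 4)), "25+",
                             latEdges = 0:3 + 0.5)
  expect_false(checkRegistration(conc, shifted))

  # edge ordering is part of the contract: the comparison is elementwise,
  # and reversed storage of the same edges is rejected at construction
  rev_pop <- fxPop(matrix(1, 3, 4))
  expect_error({rev_pop@latEdges <- rev(rev_pop@latEdges)
                validObject(rev_pop)}, "strictly increasing")

  expect_error(populationWeightedConcentration(conc, shifted),
               "not co-registered")
})

test_that("population-weighted concentration is the weighted mean", {
  conc <- fxConc(matrix(c(10, 20), 1))
  pop <- fxPop(matrix(c(1, 3), 1))
  expect_equal(populationWeightedConcentration(conc, pop), 17.5)

  # uniform field: weights are irrelevant
  u <- fxConc(matrix(7.7, 4, 4))
  w <- fxPop(matrix(runif(16), 4, 4))
  expect_equal(populationWeightedConcentration(u, w), 7.7)

  # permutation symmetry: relabeling cells jointly changes nothing
  set.seed(3)
  cv <- matrix(runif(12, 5, 80), 3, 4)
  pv <- matrix(rpois(12, 50), 3, 4)
  perm <- sample(12)
  a <- populationWeightedConcentration(fxConc(cv), fxPop(pv))
  b <- populationWeightedConcentration(fxConc(matrix(cv[perm], 3, 4)),
                                       fxPop(matrix(pv[perm], 3, 4)))
  expect_equal(a, b)
  expect_true(a >= min(cv) && a <= max(cv))

  expect_error(populationWeightedConcentration(u, fxPop(matrix(0, 4, 4))),
               "total population is 0")
})

test_that("population above a threshold is strict and monotone", {
  conc <- fxConc(matrix(c(30, 40), 1))
  pop <- fxPop(matrix(c(5, 7), 1))
  expect_equal(populationAbove(conc, pop, 35), 7)
  expect_equal(populationAbove(conc, pop, 40), 0)   # strict at the value
  expect_equal(populationAbove(conc, pop, 20), 12)
  expect_equal(populationAbove(conc, pop, 1000), 0)

  set.seed(4)
  cv <- fxConc(matrix(runif(64, 1, 100), 8, 8))
  pv <- fxPop(matrix(rpois(64, 20), 8, 8))
  thresholds <- seq(0, 110, by = 5)
  counts <- vapply(thresholds, function(t) populationAbove(cv, pv, t),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1L], sum(popCounts(pv)))  # strictly positive field
})

test_that("mean population-weighted RR averages the curve over cells", {
  p <- fxParams(theta = 0.1, alpha = 2, mu = 10, nu = 5)
  conc <- fxConc(matrix(c(2.4, 12.4), 1))
  pop <- fxPop(matrix(c(1, 1), 1))
  expect_equal(meanPopulationWeightedRR(conc, pop, p),
               (1 + exp(0.1 * log(6) * 0.5)) / 2, tolerance = 1e-12)

  # uniform field: RR at that concentration; all-below-threshold: exactly 1
  u <- fxConc(matrix(30, 3, 3))
  w <- fxPop(matrix(runif(9), 3, 3))
  expect_equal(meanPopulationWeightedRR(u, w, p), relativeRisk(30, p))
  expect_identical(meanPopulationWeightedRR(fxConc(matrix(2, 3, 3)), w, p), 1)

  # bounded by the cellwise extremes
  set.seed(5)
  cv <- matrix(runif(25, 0, 90), 5, 5)
  pv <- matrix(rpois(25, 10) + 1, 5, 5)
  m <- meanPopulationWeightedRR(fxConc(cv), fxPop(pv), p)
  rr <- relativeRisk(cv, p)
  expect_true(m >= min(rr) && m <= max(rr))

  expect_error(meanPopulationWeightedRR(u, fxPop(matrix(0, 3, 3)), p),
               "zero population")
  expect_error(
    meanPopulationWeightedRR(u, w, fxParams(age_group = "30-34")),
    "absent from population")
})

test_that("refinement invariance: splitting a cell leaves PWC and mean RR unchanged", {
  p <- fxParams()
  conc1 <- fxConc(matrix(c(10, 40), 1))
  pop1 <- fxPop(matrix(c(6, 4), 1))
  # split the 40 ug/m3 cell into two cells of the same concentration
  conc2 <- fxConc(matrix(c(10, 40, 40), 1))
  pop2 <- fxPop(matrix(c(6, 1, 3), 1))
  expect_equal(populationWeightedConcentration(conc1, pop1),
               populationWeightedConcentration(conc2, pop2))
  expect_equal(meanPopulationWeightedRR(conc1, pop1, p),
               meanPopulationWeightedRR(conc2, pop2, p))
})

test_that("region masks zero population outside the mask", {
  pop <- fxPop(matrix(1:9, 3, 3))
  mask <- matrix(FALSE, 3, 3)
  mask[1, ] <- TRUE
  masked <- applyRegionMask(pop, mask)
  expect_equal(sum(popCounts(masked)), sum((1:9)[c(1, 4, 7)]))
  expect_error(applyRegionMask(pop, matrix(TRUE, 2, 2)), "shape")
})

test_that("station evaluation is plain Pearson correlation", {
  expect_equal(pearsonStationEval(1:10, 1:10), 1)
  expect_equal(pearsonStationEval(1:10, -(1:10)), -1)
  expect_equal(pearsonStationEval(c(1, 2, 3), c(2, 4, 6)), 1)
  set.seed(6)
  a <- rnorm(50); b <- a + rnorm(50)
  expect_equal(pearsonStationEval(a, b), cor(a, b))
  expect_error(pearsonStationEval(c(1, 1, 1), 1:3), "constant")
  expect_error(pearsonStationEval(1:2, 1:2), "at least 3")
  expect_error(pearsonStationEval(1:3, 1:4), "paired")
})

test_that("fields round-trip through the long-table format", {
  set.seed(7)
  conc <- ConcentrationField(matrix(runif(12, 1, 90), 3, 4),
                             latEdges = seq(20, 35, by = 5),
                             lonEdges = seq(100, 120, by = 5),
                             scenario = "SSP1_RCP1.9", year = 2030L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeConcentrationField(conc, f)
  back <- readConcentrationField(f)
  expect_equal(concValues(back), concValues(conc))
  expect_identical(gridEdges(back), gridEdges(conc))
  expect_identical(scenarioLabel(back), "SSP1_RCP1.9")
  expect_identical(scenarioYear(back), 2030L)

  pop <- PopulationField(array(rpois(24, 30), c(2, 3, 4)), c("0-24", "25+"),
                         latEdges = seq(20, 35, by = 5),
                         lonEdges = seq(100, 120, by = 5))
  g <- withr::local_tempfile(fileext = ".tsv")
  writePopulationField(pop, g)
  pback <- readPopulationField(g)
  expect_equal(popCounts(pback), popCounts(pop))
  expect_identical(ageGroups(pback), ageGroups(pop))
  expect_true(checkRegistration(conc, pback))
})
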