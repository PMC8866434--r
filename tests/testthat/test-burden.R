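test_that("underlying incidence divides out the mean relative risk", {
  expect_equal(underlyingIncidence(0.01, 1), 0.01)
  expect_equal(underlyingIncidence(0, 1.7), 0)
  expect_equal(underlyingIncidence(0.01, 1.5), 0.0066667, tolerance = 1e-4)
  expect_true(underlyingIncidence(0.02, 1.3) <= 0.02)
  expect_error(underlyingIncidence(0.01, 0.9), ">= 1")
  expect_error(underlyingIncidence(-0.01, 1.5), ">= 0")
})

test_that("incidence table enforces key uniqueness and finite rates", {
  expect_error(incidenceTable(c("d", "d"), c("a", "a"), c(0.1, 0.2)),
               "duplicated")
  expect_error(incidenceTable("d", "a", -0.1), ">= 0")
  expect_error(incidenceTable("d", "a", Inf), "finite")
})

test_that("single-cell attributable deaths match hand arithmetic", {
  # P = 1000, I = 0.01, uniform RR = 1.5 =>
  # I-hat = 0.0066667, M = 1000 * 0.0066667 * 0.5 = 3.3333
  # choose theta so that RR(c) = 1.5 at c = 12.4 (logistic term = 1/2)
  theta <- log(1.5) / (log(6) * 0.5)
  p <- fxParams(theta = theta, alpha = 2, mu = 10, nu = 5)
  conc <- fxConc(matrix(12.4))
  pop <- fxPop(matrix(1000))
  inc <- incidenceTable("NCD+LRI", "25+", 0.01)
  b <- attributableMortality(conc, pop, inc, p)
  expect_equal(b$deaths_mean, 1000 * 0.01 * 0.5 / 1.5, tolerance = 1e-12)
  expect_equal(b$deaths_mean, 3.3333, tolerance = 1e-4)
})

test_that("uniform-field totals obey the attributable-fraction identity", {
  for (cval in c(8, 35, 53, 120)) {
    p <- fxParams(theta = 0.13, alpha = 1.6, mu = 15.5, nu = 36.8)
    conc <- fxConc(matrix(cval, 5, 5))
    pop <- fxPop(matrix(rpois(25, 400) + 1, 5, 5))
    inc <- incidenceTable("NCD+LRI", "25+", 0.012)
    b <- attributableMortality(conc, pop, inc, p)
    rr <- relativeRisk(cval, p)
    expect_equal(b$deaths_mean,
                 uniformFieldDeaths(sum(popCounts(pop)), 0.012, rr),
                 tolerance = 1e-12)
  }
})

test_that("vectorized burden equals the cell-by-cell brute-force oracle", {
  set.seed(11)
  for (rep in 1:3) {
    concMat <- matrix(runif(400, 0, 120), 20, 20)
    popMat <- matrix(rpois(400, 300), 20, 20)
    theta <- runif(1, 0.05, 0.2); alpha <- runif(1, 1, 20)
    mu <- runif(1, 5, 30); nu <- runif(1, 1, 50)
    i_rate <- runif(1, 0.001, 0.05)
    p <- fxParams(theta = theta, alpha = alpha, mu = mu, nu = nu)
    b <- attributableMortality(fxConc(concMat), fxPop(popMat),
                               incidenceTable("NCD+LRI", "25+", i_rate), p)
    expect_equal(b$deaths_mean,
                 oracleBurdenOne(concMat, popMat, i_rate, theta, alpha,
                                 mu, nu),
                 tolerance = 1e-9)
  }
})

test_that("burden is zero when the whole field sits at or below cmin", {
  p <- fxParams(theta = 0.15, theta_se = 0.02)
  b <- attributableMortality(fxConc(matrix(2.0, 4, 4)),
                             fxPop(matrix(100, 4, 4)),
                             incidenceTable("NCD+LRI", "25+", 0.01), p)
  expect_identical(b$deaths_mean, 0)
  expect_identical(b$deaths_low, 0)
  expect_identical(b$deaths_high, 0)
})

test_that("CI rows rerun the whole chain with perturbed theta", {
  set.seed(12)
  concMat <- matrix(runif(36, 5, 90), 6, 6)
  popMat <- matrix(rpois(36, 200), 6, 6)
  theta <- 0.12; se <- 0.02
  p <- fxParams(theta = theta, theta_se = se)
  inc <- incidenceTable("NCD+LRI", "25+", 0.015)
  b <- attributableMortality(fxConc(concMat), fxPop(popMat), inc, p)
  lo <- attributableMortality(fxConc(concMat), fxPop(popMat), inc,
                              fxParams(theta = theta - 1.96 * se))
  hi <- attributableMortality(fxConc(concMat), fxPop(popMat), inc,
                              fxParams(theta = theta + 1.96 * se))
  expect_equal(b$deaths_low, lo$deaths_mean, tolerance = 1e-12)
  expect_equal(b$deaths_high, hi$deaths_mean, tolerance = 1e-12)
  expect_true(b$deaths_low <= b$deaths_mean &&
              b$deaths_mean <= b$deaths_high)
  expect_match(attr(b, "ci_method"), "not propagated")
})

test_that("missing incidence for a modeled stratum is a configuration error", {
  p <- fxParams(age_group = "25-29")
  expect_error(
    attributableMortality(fxConc(matrix(30)), fxPop(matrix(10), "25-29"),
                          incidenceTable("NCD+LRI", "30-34", 0.01), p),
    "no incidence entry")
})

test_that("monotonicity: scaling all concentrations up never lowers deaths", {
  set.seed(13)
  base <- matrix(runif(64, 10, 60), 8, 8)  # everywhere above cmin
  pop <- fxPop(matrix(rpois(64, 100), 8, 8))
  inc <- incidenceTable("NCD+LRI", "25+", 0.01)
  p <- fxParams(theta = 0.14)
  totals <- vapply(c(1, 1.2, 1.5, 2, 3), function(k)
    sum(attributableMortality(fxConc(base * k), pop, inc, p)$deaths_mean),
    numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("avoided deaths difference REF minus policy, preserving sign", {
  set.seed(14)
  concMat <- matrix(runif(25, 20, 80), 5, 5)
  pop <- fxPop(matrix(rpois(25, 150), 5, 5))
  inc <- incidenceTable("NCD+LRI", "25+", 0.012)
  p <- fxParams(theta = 0.12, theta_se = 0.015)
  ref <- attributableMortality(fxConc(concMat, "REF"), pop, inc, p)
  pol <- attributableMortality(fxConc(concMat * 0.85, "RCP"), pop, inc, p)
  dm <- avoidedMortality(ref, pol)
  expect_equal(dm$deaths_mean, ref$deaths_mean - pol$deaths_mean)
  expect_true(dm$deaths_mean > 0)

  # identical tables give zero; worse policies give negative co-benefits
  expect_equal(avoidedMortality(ref, ref)$deaths_mean, 0)
  expect_true(avoidedMortality(pol, ref)$deaths_mean < 0)

  # antisymmetry of the point estimate
  expect_equal(avoidedMortality(ref, pol)$deaths_mean,
               -avoidedMortality(pol, ref)$deaths_mean)

  # key mismatch names the offending key
  other <- ref
  other$age_group <- "30-34"
  expect_error(avoidedMortality(ref, other), "30-34")
})

test_that("aggregation conserves totals under any grouping", {
  set.seed(15)
  ages <- c("25-29", "30-34", "35-39")
  concMat <- matrix(runif(16, 15, 70), 4, 4)
  pop <- PopulationField(array(rpois(48, 120), c(3, 4, 4)), ages)
  inc <- incidenceTable(rep("NCD+LRI", 3), ages, c(0.002, 0.004, 0.008))
  p <- GEMMParams(rep("NCD+LRI", 3), ages, theta = c(0.1, 0.12, 0.14),
                  theta_se = 0.01, alpha = 3, mu = 12, nu = 20)
  b <- attributableMortality(fxConc(concMat), pop, inc, p)
  total <- aggregateBurden(b)
  expect_equal(nrow(total), 1L)
  expect_equal(total$deaths_mean, sum(b$deaths_mean))
  byAge <- aggregateBurden(b, by = "age_group")
  expect_equal(sum(byAge$deaths_mean), total$deaths_mean)
  expect_equal(sum(byAge$deaths_low), total$deaths_low)
  byBoth <- aggregateBurden(b, by = c("disease", "age_group"))
  expect_equal(sum(byBoth$deaths_high), total$deaths_high)
  expect_error(aggregateBurden(b, by = "province"), "unknown grouping")

  # explicit two-group check
  two <- b[1:2, ]
  two$deaths_mean <- c(10, 20); two$deaths_low <- c(8, 15)
  two$deaths_high <- c(12, 25)
  expect_equal(aggregateBurden(two)$deaths_mean, 30)
})

test_that("burden tables round-trip with the ci_method note", {
  b <- attributableMortality(fxConc(matrix(c(20, 50), 1)),
                             fxPop(matrix(c(100, 300), 1)),
                             incidenceTable("NCD+LRI", "25+", 0.01),
                             fxParams(theta_se = 0.01))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeBurdenTable(b, f)
  back <- readBurdenTable(f)
  expect_equal(back$deaths_mean, b$deaths_mean)
  expect_equal(back$deaths_low, b$deaths_low)
  expect_match(attr(back, "ci_method"), "theta shift")
})
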