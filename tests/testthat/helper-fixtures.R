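# Shared fixture builders and independent oracles.

# Single-row GEMM parameter set with convenient defaults.
fxParams <- function(theta = 0.1, alpha = 2, mu = 10, nu = 5,
                     theta_se = 0, cmin = 2.4,
                     disease = "NCD+LRI", age_group = "25+") {
  GEMMParams(disease, age_group, theta = theta, theta_se = theta_se,
             alpha = alpha, mu = mu, nu = nu, cmin = cmin)
}

# Concentration field from a matrix (unit-degree grid).
fxConc <- function(values, scenario = "REF", year = 2050L) {
  ConcentrationField(as.matrix(values), scenario = scenario, year = year)
}

# Single-age population field matching a concentration matrix's shape.
fxPop <- function(weights, age_group = "25+") {
  w <- as.matrix(weights)
  PopulationField(array(w, dim = c(1L, nrow(w), ncol(w))), age_group)
}

# Independent step-by-step oracle for the exposure-response curve:
# deliberately different code path (plogis for the logistic factor,
# scalar log1p formulation) from the implementation.
oracleRR <- function(c, theta, alpha, mu, nu, cmin = 2.4) {
  vapply(c, function(ci) {
    if (ci <= cmin) return(1)
    z <- ci - cmin
    hazard_scale <- log1p(z / alpha)
    weight <- stats::plogis((z - mu) / nu)
    exp(theta * hazard_scale * weight)
  }, numeric(1))
}

# Unvectorized cell-by-cell oracle for attributable deaths of one
# (disease, age) stratum: explicit loops, no reuse of package internals.
oracleBurdenOne <- function(concMat, popMat, i_rate, theta, alpha, mu, nu,
                            cmin = 2.4) {
  num <- 0; den <- 0
  for (r in seq_len(nrow(concMat)))
    for (cc in seq_len(ncol(concMat))) {
      rr <- oracleRR(concMat[r, cc], theta, alpha, mu, nu, cmin)
      num <- num + popMat[r, cc] * rr
      den <- den + popMat[r, cc]
    }
  rr_bar <- num / den
  i_hat <- i_rate / rr_bar
  m <- 0
  for (r in seq_len(nrow(concMat)))
    for (cc in seq_len(ncol(concMat)))
      m <- m + popMat[r, cc] * i_hat *
        (oracleRR(concMat[r, cc], theta, alpha, mu, nu, cmin) - 1)
  m
}

# Closed-form total deaths on a spatially uniform field:
# M = P * I * (RR - 1) / RR (the attributable-fraction identity).
uniformFieldDeaths <- function(P, I, rr) P * I * (rr - 1) / rr
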