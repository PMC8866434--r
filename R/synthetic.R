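# Default China-like adult age structure: under-25 share plus 5-year adult
# bands to 85+; proportions normalized to sum exactly to 1.
.DEFAULT_AGE_GROUPS <- c("0-24", "25-29", "30-34", "35-39", "40-44",
                         "45-49", "50-54", "55-59", "60-64", "65-69",
                         "70-74", "75-79", "80-84", "85+")
.DEFAULT_AGE_WEIGHTS <- c(0.295, 0.082, 0.090, 0.078, 0.082, 0.085, 0.078,
                          0.067, 0.051, 0.038, 0.026, 0.016, 0.008, 0.004)

.defaultAgeProfile <- function() .DEFAULT_AGE_WEIGHTS / sum(.DEFAULT_AGE_WEIGHTS)

#' Build a synthetic-input specification
#'
#' Defaults describe the desk-scale study conditions the generator
#' emulates: a 48 x 48 grid with an unweighted mean of 53 \eqn{\mu g/m^3}
#' (the national population-weighted 2015 level), moderate log-normal
#' spatial variability, a 50-million-person clustered population with a
#' China-like age structure (adult 5-year bands from 25 to 85+), and a
#' policy scenario 10\% below the reference field cell-wise.
#'
#' @param gridShape integer (nlat, nlon).
#' @param concMean target grid-mean PM2.5, \eqn{\mu g/m^3}.
#' @param concCorrLength moving-average smoothing length, cells.
#' @param concSigma log-scale SD of the field; 0 gives an exactly uniform
#'   field (useful for closed-form checks).
#' @param popTotal total persons.
#' @param popClusters number of population clusters.
#' @param ageGroups,ageProfile labels and proportions (sum to 1); defaults
#'   to the built-in structure.
#' @param reductionFraction policy-scenario fractional reduction in [0, 1).
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(gridShape = c(48L, 48L), concMean = 53,
                          concCorrLength = 4, concSigma = 0.45,
                          popTotal = 5e7, popClusters = 6L,
                          ageGroups = .DEFAULT_AGE_GROUPS,
                          ageProfile = .defaultAgeProfile(),
                          reductionFraction = 0.1, seed = 1L) {
  new("SyntheticSpec", gridShape = as.integer(gridShape),
      concMean = as.numeric(concMean),
      concCorrLength = as.numeric(concCorrLength),
      concSigma = as.numeric(concSigma), popTotal = as.numeric(popTotal),
      popClusters = as.integer(popClusters),
      ageGroups = as.character(ageGroups),
      ageProfile = as.numeric(ageProfile),
      reductionFraction = as.numeric(reductionFraction),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d x %d grid, mean %.1f ug/m3 (sigma %.2f, corr %.1f cells)\n",
    object@gridShape[1L], object@gridShape[2L], object@concMean,
    object@concSigma, object@concCorrLength))
  cat(sprintf("  population %.3g in %d cluster(s), %d age group(s)\n",
              object@popTotal, object@popClusters, length(object@ageGroups)))
  cat(sprintf("  policy reduction %.1f%%, seed %d\n",
              100 * object@reductionFraction, object@seed))
  invisible(object)
})

# Run fn with a seed derived from the spec seed plus a small stream offset,
# restoring the caller's RNG state afterwards.
.withSpecSeed <- function(seed, offset, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  fn()
}

#' Largest-remainder integer apportionment
#'
#' Distributes an integer \code{total} across categories proportionally to
#' non-negative \code{weights}: floors of the exact shares, then one extra
#' unit to the categories with the largest fractional remainders (ties
#' broken by first index). Sums to \code{total} exactly.
#'
#' @param weights non-negative weights (not all zero unless total is 0).
#' @param total non-negative integer.
#' @return Integer-valued numeric vector summing to \code{total}.
#' @export
largestRemainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0, total == round(total))
  if (total == 0) return(numeric(length(weights)))
  if (sum(weights) <= 0) stop("all-zero weights with a positive total")
  exact <- weights / sum(weights) * total
  base <- floor(exact)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base
}

# Separable moving-average smoother with reflecting edges; kernel width
# ~ correlation length.
.smoothField <- function(x, corrLength) {
  w <- max(1L, as.integer(round(corrLength)))
  if (w == 1L) return(x)
  k <- rep(1 / w, w)
  smooth1 <- function(m) {
    pad <- (w %/% 2) + 1L
    mp <- rbind(m[rev(seq_len(pad)), , drop = FALSE], m,
                m[nrow(m) - seq_len(pad) + 1L, , drop = FALSE])
    sm <- apply(mp, 2L, function(col)
      stats::filter(col, k, sides = 2L))
    sm[pad + seq_len(nrow(m)), , drop = FALSE]
  }
  t(smooth1(t(smooth1(x))))
}

#' Generate a paired reference/policy concentration scenario
#'
#' The reference field is a positive, spatially correlated log-Gaussian
#' surface: smoothed white noise standardized to the requested log-scale
#' SD, exponentiated, then rescaled so the unweighted grid mean equals
#' \code{concMean} exactly. The policy field is the reference scaled
#' cell-wise by \code{1 - reductionFraction}. Deterministic under the spec
#' seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param refLabel,policyLabel scenario labels.
#' @param year year label attached to both fields.
#' @param ... unused.
#' @return List with elements \code{ref} and \code{policy}, both
#'   [ConcentrationField-class] objects on the same grid.
#' @export
setMethod("makeConcentrationPair", "SyntheticSpec",
  function(spec, refLabel = "REF", policyLabel = "POLICY",
           year = 2050L, ...) {
    validObject(spec)
    nlat <- spec@gridShape[1L]
    nlon <- spec@gridShape[2L]
    vals <- .withSpecSeed(spec@seed, 0L, function() {
      if (spec@concSigma == 0)
        return(matrix(spec@concMean, nlat, nlon))
      z <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
      z <- .smoothField(z, spec@concCorrLength)
      s <- stats::sd(as.vector(z))
      if (s > 0) z <- (z - mean(z)) / s * spec@concSigma
      f <- exp(z)
      f * (spec@concMean / mean(f))
    })
    ref <- ConcentrationField(vals, scenario = refLabel, year = year)
    pol <- ConcentrationField(vals * (1 - spec@reductionFraction),
                              latEdges = ref@latEdges,
                              lonEdges = ref@lonEdges,
                              scenario = policyLabel, year = year)
    list(ref = ref, policy = pol)
  })

#' Generate a clustered, age-structured population grid
#'
#' Spatial density is a mixture of Gaussian clusters over a small uniform
#' background. Counts are integers: the total is first apportioned across
#' age groups by largest remainder on \code{ageProfile}, then each age
#' total is apportioned across cells by largest remainder on the shared
#' density, so the grand total equals \code{popTotal} exactly.
#'
#' @param spec a [SyntheticSpec-class].
#' @param ... unused.
#' @return A [PopulationField-class] on the same grid convention as
#'   [makeConcentrationPair()].
#' @export
setMethod("makePopulation", "SyntheticSpec",
  function(spec, ...) {
    validObject(spec)
    nlat <- spec@gridShape[1L]
    nlon <- spec@gridShape[2L]
    dens <- .withSpecSeed(spec@seed, 1L, function() {
      lat <- matrix(seq_len(nlat), nlat, nlon)
      lon <- matrix(seq_len(nlon), nlat, nlon, byrow = TRUE)
      d <- matrix(0.02, nlat, nlon)  # diffuse rural background
      for (k in seq_len(spec@popClusters)) {
        c_lat <- stats::runif(1, 1, nlat)
        c_lon <- stats::runif(1, 1, nlon)
        width <- stats::runif(1, 1.5, max(3, min(nlat, nlon) / 6))
        weight <- stats::runif(1, 0.5, 1)
        d <- d + weight *
          exp(-((lat - c_lat)^2 + (lon - c_lon)^2) / (2 * width^2))
      }
      d
    })
    nAge <- length(spec@ageGroups)
    perAge <- largestRemainder(spec@ageProfile, spec@popTotal)
    counts <- array(0, dim = c(nAge, nlat, nlon))
    for (j in seq_len(nAge)) {
      if (perAge[j] > 0)
        counts[j, , ] <- matrix(largestRemainder(as.vector(dens), perAge[j]),
                                nlat, nlon)
    }
    PopulationField(counts, spec@ageGroups)
  })

#' Generate a baseline incidence table and GEMM-like parameters
#'
#' Emulates a burden-of-disease style cause-specific mortality table and
#' a GEMM-shaped fit-parameter table for the combined NCD+LRI endpoint:
#' incidence rises roughly exponentially with adult age (from a few per
#' 10,000 person-years at 25-29 to above 1 per 10 at 85+), and each adult
#' age band gets a positive \eqn{\theta} with a 10\% relative standard
#' error and curve-shape parameters in plausible ranges
#' (\eqn{\alpha \in [1, 20]}, \eqn{\mu \in [5, 30]},
#' \eqn{\nu \in [1, 50]} \eqn{\mu g/m^3}). Age groups below 25 get no
#' parameter row (relative risk applies to adults only). Deterministic
#' under the spec seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param diseases disease labels (default the combined \code{"NCD+LRI"}).
#' @param thetaZero generate a null-effect table (\eqn{\theta = 0},
#'   SE = 0) so the downstream burden is exactly 0.
#' @param ... unused.
#' @return List with \code{incidence} (an [incidenceTable()]) and
#'   \code{params} (a [GEMMParams-class]).
#' @export
setMethod("makeIncidenceAndParams", "SyntheticSpec",
  function(spec, diseases = "NCD+LRI", thetaZero = FALSE, ...) {
    validObject(spec)
    adult <- grep("^(2[5-9]|[3-9][0-9])", spec@ageGroups, value = TRUE)
    if (!length(adult))
      stop("spec has no adult (>= 25) age groups")
    ageMid <- vapply(adult, function(a) {
      n <- as.numeric(sub("[-+].*$", "", a))
      if (grepl("\\+$", a)) n + 5 else n + 2.5
    }, numeric(1))
    .withSpecSeed(spec@seed, 2L, function() {
      inc <- do.call(rbind, lapply(diseases, function(d) {
        jitter <- exp(stats::rnorm(length(adult), 0, 0.05))
        incidenceTable(d, adult,
                       3e-4 * exp(0.095 * (ageMid - 27.5)) * jitter)
      }))
      par <- do.call(rbind, lapply(diseases, function(d) {
        theta <- if (thetaZero) rep(0, length(adult)) else
          stats::runif(length(adult), 0.08, 0.18)
        data.frame(disease = d, age_group = adult, theta = theta,
                   theta_se = if (thetaZero) 0 else 0.1 * theta,
                   alpha = stats::runif(length(adult), 1, 20),
                   mu = stats::runif(length(adult), 5, 30),
                   nu = stats::runif(length(adult), 1, 50),
                   stringsAsFactors = FALSE)
      }))
      list(incidence = inc,
           params = GEMMParams(par$disease, par$age_group,
                               theta = par$theta, theta_se = par$theta_se,
                               alpha = par$alpha, mu = par$mu, nu = par$nu))
    })
  })
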