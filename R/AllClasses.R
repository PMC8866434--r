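#' @import methods
NULL

#' GEMM concentration-response parameter sets
#'
#' Container for Global Exposure Mortality Model (GEMM) fit parameters, one
#' row per (disease, age group): the log-relative-risk scale coefficient
#' \eqn{\theta} with its standard error, the log-term scale \eqn{\alpha}
#' (\eqn{\mu g/m^3}), the logistic center \eqn{\mu} and width \eqn{\nu}
#' (\eqn{\mu g/m^3}), and the theoretical minimum-risk concentration
#' \code{cmin} below which no excess risk is attributed (default
#' 2.4 \eqn{\mu g/m^3}).
#'
#' @slot params data.frame with columns \code{disease}, \code{age_group},
#'   \code{theta}, \code{theta_se}, \code{alpha}, \code{mu}, \code{nu},
#'   \code{cmin}.
#' @seealso [GEMMParams()], [relativeRisk()], [readGEMMParams()]
#' @export
setClass("GEMMParams", representation(params = "data.frame"))

.validGEMMParams <- function(object) {
  p <- object@params
  need <- c("disease", "age_group", "theta", "theta_se",
            "alpha", "mu", "nu", "cmin")
  miss <- setdiff(need, names(p))
  if (length(miss))
    return(paste("missing parameter columns:", paste(miss, collapse = ", ")))
  num <- c("theta", "theta_se", "alpha", "mu", "nu", "cmin")
  for (cl in num) {
    if (!is.numeric(p[[cl]]) || anyNA(p[[cl]]) || any(!is.finite(p[[cl]])))
      return(paste0("column '", cl, "' must be finite numeric"))
  }
  if (any(p$alpha <= 0)) return("alpha must be > 0")
  if (any(p$nu <= 0)) return("nu must be > 0")
  if (any(p$cmin < 0)) return("cmin must be >= 0")
  if (any(p$theta_se < 0)) return("theta_se must be >= 0")
  key <- paste(p$disease, p$age_group, sep = " / ")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    return(paste("duplicated (disease, age_group):",
                 paste(dup, collapse = "; ")))
  }
  TRUE
}
setValidity("GEMMParams", .validGEMMParams)

#' Gridded annual-mean PM2.5 concentration field
#'
#' A 2-D concentration field on a regular latitude/longitude grid described
#' by strictly increasing cell-edge coordinates. Values are annual-mean
#' PM2.5 in \eqn{\mu g/m^3}; rows index latitude, columns longitude.
#'
#' @slot values numeric matrix (nlat x nlon), finite and non-negative.
#' @slot latEdges,lonEdges strictly increasing numeric cell edges of length
#'   \code{nrow(values) + 1} and \code{ncol(values) + 1}.
#' @slot scenario scenario label, e.g. \code{"SSP1_RCP1.9"}.
#' @slot year calendar year label (no time dynamics are implied).
#' @seealso [ConcentrationField()], [populationWeightedConcentration()]
#' @export
setClass("ConcentrationField",
         representation(values = "matrix", latEdges = "numeric",
                        lonEdges = "numeric", scenario = "character",
                        year = "integer"))

.checkEdges <- function(edges, n, what) {
  if (length(edges) != n + 1L)
    return(sprintf("%s must have length %d (cells + 1), got %d",
                   what, n + 1L, length(edges)))
  if (anyNA(edges) || any(!is.finite(edges)))
    return(paste(what, "must be finite"))
  if (any(diff(edges) <= 0))
    return(paste(what, "must be strictly increasing"))
  NULL
}

.validConcentrationField <- function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite")
  if (any(v < 0)) return("concentrations must be >= 0")
  e <- .checkEdges(object@latEdges, nrow(v), "latEdges")
  if (!is.null(e)) return(e)
  e <- .checkEdges(object@lonEdges, ncol(v), "lonEdges")
  if (!is.null(e)) return(e)
  if (length(object@scenario) != 1L) return("scenario must be length 1")
  if (length(object@year) != 1L) return("year must be length 1")
  TRUE
}
setValidity("ConcentrationField", .validConcentrationField)

#' Gridded age-structured population field
#'
#' Person counts on the same grid convention as [ConcentrationField-class],
#' with a leading age-group dimension: \code{counts[j, , ]} is the gridded
#' population of age group \code{j}.
#'
#' @slot counts numeric array (n_age x nlat x nlon), finite, non-negative.
#' @slot ageGroups unique ordered age-group labels, one per slice.
#' @slot latEdges,lonEdges as for [ConcentrationField-class].
#' @seealso [PopulationField()], [makePopulation()]
#' @export
setClass("PopulationField",
         representation(counts = "array", ageGroups = "character",
                        latEdges = "numeric", lonEdges = "numeric"))

.validPopulationField <- function(object) {
  a <- object@counts
  if (!is.numeric(a) || length(dim(a)) != 3L)
    return("counts must be a 3-D numeric array (age x lat x lon)")
  if (anyNA(a) || any(!is.finite(a))) return("counts must be finite")
  if (any(a < 0)) return("counts must be >= 0")
  if (length(object@ageGroups) != dim(a)[1L])
    return("one age-group label per array slice is required")
  if (anyDuplicated(object@ageGroups)) return("age groups must be unique")
  e <- .checkEdges(object@latEdges, dim(a)[2L], "latEdges")
  if (!is.null(e)) return(e)
  e <- .checkEdges(object@lonEdges, dim(a)[3L], "lonEdges")
  if (!is.null(e)) return(e)
  TRUE
}
setValidity("PopulationField", .validPopulationField)

#' Value-of-statistical-life model
#'
#' Two variants are supported. \code{"local_linear"} follows a linear
#' relationship between VSL and per-capita income:
#' \deqn{VSL(inc) = VSL_{baseline} + (inc - INC_{baseline}) \cdot MVSL,}
#' with \eqn{MVSL} the marginal VSL in USD of VSL per USD of annual income.
#' \code{"international_transfer"} is the standard benefit-transfer power
#' law \eqn{VSL(inc) = VSL_{ref} (inc / INC_{ref})^{\beta}} with income
#' elasticity \eqn{\beta \in [0, 2]}.
#'
#' @slot variant \code{"local_linear"} or \code{"international_transfer"}.
#' @slot vslBaseline,incomeBaseline,mvslSlope local-linear parameters (USD,
#'   USD/person/year, USD of VSL per USD of income).
#' @slot vslReference,incomeReference,beta transfer parameters.
#' @seealso [vslModelLocalLinear()], [vslModelInternationalTransfer()],
#'   [vsl()]
#' @export
setClass("VSLModel",
         representation(variant = "character", vslBaseline = "numeric",
                        incomeBaseline = "numeric", mvslSlope = "numeric",
                        vslReference = "numeric", incomeReference = "numeric",
                        beta = "numeric"))

.validVSLModel <- function(object) {
  if (!object@variant %in% c("local_linear", "international_transfer"))
    return("variant must be 'local_linear' or 'international_transfer'")
  mono <- c(vslBaseline = object@vslBaseline,
            incomeBaseline = object@incomeBaseline,
            vslReference = object@vslReference,
            incomeReference = object@incomeReference)
  if (anyNA(mono) || any(!is.finite(mono)) || any(mono < 0))
    return("monetary parameters must be finite and >= 0")
  if (!is.finite(object@mvslSlope))
    return("mvslSlope must be finite")
  if (!is.finite(object@beta) || object@beta < 0 || object@beta > 2)
    return("beta must lie in [0, 2]")
  if (object@variant == "international_transfer" &&
      object@incomeReference <= 0)
    return("incomeReference must be > 0 for international transfer")
  TRUE
}
setValidity("VSLModel", .validVSLModel)

#' Specification for the synthetic input generator
#'
#' Describes a desk-scale emulation of the study's inputs: a spatially
#' correlated log-Gaussian concentration field with a paired policy
#' scenario scaled down by \code{reductionFraction}, a clustered population
#' grid split by \code{ageProfile}, and a cause-specific incidence table
#' with GEMM-like parameters. All randomness derives from \code{seed}.
#'
#' @slot gridShape integer (nlat, nlon).
#' @slot concMean target unweighted grid-mean concentration, \eqn{\mu g/m^3}.
#' @slot concCorrLength smoothing length of the noise field, in cells.
#' @slot concSigma log-scale standard deviation; 0 gives an exactly uniform
#'   field.
#' @slot popTotal total persons across all ages and cells.
#' @slot popClusters number of Gaussian population clusters.
#' @slot ageGroups,ageProfile age-group labels and proportions (sum to 1).
#' @slot reductionFraction fractional cell-wise concentration reduction of
#'   the policy scenario relative to REF, in [0, 1).
#' @slot seed integer RNG seed.
#' @seealso [syntheticSpec()], [makeConcentrationPair()],
#'   [makePopulation()], [makeIncidenceAndParams()]
#' @export
setClass("SyntheticSpec",
         representation(gridShape = "integer", concMean = "numeric",
                        concCorrLength = "numeric", concSigma = "numeric",
                        popTotal = "numeric", popClusters = "integer",
                        ageGroups = "character", ageProfile = "numeric",
                        reductionFraction = "numeric", seed = "integer"))

.validSyntheticSpec <- function(object) {
  if (length(object@gridShape) != 2L || any(object@gridShape < 1L))
    return("gridShape must be two positive integers")
  if (object@concMean <= 0) return("concMean must be > 0")
  if (object@concCorrLength <= 0) return("concCorrLength must be > 0")
  if (object@concSigma < 0) return("concSigma must be >= 0")
  if (object@popTotal < 0) return("popTotal must be >= 0")
  if (object@popClusters < 1L) return("popClusters must be >= 1")
  if (length(object@ageProfile) != length(object@ageGroups))
    return("ageProfile and ageGroups must have equal length")
  if (any(object@ageProfile < 0))
    return("age proportions must be >= 0")
  if (abs(sum(object@ageProfile) - 1) > 1e-9)
    return("age proportions must sum to 1 (within 1e-9)")
  if (object@reductionFraction < 0 || object@reductionFraction >= 1)
    return("reductionFraction must lie in [0, 1)")
  TRUE
}
setValidity("SyntheticSpec", .validSyntheticSpec)
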