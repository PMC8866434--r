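#' Construct a gridded concentration field
#'
#' @param values numeric matrix of annual-mean PM2.5 (\eqn{\mu g/m^3});
#'   rows are latitude cells, columns longitude cells.
#' @param latEdges,lonEdges strictly increasing cell-edge coordinates
#'   (degrees), lengths \code{nrow(values) + 1} / \code{ncol(values) + 1}.
#'   Default: unit-degree edges starting at 0.
#' @param scenario scenario label.
#' @param year calendar year label.
#' @return A validated [ConcentrationField-class] object.
#' @export
ConcentrationField <- function(values,
                               latEdges = seq_len(nrow(values) + 1L) - 1,
                               lonEdges = seq_len(ncol(values) + 1L) - 1,
                               scenario = "unnamed", year = NA_integer_) {
  if (!is.matrix(values)) values <- as.matrix(values)
  new("ConcentrationField", values = values,
      latEdges = as.numeric(latEdges), lonEdges = as.numeric(lonEdges),
      scenario = as.character(scenario), year = as.integer(year))
}

#' Construct a gridded age-structured population field
#'
#' @param counts 3-D numeric array (age group x lat x lon) of persons.
#' @param ageGroups unique ordered labels, one per leading slice.
#' @param latEdges,lonEdges as for [ConcentrationField()].
#' @return A validated [PopulationField-class] object.
#' @export
PopulationField <- function(counts, ageGroups,
                            latEdges = seq_len(dim(counts)[2L] + 1L) - 1,
                            lonEdges = seq_len(dim(counts)[3L] + 1L) - 1) {
  new("PopulationField", counts = counts, ageGroups = as.character(ageGroups),
      latEdges = as.numeric(latEdges), lonEdges = as.numeric(lonEdges))
}

#' @describeIn ConcentrationField Concentration matrix accessor.
#' @param object a field object.
#' @export
concValues <- function(object) {
  stopifnot(is(object, "ConcentrationField"))
  object@values
}

#' @describeIn ConcentrationField Scenario label accessor.
#' @export
scenarioLabel <- function(object) {
  stopifnot(is(object, "ConcentrationField"))
  object@scenario
}

#' @describeIn ConcentrationField Year label accessor.
#' @export
scenarioYear <- function(object) {
  stopifnot(is(object, "ConcentrationField"))
  object@year
}

#' @describeIn PopulationField Count array accessor (age x lat x lon).
#' @param object a field object.
#' @export
popCounts <- function(object) {
  stopifnot(is(object, "PopulationField"))
  object@counts
}

#' @describeIn PopulationField Age-group label accessor.
#' @export
ageGroups <- function(object) {
  stopifnot(is(object, "PopulationField"))
  object@ageGroups
}

#' Grid cell-edge accessor
#'
#' @param object a [ConcentrationField-class] or [PopulationField-class].
#' @return List with \code{lat} and \code{lon} edge vectors.
#' @export
gridEdges <- function(object) {
  stopifnot(is(object, "ConcentrationField") || is(object, "PopulationField"))
  list(lat = object@latEdges, lon = object@lonEdges)
}

setMethod("show", "ConcentrationField", function(object) {
  v <- object@values
  cat(sprintf("ConcentrationField '%s' (year %s): %d x %d cells\n",
              object@scenario, object@year, nrow(v), ncol(v)))
  cat(sprintf("  PM2.5 range %.2f - %.2f, unweighted mean %.2f ug/m3\n",
              min(v), max(v), mean(v)))
  invisible(object)
})

setMethod("show", "PopulationField", function(object) {
  d <- dim(object@counts)
  cat(sprintf("PopulationField: %d age group(s) on %d x %d cells, %s persons\n",
              d[1L], d[2L], d[3L],
              format(sum(object@counts), big.mark = ",")))
  invisible(object)
})

#' Are two gridded fields co-registered?
#'
#' Two fields are co-registered when their latitude and longitude cell
#' edges agree elementwise (same lengths, same order) within \code{tol}
#' degrees. Edge ordering is part of the contract: the same edges stored
#' reversed are not registered. All exposure and burden computations refuse
#' misregistered inputs; no regridding happens inside the pipeline.
#'
#' @param conc a [ConcentrationField-class].
#' @param pop a [PopulationField-class] (or second concentration field).
#' @param tol absolute edge tolerance in degrees.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
setMethod("checkRegistration",
          signature(conc = "ANY", pop = "ANY"),
  function(conc, pop, tol = 1e-9) {
    a <- gridEdges(conc)
    b <- gridEdges(pop)
    length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
      all(abs(a$lat - b$lat) <= tol) && all(abs(a$lon - b$lon) <= tol)
  })

.stopIfMisregistered <- function(conc, pop) {
  if (!checkRegistration(conc, pop))
    stop("concentration and population grids are not co-registered; ",
         "inputs must share identical cell edges (no regridding is done)")
  invisible(TRUE)
}

# All-age population matrix (lat x lon).
.popAllAges <- function(pop) {
  apply(pop@counts, c(2L, 3L), sum)
}

.popForAge <- function(pop, age_group) {
  j <- match(age_group, pop@ageGroups)
  if (is.na(j))
    stop("age group '", age_group, "' absent from population field (has: ",
         paste(pop@ageGroups, collapse = ", "), ")")
  matrix(pop@counts[j, , ], nrow = dim(pop@counts)[2L])
}

#' Population-weighted mean concentration (PWC)
#'
#' \deqn{PWC = \sum_g C_g P_g / \sum_g P_g} with cell population summed
#' over all age groups. The exposure summary the study reports per
#' scenario (e.g. 53.0 \eqn{\mu g/m^3} nationally in 2015).
#'
#' @param conc a [ConcentrationField-class].
#' @param pop a co-registered [PopulationField-class] with positive total.
#' @return Scalar PWC in \eqn{\mu g/m^3}, bounded by the field's range.
#' @export
setMethod("populationWeightedConcentration",
          signature(conc = "ConcentrationField", pop = "PopulationField"),
  function(conc, pop) {
    .stopIfMisregistered(conc, pop)
    w <- .popAllAges(pop)
    tw <- sum(w)
    if (tw <= 0)
      stop("population-weighted concentration undefined: total population is 0")
    sum(conc@values * w) / tw
  })

#' Population above a concentration threshold
#'
#' Total persons (all ages) living in cells whose annual-mean concentration
#' strictly exceeds \code{threshold}. Strict inequality: an air-quality
#' goal of "at most 35 \eqn{\mu g/m^3}" is attained at exactly 35, so
#' non-attainment is \eqn{C > 35}.
#'
#' @param conc a [ConcentrationField-class].
#' @param pop a co-registered [PopulationField-class].
#' @param threshold \eqn{\mu g/m^3}.
#' @return Persons; monotone non-increasing in \code{threshold}.
#' @export
setMethod("populationAbove",
          signature(conc = "ConcentrationField", pop = "PopulationField",
                    threshold = "numeric"),
  function(conc, pop, threshold) {
    .stopIfMisregistered(conc, pop)
    stopifnot(length(threshold) == 1L, is.finite(threshold))
    sum(.popAllAges(pop)[conc@values > threshold])
  })

#' Average population-weighted relative risk
#'
#' \deqn{\bar{RR} = \sum_g P_{g,j} RR(C_g) / \sum_g P_{g,j}} over grid
#' cells \eqn{g}, using one age group's population as weights. This is the
#' quantity that converts reported incidence into the hypothetical
#' underlying incidence (see [underlyingIncidence()]).
#'
#' @param conc a [ConcentrationField-class].
#' @param pop a co-registered [PopulationField-class] containing the
#'   parameter set's age group.
#' @param params a single-set [GEMMParams-class].
#' @param ... unused.
#' @return Scalar \eqn{\bar{RR} \ge 1} for \eqn{\theta \ge 0}; exactly 1
#'   when every cell is at or below \code{cmin}.
#' @export
setMethod("meanPopulationWeightedRR",
          signature(conc = "ConcentrationField", pop = "PopulationField",
                    params = "GEMMParams"),
  function(conc, pop, params, ...) {
    .stopIfMisregistered(conc, pop)
    p <- .singleParams(params)
    w <- .popForAge(pop, p$age_group)
    tw <- sum(w)
    if (tw <= 0)
      stop("mean population-weighted RR undefined: age group '",
           p$age_group, "' has zero population")
    rr <- relativeRisk(conc@values, params)
    sum(w * rr) / tw
  })

#' Restrict a population field to a region mask
#'
#' Zeroes population outside a boolean lat x lon mask, so downstream
#' exposure and burden summaries become region-specific without any GIS
#' machinery.
#'
#' @param pop a [PopulationField-class].
#' @param mask logical matrix matching the grid shape; \code{TRUE} keeps a
#'   cell.
#' @return A new [PopulationField-class].
#' @export
applyRegionMask <- function(pop, mask) {
  stopifnot(is(pop, "PopulationField"), is.logical(mask))
  d <- dim(pop@counts)
  if (!identical(dim(mask), d[2:3]))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match grid ", paste(d[2:3], collapse = "x"))
  cnt <- pop@counts
  keep <- array(rep(as.numeric(mask), each = d[1L]), dim = d)
  PopulationField(cnt * keep, pop@ageGroups, pop@latEdges, pop@lonEdges)
}

#' Pearson evaluation of simulated against observed values
#'
#' Standard Pearson correlation between paired simulated and observed
#' annual means (the station-evaluation statistic for chemical-transport
#' output; the study reports r of about 0.81 against ~1500 stations).
#'
#' @param simulated,observed numeric vectors of equal length \eqn{\ge 3}.
#' @return Pearson r in \eqn{[-1, 1]}.
#' @export
pearsonStationEval <- function(simulated, observed) {
  stopifnot(is.numeric(simulated), is.numeric(observed))
  if (length(simulated) != length(observed))
    stop("simulated and observed must be paired (equal length)")
  if (length(simulated) < 3L)
    stop("at least 3 station pairs are required")
  if (stats::sd(simulated) == 0 || stats::sd(observed) == 0)
    stop("correlation undefined for a constant series")
  stats::cor(simulated, observed, method = "pearson")
}
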