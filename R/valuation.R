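#' Local linear VSL model
#'
#' VSL grows linearly with per-capita annual income:
#' \code{VSL(inc) = vslBaseline + (inc - incomeBaseline) * mvslSlope}.
#' The default slope is the Chongqing contingent-valuation marginal VSL —
#' a 14,550 USD rise in VSL per 145.8 USD rise in annual income
#' (about 99.79 USD of VSL per USD of income).
#'
#' The default \code{vslBaseline} and \code{incomeBaseline} are
#' order-of-magnitude placeholders for a 2015 China baseline, not study
#' values; set them from your own valuation baseline.
#'
#' @param vslBaseline VSL at the baseline income, USD.
#' @param incomeBaseline baseline per-capita annual income, USD.
#' @param mvslSlope marginal VSL, USD of VSL per USD of income.
#' @return A [VSLModel-class] with variant \code{"local_linear"}.
#' @export
vslModelLocalLinear <- function(vslBaseline = 1.675e6,
                                incomeBaseline = 3277,
                                mvslSlope = 14550 / 145.8) {
  new("VSLModel", variant = "local_linear",
      vslBaseline = vslBaseline, incomeBaseline = incomeBaseline,
      mvslSlope = mvslSlope, vslReference = 0, incomeReference = 1,
      beta = 0)
}

#' International benefit-transfer VSL model
#'
#' Scales a reference country's VSL to the target setting through relative
#' income: \code{VSL(inc) = vslReference * (inc / incomeReference)^beta},
#' the standard "scaled international VSL" with income elasticity
#' \code{beta} (typical sensitivity values 0.8 and 0.4).
#'
#' @param vslReference reference VSL, USD.
#' @param incomeReference reference per-capita income, USD (> 0).
#' @param beta income elasticity in [0, 2].
#' @return A [VSLModel-class] with variant \code{"international_transfer"}.
#' @export
vslModelInternationalTransfer <- function(vslReference, incomeReference,
                                          beta = 0.8) {
  new("VSLModel", variant = "international_transfer",
      vslBaseline = 0, incomeBaseline = 0, mvslSlope = 0,
      vslReference = vslReference, incomeReference = incomeReference,
      beta = beta)
}

setMethod("show", "VSLModel", function(object) {
  if (object@variant == "local_linear") {
    cat(sprintf(
      "VSLModel (local linear): VSL = %.4g + (inc - %.4g) * %.4f USD\n",
      object@vslBaseline, object@incomeBaseline, object@mvslSlope))
  } else {
    cat(sprintf(
      "VSLModel (international transfer): VSL = %.4g * (inc / %.4g)^%.2f USD\n",
      object@vslReference, object@incomeReference, object@beta))
  }
  invisible(object)
})

#' Evaluate a VSL model at a target income
#'
#' @param model a [VSLModel-class].
#' @param incomeTarget per-capita annual income, USD (> 0 for the transfer
#'   variant).
#' @param floorAtZero local-linear only: clamp a negative extrapolated VSL
#'   to 0 with a warning (default); if \code{FALSE}, a negative result is
#'   an error.
#' @param ... unused.
#' @return VSL in USD.
#' @export
setMethod("vsl", signature(model = "VSLModel", incomeTarget = "numeric"),
  function(model, incomeTarget, floorAtZero = TRUE, ...) {
    stopifnot(is.finite(incomeTarget))
    if (model@variant == "local_linear") {
      v <- model@vslBaseline +
        (incomeTarget - model@incomeBaseline) * model@mvslSlope
      if (any(v < 0)) {
        if (!floorAtZero)
          stop("local-linear VSL extrapolates below 0 at income ",
               paste(incomeTarget[v < 0], collapse = ", "))
        warning("local-linear VSL extrapolated below 0; floored at 0")
        v <- pmax(v, 0)
      }
      v
    } else {
      if (any(incomeTarget <= 0))
        stop("international transfer requires positive target income")
      model@vslReference * (incomeTarget / model@incomeReference)^model@beta
    }
  })

#' Monetize avoided deaths
#'
#' Total avoided deaths times the VSL, in billion USD. Sign follows the
#' sign of the avoided deaths: a policy scenario with the larger burden
#' yields a negative benefit.
#'
#' @param avoided a burden-shaped difference table from
#'   [avoidedMortality()] (or any burden table to value its total).
#' @param vslUSD VSL in USD, \eqn{\ge 0}.
#' @return Named numeric: \code{benefit_mean}, \code{benefit_low},
#'   \code{benefit_high} in billion USD (bounds ordered low \eqn{\le}
#'   high).
#' @export
monetize <- function(avoided, vslUSD) {
  validateBurdenTable(avoided, allowNegative = TRUE)
  stopifnot(is.numeric(vslUSD), length(vslUSD) == 1L, vslUSD >= 0)
  tot <- colSums(avoided[, c("deaths_mean", "deaths_low", "deaths_high")])
  v <- tot * vslUSD / 1e9
  c(benefit_mean = unname(v[1L]),
    benefit_low = min(v), benefit_high = max(v))
}

#' Net benefit of a policy
#'
#' @param benefit monetized health benefit, billion USD.
#' @param cost mitigation cost, billion USD (\eqn{\ge 0}).
#' @return \code{benefit - cost}, billion USD (vectorized).
#' @export
netBenefit <- function(benefit, cost) {
  stopifnot(is.numeric(benefit), is.numeric(cost))
  if (any(cost < 0)) stop("mitigation cost must be >= 0")
  benefit - cost
}

#' Assemble a cost-benefit valuation table
#'
#' One row per scenario pair, mirroring a costs-and-benefits comparison
#' table: health benefit (with interval bounds), mitigation cost, net
#' benefit, and benefit-cost ratio (NA with \code{ratio_defined = FALSE}
#' when the cost is 0).
#'
#' @param pair scenario-pair labels.
#' @param year years.
#' @param benefit_mean,benefit_low,benefit_high billion USD.
#' @param cost billion USD.
#' @return data.frame; \code{net_benefit == benefit_mean - cost} holds to
#'   1e-9 by construction and is re-verified by [writeValuationTable()].
#' @export
valuationTable <- function(pair, year, benefit_mean, benefit_low,
                           benefit_high, cost) {
  if (any(cost < 0)) stop("mitigation cost must be >= 0")
  if (any(benefit_low > benefit_mean + 1e-9) ||
      any(benefit_mean > benefit_high + 1e-9))
    stop("benefit bounds must bracket the mean")
  data.frame(pair = as.character(pair), year = as.integer(year),
             benefit_mean = benefit_mean, benefit_low = benefit_low,
             benefit_high = benefit_high, cost = cost,
             net_benefit = netBenefit(benefit_mean, cost),
             benefit_cost_ratio = ifelse(cost > 0, benefit_mean / cost, NA),
             ratio_defined = cost > 0,
             stringsAsFactors = FALSE)
}

#' Write / read a valuation table
#'
#' Tab-delimited with a header; refuses to write rows violating the
#' \code{net_benefit = benefit - cost} identity (1e-9 tolerance).
#'
#' @param v a [valuationTable()].
#' @param path file path.
#' @return \code{path} invisibly / the table.
#' @export
writeValuationTable <- function(v, path) {
  if (any(abs(v$net_benefit - (v$benefit_mean - v$cost)) > 1e-9))
    stop("refusing to write: net_benefit != benefit_mean - cost")
  v <- v[order(v$pair, v$year), , drop = FALSE]
  utils::write.table(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeValuationTable
#' @export
readValuationTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
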