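#' @rdname relativeRisk
#' @export
setGeneric("relativeRisk",
           function(conc, params, ...) standardGeneric("relativeRisk"))

#' @rdname relativeRiskCI
#' @export
setGeneric("relativeRiskCI",
           function(conc, params, zCrit = 1.96, ...)
             standardGeneric("relativeRiskCI"))

#' @rdname checkRegistration
#' @export
setGeneric("checkRegistration",
           function(conc, pop, tol = 1e-9) standardGeneric("checkRegistration"))

#' @rdname populationWeightedConcentration
#' @export
setGeneric("populationWeightedConcentration",
           function(conc, pop) standardGeneric("populationWeightedConcentration"))

#' @rdname populationAbove
#' @export
setGeneric("populationAbove",
           function(conc, pop, threshold) standardGeneric("populationAbove"))

#' @rdname meanPopulationWeightedRR
#' @export
setGeneric("meanPopulationWeightedRR",
           function(conc, pop, params, ...)
             standardGeneric("meanPopulationWeightedRR"))

#' @rdname attributableMortality
#' @export
setGeneric("attributableMortality",
           function(conc, pop, incidence, params, ...)
             standardGeneric("attributableMortality"))

#' @rdname vsl
#' @export
setGeneric("vsl",
           function(model, incomeTarget, ...) standardGeneric("vsl"))

#' @rdname makeConcentrationPair
#' @export
setGeneric("makeConcentrationPair",
           function(spec, ...) standardGeneric("makeConcentrationPair"))

#' @rdname makePopulation
#' @export
setGeneric("makePopulation",
           function(spec, ...) standardGeneric("makePopulation"))

#' @rdname makeIncidenceAndParams
#' @export
setGeneric("makeIncidenceAndParams",
           function(spec, ...) standardGeneric("makeIncidenceAndParams"))
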