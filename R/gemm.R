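#' Construct GEMM parameter sets
#'
#' Builds a validated [GEMMParams-class] object from vectors of fit
#' parameters, recycling scalars. The GEMM relative risk at concentration
#' \eqn{c} is
#' \deqn{RR(c) = \exp\left\{\frac{\theta \log(z/\alpha + 1)}
#'   {1 + \exp(-(z - \mu)/\nu)}\right\}, \quad z = c - c_{min},}
#' for \eqn{c > c_{min}} and 1 otherwise.
#'
#' @param disease disease category labels (e.g. \code{"NCD+LRI"}).
#' @param age_group age-group labels (5-year adult bands such as
#'   \code{"25-29"} ... \code{"85+"}, or an all-adult aggregate).
#' @param theta log-RR scale coefficient (dimensionless).
#' @param alpha,mu,nu curve-shape parameters in \eqn{\mu g/m^3}.
#' @param theta_se standard error of \code{theta} (default 0).
#' @param cmin theoretical minimum-risk concentration, \eqn{\mu g/m^3}
#'   (default 2.4).
#' @return A [GEMMParams-class] object.
#' @examples
#' p <- GEMMParams("NCD+LRI", "25+", theta = 0.143, theta_se = 0.01807,
#'                 alpha = 1.6, mu = 15.5, nu = 36.8)
#' relativeRisk(c(0, 2.4, 35, 70), p)
#' @export
GEMMParams <- function(disease, age_group, theta, alpha, mu, nu,
                       theta_se = 0, cmin = 2.4) {
  df <- data.frame(disease = as.character(disease),
                   age_group = as.character(age_group),
                   theta = as.numeric(theta),
                   theta_se = as.numeric(theta_se),
                   alpha = as.numeric(alpha),
                   mu = as.numeric(mu),
                   nu = as.numeric(nu),
                   cmin = as.numeric(cmin),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  new("GEMMParams", params = df)
}

#' @describeIn GEMMParams Number of (disease, age group) parameter sets.
#' @param x a \code{GEMMParams} object.
#' @export
setMethod("length", "GEMMParams", function(x) nrow(x@params))

#' Parameter table accessor
#'
#' @param object a [GEMMParams-class] object.
#' @return The underlying data.frame of fit parameters.
#' @export
gemmTable <- function(object) {
  stopifnot(is(object, "GEMMParams"))
  object@params
}

#' Select one (disease, age group) parameter set
#'
#' @param object a [GEMMParams-class] object.
#' @param disease,age_group labels identifying the set.
#' @return A single-row [GEMMParams-class] object.
#' @export
paramsFor <- function(object, disease, age_group) {
  stopifnot(is(object, "GEMMParams"))
  p <- object@params
  hit <- p$disease == disease & p$age_group == age_group
  if (!any(hit))
    stop("no GEMM parameters for (", disease, ", ", age_group, ")")
  new("GEMMParams", params = p[hit, , drop = FALSE])
}

setMethod("show", "GEMMParams", function(object) {
  p <- object@params
  cat("GEMMParams:", nrow(p), "parameter set(s)\n")
  cat("  diseases:  ", paste(unique(p$disease), collapse = ", "), "\n")
  cat("  age groups:", paste(unique(p$age_group), collapse = ", "), "\n")
  cat("  cmin:      ", paste(unique(p$cmin), collapse = ", "), "ug/m3\n")
  invisible(object)
})

.singleParams <- function(params) {
  if (length(params) != 1L)
    stop("a single (disease, age_group) parameter set is required; ",
         "use paramsFor() to select one of ", length(params))
  params@params
}

.checkConc <- function(conc) {
  if (!is.numeric(conc))
    stop("concentrations must be numeric")
  if (anyNA(conc) || any(!is.finite(conc)))
    stop("concentrations must be finite (no NA/NaN/Inf)")
  if (any(conc < 0))
    stop("concentrations must be >= 0")
  invisible(TRUE)
}

# Core GEMM evaluation with an explicit theta, used by both the point
# estimate and the +/- z*SE perturbed bounds. Preserves dim() of conc.
.gemmRR <- function(conc, theta, alpha, mu, nu, cmin) {
  z <- conc - cmin
  rr <- conc
  rr[] <- 1
  up <- z > 0
  if (any(up)) {
    zu <- z[up]
    logterm <- log(zu / alpha + 1)
    logistic <- 1 / (1 + exp(-(zu - mu) / nu))
    rr[up] <- exp(theta * logterm * logistic)
  }
  rr
}

#' GEMM relative risk
#'
#' Evaluates the GEMM exposure-response function elementwise over a vector
#' or matrix of annual-mean PM2.5 concentrations. Below (or at) the
#' minimum-risk concentration \code{cmin} the relative risk is exactly 1.
#'
#' @param conc numeric vector or matrix of concentrations, \eqn{\mu g/m^3},
#'   finite and non-negative.
#' @param params a single-set [GEMMParams-class] object (see [paramsFor()]).
#' @param ... unused.
#' @return Relative risks (\eqn{\ge 1} for \eqn{\theta \ge 0}), with the
#'   shape of \code{conc}.
#' @seealso [relativeRiskCI()] for the parameter-uncertainty envelope.
#' @export
setMethod("relativeRisk", signature(conc = "numeric", params = "GEMMParams"),
  function(conc, params, ...) {
    .checkConc(conc)
    p <- .singleParams(params)
    .gemmRR(conc, p$theta, p$alpha, p$mu, p$nu, p$cmin)
  })

#' @rdname relativeRisk
#' @export
setMethod("relativeRisk", signature(conc = "matrix", params = "GEMMParams"),
  function(conc, params, ...) {
    .checkConc(conc)
    p <- .singleParams(params)
    .gemmRR(conc, p$theta, p$alpha, p$mu, p$nu, p$cmin)
  })

#' GEMM relative risk with parameter-uncertainty bounds
#'
#' Propagates the standard error of \eqn{\theta} into the exposure-response
#' function: the lower/upper curves are the GEMM function evaluated with
#' \eqn{\theta \mp z_{crit} \cdot SE(\theta)}. Only \eqn{\theta} carries
#' uncertainty; this matches the public fit tables, which report a standard
#' error for \eqn{\theta} alone.
#'
#' @inheritParams relativeRisk
#' @param zCrit normal quantile multiplier (1.96 for a ~95\% interval; 0
#'   collapses the bounds onto the point estimate).
#' @return A list with elements \code{low}, \code{mean}, \code{high}, each
#'   shaped like \code{conc}. All three are 1 at or below \code{cmin}.
#' @export
setMethod("relativeRiskCI", signature(conc = "ANY", params = "GEMMParams"),
  function(conc, params, zCrit = 1.96, ...) {
    .checkConc(conc)
    stopifnot(is.numeric(zCrit), length(zCrit) == 1L, zCrit >= 0)
    p <- .singleParams(params)
    rr <- function(th) .gemmRR(conc, th, p$alpha, p$mu, p$nu, p$cmin)
    list(low = rr(p$theta - zCrit * p$theta_se),
         mean = rr(p$theta),
         high = rr(p$theta + zCrit * p$theta_se))
  })

.GEMM_COLS <- c("disease", "age_group", "theta", "theta_se",
                "alpha", "mu", "nu")

#' Read a GEMM fit-parameter table
#'
#' Reads a delimited text file with a header row containing at least the
#' columns \code{disease}, \code{age_group}, \code{theta}, \code{theta_se},
#' \code{alpha}, \code{mu}, \code{nu} (an optional \code{cmin} column
#' overrides the default threshold). Unknown columns are ignored. The
#' column content matches the public GEMM fit-parameter file layout.
#'
#' @param path file path.
#' @param cmin default minimum-risk concentration applied when the file has
#'   no \code{cmin} column.
#' @param sep field separator (default tab).
#' @return A validated [GEMMParams-class] object.
#' @export
readGEMMParams <- function(path, cmin = 2.4, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(.GEMM_COLS, names(df))
  if (length(miss))
    stop("GEMM parameter file '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  for (cl in c("theta", "theta_se", "alpha", "mu", "nu")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric '", cl, "' in GEMM parameter file row(s) ",
           paste(bad, collapse = ", "))
    df[[cl]] <- v
  }
  key <- paste(df$disease, df$age_group, sep = " / ")
  if (anyDuplicated(key))
    stop("duplicate (disease, age_group) in '", path, "': ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  GEMMParams(df$disease, df$age_group, theta = df$theta,
             theta_se = df$theta_se, alpha = df$alpha, mu = df$mu,
             nu = df$nu,
             cmin = if ("cmin" %in% names(df)) as.numeric(df$cmin) else cmin)
}

#' Write a GEMM fit-parameter table
#'
#' Inverse of [readGEMMParams()]; a write-then-read round trip reproduces
#' the parameter values bit-exactly.
#'
#' @param object a [GEMMParams-class] object.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
writeGEMMParams <- function(object, path, sep = "\t") {
  stopifnot(is(object, "GEMMParams"))
  utils::write.table(format(object@params, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
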