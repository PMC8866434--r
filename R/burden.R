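#' Build a cause-specific baseline incidence table
#'
#' Reported national average annual mortality incidence \eqn{I_{i,j}}
#' (deaths per person-year) keyed by disease \eqn{i} and age group
#' \eqn{j}. Baseline incidence is held fixed across projection years; the
#' pipeline makes no mortality-rate projection.
#'
#' @param disease,age_group key vectors.
#' @param incidence deaths per person-year, finite and \eqn{\ge 0}.
#' @return data.frame with class hint \code{"IncidenceTable"} columns
#'   \code{disease}, \code{age_group}, \code{incidence}.
#' @export
incidenceTable <- function(disease, age_group, incidence) {
  df <- data.frame(disease = as.character(disease),
                   age_group = as.character(age_group),
                   incidence = as.numeric(incidence),
                   stringsAsFactors = FALSE)
  if (anyNA(df$incidence) || any(!is.finite(df$incidence)))
    stop("incidence must be finite")
  if (any(df$incidence < 0))
    stop("incidence must be >= 0")
  key <- paste(df$disease, df$age_group, sep = " / ")
  if (anyDuplicated(key))
    stop("duplicated (disease, age_group) in incidence table: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rownames(df) <- NULL
  df
}

.incidenceFor <- function(inc, disease, age_group) {
  hit <- inc$disease == disease & inc$age_group == age_group
  if (!any(hit))
    stop("no incidence entry for modeled (", disease, ", ", age_group, ")")
  inc$incidence[hit][1L]
}

#' Hypothetical underlying incidence
#'
#' \deqn{\hat{I} = I / \bar{RR}:} the cause-specific mortality rate that
#' would remain if PM2.5 were everywhere reduced to the minimum-risk
#' concentration. Always \eqn{\le} the reported rate since
#' \eqn{\bar{RR} \ge 1}.
#'
#' @param i_rate reported incidence, deaths per person-year, \eqn{\ge 0}.
#' @param rr_bar average population-weighted relative risk, \eqn{\ge 1}.
#' @return Underlying incidence, same units as \code{i_rate}.
#' @export
underlyingIncidence <- function(i_rate, rr_bar) {
  stopifnot(is.numeric(i_rate), is.numeric(rr_bar))
  if (any(i_rate < 0)) stop("incidence must be >= 0")
  if (any(rr_bar < 1)) stop("mean population-weighted RR must be >= 1")
  i_rate / rr_bar
}

.BURDEN_COLS <- c("scenario", "year", "disease", "age_group", "region",
                  "deaths_mean", "deaths_low", "deaths_high")

#' Validate a burden table
#'
#' Checks the long-format burden-table contract: the key and deaths
#' columns are present, all deaths are finite with
#' \code{deaths_low <= deaths_mean <= deaths_high}, and (for attributable
#' burden, \code{allowNegative = FALSE}) non-negative.
#'
#' @param b data.frame in burden layout.
#' @param allowNegative permit negative entries (scenario differences).
#' @return \code{b}, invisibly.
#' @export
validateBurdenTable <- function(b, allowNegative = FALSE) {
  miss <- setdiff(.BURDEN_COLS, names(b))
  if (length(miss))
    stop("burden table lacks column(s): ", paste(miss, collapse = ", "))
  d <- as.matrix(b[, c("deaths_low", "deaths_mean", "deaths_high")])
  if (anyNA(d) || any(!is.finite(d)))
    stop("burden entries must be finite")
  if (any(b$deaths_low > b$deaths_mean + 1e-9) ||
      any(b$deaths_mean > b$deaths_high + 1e-9))
    stop("burden table violates deaths_low <= deaths_mean <= deaths_high")
  if (!allowNegative && any(d < 0))
    stop("attributable burden entries must be >= 0")
  invisible(b)
}

# One full Eq. 1-3 pass at a fixed theta shift: for each (disease, age)
# parameter row, RRbar over the whole grid with that age group's
# population, underlying incidence, then the cell sum
# sum_g P_gj * Ihat * (RR_g - 1).
.burdenAtShift <- function(conc, pop, inc, params, shift) {
  p <- params@params
  vapply(seq_len(nrow(p)), function(k) {
    row <- p[k, , drop = FALSE]
    row$theta <- row$theta + shift * row$theta_se
    one <- new("GEMMParams", params = row)
    w <- .popForAge(pop, row$age_group)
    tw <- sum(w)
    if (tw <= 0) return(0)
    rr <- relativeRisk(conc@values, one)
    rr_bar <- sum(w * rr) / tw
    i_hat <- .incidenceFor(inc, row$disease, row$age_group) / rr_bar
    sum(w * i_hat * (rr - 1))
  }, numeric(1))
}

#' Attributable mortality on a gridded scenario
#'
#' For each modeled (disease, age group), computes the deaths attributable
#' to ambient PM2.5 via the attributable-fraction relationship
#' \deqn{M_{i,j} = \sum_g P_{g,j} \, \hat{I}_{i,j} \, (RR(C_g) - 1),}
#' with \eqn{\hat{I}_{i,j} = I_{i,j} / \bar{RR}} and \eqn{\bar{RR}} the
#' national (whole-grid) population-weighted mean relative risk. The ~95\%
#' interval re-runs the whole chain (including \eqn{\bar{RR}} and
#' \eqn{\hat{I}}) with \eqn{\theta \mp zCrit \cdot SE(\theta)}.
#'
#' Age groups present in the population but absent from \code{params}
#' (e.g. children under 25) contribute no attributable deaths and emit no
#' rows.
#'
#' @param conc a [ConcentrationField-class].
#' @param pop a co-registered [PopulationField-class].
#' @param incidence an [incidenceTable()] covering every modeled
#'   (disease, age group).
#' @param params a [GEMMParams-class] collection.
#' @param zCrit quantile multiplier for the interval (default 1.96).
#' @param region region label recorded in the output (default
#'   \code{"national"}; use [applyRegionMask()] for sub-regions).
#' @param ... unused.
#' @return A burden table (see [validateBurdenTable()]) with one row per
#'   (disease, age group), carrying attribute \code{ci_method}: bounds come
#'   from a global \eqn{\theta} shift, not an independently propagated
#'   interval.
#' @export
setMethod("attributableMortality",
          signature(conc = "ConcentrationField", pop = "PopulationField",
                    incidence = "data.frame", params = "GEMMParams"),
  function(conc, pop, incidence, params, zCrit = 1.96,
           region = "national", ...) {
    .stopIfMisregistered(conc, pop)
    p <- params@params
    # fail fast on configuration gaps before any heavy work
    for (k in seq_len(nrow(p)))
      .incidenceFor(incidence, p$disease[k], p$age_group[k])
    m0 <- .burdenAtShift(conc, pop, incidence, params, 0)
    ml <- .burdenAtShift(conc, pop, incidence, params, -zCrit)
    mh <- .burdenAtShift(conc, pop, incidence, params, +zCrit)
    b <- data.frame(scenario = conc@scenario, year = conc@year,
                    disease = p$disease, age_group = p$age_group,
                    region = region,
                    deaths_mean = m0,
                    deaths_low = pmin(ml, m0, mh),
                    deaths_high = pmax(ml, m0, mh),
                    stringsAsFactors = FALSE)
    rownames(b) <- NULL
    attr(b, "ci_method") <- "global theta shift (theta -/+ zCrit*SE); bound, not propagated interval"
    validateBurdenTable(b)
    b
  })

.burdenKey <- function(b) paste(b$year, b$disease, b$age_group, b$region,
                                sep = " / ")

#' Avoided deaths between a reference and a policy scenario
#'
#' The health co-benefit of a climate policy is the difference in
#' attributable deaths against the matching no-policy reference:
#' \deqn{\Delta M = M_{REF} - M_{policy}} per (year, disease, age group,
#' region) key. Sign is preserved: negative means the policy scenario
#' carries the larger burden.
#'
#' @param ref,policy burden tables with identical key sets.
#' @return A burden-shaped difference table (negative entries allowed),
#'   scenario labeled \code{"<ref> - <policy>"}. Interval bounds are
#'   differenced per bound (the \eqn{\theta} shift is global) and
#'   reordered so low \eqn{\le} high.
#' @export
avoidedMortality <- function(ref, policy) {
  validateBurdenTable(ref, allowNegative = TRUE)
  validateBurdenTable(policy, allowNegative = TRUE)
  kr <- .burdenKey(ref)
  kp <- .burdenKey(policy)
  unmatched <- c(setdiff(kr, kp), setdiff(kp, kr))
  if (length(unmatched) || anyDuplicated(kr))
    stop("burden tables do not align on (year, disease, age_group, region); ",
         "unmatched key(s): ",
         paste(unique(c(unmatched, kr[duplicated(kr)])), collapse = "; "))
  i <- match(kr, kp)
  dm <- ref$deaths_mean - policy$deaths_mean[i]
  dl <- ref$deaths_low - policy$deaths_low[i]
  dh <- ref$deaths_high - policy$deaths_high[i]
  out <- data.frame(scenario = paste(ref$scenario, "-", policy$scenario[i]),
                    year = ref$year, disease = ref$disease,
                    age_group = ref$age_group, region = ref$region,
                    deaths_mean = dm,
                    deaths_low = pmin(dl, dm, dh),
                    deaths_high = pmax(dl, dm, dh),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ci_method") <- "per-bound difference under global theta shift; bound, not propagated interval"
  out
}

#' Aggregate a burden table over strata
#'
#' Sums deaths (mean and both bounds) within groups defined by a subset of
#' \code{disease}, \code{age_group}, \code{region}; \code{scenario} and
#' \code{year} are always retained. Collapsed keys are labeled
#' \code{"all"}. The grand total is invariant under any grouping. Summing
#' bounds across strata assumes perfect dependence (the \eqn{\theta} shift
#' is applied globally), so the result is a bound, not a propagated
#' interval; the \code{ci_method} attribute records this.
#'
#' @param b a burden table.
#' @param by character subset of \code{c("disease", "age_group", "region")}
#'   to retain (default: none, i.e. total over all three).
#' @return Aggregated burden table, deterministically ordered.
#' @export
aggregateBurden <- function(b, by = character(0)) {
  validateBurdenTable(b, allowNegative = TRUE)
  allowed <- c("disease", "age_group", "region")
  bad <- setdiff(by, allowed)
  if (length(bad))
    stop("unknown grouping key(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  keys <- c("scenario", "year", by)
  g <- b[, keys, drop = FALSE]
  agg <- stats::aggregate(
    b[, c("deaths_mean", "deaths_low", "deaths_high")], by = as.list(g), sum)
  for (cl in setdiff(allowed, by)) agg[[cl]] <- "all"
  agg <- agg[, .BURDEN_COLS]
  agg <- agg[do.call(order, agg[, c("scenario", "year", "disease",
                                    "age_group", "region")]), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "ci_method") <- "per-stratum bounds summed (perfect dependence); bound, not propagated interval"
  agg
}

#' Read / write burden tables
#'
#' Burden tables are serialized as tab-delimited long-format text with a
#' header and deterministic row ordering (scenario, year, disease,
#' age_group, region). The \code{ci_method} note travels as a \code{#}
#' comment line.
#'
#' @param b a burden table.
#' @param path file path.
#' @return \code{writeBurdenTable}: \code{path} invisibly;
#'   \code{readBurdenTable}: the table.
#' @export
writeBurdenTable <- function(b, path) {
  validateBurdenTable(b, allowNegative = TRUE)
  note <- attr(b, "ci_method")  # subsetting drops attributes; keep it first
  b <- b[do.call(order, b[, c("scenario", "year", "disease", "age_group",
                              "region")]), .BURDEN_COLS, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(note)) writeLines(paste("# ci_method:", note), con)
  utils::write.table(format(b, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBurdenTable
#' @export
readBurdenTable <- function(path) {
  lines <- readLines(path)
  note <- grep("^# ci_method:", lines, value = TRUE)
  b <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  b$scenario <- as.character(b$scenario)
  b$region <- as.character(b$region)
  if (length(note))
    attr(b, "ci_method") <- sub("^# ci_method: ", "", note[1L])
  validateBurdenTable(b, allowNegative = TRUE)
  b
}
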