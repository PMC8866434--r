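#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file with keys: \code{seed};
#' \code{output_dir}; file paths \code{population}, \code{incidence},
#' \code{gemm_params}; \code{pm25_goal} (air-quality goal for the
#' population-above summary, default 35 \eqn{\mu g/m^3}); a \code{vsl}
#' block (\code{variant} plus the variant's parameters); optional
#' \code{incomes} and \code{gdp} maps keyed by year; and a
#' \code{scenarios} list, each entry carrying \code{label}, \code{year},
#' \code{concentration} (file), \code{cost} (billion USD) and, for policy
#' scenarios, \code{reference}: the label of its no-policy counterpart in
#' the same year.
#'
#' @param path YAML file path.
#' @return A validated config list with attribute \code{config_md5}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  attr(cfg, "config_md5") <- unname(tools::md5sum(path))
  validateRunConfig(cfg)
}

.resolvePath <- function(p, base) {
  if (is.null(base) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
}

#' @rdname readRunConfig
#' @param cfg a config list (as from [readRunConfig()] or built in code).
#' @export
validateRunConfig <- function(cfg) {
  for (key in c("population", "incidence", "gemm_params", "scenarios"))
    if (is.null(cfg[[key]]))
      stop("config lacks required key '", key, "'")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$pm25_goal)) cfg$pm25_goal <- 35
  for (key in c("population", "incidence", "gemm_params")) {
    cfg[[key]] <- .resolvePath(cfg[[key]], cfg$.dir)
    if (!file.exists(cfg[[key]]))
      stop("config: ", key, " file not found: ", cfg[[key]])
  }
  labels <- vapply(cfg$scenarios, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("config: duplicated scenario label(s): ",
         paste(labels[duplicated(labels)], collapse = ", "))
  for (i in seq_along(cfg$scenarios)) {
    sc <- cfg$scenarios[[i]]
    for (key in c("label", "year", "concentration"))
      if (is.null(sc[[key]]))
        stop("config: scenario ", i, " lacks '", key, "'")
    sc$concentration <- .resolvePath(sc$concentration, cfg$.dir)
    if (!file.exists(sc$concentration))
      stop("config: concentration file not found for scenario '",
           sc$label, "': ", sc$concentration)
    if (is.null(sc$cost)) sc$cost <- 0
    if (!is.null(sc$reference)) {
      j <- match(sc$reference, labels)
      if (is.na(j))
        stop("config: scenario '", sc$label, "' references unknown '",
             sc$reference, "'")
      if (cfg$scenarios[[j]]$year != sc$year)
        stop("config: scenario '", sc$label, "' (year ", sc$year,
             ") references '", sc$reference, "' of a different year")
    }
    cfg$scenarios[[i]] <- sc
  }
  cfg
}

.vslFromConfig <- function(block) {
  if (is.null(block)) return(vslModelLocalLinear())
  if (identical(block$variant, "international_transfer"))
    vslModelInternationalTransfer(
      vslReference = block$vsl_reference,
      incomeReference = block$income_reference,
      beta = if (is.null(block$beta)) 0.8 else block$beta)
  else
    vslModelLocalLinear(
      vslBaseline = if (is.null(block$vsl_baseline))
        formals(vslModelLocalLinear)$vslBaseline else block$vsl_baseline,
      incomeBaseline = if (is.null(block$income_baseline))
        formals(vslModelLocalLinear)$incomeBaseline else block$income_baseline,
      mvslSlope = if (is.null(block$mvsl_slope))
        eval(formals(vslModelLocalLinear)$mvslSlope) else block$mvsl_slope)
}

#' Run the scenario pipeline end-to-end
#'
#' For every configured scenario: reads the concentration field, checks
#' registration against the population grid, and computes the
#' population-weighted concentration, the population above the air-quality
#' goal, and the attributable-mortality burden table. For every
#' policy/reference pair: avoided deaths, the scenario-year VSL, and a
#' cost-benefit valuation row. The run is a pure function of (config,
#' input files, seed): repeated runs produce byte-identical outputs.
#'
#' @param config a config list or a YAML path (see [readRunConfig()]).
#' @param outDir report directory; overrides \code{config$output_dir}.
#' @param writeOutput write the report bundle (default: only when
#'   \code{outDir} is given); with \code{outDir = NULL} and
#'   \code{writeOutput = TRUE} the config's \code{output_dir} is used.
#' @return Invisibly, a list with \code{exposure}, \code{burden},
#'   \code{avoided}, \code{valuation} tables and \code{log} lines.
#' @export
runPipeline <- function(config, outDir = NULL,
                        writeOutput = !is.null(outDir)) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else validateRunConfig(config)
  params <- readGEMMParams(cfg$gemm_params)
  inc <- readIncidenceTable(cfg$incidence)
  pop <- readPopulationField(cfg$population)
  vslModel <- .vslFromConfig(cfg$vsl)

  labels <- vapply(cfg$scenarios, `[[`, "", "label")
  fields <- list()
  exposure <- NULL
  burdens <- list()
  for (sc in cfg$scenarios) {
    f <- readConcentrationField(sc$concentration)
    # config label/year win over whatever the file header says
    f@scenario <- sc$label
    f@year <- as.integer(sc$year)
    if (!checkRegistration(f, pop))
      stop("stage exposure: scenario '", sc$label,
           "' grid is not co-registered with the population grid")
    fields[[sc$label]] <- f
    b <- tryCatch(
      attributableMortality(f, pop, inc, params),
      error = function(e) stop("stage burden: scenario '", sc$label,
                               "': ", conditionMessage(e)))
    burdens[[sc$label]] <- b
    exposure <- rbind(exposure, data.frame(
      scenario = sc$label, year = as.integer(sc$year),
      pwc = populationWeightedConcentration(f, pop),
      pop_above_goal = populationAbove(f, pop, cfg$pm25_goal),
      goal = cfg$pm25_goal,
      total_deaths_mean = sum(b$deaths_mean),
      stringsAsFactors = FALSE))
  }

  avoided <- NULL
  valuation <- NULL
  for (sc in cfg$scenarios) {
    if (is.null(sc$reference)) next
    dm <- tryCatch(
      avoidedMortality(burdens[[sc$reference]], burdens[[sc$label]]),
      error = function(e) stop("stage cobenefit: pair '", sc$label,
                               "': ", conditionMessage(e)))
    avoided <- rbind(avoided, dm)
    income <- cfg$incomes[[as.character(sc$year)]]
    v <- if (is.null(income)) {
      if (vslModel@variant == "local_linear") vslModel@vslBaseline
      else vslModel@vslReference
    } else vsl(vslModel, income)
    ben <- monetize(dm, v)
    vt <- valuationTable(sc$label, sc$year, ben[["benefit_mean"]],
                         ben[["benefit_low"]], ben[["benefit_high"]],
                         sc$cost)
    vt$vsl_usd <- v
    gdp <- cfg$gdp[[as.character(sc$year)]]
    vt$net_benefit_gdp_pct <- if (is.null(gdp)) NA_real_
                              else 100 * vt$net_benefit / gdp
    valuation <- rbind(valuation, vt)
  }

  burden <- do.call(rbind, burdens[intersect(labels, names(burdens))])
  if (!is.null(burden)) {
    rownames(burden) <- NULL
    attr(burden, "ci_method") <- attr(burdens[[1L]], "ci_method")
  }
  log <- c(paste("pm25cobenefit version:",
                 as.character(utils::packageVersion("pm25cobenefit"))),
           paste("R version:", R.version.string),
           paste("seed:", cfg$seed),
           paste("config md5:",
                 if (is.null(attr(cfg, "config_md5"))) "(in-memory config)"
                 else attr(cfg, "config_md5")),
           paste("scenarios:", paste(labels, collapse = ", ")))
  res <- list(exposure = exposure, burden = burden, avoided = avoided,
              valuation = valuation, log = log)
  if (writeOutput) {
    if (is.null(outDir)) outDir <- cfg$output_dir
    if (is.null(outDir))
      stop("writeOutput = TRUE but neither outDir nor config$output_dir is set")
    writeReport(res, outDir)
  }
  invisible(res)
}

#' Write the pipeline report bundle
#'
#' Emits deterministic tab-delimited tables (\code{exposure_summary.tsv},
#' \code{burden.tsv}, \code{avoided_deaths.tsv}, \code{valuation.tsv}),
#' a plain-text \code{summary.txt}, and \code{run_log.txt}. Table
#' invariants (bound ordering, the net-benefit identity) are re-verified
#' before anything is written.
#'
#' @param results list as returned by [runPipeline()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(results, dir) {
  if (!is.null(results$burden)) validateBurdenTable(results$burden)
  if (!is.null(results$avoided))
    validateBurdenTable(results$avoided, allowNegative = TRUE)
  if (!is.null(results$valuation) &&
      any(abs(results$valuation$net_benefit -
              (results$valuation$benefit_mean - results$valuation$cost)) >
          1e-9))
    stop("refusing to write: net_benefit != benefit - cost")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    if (is.null(df)) df <- data.frame()
    utils::write.table(format(df, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(results$exposure, "exposure_summary.tsv")
  if (!is.null(results$burden))
    writeBurdenTable(results$burden, file.path(dir, "burden.tsv"))
  if (!is.null(results$avoided))
    writeBurdenTable(results$avoided, file.path(dir, "avoided_deaths.tsv"))
  wt(results$valuation, "valuation.tsv")

  s <- c("PM2.5 health co-benefit pipeline summary", "")
  if (!is.null(results$exposure) && nrow(results$exposure) > 0L)
    s <- c(s, apply(results$exposure, 1L, function(r) sprintf(
      "%s (%s): PWC %.2f ug/m3; %s persons above %s ug/m3; %.1f attributable deaths",
      r[["scenario"]], r[["year"]], as.numeric(r[["pwc"]]),
      format(as.numeric(r[["pop_above_goal"]]), big.mark = ","),
      r[["goal"]], as.numeric(r[["total_deaths_mean"]]))))
  if (!is.null(results$valuation) && nrow(results$valuation) > 0L)
    s <- c(s, "", apply(results$valuation, 1L, function(r) sprintf(
      "%s (%s): benefit %.2f, cost %.2f, net benefit %.2f billion USD",
      r[["pair"]], r[["year"]], as.numeric(r[["benefit_mean"]]),
      as.numeric(r[["cost"]]), as.numeric(r[["net_benefit"]]))))
  writeLines(s, file.path(dir, "summary.txt"))
  writeLines(results$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Write a complete synthetic input bundle
#'
#' Materializes everything [runPipeline()] needs from a
#' [SyntheticSpec-class]: the reference and policy concentration fields,
#' the population grid, the incidence and GEMM parameter tables, and a
#' ready-to-run \code{config.yaml} pairing the policy scenario with its
#' reference.
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory (created if needed).
#' @param refLabel,policyLabel,year scenario labels.
#' @param cost policy mitigation cost, billion USD.
#' @return Path of the written config file, invisibly.
#' @export
simulateDataFiles <- function(spec, dir, refLabel = "REF",
                              policyLabel = "POLICY", year = 2050L,
                              cost = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pair <- makeConcentrationPair(spec, refLabel, policyLabel, year)
  writeConcentrationField(pair$ref, file.path(dir, "conc_ref.tsv"))
  writeConcentrationField(pair$policy, file.path(dir, "conc_policy.tsv"))
  writePopulationField(makePopulation(spec), file.path(dir, "population.tsv"))
  ip <- makeIncidenceAndParams(spec)
  writeIncidenceTable(ip$incidence, file.path(dir, "incidence.tsv"))
  writeGEMMParams(ip$params, file.path(dir, "gemm_params.tsv"))
  cfg <- list(seed = spec@seed, output_dir = "output",
              population = "population.tsv", incidence = "incidence.tsv",
              gemm_params = "gemm_params.tsv", pm25_goal = 35,
              vsl = list(variant = "local_linear"),
              scenarios = list(
                list(label = refLabel, year = as.integer(year),
                     concentration = "conc_ref.tsv", cost = 0),
                list(label = policyLabel, year = as.integer(year),
                     concentration = "conc_policy.tsv", cost = cost,
                     reference = refLabel)))
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
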