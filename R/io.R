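# Plain-text grid I/O. Fields travel as delimited long tables
# (lat_index, lon_index, value[, age_group]) with the grid edges and
# metadata in leading '#' header lines, so fixtures stay human-readable
# and diff-able.

.writeEdgeHeader <- function(con, latEdges, lonEdges) {
  fmt <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                  scientific = FALSE), collapse = ",")
  writeLines(c(paste0("# lat_edges: ", fmt(latEdges)),
               paste0("# lon_edges: ", fmt(lonEdges))), con)
}

.readHeaderMeta <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^# ", lines, value = TRUE)
  pick <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^# ", key, ": "), "", hit[1L])
  }
  list(lat = as.numeric(strsplit(pick("lat_edges"), ",")[[1L]]),
       lon = as.numeric(strsplit(pick("lon_edges"), ",")[[1L]]),
       scenario = pick("scenario"), year = pick("year"))
}

#' Write / read a concentration field as a delimited long table
#'
#' Layout: comment header lines carrying the grid edges, scenario and
#' year, then tab-separated columns \code{lat_index}, \code{lon_index},
#' \code{value} in row-major cell order.
#'
#' @param field a [ConcentrationField-class].
#' @param path file path.
#' @return \code{path} invisibly / the field.
#' @export
writeConcentrationField <- function(field, path) {
  stopifnot(is(field, "ConcentrationField"))
  con <- file(path, "w")
  on.exit(close(con))
  .writeEdgeHeader(con, field@latEdges, field@lonEdges)
  writeLines(c(paste0("# scenario: ", field@scenario),
               paste0("# year: ", field@year)), con)
  v <- field@values
  df <- data.frame(lat_index = rep(seq_len(nrow(v)), each = ncol(v)),
                   lon_index = rep(seq_len(ncol(v)), times = nrow(v)),
                   value = as.vector(t(v)))
  utils::write.table(format(df, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConcentrationField
#' @export
readConcentrationField <- function(path) {
  meta <- .readHeaderMeta(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  nlat <- length(meta$lat) - 1L
  nlon <- length(meta$lon) - 1L
  v <- matrix(NA_real_, nlat, nlon)
  v[cbind(df$lat_index, df$lon_index)] <- df$value
  if (anyNA(v))
    stop("incomplete grid in '", path, "': ", sum(is.na(v)),
         " cell(s) missing")
  ConcentrationField(v, meta$lat, meta$lon,
                     scenario = if (is.null(meta$scenario)) "unnamed"
                                else meta$scenario,
                     year = if (is.null(meta$year)) NA_integer_
                            else as.integer(meta$year))
}

#' Write / read an age-structured population field
#'
#' Same long-table convention as [writeConcentrationField()] with an
#' added \code{age_group} column; age-group order is recorded in a header
#' line and restored on read.
#'
#' @param pop a [PopulationField-class].
#' @param path file path.
#' @return \code{path} invisibly / the field.
#' @export
writePopulationField <- function(pop, path) {
  stopifnot(is(pop, "PopulationField"))
  con <- file(path, "w")
  on.exit(close(con))
  .writeEdgeHeader(con, pop@latEdges, pop@lonEdges)
  writeLines(paste0("# age_groups: ",
                    paste(pop@ageGroups, collapse = ",")), con)
  d <- dim(pop@counts)
  df <- data.frame(
    age_group = rep(pop@ageGroups, each = d[2L] * d[3L]),
    lat_index = rep(rep(seq_len(d[2L]), each = d[3L]), times = d[1L]),
    lon_index = rep(seq_len(d[3L]), times = d[1L] * d[2L]),
    value = as.vector(aperm(pop@counts, c(3L, 2L, 1L))))
  utils::write.table(format(df, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePopulationField
#' @export
readPopulationField <- function(path) {
  lines <- readLines(path, n = 10L)
  ageLine <- grep("^# age_groups: ", lines, value = TRUE)
  if (!length(ageLine))
    stop("population file '", path, "' lacks the age_groups header")
  ages <- strsplit(sub("^# age_groups: ", "", ageLine[1L]), ",")[[1L]]
  meta <- .readHeaderMeta(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  nlat <- length(meta$lat) - 1L
  nlon <- length(meta$lon) - 1L
  counts <- array(NA_real_, dim = c(length(ages), nlat, nlon))
  j <- match(df$age_group, ages)
  if (anyNA(j))
    stop("population file has age group(s) absent from its header: ",
         paste(unique(df$age_group[is.na(j)]), collapse = ", "))
  counts[cbind(j, df$lat_index, df$lon_index)] <- df$value
  if (anyNA(counts))
    stop("incomplete population grid in '", path, "'")
  PopulationField(counts, ages, meta$lat, meta$lon)
}

#' Write / read an incidence table
#'
#' Tab-delimited with header \code{disease}, \code{age_group},
#' \code{incidence} (deaths per person-year).
#'
#' @param inc an [incidenceTable()].
#' @param path file path.
#' @return \code{path} invisibly / the table.
#' @export
writeIncidenceTable <- function(inc, path) {
  utils::write.table(format(inc, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIncidenceTable
#' @export
readIncidenceTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("disease", "age_group", "incidence"), names(df))
  if (length(miss))
    stop("incidence file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  incidenceTable(df$disease, df$age_group, df$incidence)
}
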