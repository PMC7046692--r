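#' Table schemas and validated CSV I/O
#'
#' Every pipeline stage exchanges plain data frames validated against a named
#' schema; no stage parses raw files itself. The interchange dialect is
#' comma-separated UTF-8 with "." decimals and ISO-8601 dates, and the
#' canonical concentration unit is mg/L (a `units` column with mg/L, ug/L or
#' the micro sign is accepted on read and converted).
#'
#' @name tables-io
NULL

ANALYTES <- c("TN", "TP", "NO3N", "DRP")

# schema registry: required columns with types, optional columns, and a
# row-level invariant checker returning character(0) or messages
.schemas <- local({
  msg <- function(rows, what)
    if (length(rows) == 0) character(0) else
      sprintf("row %d: %s", rows, what)

  list(
    samples = list(
      required = c(site_id = "character", date = "date", analyte = "character",
                   value = "numeric", detection_limit = "numeric",
                   censored = "logical", method_code = "character"),
      optional = c(filter_pore_um = "numeric", units = "character"),
      check = function(df) {
        c(msg(which(!df$analyte %in% ANALYTES), "unknown analyte"),
          msg(which(!df$censored & (is.na(df$value) | df$value < 0)),
              "value must be >= 0 when not censored"),
          msg(which(is.na(df$detection_limit) | df$detection_limit <= 0),
              "detection_limit must be > 0"),
          msg(which(df$censored & is.na(df$value)),
              "censored rows must carry the detection limit in 'value'"))
      }),
    sites = list(
      required = c(site_id = "character", latitude = "numeric",
                   catchment_id = "character"),
      optional = c(gauge_id = "character", gauge_distance_km = "numeric"),
      check = function(df) {
        out <- msg(which(is.na(df$latitude) | abs(df$latitude) > 90),
                   "latitude must lie in [-90, 90]")
        if (all(c("gauge_id", "gauge_distance_km") %in% names(df))) {
          bad <- which(is.na(df$gauge_id) != is.na(df$gauge_distance_km))
          out <- c(out, msg(bad, "gauge_distance_km present iff gauge_id present"))
          out <- c(out, msg(which(!is.na(df$gauge_distance_km) &
                                    df$gauge_distance_km < 0),
                            "gauge_distance_km must be >= 0"))
        }
        out
      }),
    discharge = list(
      required = c(gauge_id = "character", date = "date", flow_m3s = "numeric"),
      optional = c(),
      check = function(df)
        msg(which(!is.na(df$flow_m3s) & df$flow_m3s < 0), "flow must be >= 0")),
    site_gauge_links = list(
      required = c(site_id = "character", gauge_id = "character",
                   distance_km = "numeric"),
      optional = c(),
      check = function(df)
        msg(which(is.na(df$distance_km) | df$distance_km < 0),
            "distance_km must be >= 0")),
    catchments = list(
      required = c(catchment_id = "character", continent = "character",
                   area_km2 = "numeric", population = "numeric",
                   agriculture_km2 = "numeric", forest_km2 = "numeric",
                   other_km2 = "numeric"),
      optional = NULL,  # extra columns are predictors, any type
      check = function(df) {
        lu <- df$agriculture_km2 + df$forest_km2 + df$other_km2
        c(msg(which(is.na(df$area_km2) | df$area_km2 <= 0),
              "area_km2 must be > 0"),
          msg(which(!is.na(df$population) & df$population < 0),
              "population must be >= 0"),
          msg(which(!is.na(lu) & lu > df$area_km2 * (1 + 1e-6)),
              "land-use areas exceed catchment area"))
      }),
    thresholds = list(
      required = c(study_id = "character", analyte = "character",
                   threshold_mgL = "numeric", biome = "character",
                   region = "character"),
      optional = c(),
      check = function(df)
        c(msg(which(!df$analyte %in% ANALYTES), "unknown analyte"),
          msg(which(is.na(df$threshold_mgL) | df$threshold_mgL <= 0),
              "threshold must be > 0")))
  )
})

#' List the table schemas the pipeline understands
#' @return Character vector of schema ids.
#' @export
table_schemas <- function() names(.schemas)

.coerce_col <- function(x, type, col) {
  out <- switch(type,
    character = as.character(x),
    logical   = if (is.logical(x)) x else as.logical(x),
    date      = as.Date(x),
    numeric   = {
      if (is.character(x)) suppressWarnings(as.numeric(x)) else as.numeric(x)
    },
    stop(sprintf("internal: unknown column type '%s'", type)))
  if (type %in% c("numeric", "date", "logical")) {
    bad <- which(is.na(out) & !is.na(x) & !(is.character(x) & x == ""))
    if (length(bad) > 0)
      stop(sprintf("column '%s': cannot parse value at row %d", col, bad[1]))
  }
  out
}

#' Read and validate a pipeline table
#'
#' @param path CSV file path.
#' @param schema Schema id; see [table_schemas()].
#' @return A validated data frame. Concentration values with a `units` column
#'   of `ug/L` (or the micro-sign spelling) are divided by 1000 into mg/L and
#'   the column is dropped.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(.schemas))
  sc <- .schemas[[schema]]
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(names(sc$required), names(df))
  if (length(missing) > 0)
    stop(sprintf("schema '%s': missing column(s): %s", schema,
                 paste(missing, collapse = ", ")))
  for (col in names(sc$required))
    df[[col]] <- .coerce_col(df[[col]], sc$required[[col]], col)
  if (!is.null(sc$optional))
    for (col in intersect(names(sc$optional), names(df)))
      df[[col]] <- .coerce_col(df[[col]], sc$optional[[col]], col)
  df <- .apply_units(df, schema)
  validate_table(df, schema)
  df
}

# convert a recognised units column to mg/L and drop it
.apply_units <- function(df, schema) {
  if (schema == "samples" && "units" %in% names(df)) {
    u <- tolower(trimws(df$units))
    micro <- u %in% c("ug/l", "µg/l", "μg/l")
    ok <- micro | u %in% c("mg/l", "")
    if (any(!ok))
      stop(sprintf("row %d: unrecognised units '%s'",
                   which(!ok)[1], df$units[which(!ok)[1]]))
    df$value[micro] <- df$value[micro] / 1000
    df$detection_limit[micro] <- df$detection_limit[micro] / 1000
    df$units <- NULL
  }
  df
}

#' Validate a data frame against a schema
#'
#' @param df Data frame.
#' @param schema Schema id.
#' @return `df`, invisibly; errors list every violated row invariant.
#' @export
validate_table <- function(df, schema) {
  schema <- match.arg(schema, names(.schemas))
  sc <- .schemas[[schema]]
  missing <- setdiff(names(sc$required), names(df))
  if (length(missing) > 0)
    stop(sprintf("schema '%s': missing column(s): %s", schema,
                 paste(missing, collapse = ", ")))
  if (nrow(df) > 0) {
    problems <- sc$check(df)
    if (length(problems) > 0)
      stop(sprintf("schema '%s': %s", schema,
                   paste(utils::head(problems, 10), collapse = "; ")))
  }
  invisible(df)
}

#' Write a pipeline table to CSV
#'
#' Round-trips exactly: `read_table(write_table(df, p), schema)` reproduces
#' `df` (dates as ISO-8601, full numeric precision).
#'
#' @param df Validated data frame.
#' @param path Output path.
#' @param schema Schema id.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema) {
  schema <- match.arg(schema, names(.schemas))
  validate_table(df, schema)
  out <- df
  for (col in names(out)) {
    if (inherits(out[[col]], "Date")) {
      out[[col]] <- format(out[[col]], "%Y-%m-%d")
    } else if (is.double(out[[col]])) {
      # %.17g guarantees exact double round-trip through text
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
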