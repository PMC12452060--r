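# Schema-validated plain-text table I/O shared by all stages.
# Schemas: required columns with type and (optionally) a positivity rule;
# unknown columns warn, missing required columns are fatal, and value
# violations report the offending data row.

.schemas <- list(
  growth = list(
    sep = ",",
    required = c(mouse_id = "character", cell_line = "character",
                 host = "character", day = "numeric", volume_mm3 = "numeric"),
    optional = c(length_mm = "numeric", width_mm = "numeric"),
    checks = list(
      day = function(x) x >= 0,
      volume_mm3 = function(x) x > 0)),
  plate = list(
    sep = ",",
    required = c(drug = "character", concentration = "numeric",
                 concentration_unit = "character", replicate = "numeric",
                 viability_pct = "numeric"),
    optional = c(cell_line = "character"),
    checks = list(
      concentration = function(x) x >= 0,
      viability_pct = function(x) x >= 0)),
  array = list(
    sep = "\t",
    required = c(probe = "character", role = "character",
                 condition = "character", spot1 = "numeric",
                 spot2 = "numeric"),
    optional = character(),
    checks = list(
      role = function(x) x %in% c("analyte", "pos_control", "neg_control"),
      condition = function(x) x %in% c("A", "B"),
      spot1 = function(x) x >= 0,
      spot2 = function(x) x >= 0)),
  chains = list(
    sep = ",",
    required = c(chain = "numeric", draw = "numeric"),
    optional = NULL,  # any parameter columns allowed
    checks = list())
)

.validate_table <- function(df, schema_name, path = "<data>") {
  sc <- .schemas[[schema_name]]
  missing_cols <- setdiff(names(sc$required), names(df))
  if (length(missing_cols))
    stop(path, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "), " for the ", schema_name,
         " schema")
  if (!is.null(sc$optional)) {
    unknown <- setdiff(names(df), c(names(sc$required), names(sc$optional)))
    if (length(unknown))
      warning(path, ": ignoring unknown column(s) ",
              paste(unknown, collapse = ", "))
  }
  for (col in names(sc$required)) {
    if (sc$required[[col]] == "numeric") {
      if (!is.numeric(df[[col]]))
        stop(path, ": column ", col, " must be numeric")
      if (anyNA(df[[col]]))
        stop(path, ": column ", col, " has missing values (row ",
             which(is.na(df[[col]]))[1], ")")
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  for (col in names(sc$checks)) {
    bad <- which(!sc$checks[[col]](df[[col]]))
    if (length(bad))
      stop(path, ": column ", col, " violates the ", schema_name,
           " schema at data row ", bad[1], " (value ", df[[col]][bad[1]],
           ")")
  }
  df
}

#' Read or write a validated analysis table
#'
#' Plain-text table I/O with strict schema validation. Four schemas are
#' supported: `"growth"` (longitudinal tumor volumes; CSV with columns
#' `mouse_id`, `cell_line`, `host`, `day`, `volume_mm3`, optional
#' `length_mm`/`width_mm`), `"plate"` (viability plates; CSV with `drug`,
#' `concentration`, `concentration_unit`, `replicate`, `viability_pct`,
#' optional `cell_line`), `"array"` (duplicate-spot arrays; TSV with
#' `probe`, `role`, `condition`, `spot1`, `spot2`), and `"chains"` (MCMC
#' draws; CSV with `chain`, `draw`, one column per parameter). Missing
#' required columns are fatal; unknown columns produce a warning; value
#' violations report the first offending data row. CRLF and quoted fields
#' are handled by the base readers.
#'
#' @param path file path.
#' @param schema one of `"growth"`, `"plate"`, `"array"`, `"chains"`.
#' @return `read_table_schema()` returns the validated data frame;
#'   `write_table_schema()` writes `df` (after validation) and returns
#'   `path` invisibly.
#' @export
read_table_schema <- function(path, schema = c("growth", "plate", "array",
                                               "chains")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .schemas[[schema]]$sep
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  .validate_table(df, schema, path)
}

#' @rdname read_table_schema
#' @param df data frame to write.
#' @export
write_table_schema <- function(df, path, schema = c("growth", "plate",
                                                    "array", "chains")) {
  schema <- match.arg(schema)
  df <- .validate_table(df, schema, "<data>")
  write.table(df, path, sep = .schemas[[schema]]$sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname read_table_schema
#' @export
read_growth_table <- function(path) read_table_schema(path, "growth")

#' @rdname read_table_schema
#' @export
read_plate_table <- function(path) read_table_schema(path, "plate")

#' @rdname read_table_schema
#' @export
read_array_table <- function(path) read_table_schema(path, "array")
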