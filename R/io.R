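# CSV schemas with an explicit unit metadata row.
#
# Every table this package reads or writes starts with a single comment
# line declaring the unit of each dimensioned column, e.g.
#   # units: time=day; concentration=ug/mL
# Units are converted to the package's canonical units on read (with a
# message); an unknown unit is a hard error, never a silent pass-through.

.unit_tables <- list(
  time = c("day" = 1, "d" = 1, "hour" = 1 / 24, "h" = 1 / 24),
  concentration = c("ug/mL" = 1, "mg/L" = 1, "ng/mL" = 1e-3),
  dose = c("ug/kg" = 1, "mg/kg" = 1000),
  mass = c("g" = 1, "mg" = 1e-3),
  length = c("mm" = 1, "cm" = 10),
  count = c("counts" = 1)
)

.canonical_unit <- function(quantity) {
  names(.unit_tables[[quantity]])[1]
}

.schemas <- list(
  concentration = list(
    required = c("group_id", "analyte", "assay", "time", "concentration"),
    optional = "dose_group",
    labels = c("group_id", "analyte", "assay"),
    quantity = c(time = "time", concentration = "concentration",
                 dose_group = "dose")
  ),
  tissue_counts = list(
    required = c("animal_id", "tissue", "mass", "counts", "background",
                 "count_time", "isotope"),
    optional = c("group", "timepoint"),
    labels = c("animal_id", "tissue", "isotope", "group"),
    quantity = c(mass = "mass", count_time = "time", timepoint = "time",
                 counts = "count", background = "count")
  ),
  standards = list(
    required = c("isotope", "counts", "background", "count_time"),
    optional = character(),
    labels = "isotope",
    quantity = c(count_time = "time", counts = "count", background = "count")
  ),
  caliper = list(
    required = c("animal_id", "group", "study_day", "length", "width"),
    optional = character(),
    labels = c("animal_id", "group"),
    quantity = c(length = "length", width = "length")
  )
)

.write_units_csv <- function(x, path, schema) {
  sc <- .schemas[[schema]]
  known <- c(sc$required, sc$optional)
  cols <- intersect(names(x), known)
  miss <- setdiff(sc$required, names(x))
  if (length(miss) > 0) {
    abort(sprintf("Cannot write %s table: missing column(s) %s.",
                  schema, paste(miss, collapse = ", ")),
          class = "adcpk_io_error")
  }
  x <- as.data.frame(x)[, cols, drop = FALSE]
  qty <- sc$quantity[intersect(names(sc$quantity), cols)]
  units_line <- paste0("# units: ", paste(
    sprintf("%s=%s", names(qty), vapply(qty, .canonical_unit, "")),
    collapse = "; "))
  body <- vapply(x, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, FUN.VALUE = character(nrow(x)))
  if (nrow(x) == 1L) body <- matrix(body, nrow = 1)
  lines <- c(units_line,
             paste(cols, collapse = ","),
             apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

.read_units_csv <- function(path, schema) {
  sc <- .schemas[[schema]]
  first <- readLines(path, n = 1)
  if (!grepl("^# units:", first)) {
    abort(sprintf("%s: missing '# units:' metadata row (first line).", path),
          class = "adcpk_io_error")
  }
  decl <- strsplit(sub("^# units:\\s*", "", first), ";")[[1]]
  decl <- trimws(decl)
  decl <- decl[nzchar(decl)]
  kv <- strsplit(decl, "=")
  units <- setNames(trimws(vapply(kv, `[`, "", 2)),
                    trimws(vapply(kv, `[`, "", 1)))
  hdr <- strsplit(readLines(path, n = 2)[2], ",", fixed = TRUE)[[1]]
  num_cols <- intersect(names(sc$quantity), hdr)
  chr_cols <- intersect(sc$labels %||% character(), hdr)
  x <- readr::read_csv(path, skip = 1, show_col_types = FALSE,
                       progress = FALSE,
                       col_types = do.call(readr::cols, c(
                         setNames(rep(list(readr::col_double()),
                                      length(num_cols)), num_cols),
                         setNames(rep(list(readr::col_character()),
                                      length(chr_cols)), chr_cols),
                         list(.default = readr::col_guess()))))
  miss <- setdiff(sc$required, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing required column(s): %s.", path,
                  paste(miss, collapse = ", ")),
          class = "adcpk_io_error")
  }
  for (col in names(units)) {
    if (!col %in% names(x)) next
    qname <- sc$quantity[[col]]
    if (is.null(qname)) next
    tab <- .unit_tables[[qname]]
    u <- units[[col]]
    if (!u %in% names(tab)) {
      abort(sprintf("%s: unit '%s' for column '%s' is not recognised (expected one of: %s).",
                    path, u, col, paste(names(tab), collapse = ", ")),
            class = "adcpk_unit_error")
    }
    if (tab[[u]] != 1) {
      inform(sprintf("Converting column '%s' from %s to %s.",
                     col, u, .canonical_unit(qname)))
      x[[col]] <- x[[col]] * tab[[u]]
    }
  }
  x
}

#' Read and write the package's CSV schemas
#'
#' Three tidy CSV schemas cover the pipeline inputs: concentration records
#' (`group_id`, `analyte`, `assay`, `time`, `concentration`, optionally
#' `dose_group`), gamma-count records plus dosing-solution standards, and
#' caliper measurements. Every file carries a `# units:` metadata row as
#' its first line; recognised non-canonical units (ng/mL, mg/kg, hours,
#' ...) are converted on read with a message, unknown units are an error.
#' `read_*(write_*(x))` round-trips values exactly.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Readers return a tibble (canonical units: days, ug/mL, ug/kg,
#'   g, mm); writers return `path` invisibly.
#' @name adcpk_io
NULL

#' @rdname adcpk_io
#' @export
write_concentration_csv <- function(x, path) .write_units_csv(x, path, "concentration")

#' @rdname adcpk_io
#' @export
read_concentration_csv <- function(path) .read_units_csv(path, "concentration")

#' @rdname adcpk_io
#' @export
write_tissue_counts_csv <- function(x, path) .write_units_csv(x, path, "tissue_counts")

#' @rdname adcpk_io
#' @export
read_tissue_counts_csv <- function(path) .read_units_csv(path, "tissue_counts")

#' @rdname adcpk_io
#' @export
write_standards_csv <- function(x, path) .write_units_csv(x, path, "standards")

#' @rdname adcpk_io
#' @export
read_standards_csv <- function(path) .read_units_csv(path, "standards")

#' @rdname adcpk_io
#' @export
write_caliper_csv <- function(x, path) .write_units_csv(x, path, "caliper")

#' @rdname adcpk_io
#' @export
read_caliper_csv <- function(path) .read_units_csv(path, "caliper")
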