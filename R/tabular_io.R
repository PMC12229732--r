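#' Read an agronomic record table
#'
#' Loads a delimited text file of agronomic records and maps its columns onto
#' the canonical schema (case-insensitive header matching with common aliases
#' such as `Lat`, `Long`, `Crops`). Duplicated columns -- some source tables
#' repeat trailing pH/EC columns as a printing artifact -- are dropped,
#' keeping the first occurrence. Numeric cells may use comma thousands
#' separators; cells that fail numeric parsing abort with their row and
#' column, while genuinely empty cells become `NA`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter, default comma.
#' @param required Canonical column names that must be present after header
#'   normalization. Defaults to the full schema; pass a subset for partial
#'   tables.
#' @param aliases Optional named character vector of extra header aliases
#'   (`c(alias = "canonical")`), merged over the built-in ones.
#'
#' @return A tibble with a leading `row_id` column, canonical column names,
#'   numeric measurement columns and character category columns. Columns not
#'   in the schema are kept verbatim after the canonical ones.
#' @export
#' @examples
#' tab <- read_record_table(
#'   system.file("extdata", "davangere_sample.csv", package = "agrioutlier")
#' )
#' dplyr::glimpse(tab)
read_record_table <- function(path, delim = ",", required = agri_all_columns(),
                              aliases = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "agri_io_error")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), name_repair = "minimal", progress = FALSE)

  raw <- raw[, !tolower(names(raw)) %in% "row_id", drop = FALSE]
  header <- names(raw)
  canon <- normalize_header(header)
  if (!is.null(aliases)) {
    key <- gsub("[^a-z0-9]", "", tolower(header))
    hit <- match(key, names(aliases))
    canon[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  # duplicated canonical names: keep first occurrence
  keep <- !duplicated(canon)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- canon[keep]

  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "agri_schema_error")
  }
  if (nrow(raw) == 0) {
    abort("table has a valid header but zero data rows",
          class = "agri_empty_error")
  }

  num_cols <- intersect(agri_numeric_columns(), names(raw))
  failures <- list()
  for (cn in num_cols) {
    cell <- raw[[cn]]
    # strip grouping commas, then exact (correctly rounded) base parsing
    parsed <- suppressWarnings(as.numeric(gsub(",", "", trimws(cell))))
    bad <- which(is.na(parsed) & !is.na(cell) & cell != "" & cell != "NA")
    if (length(bad) > 0) {
      failures[[cn]] <- bad
    }
    raw[[cn]] <- as.numeric(parsed)
  }
  if (length(failures) > 0) {
    msg <- paste(vapply(names(failures), function(cn) {
      paste0(cn, " (rows ", paste(failures[[cn]], collapse = ", "), ")")
    }, character(1)), collapse = "; ")
    abort(paste0("unparseable numeric cell(s): ", msg),
          class = "agri_parse_error")
  }

  if ("latitude" %in% names(raw)) {
    bad <- which(!is.na(raw$latitude) & abs(raw$latitude) > 90)
    if (length(bad) > 0) {
      abort(paste0("latitude outside [-90, 90] at row(s) ",
                   paste(bad, collapse = ", ")), class = "agri_parse_error")
    }
  }
  if ("longitude" %in% names(raw)) {
    bad <- which(!is.na(raw$longitude) & abs(raw$longitude) > 180)
    if (length(bad) > 0) {
      abort(paste0("longitude outside [-180, 180] at row(s) ",
                   paste(bad, collapse = ", ")), class = "agri_parse_error")
    }
  }

  ordered <- c(intersect(agri_all_columns(), names(raw)),
               setdiff(names(raw), agri_all_columns()))
  out <- tibble::as_tibble(raw[, ordered, drop = FALSE])
  tibble::add_column(out, row_id = seq_len(nrow(out)), .before = 1)
}

#' Write an agronomic record table
#'
#' Writes a record table back to CSV at full numeric precision (15
#' significant digits), so a write/read round trip reproduces every numeric
#' value exactly and every category verbatim. The `row_id` bookkeeping column
#' is dropped on write and regenerated on read.
#'
#' @param table A record-table tibble, e.g. from [read_record_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record_table <- function(table, path) {
  out <- table[, setdiff(names(table), "row_id"), drop = FALSE]
  # shortest decimal text that parses back to the identical double
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric), function(x) {
    s <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
    lossy <- !is.na(x) & as.numeric(s) != x
    s[lossy] <- sprintf("%.17g", x[lossy])
    s[is.na(x)] <- NA_character_
    s
  }))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Sample records from the study region
#'
#' Returns the 25 published sample records from the Davangere-region
#' agricultural dataset, exactly as printed: the repeated trailing pH/EC
#' columns are deduplicated on load, and the anomalous record whose soil cell
#' reads `"Maize"` (pH 7.74) is preserved verbatim. Temperature, rainfall,
#' area, production and yield are constant across this sample.
#'
#' @return A 25-row record-table tibble.
#' @export
#' @examples
#' table1_fixture()
table1_fixture <- function() {
  path <- system.file("extdata", "davangere_sample.csv",
                      package = "agrioutlier")
  read_record_table(path)
}

#' Validate a record table against the schema
#'
#' Report-only checks; the table is never mutated. Three kinds of findings
#' are reported: `"range"` (pH outside \[0, 14\], negative area, production or
#' yield, coordinates outside valid degrees), `"vocabulary"` (season, soil or
#' crop labels outside the known vocabularies, one finding per distinct
#' offending value) and `"constant"` (numeric columns with zero variance,
#' which degrade distance-based detectors).
#'
#' @param table A record-table tibble.
#' @return A tibble with columns `check`, `column`, `value`, `rows` (comma
#'   separated indices) and `message`; zero rows when the table is clean.
#' @export
#' @examples
#' validate_schema(table1_fixture())
validate_schema <- function(table) {
  findings <- list()
  add <- function(check, column, value, rows, message) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      check = check, column = column, value = as.character(value),
      rows = paste(rows, collapse = ","), message = message
    )
  }

  range_rules <- list(
    ph = function(x) x < 0 | x > 14,
    area = function(x) x < 0,
    production = function(x) x < 0,
    yield = function(x) x < 0,
    latitude = function(x) abs(x) > 90,
    longitude = function(x) abs(x) > 180
  )
  for (cn in intersect(names(range_rules), names(table))) {
    x <- table[[cn]]
    bad <- which(!is.na(x) & range_rules[[cn]](x))
    if (length(bad) > 0) {
      add("range", cn, paste(unique(x[bad]), collapse = ","), bad,
          paste0(cn, " out of valid range at ", length(bad), " row(s)"))
    }
  }

  vocab <- agri_vocabularies()
  vocab_cols <- c(season = "season", soil = "soil", crop = "crop")
  for (cn in intersect(vocab_cols, names(table))) {
    x <- table[[cn]]
    for (v in setdiff(unique(x[!is.na(x)]), vocab[[cn]])) {
      add("vocabulary", cn, v, which(x == v),
          paste0("value \"", v, "\" is not a known ", cn, " category"))
    }
  }

  for (cn in intersect(agri_numeric_columns(), names(table))) {
    x <- table[[cn]]
    x <- x[!is.na(x)]
    if (length(x) > 1 && diff(range(x)) == 0) {
      add("constant", cn, x[1], integer(0),
          paste0(cn, " is constant across all rows"))
    }
  }

  if (length(findings) == 0) {
    return(tibble::tibble(check = character(), column = character(),
                          value = character(), rows = character(),
                          message = character()))
  }
  dplyr::bind_rows(findings)
}
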