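#' @importFrom utils read.csv write.csv
#' @importFrom stats sd complete.cases
NULL

# canonical measurement columns of a footprint record, all in cm except the
# two angles (degrees). Dt1..Dt5 are digit-tip to heel-baseline lengths.
MEASUREMENT_COLUMNS <- c(
  "Dt1", "Dt2", "Dt3", "Dt4", "Dt5",
  "mtm_BL", "mtl_BL", "ntu_BL", "mttu_BL", "ccm_BL", "ctul_BL",
  "mtm_horiz", "mttu_horiz", "ctul_horiz",
  "T1_T5", "max_FL", "max_FW", "Aa"
)

# the nine anatomical lengths/widths entering the principal component analysis
PCA_VARIABLES <- c(
  "Dt1", "Dt2", "Dt3", "mtm_BL", "mtl_BL",
  "ccm_BL", "ctul_BL", "mtm_horiz", "ctul_horiz"
)

# aliases used by the PCA measurement table (suffix -BL on digit lengths)
.canonical_aliases <- c(
  Dt1_BL = "Dt1", Dt2_BL = "Dt2", Dt3_BL = "Dt3",
  Dt4_BL = "Dt4", Dt5_BL = "Dt5"
)

#' Construct a footprint measurement table
#'
#' A `footprint_table` is a data frame with one row per footprint, a unique
#' `id` column, and any subset of the canonical measurement columns
#' (lengths/widths in cm, `T1_T5` and `Aa` in degrees). Missing measurements
#' are `NA`; they are never zero-filled.
#'
#' @param df data frame with at least an `id` column.
#' @param validate if `TRUE` (default), signal an error when any record has
#'   a hard violation (negative measurement, duplicated id).
#' @return a `footprint_table` (data frame subclass, units fixed cm/degrees).
#' @seealso [read_footprint_table()], [validate_record()]
#' @export
footprint_table <- function(df, validate = TRUE) {
  stopifnot(is.data.frame(df))
  if (!"id" %in% names(df)) stop("footprint table needs an 'id' column")
  df$id <- as.character(df$id)
  # accept alias column names from the PCA-style table layout
  hits <- intersect(names(df), names(.canonical_aliases))
  names(df)[match(hits, names(df))] <- .canonical_aliases[hits]
  if (anyDuplicated(df$id))
    stop("duplicate footprint_id: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  meas <- intersect(MEASUREMENT_COLUMNS, names(df))
  for (v in meas) df[[v]] <- as.numeric(df[[v]])
  if (validate) {
    bad <- unlist(lapply(meas, function(v) {
      i <- which(!is.na(df[[v]]) & df[[v]] <= 0)
      if (length(i)) paste0(df$id[i], "/", v) else character()
    }))
    if (length(bad))
      stop("non-positive measurement(s): ", paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, class = c("footprint_table", "data.frame"),
            units = c(length = "cm", angle = "degrees"))
}

#' @export
print.footprint_table <- function(x, ...) {
  meas <- intersect(MEASUREMENT_COLUMNS, names(x))
  cat("Footprint measurement table: ", nrow(x), " record(s), ",
      length(meas), " measurement column(s) [cm/degrees]\n", sep = "")
  if (nrow(x)) {
    miss <- sum(is.na(as.matrix(x[meas])))
    cat("missing cells: ", miss, "\n", sep = "")
  }
  NextMethod()
}

# parse one numeric CSV cell; "" -> NA; decimal comma accepted ("3,20")
.parse_cell <- function(cell, row, col) {
  cell <- trimws(cell)
  if (cell == "" || cell == "-" || is.na(cell)) return(NA_real_)
  v <- suppressWarnings(as.numeric(gsub(",", ".", cell, fixed = TRUE)))
  if (is.na(v))
    stop(sprintf("unparseable numeric cell '%s' (row %s, column %s)",
                 cell, row, col))
  v
}

#' Read a footprint measurement table from CSV
#'
#' Reads an RFC-4180 CSV (header row required, UTF-8). Empty cells and "-"
#' denote missing measurements and are preserved as `NA`. Both decimal point
#' and decimal comma are accepted in numeric cells (the published tables mix
#' "3,20" and "3.33"); output is always written with a decimal point.
#'
#' @param path CSV file path.
#' @return a [footprint_table()].
#' @export
read_footprint_table <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL, fileEncoding = "UTF-8")
  if (!"id" %in% names(raw)) stop("CSV must have an 'id' header column")
  hits <- intersect(names(raw), names(.canonical_aliases))
  names(raw)[match(hits, names(raw))] <- .canonical_aliases[hits]
  numcols <- intersect(c(MEASUREMENT_COLUMNS,
                         "FI", "stature", "mass_a", "mass_b", "mass_c"),
                       names(raw))
  for (v in numcols) {
    raw[[v]] <- vapply(seq_len(nrow(raw)), function(i)
      .parse_cell(raw[[v]][i], raw$id[i], v), numeric(1))
  }
  for (v in intersect(c("summary_subset", "in_situ", "cast_1950"), names(raw)))
    raw[[v]] <- as.logical(raw[[v]])
  if ("morphotype" %in% names(raw)) raw$morphotype <- as.integer(raw$morphotype)
  footprint_table(raw)
}

#' Write a footprint table to CSV
#'
#' Missing cells are written as empty strings; all numbers use a decimal
#' point. `read_footprint_table(write_footprint_table(T))` round-trips all
#' values and missingness.
#'
#' @param x a [footprint_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_footprint_table <- function(x, path) {
  stopifnot(inherits(x, "footprint_table"))
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a single footprint record
#'
#' Pure check of the record invariants: all present lengths/widths positive,
#' `max_FL >= max_FW`, arch angle strictly between 0 and 90 degrees, side
#' (when present) left or right. Issues are returned, never raised.
#'
#' @param r one-row data frame or named list holding measurement fields.
#' @return character vector of issues (empty when the record is clean).
#' @export
validate_record <- function(r) {
  issues <- character()
  num <- function(v) if (!is.null(r[[v]]) && !is.na(r[[v]])) as.numeric(r[[v]]) else NA_real_
  for (v in intersect(MEASUREMENT_COLUMNS, names(r))) {
    x <- num(v)
    if (!is.na(x) && x <= 0)
      issues <- c(issues, sprintf("%s must be positive (got %g)", v, x))
  }
  fl <- num("max_FL"); fw <- num("max_FW")
  if (!is.na(fl) && !is.na(fw) && fw > fl)
    issues <- c(issues, sprintf("max_FW (%g) exceeds max_FL (%g)", fw, fl))
  aa <- num("Aa")
  if (!is.na(aa) && (aa <= 0 || aa >= 90))
    issues <- c(issues, sprintf("arch angle Aa (%g) outside (0, 90)", aa))
  if (!is.null(r[["side"]]) && !is.na(r[["side"]]) &&
      !r[["side"]] %in% c("left", "right"))
    issues <- c(issues, sprintf("side '%s' not left/right", r[["side"]]))
  issues
}

#' Validate every record of a footprint table
#'
#' @param x a [footprint_table()].
#' @return named list of per-record issue vectors, only for records with
#'   at least one issue.
#' @export
validate_footprint_table <- function(x) {
  stopifnot(inherits(x, "footprint_table"))
  out <- lapply(seq_len(nrow(x)), function(i) validate_record(x[i, ]))
  names(out) <- x$id
  out[vapply(out, length, integer(1)) > 0]
}

#' Load the packaged Bàsura cave measurement tables
#'
#' The three published measurement tables of the Bàsura cave human footprint
#' record, transcribed as packaged CSV fixtures:
#' \describe{
#'   \item{`table2`}{qualitative shape descriptors (Robbins recording form)
#'     with the published morphotype label of each footprint (26 records).}
#'   \item{`table3`}{full measurement set plus the published elaborations
#'     (foot index, stature, body mass per model) for the 26 best-preserved
#'     footprints; `summary_subset` flags the rows entering each published
#'     morphotype summary (reverse-engineered arithmetically, as the paper
#'     never states the subsets).}
#'   \item{`table3_summary`}{the published per-morphotype summary rows
#'     (mean ± sample SD and age class).}
#'   \item{`table4`}{the nine anatomical lengths/widths of the 23 footprints
#'     used for the principal component analysis.}
#' }
#' Known transcription notes: SM26 is printed with side R in the measurement
#' table but L in the descriptor table (both preserved); the descriptor table
#' prints "CA10" where the measurement tables print "C10"; age-class strings
#' use ASCII hyphens ("5-6").
#'
#' @param which one of `"table2"`, `"table3"`, `"table3_summary"`, `"table4"`.
#' @return a [footprint_table()] (`table3_summary`: a plain data frame).
#' @export
load_basura_fixtures <- function(which = c("table3", "table4", "table2",
                                           "table3_summary")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".csv"),
                      package = "ichnometry", mustWork = TRUE)
  if (which == "table3_summary")
    return(read.csv(path, check.names = FALSE))
  if (which == "table2") {
    df <- read.csv(path, colClasses = "character", check.names = FALSE)
    df$morphotype <- as.integer(df$morphotype)
    return(footprint_table(df))
  }
  read_footprint_table(path)
}
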