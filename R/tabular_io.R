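#' @title Colony and ROV observation tables
#' @description Readers, writers and validators for the two tabular inputs
#'   used throughout the package: a colony measurement table (one row per
#'   physically measured colony) and an ROV observation table (one row per
#'   colony seen on video, with its visible-side polyp-leaf count).
#' @name tabular_io
NULL

colony_columns <- c(
  "colony_id", "leaves_left", "leaves_right",
  "total_length_mm", "peduncle_length_mm", "fresh_weight_g"
)

rov_columns <- c("colony_id", "leaf_count")

is_count <- function(x) {
  is.numeric(x) & is.finite(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

stop_row <- function(row, rule) {
  stop(sprintf("colony table validation failed at row %d: %s", row, rule),
       call. = FALSE)
}

#' Validate a colony measurement table
#'
#' Checks every structural invariant of a colony table: non-negative integer
#' leaf counts per side, positive total length, non-negative peduncle length
#' strictly below total length (so rachis length, the visible part, is
#' positive), positive fresh weight, and -- where present -- dry weight
#' strictly between zero and fresh weight. Lengths are millimetres, weights
#' grams.
#'
#' @param colonies data frame with columns `colony_id`, `leaves_left`,
#'   `leaves_right`, `total_length_mm`, `peduncle_length_mm`,
#'   `fresh_weight_g` and optionally `dry_weight_g` (`NA` = not measured).
#' @return The validated data frame, invisibly usable in pipelines; a
#'   `dry_weight_g` column is added (all `NA`) when absent.
#' @export
validate_colony_table <- function(colonies) {
  if (!is.data.frame(colonies)) {
    stop("colony table must be a data frame", call. = FALSE)
  }
  missing <- setdiff(colony_columns, names(colonies))
  if (length(missing) > 0) {
    stop("colony table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(colonies) == 0) {
    stop("colony table is empty (no data rows)", call. = FALSE)
  }
  if (!"dry_weight_g" %in% names(colonies)) {
    colonies$dry_weight_g <- NA_real_
  }
  colonies$colony_id <- as.character(colonies$colony_id)
  for (col in setdiff(colony_columns, "colony_id")) {
    if (!is.numeric(colonies[[col]])) {
      stop(sprintf("colony table column '%s' must be numeric", col),
           call. = FALSE)
    }
  }
  for (i in seq_len(nrow(colonies))) {
    r <- colonies[i, ]
    if (!is_count(r$leaves_left) || !is_count(r$leaves_right)) {
      stop_row(i, "leaf counts must be non-negative integers")
    }
    if (!is.finite(r$total_length_mm) || r$total_length_mm <= 0) {
      stop_row(i, "total_length_mm must be > 0")
    }
    if (!is.finite(r$peduncle_length_mm) || r$peduncle_length_mm < 0) {
      stop_row(i, "peduncle_length_mm must be >= 0")
    }
    if (r$peduncle_length_mm >= r$total_length_mm) {
      stop_row(i, paste(
        "peduncle_length_mm must be < total_length_mm",
        "(rachis length = total - peduncle must be positive)"
      ))
    }
    if (!is.finite(r$fresh_weight_g) || r$fresh_weight_g <= 0) {
      stop_row(i, "fresh_weight_g must be > 0")
    }
    if (!is.na(r$dry_weight_g)) {
      if (!is.finite(r$dry_weight_g) || r$dry_weight_g <= 0 ||
          r$dry_weight_g >= r$fresh_weight_g) {
        stop_row(i, "dry_weight_g must satisfy 0 < dry < fresh")
      }
    }
  }
  if (anyDuplicated(colonies$colony_id)) {
    warning("duplicate colony_id values present; ids are labels, not keys",
            call. = FALSE)
  }
  colonies$leaves_left <- as.integer(round(colonies$leaves_left))
  colonies$leaves_right <- as.integer(round(colonies$leaves_right))
  rownames(colonies) <- NULL
  colonies
}

#' Validate an ROV observation table
#'
#' @param observations data frame with columns `colony_id` and `leaf_count`
#'   (visible-side polyp-leaf count, non-negative integer).
#' @return The validated data frame.
#' @export
validate_rov_table <- function(observations) {
  if (!is.data.frame(observations)) {
    stop("ROV table must be a data frame", call. = FALSE)
  }
  missing <- setdiff(rov_columns, names(observations))
  if (length(missing) > 0) {
    stop("ROV table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(observations) == 0) {
    stop("ROV table is empty (no data rows)", call. = FALSE)
  }
  observations$colony_id <- as.character(observations$colony_id)
  if (!is.numeric(observations$leaf_count)) {
    stop("ROV table column 'leaf_count' must be numeric", call. = FALSE)
  }
  bad <- which(!is_count(observations$leaf_count))
  if (length(bad) > 0) {
    stop(sprintf(
      "ROV table validation failed at row %d: leaf_count must be a non-negative integer",
      bad[1]
    ), call. = FALSE)
  }
  if (anyDuplicated(observations$colony_id)) {
    warning("duplicate colony_id values present; ids are labels, not keys",
            call. = FALSE)
  }
  observations$leaf_count <- as.integer(round(observations$leaf_count))
  rownames(observations) <- NULL
  observations
}

#' Read a colony measurement table from CSV
#'
#' Comma-separated, UTF-8, decimal point, header row required. Expected
#' columns: `colony_id`, `leaves_left`, `leaves_right`, `total_length_mm`,
#' `peduncle_length_mm`, `fresh_weight_g`, and optionally `dry_weight_g`
#' (blank cells mean "not measured"). Validation is all-or-nothing: any
#' malformed row aborts the read with a diagnostic naming the row and the
#' violated rule.
#'
#' @param path path to a CSV file.
#' @return Validated colony data frame, rows in file order.
#' @seealso [validate_colony_table()], [write_colony_table()]
#' @export
read_colony_table <- function(path) {
  if (!file.exists(path)) {
    stop("colony table file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_colony_table(df)
}

#' Read an ROV observation table from CSV
#'
#' Expected columns: `colony_id`, `leaf_count`.
#'
#' @param path path to a CSV file.
#' @return Validated ROV data frame, rows in file order.
#' @export
read_rov_table <- function(path) {
  if (!file.exists(path)) {
    stop("ROV table file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_rov_table(df)
}

# Full-precision CSV serialisation so that write -> read round-trips
# doubles exactly.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

#' Write a colony table to CSV
#'
#' Numeric fields are written with enough digits that reading the file back
#' reproduces every value exactly.
#'
#' @param colonies validated colony data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_colony_table <- function(colonies, path) {
  colonies <- validate_colony_table(colonies)
  out <- data.frame(
    colony_id = colonies$colony_id,
    leaves_left = colonies$leaves_left,
    leaves_right = colonies$leaves_right,
    total_length_mm = format_full(colonies$total_length_mm),
    peduncle_length_mm = format_full(colonies$peduncle_length_mm),
    fresh_weight_g = format_full(colonies$fresh_weight_g),
    dry_weight_g = format_full(colonies$dry_weight_g),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ROV observation table to CSV
#'
#' @param observations validated ROV data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rov_table <- function(observations, path) {
  observations <- validate_rov_table(observations)
  utils::write.csv(observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Recursively strip S3 classes so jsonlite serialises model objects and
# summaries as plain JSON objects.
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    if (!is.data.frame(x)) attributes(x)$class <- NULL
  }
  x
}

#' Write a structured analysis report to JSON
#'
#' Serialises a report (any nested list of fitted models, moment summaries,
#' biomass estimates and metadata, e.g. the output of [run_pipeline()]) to
#' a machine-readable JSON file. Numbers are written at full precision so a
#' write-then-read round trip reproduces them bit-exactly.
#'
#' @param report nested list; S3 model/summary objects are serialised as
#'   plain objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    strip_classes(report), path,
    auto_unbox = TRUE, digits = I(17), na = "null", null = "null",
    pretty = TRUE
  )
  invisible(path)
}

#' Read a JSON analysis report
#'
#' @param path path to a report written by [write_report()].
#' @return Nested list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    stop("report file not found: ", path, call. = FALSE)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}
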