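# Enrichment time series: the package-internal unit is always a fraction in
# [0, 1]; percent is accepted only at the CSV boundary and converted there.

#' Construct an enrichment time series
#'
#' An enrichment series holds time-stamped deuterium-enrichment observations
#' for one subject and one compartment (plasma, urine, or the DNA of a named
#' cell population). Enrichments are fractions in \[0, 1\]; records are sorted
#' by time.
#'
#' @param time_days Observation times in days (>= 0).
#' @param enrichment Deuterium enrichment as a fraction in \[0, 1\].
#' @param subject_id Opaque subject label.
#' @param compartment One of `"plasma"`, `"urine"`, `"dna"`.
#' @param population Cell-population label (e.g. `"thymocytes"`); empty for
#'   fluid compartments.
#' @return A data frame of class `"enrichment_series"` with columns
#'   `subject_id`, `compartment`, `population`, `time_days`, `enrichment`.
#' @examples
#' enrichment_series(c(0, 1, 2), c(0, 0.01, 0.02), population = "PBMC")
#' @export
enrichment_series <- function(time_days, enrichment, subject_id = "s1",
                              compartment = c("dna", "plasma", "urine"),
                              population = "") {
  compartment <- match.arg(compartment)
  if (length(time_days) != length(enrichment))
    stop("time_days and enrichment must have equal length")
  if (length(time_days) < 1L) stop("an enrichment series needs at least one record")
  if (any(time_days < 0)) stop("time_days must be non-negative")
  if (any(enrichment < 0 | enrichment > 1))
    stop("enrichment must be a fraction in [0, 1]")
  ord <- order(time_days)
  out <- data.frame(subject_id = as.character(subject_id),
                    compartment = compartment,
                    population = as.character(population),
                    time_days = as.numeric(time_days)[ord],
                    enrichment = as.numeric(enrichment)[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_series", "data.frame")
  out
}

# Stamp the class without re-validating; used after normalization, whose
# output may legitimately exceed 1.
.as_series <- function(df) {
  class(df) <- unique(c("enrichment_series", class(df)))
  df
}

.series_cols <- c("subject_id", "compartment", "population", "time_days",
                  "enrichment")

#' Read enrichment data from CSV
#'
#' The exchange schema has exactly the columns `subject_id`, `compartment`,
#' `population`, `time_days`, `enrichment`, `unit`. The `unit` column must be
#' uniformly `"fraction"` or `"percent"` within a file; percent values are
#' converted to fractions on read.
#'
#' @param path Path to a CSV file.
#' @return A data frame of class `"enrichment_series"` (without the `unit`
#'   column; values are fractions).
#' @export
read_enrichment_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c(.series_cols, "unit")
  missing <- setdiff(expected, names(df))
  extra <- setdiff(names(df), expected)
  if (length(missing))
    stop("CSV is missing required column(s): ", paste(missing, collapse = ", "))
  if (length(extra))
    stop("CSV has unexpected column(s): ", paste(extra, collapse = ", "))
  unit <- unique(df$unit)
  if (length(unit) != 1L)
    stop("mixed units within one file are not allowed: ",
         paste(unit, collapse = ", "))
  if (!unit %in% c("fraction", "percent"))
    stop("unit must be 'fraction' or 'percent', got '", unit, "'")
  if (unit == "percent") df$enrichment <- df$enrichment / 100
  bad <- !df$compartment %in% c("plasma", "urine", "dna")
  if (any(bad))
    stop("compartment must be plasma/urine/dna; offending value(s): ",
         paste(unique(df$compartment[bad]), collapse = ", "))
  if (any(df$time_days < 0)) stop("time_days must be non-negative")
  if (any(df$enrichment < 0))
    stop("enrichment must be non-negative after unit conversion")
  if (any(df$enrichment > 1))
    warning("enrichment values above 1 read as-is ",
            "(normalized data with an over-unity flag?)")
  df <- df[order(df$subject_id, df$compartment, df$population, df$time_days),
           .series_cols]
  rownames(df) <- NULL
  .as_series(df)
}

#' Write enrichment data to CSV
#'
#' @param x An enrichment series (or compatible data frame, fractions).
#' @param path Output path.
#' @param unit `"fraction"` (default) or `"percent"`.
#' @return `path`, invisibly.
#' @export
write_enrichment_csv <- function(x, path, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  df <- as.data.frame(x)[, .series_cols]
  if (unit == "percent") df$enrichment <- df$enrichment * 100
  df$unit <- unit
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Split a multi-series data frame into single (subject, compartment,
# population) series, preserving class.
split_series <- function(x) {
  key <- interaction(x$subject_id, x$compartment, x$population, drop = TRUE)
  lapply(split(as.data.frame(x), key), .as_series)
}

# Extract one series by filters; errors if empty.
.pick_series <- function(x, compartment = NULL, population = NULL,
                         subject_id = NULL) {
  df <- as.data.frame(x)
  if (!is.null(compartment)) df <- df[df$compartment %in% compartment, ]
  if (!is.null(population)) df <- df[df$population %in% population, ]
  if (!is.null(subject_id)) df <- df[df$subject_id %in% subject_id, ]
  if (nrow(df) == 0L) stop("no records match the requested series")
  df <- df[order(df$time_days), ]
  rownames(df) <- NULL
  .as_series(df)
}
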