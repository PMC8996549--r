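# Record data model, CSV in/out, and age/sex strata.
#
# A record set is a plain data.frame with the canonical columns
#   subject_id, collection_date, age, sex, analyte, value, units, source
# where age is in decimal years, sex is "male"/"female", and value carries
# the analyte's conventional units (umol/L for creatinine and uric acid,
# mmol/L for urea).

#' Conventional units per analyte
#'
#' @return Named character vector mapping analyte name to units.
#' @export
analyte_units <- function() {
  c(creatinine = "umol/L", urea = "mmol/L", uric_acid = "umol/L")
}

.canonical_cols <- c("subject_id", "collection_date", "age", "sex",
                     "analyte", "value", "units", "source")

.default_schema <- c(subject_id = "subject_id", date = "date",
                     age = "age_years", sex = "sex", analyte = "analyte",
                     value = "value", units = "units", source = "source")

normalize_sex <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("m", "male", "boy", "boys")] <- "male"
  out[s %in% c("f", "female", "girl", "girls")] <- "female"
  out
}

#' Read laboratory records from CSV
#'
#' Reads a comma-separated file of per-test records into the canonical record
#' data.frame. Rows with an unparseable or blank value, age, sex, or date are
#' dropped with a single warning reporting the count; a missing required
#' column is a hard error naming the column.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector remapping nonstandard
#'   headers; names are the canonical fields (\code{subject_id}, \code{date},
#'   \code{age}, \code{sex}, \code{analyte}, \code{value}, \code{units},
#'   \code{source}), values the column names found in the file. Defaults:
#'   \code{subject_id, date, age_years, sex, analyte, value, units, source}.
#' @return A data.frame of records (see package docs for the canonical
#'   columns). Dates are parsed as ISO-8601.
#' @seealso \code{\link{write_records}}
#' @export
read_records <- function(path, schema = NULL) {
  map <- .default_schema
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), names(map))
    if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    map[names(schema)] <- schema
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "age", "sex", "analyte", "value")
  for (f in required) {
    if (!map[[f]] %in% names(raw)) {
      stop("required column '", map[[f]], "' (field '", f, "') not found in ", path)
    }
  }
  grab <- function(f) if (map[[f]] %in% names(raw)) raw[[map[[f]]]] else NULL
  n <- nrow(raw)
  date_raw <- grab("date")
  dates <- if (is.null(date_raw)) rep(as.Date(NA), n) else {
    as.Date(suppressWarnings(as.character(date_raw)), format = "%Y-%m-%d",
            optional = TRUE)
  }
  ds <- data.frame(
    subject_id      = as.character(grab("subject_id")),
    collection_date = dates,
    age             = suppressWarnings(as.numeric(grab("age"))),
    sex             = normalize_sex(grab("sex")),
    analyte         = as.character(grab("analyte")),
    value           = suppressWarnings(as.numeric(grab("value"))),
    stringsAsFactors = FALSE
  )
  units <- grab("units")
  ds$units <- if (is.null(units)) unname(analyte_units()[ds$analyte]) else as.character(units)
  src <- grab("source")
  ds$source <- if (is.null(src)) NA_character_ else as.character(src)

  date_bad <- if (is.null(date_raw)) rep(FALSE, n) else {
    !is.na(date_raw) & nzchar(trimws(as.character(date_raw))) & is.na(dates)
  }
  bad <- !is.finite(ds$value) | !is.finite(ds$age) | ds$age < 0 |
    is.na(ds$sex) | is.na(ds$analyte) | date_bad
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped while reading ", basename(path))
    ds <- ds[!bad, , drop = FALSE]
  }
  rownames(ds) <- NULL
  ds
}

#' Write laboratory records to CSV
#'
#' Inverse of \code{\link{read_records}} under the default schema: writing a
#' record set and reading it back reproduces every field.
#'
#' @param records Canonical record data.frame.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_records <- function(records, path) {
  out <- data.frame(
    subject_id = records$subject_id,
    date       = format(records$collection_date, "%Y-%m-%d"),
    age_years  = records$age,
    sex        = records$sex,
    analyte    = records$analyte,
    value      = records$value,
    units      = records$units,
    source     = records$source,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Build an age/sex stratum scheme
#'
#' A scheme is a set of half-open age bands \code{[age_lo, age_hi)} in decimal
#' years, optionally sex-specific, for one analyte. Strata must be pairwise
#' disjoint (overlap is a hard error).
#'
#' @param analyte Analyte name (recycled).
#' @param age_lo,age_hi Inclusive lower / exclusive upper age bounds, years.
#' @param sex "any", "male" or "female" (recycled).
#' @param label Optional human-readable labels; generated when NULL.
#' @return A data.frame of class \code{"stratum_scheme"}.
#' @examples
#' stratum_scheme("creatinine", c(1, 6, 12, 12), c(6, 12, 17, 17),
#'                c("any", "any", "male", "female"))
#' @export
stratum_scheme <- function(analyte, age_lo, age_hi, sex = "any", label = NULL) {
  k <- max(length(age_lo), length(age_hi), length(sex))
  sch <- data.frame(
    analyte = rep_len(as.character(analyte), k),
    age_lo  = rep_len(as.numeric(age_lo), k),
    age_hi  = rep_len(as.numeric(age_hi), k),
    sex     = rep_len(as.character(sex), k),
    stringsAsFactors = FALSE
  )
  if (any(sch$age_lo >= sch$age_hi)) stop("age_lo must be < age_hi in every stratum")
  if (!all(sch$sex %in% c("any", "male", "female"))) {
    stop("sex must be one of 'any', 'male', 'female'")
  }
  if (is.null(label)) {
    suffix <- c(any = "", male = " boys", female = " girls")[sch$sex]
    label <- sprintf("%g to <%g years%s", sch$age_lo, sch$age_hi, suffix)
  }
  sch$label <- rep_len(as.character(label), k)
  class(sch) <- c("stratum_scheme", "data.frame")
  validate_scheme(sch)
  sch
}

# hard error on overlapping strata (same analyte, compatible sex, age overlap)
validate_scheme <- function(scheme) {
  n <- nrow(scheme)
  if (n < 2L) return(invisible(scheme))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (scheme$analyte[i] != scheme$analyte[j]) next
      sex_overlap <- scheme$sex[i] == "any" || scheme$sex[j] == "any" ||
        scheme$sex[i] == scheme$sex[j]
      age_overlap <- scheme$age_lo[i] < scheme$age_hi[j] &&
        scheme$age_lo[j] < scheme$age_hi[i]
      if (sex_overlap && age_overlap) {
        stop("overlapping strata: '", scheme$label[i], "' and '",
             scheme$label[j], "'")
      }
    }
  }
  invisible(scheme)
}

#' Default published stratum schemes
#'
#' Creatinine: 1 to <6 years, 6 to <12 years, and 12 to <17 years split by
#' sex (four strata). Urea and uric acid: a single 1 to <17 years stratum.
#' These published partitions ship as defaults so the pipeline does not
#' depend on the decision-tree reproduction in
#' \code{\link{age_partition_tree}}.
#'
#' @param analyte "creatinine", "urea" or "uric_acid".
#' @return A \code{\link{stratum_scheme}}.
#' @export
default_strata <- function(analyte = c("creatinine", "urea", "uric_acid")) {
  analyte <- match.arg(analyte)
  if (analyte == "creatinine") {
    stratum_scheme("creatinine",
                   age_lo = c(1, 6, 12, 12), age_hi = c(6, 12, 17, 17),
                   sex = c("any", "any", "male", "female"))
  } else {
    stratum_scheme(analyte, age_lo = 1, age_hi = 17, sex = "any")
  }
}

#' Assign records to strata
#'
#' Maps each (age, sex) pair to the unique stratum with
#' \code{age_lo <= age < age_hi} and compatible sex, or NA when none matches.
#'
#' @param age Numeric vector of ages in years.
#' @param sex Character vector ("male"/"female"), recycled.
#' @param scheme A \code{\link{stratum_scheme}}.
#' @return Character vector of stratum labels (NA where unassigned).
#' @export
assign_stratum <- function(age, sex, scheme) {
  validate_scheme(scheme)
  sex <- rep_len(as.character(sex), length(age))
  idx <- rep(NA_integer_, length(age))
  for (i in seq_len(nrow(scheme))) {
    hit <- age >= scheme$age_lo[i] & age < scheme$age_hi[i] &
      (scheme$sex[i] == "any" | sex == scheme$sex[i])
    hit[is.na(hit)] <- FALSE
    if (any(hit & !is.na(idx))) stop("overlapping strata in scheme")
    idx[hit] <- i
  }
  scheme$label[idx]
}
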