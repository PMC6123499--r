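# CSV writers format doubles with %.17g so that numeric round trips are
# exact; readers validate cell types and name the offending cell.

.format_for_csv <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

.write_csv <- function(df, path) {
  utils::write.csv(.format_for_csv(df), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# coerce a column to numeric/integer/logical, erroring with row context on
# any cell that does not parse
.coerce_col <- function(x, type, col, file) {
  if (type == "character") return(as.character(x))
  suppress <- function(e) e
  conv <- switch(type,
                 numeric = suppressWarnings(as.numeric(x)),
                 integer = suppressWarnings(as.integer(as.numeric(x))),
                 logical = as.logical(x))
  bad <- which(is.na(conv) & !is.na(x) & x != "NA")
  if (length(bad)) {
    .stopf("%s: column '%s' row %d: cannot parse '%s' as %s",
           basename(file), col, bad[1], x[bad[1]], type)
  }
  conv
}

# expected column types of an individual-state table
.state_col_types <- function() {
  types <- c(id = "character", sex = "character", age_months = "integer",
             education = "character", occupation = "character",
             smoking = "character", bmi_class = "character",
             physical_activity = "character",
             vision_impairment = "character",
             hearing_impairment = "character", mmse = "integer",
             physical_dependency = "character", residence = "character",
             dementia = "logical", alive = "logical", weight = "numeric")
  dis <- rep("logical", length(disease_names()))
  names(dis) <- disease_names()
  c(types, dis)
}

.read_validated <- function(path, types, required = names(types)) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    .stopf("%s: missing column(s): %s", basename(path),
           paste(miss, collapse = ", "))
  }
  for (nm in intersect(names(types), names(raw))) {
    raw[[nm]] <- .coerce_col(raw[[nm]], types[[nm]], nm, path)
  }
  raw
}

#' Write / read a two-wave study extract as CSV
#'
#' One file with a `wave` column (1 = baseline, 2 = follow-up) and a
#' `study` column; attrited individuals simply have no wave-2 row.
#'
#' @param extract A `study_extract`.
#' @param path CSV path.
#' @return `read_study_extract` returns the `study_extract`.
#' @export
write_study_extract <- function(extract, path) {
  b <- extract$baseline
  b$wave <- 1L
  f <- extract$followup
  if (nrow(f)) f$wave <- 2L else f$wave <- integer(0)
  both <- rbind(b, f)
  both$study <- extract$study_label
  .write_csv(both, path)
}

#' @rdname write_study_extract
#' @export
read_study_extract <- function(path) {
  types <- c(.state_col_types(), wave = "integer", study = "character")
  d <- .read_validated(path, types)
  lab <- unique(d$study)
  if (length(lab) != 1) .stopf("%s: expected one study label", basename(path))
  keep <- setdiff(names(d), c("wave", "study"))
  structure(list(study_label = lab,
                 baseline = d[d$wave == 1L, keep],
                 followup = d[d$wave == 2L, keep],
                 seed = NA_integer_),
            class = "study_extract")
}

#' Write / read an individual-state population table as CSV
#' @param pop Population data.frame.
#' @param path CSV path.
#' @param scaling_factor Population multiplier restored on read.
#' @return `read_population` returns the data.frame with the
#'   `scaling_factor` attribute set.
#' @export
write_population <- function(pop, path) .write_csv(pop, path)

#' @rdname write_population
#' @export
read_population <- function(path, scaling_factor = 1) {
  pop <- .read_validated(path, .state_col_types())
  attr(pop, "scaling_factor") <- scaling_factor
  pop
}

#' Write / read a lifetable as CSV
#' @param lt A `lifetable`.
#' @param path CSV path.
#' @return `read_lifetable` returns the `lifetable`.
#' @export
write_lifetable <- function(lt, path) .write_csv(as.data.frame(lt), path)

#' @rdname write_lifetable
#' @export
read_lifetable <- function(path) {
  types <- c(sex = "character", age = "integer", survival = "numeric",
             l_x = "numeric", L_x = "numeric")
  lt <- .read_validated(path, types)
  if (any(lt$survival <= 0 | lt$survival > 1)) {
    .stopf("%s: survival probabilities must be in (0, 1]", basename(path))
  }
  structure(lt, class = c("lifetable", "data.frame"))
}

#' Write / read a dementia allocation table as CSV
#' @param dt A `dementia_table`.
#' @param path CSV path.
#' @return `read_dementia_table` returns the `dementia_table`.
#' @export
write_dementia_table <- function(dt, path) .write_csv(as.data.frame(dt), path)

#' @rdname write_dementia_table
#' @export
read_dementia_table <- function(path) {
  types <- c(age_group = "character", cognition = "character",
             residence = "character", prob = "numeric")
  dt <- .read_validated(path, types)
  if (any(dt$prob < 0 | dt$prob > 1)) {
    .stopf("%s: probabilities must be in [0, 1]", basename(path))
  }
  structure(dt, class = c("dementia_table", "data.frame"))
}

#' Read a care-need item table
#'
#' Delimited text with one column per indicator, values 0/1/NA, plus
#' optional `mmse` and `dialect` columns.
#'
#' @param path CSV path.
#' @param dialect Dialect to assume when the file has no `dialect` column.
#' @return Data.frame with logical indicator columns, ready for
#'   [classify_interval_of_need()] row by row.
#' @export
read_care_need_items <- function(path, dialect = "study_b") {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (!"dialect" %in% names(raw)) raw$dialect <- dialect
  all_items <- union(care_need_items("study_a"), care_need_items("study_b"))
  for (nm in intersect(names(raw), all_items)) {
    v <- .coerce_col(raw[[nm]], "integer", nm, path)
    if (any(!v %in% c(0L, 1L) & !is.na(v))) {
      .stopf("%s: column '%s' must be 0/1/NA", basename(path), nm)
    }
    raw[[nm]] <- as.logical(v)
  }
  if ("mmse" %in% names(raw)) {
    raw$mmse <- .coerce_col(raw$mmse, "integer", "mmse", path)
  }
  raw
}
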