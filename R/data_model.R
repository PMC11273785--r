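# Region-level resource tables: schema, CSV I/O, validation, bundled dataset.

# Optional staff-structure columns recognised by the schema.
.age_cols <- c("age_le35", "age_36_45", "age_46_55", "age_ge56")
.edu_cols <- c("edu_junior_college", "edu_bachelor_plus")
.core_cols <- c("name", "region", "area", "population_65plus")

#' Construct a province table
#'
#' A `province_table` is a data frame with one row per administrative unit and
#' columns `name`, `region`, `area` (geographical area in units of
#' 10,000 km^2), `population_65plus` (persons aged 65 and above) and one or
#' more non-negative integer resource-count columns. Optional staff-structure
#' columns (`age_le35`, `age_36_45`, `age_46_55`, `age_ge56`,
#' `edu_junior_college`, `edu_bachelor_plus`) carry employee age and education
#' counts. Column totals over all units (the denominators of the agglomeration
#' and Gini statistics) are attached as the `totals` attribute and can be read
#' with [province_totals()].
#'
#' The constructor checks structure only (required columns present, resource
#' columns known); value-level invariants are reported by
#' [validate_provinces()], so invalid tables can be built and then diagnosed.
#'
#' @param data a data frame with the columns described above.
#' @param resources character vector of resource column names. Defaults to all
#'   columns other than the core and staff-structure columns.
#' @return an object of class `province_table`.
#' @seealso [load_provinces()], [builtin_china_2020()], [validate_provinces()]
#' @export
#' @examples
#' tab <- province_table(data.frame(
#'   name = c("A", "B"), region = "r", area = c(1, 2),
#'   population_65plus = c(1000L, 3000L), beds = c(50L, 60L)))
#' province_totals(tab)
province_table <- function(data, resources = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  missing_core <- setdiff(.core_cols, names(data))
  if (length(missing_core) > 0L) {
    stop("missing required column(s): ", paste(missing_core, collapse = ", "))
  }
  if (is.null(resources)) {
    resources <- setdiff(names(data), c(.core_cols, .age_cols, .edu_cols))
  }
  if (length(resources) == 0L) {
    stop("table has no resource columns")
  }
  missing_res <- setdiff(resources, names(data))
  if (length(missing_res) > 0L) {
    stop("missing resource column(s): ", paste(missing_res, collapse = ", "))
  }
  data$name <- as.character(data$name)
  data$region <- as.character(data$region)
  rownames(data) <- NULL
  structure(data,
            resources = resources,
            totals = .compute_totals(data, resources),
            class = c("province_table", "data.frame"))
}

.compute_totals <- function(data, resources) {
  tot <- c(list(area = sum(data$area),
                population_65plus = sum(data$population_65plus)),
           lapply(data[resources], sum))
  tot
}

#' Column totals of a province table
#'
#' @param table a [province_table()].
#' @return named list with `area`, `population_65plus` and one entry per
#'   resource, each the sum over all rows.
#' @export
province_totals <- function(table) {
  stopifnot(inherits(table, "province_table"))
  .compute_totals(table, attr(table, "resources"))
}

#' Resource column names of a province table
#'
#' @param table a [province_table()].
#' @return character vector of resource names.
#' @export
resource_names <- function(table) {
  stopifnot(inherits(table, "province_table"))
  attr(table, "resources")
}

#' Read a province table from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row, decimal points and
#' no thousands separators, with columns
#' `name,region,area,population_65plus,<resource...>` and optionally the six
#' staff-structure columns. The file is validated on load; value-level
#' violations (non-positive area or population, negative or non-integer
#' resource counts, duplicate names, fewer than two rows) raise an error
#' carrying the full [validate_provinces()] report in its `report` field.
#'
#' @param path path to a CSV file.
#' @param resources optional character vector naming the resource columns to
#'   load; defaults to every non-core, non-staff column in the header.
#' @return a [province_table()].
#' @export
load_provinces <- function(path, resources = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  tab <- province_table(raw, resources = resources)
  report <- validate_provinces(tab)
  if (nrow(report$errors) > 0L) {
    stop(.validation_condition(report, paste0("invalid province table: ", path)))
  }
  attr(tab, "source") <- path
  tab
}

#' Write a province table to CSV
#'
#' Writes the data-model CSV dialect (UTF-8, comma-separated, header row,
#' decimal point, no thousands separators, no row names), preserving row order
#' and full numeric precision so that [load_provinces()] round-trips the file.
#'
#' @param table a [province_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_provinces <- function(table, path) {
  stopifnot(inherits(table, "province_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The 31-province Chinese older-adult care resource table, 2020
#'
#' Returns the bundled region-level dataset of older-adult care resources in
#' the 31 provinces, autonomous regions and municipalities of mainland China
#' at the end of 2020: counts of care institutions, employees, professional
#' (technical) staff and beds, geographical area (10,000 km^2), population
#' aged 65 and above, the employee age structure in four bins and the employee
#' education structure (junior college; bachelor or above). Each unit carries
#' an `eastern` / `middle` / `western` super-region label following the China
#' Health Statistics Yearbook partition.
#'
#' @return a [province_table()] with 31 rows and resource columns
#'   `institutions`, `employees`, `professionals`, `beds`.
#' @export
#' @examples
#' tab <- builtin_china_2020()
#' province_totals(tab)$institutions  # 38158
builtin_china_2020 <- function() {
  path <- system.file("extdata", "china_older_adult_resources_2020.csv",
                      package = "equigeo", mustWork = TRUE)
  load_provinces(path)
}

#' Subset a province table to one super-region
#'
#' Totals are recomputed over the subset, so downstream agglomeration and Gini
#' statistics use the region's own denominators — the construction needed for
#' within-region equity tables.
#'
#' @param table a [province_table()].
#' @param region a region label present in the table.
#' @return a [province_table()] of the matching rows.
#' @export
region_subset <- function(table, region) {
  stopifnot(inherits(table, "province_table"))
  available <- unique(table$region)
  if (!region %in% available) {
    stop("unknown region ", sQuote(region), "; available: ",
         paste(available, collapse = ", "))
  }
  keep <- table$region == region
  province_table(as.data.frame(table)[keep, , drop = FALSE],
                 resources = attr(table, "resources"))
}

#' Validate a province table
#'
#' Checks every schema invariant and returns all violations at once rather
#' than failing on the first. Errors: non-positive or non-numeric area or
#' population, negative or non-integer resource counts, missing values,
#' duplicate unit names, fewer than two rows (the Gini coefficient is
#' undefined on a single unit). Warnings: staff age-bin counts present but not
#' summing to the employee total, or education counts exceeding it — tolerated
#' because user data may carry partial staff breakdowns.
#'
#' @param table a [province_table()].
#' @return a `validation_report`: list with data frames `errors` and
#'   `warnings`, each with columns `unit`, `field`, `message`.
#' @export
validate_provinces <- function(table) {
  stopifnot(inherits(table, "province_table"))
  errs <- list()
  warns <- list()
  note <- function(store, unit, field, message) {
    c(store, list(data.frame(unit = unit, field = field, message = message)))
  }

  if (nrow(table) < 2L) {
    errs <- note(errs, "(table)", "records",
                 "at least 2 units required (Gini undefined on a single unit)")
  }
  dup <- unique(table$name[duplicated(table$name)])
  for (d in dup) {
    errs <- note(errs, d, "name", "duplicate unit name")
  }

  check_num <- function(col, pred, msg) {
    v <- table[[col]]
    if (!is.numeric(v)) {
      errs <<- note(errs, "(table)", col, "column is not numeric")
      return(invisible())
    }
    bad <- which(is.na(v) | !pred(v))
    for (i in bad) errs <<- note(errs, table$name[i], col, msg)
  }
  check_num("area", function(v) v > 0, "area must be positive")
  check_num("population_65plus", function(v) v > 0 & v == round(v),
            "population must be a positive integer")
  for (rc in attr(table, "resources")) {
    check_num(rc, function(v) v >= 0 & v == round(v),
              "resource count must be a non-negative integer")
  }

  if (all(.age_cols %in% names(table)) && "employees" %in% names(table)) {
    binsum <- rowSums(as.data.frame(table)[.age_cols])
    bad <- which(!is.na(binsum) & binsum != table$employees)
    for (i in bad) {
      warns <- note(warns, table$name[i], "staff_age_counts",
                    sprintf("age bins sum to %d but employees = %d",
                            binsum[i], table$employees[i]))
    }
  }
  if (all(.edu_cols %in% names(table)) && "employees" %in% names(table)) {
    edusum <- rowSums(as.data.frame(table)[.edu_cols])
    bad <- which(!is.na(edusum) & edusum > table$employees)
    for (i in bad) {
      warns <- note(warns, table$name[i], "staff_edu_counts",
                    "education counts exceed employee total")
    }
  }

  empty <- data.frame(unit = character(), field = character(),
                      message = character())
  structure(list(errors = if (length(errs)) do.call(rbind, errs) else empty,
                 warnings = if (length(warns)) do.call(rbind, warns) else empty),
            class = "validation_report")
}

.validation_condition <- function(report, message) {
  lines <- sprintf("  %s / %s: %s", report$errors$unit, report$errors$field,
                   report$errors$message)
  structure(
    class = c("equigeo_validation_error", "error", "condition"),
    list(message = paste(c(message, lines), collapse = "\n"),
         call = sys.call(-1), report = report))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation report: %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) {
    cat("errors:\n")
    print(x$errors, row.names = FALSE)
  }
  if (nrow(x$warnings)) {
    cat("warnings:\n")
    print(x$warnings, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.province_table <- function(x, ...) {
  tot <- province_totals(x)
  cat(sprintf("province_table: %d units, %d region label(s)\n",
              nrow(x), length(unique(x$region))))
  cat(sprintf("  area total %.2f (10,000 km^2), population 65+ total %s\n",
              tot$area, format(tot$population_65plus, big.mark = ",")))
  for (rc in attr(x, "resources")) {
    cat(sprintf("  %s: total %s\n", rc, format(tot[[rc]], big.mark = ",")))
  }
  NextMethod()
}

# data.frame subsetting drops our attributes; rebuild when the result still
# looks like a province table, otherwise return a plain data frame.
#' @export
`[.province_table` <- function(x, ...) {
  out <- NextMethod()
  res <- attr(x, "resources")
  if (is.data.frame(out) && all(.core_cols %in% names(out)) &&
      all(res %in% names(out))) {
    province_table(out, resources = res)
  } else {
    out
  }
}
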