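# Full-analysis orchestration: rates, agglomeration, national and regional
# Gini tables, staff structure, Lorenz exports.

#' Run the full equity analysis on a province table
#'
#' Computes, per resource: per-1,000 rates for every unit plus the overall
#' total; the agglomeration table (HRAD, PAD, HRAD/PAD with classifications);
#' national Gini coefficients for each requested dimension; within-region Gini
#' coefficients computed on each regional subset with the subset's own totals;
#' staff-structure percentages where staff columns are present; and the Lorenz
#' curve behind every national Gini. The computation is deterministic.
#'
#' @param table a [province_table()]; aborted with the attached
#'   [validate_provinces()] report if it has validation errors.
#' @param resources resource columns to analyse (default: all in the table).
#' @param dimensions subset of `c("area", "population")`.
#' @param regions region labels for the regional Gini table; defaults to every
#'   label in the table with at least two units, and is skipped if fewer than
#'   two labels qualify.
#' @param verbose print one summary line per table computed.
#' @return a `report_bundle`: list with elements `rates_table`,
#'   `agglomeration_table`, `gini_table`, `regional_gini_table`,
#'   `staff_table`, `lorenz_curves` and `run_metadata`.
#' @export
#' @examples
#' bundle <- run_analysis(builtin_china_2020())
#' subset(bundle$gini_table, resource == "professionals")
run_analysis <- function(table, resources = NULL,
                         dimensions = c("area", "population"),
                         regions = NULL, verbose = FALSE) {
  stopifnot(inherits(table, "province_table"))
  dimensions <- match.arg(dimensions, several.ok = TRUE)
  if (is.null(resources)) resources <- attr(table, "resources")
  report <- validate_provinces(table)
  if (nrow(report$errors) > 0L) {
    stop(.validation_condition(report, "run_analysis: table failed validation"))
  }
  say <- function(...) if (verbose) message(sprintf(...))
  tot <- province_totals(table)

  rates <- do.call(rbind, lapply(resources, function(rc) {
    data.frame(unit = c(table$name, "(total)"), resource = rc,
               per_1000 = rate_per_thousand(c(table[[rc]], tot[[rc]]),
                                            c(table$population_65plus,
                                              tot$population_65plus)))
  }))
  rownames(rates) <- NULL
  say("rates_table: %d rows, national range %.2f-%.2f per 1,000",
      nrow(rates), min(rates$per_1000), max(rates$per_1000))

  agg <- agglomeration(table, resources)
  say("agglomeration_table: %d rows, HRAD max %.3f (%s)", nrow(agg),
      max(agg$hrad), agg$unit[which.max(agg$hrad)])

  grid <- expand.grid(resource = resources, dimension = dimensions,
                      stringsAsFactors = FALSE)
  attr(grid, "out.attrs") <- NULL
  curves <- vector("list", nrow(grid))
  gini_tab <- grid
  gini_tab$gini <- NA_real_
  gini_tab$band <- NA_character_
  for (i in seq_len(nrow(grid))) {
    res <- gini(table, grid$resource[i], grid$dimension[i])
    gini_tab$gini[i] <- res$gini
    gini_tab$band[i] <- res$band
    curves[[i]] <- res$curve
  }
  names(curves) <- paste(grid$resource, grid$dimension, sep = ".")
  say("gini_table: %d cells, range %.3f-%.3f", nrow(gini_tab),
      min(gini_tab$gini), max(gini_tab$gini))

  if (is.null(regions)) {
    counts <- table(table$region)
    regions <- names(counts)[counts >= 2L]
    if (length(regions) < 2L) regions <- character()
  }
  regional <- NULL
  if (length(regions) > 0L) {
    regional <- do.call(rbind, lapply(regions, function(reg) {
      sub <- region_subset(table, reg)
      out <- expand.grid(resource = resources, dimension = dimensions,
                         stringsAsFactors = FALSE)
      attr(out, "out.attrs") <- NULL
      out$region <- reg
      for (i in seq_len(nrow(out))) {
        r <- gini(sub, out$resource[i], out$dimension[i])
        out$gini[i] <- r$gini
        out$band[i] <- r$band
      }
      out[c("region", "resource", "dimension", "gini", "band")]
    }))
    rownames(regional) <- NULL
    say("regional_gini_table: %d cells over %d regions", nrow(regional),
        length(regions))
  }

  staff <- staff_proportions(table)
  if (!any(staff$available)) staff <- NULL else
    say("staff_table: %d units with staff structure", sum(staff$available))

  structure(list(
    rates_table = rates,
    agglomeration_table = agg,
    gini_table = gini_tab,
    regional_gini_table = regional,
    staff_table = staff,
    lorenz_curves = curves,
    run_metadata = list(
      source = attr(table, "source") %||% "(in-memory table)",
      n_units = nrow(table),
      resources = resources,
      dimensions = dimensions,
      regions = regions,
      package_version = as.character(utils::packageVersion("equigeo")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "report_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.report_bundle <- function(x, ...) {
  cat("equity report bundle\n")
  cat(sprintf("  source: %s (%d units)\n", x$run_metadata$source,
              x$run_metadata$n_units))
  g <- x$gini_table
  g$gini <- .round_half_up(g$gini, 3)
  cat("  Gini coefficients:\n")
  print(g, row.names = FALSE)
  if (!is.null(x$regional_gini_table)) {
    cat(sprintf("  regional Gini cells: %d\n", nrow(x$regional_gini_table)))
  }
  invisible(x)
}

# round-half-up at the given number of decimals (base round() is half-even);
# used for display so internals keep full precision
.round_half_up <- function(x, digits) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Export a report bundle to disk
#'
#' Writes one CSV per table, one CSV per Lorenz curve
#' (`lorenz_<resource>_<dimension>.csv`, columns `x,y,unit`), and/or a JSON
#' mirror `bundle.json` of all table content. The run metadata — the only
#' non-deterministic content (timestamp) — goes to a separate
#' `run_metadata.json`, so re-running the same input yields byte-identical
#' table files.
#'
#' @param bundle a `report_bundle` from [run_analysis()].
#' @param out_dir output directory, created if needed.
#' @param formats non-empty subset of `c("csv", "json")`.
#' @return character vector of the files written.
#' @export
export_bundle <- function(bundle, out_dir, formats = c("csv", "json")) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (length(formats) == 0L) stop("formats must be non-empty")
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  tables <- list(rates = bundle$rates_table,
                 agglomeration = bundle$agglomeration_table,
                 gini = bundle$gini_table,
                 gini_regional = bundle$regional_gini_table,
                 staff = bundle$staff_table)
  tables <- Filter(Negate(is.null), tables)

  if ("csv" %in% formats) {
    for (nm in names(tables)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(tables[[nm]], f, row.names = FALSE,
                       fileEncoding = "UTF-8")
      written <- c(written, f)
    }
    for (nm in names(bundle$lorenz_curves)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      f <- file.path(out_dir,
                     sprintf("lorenz_%s_%s.csv", parts[1], parts[2]))
      write_lorenz(bundle$lorenz_curves[[nm]], f)
      written <- c(written, f)
    }
  }
  if ("json" %in% formats) {
    payload <- c(tables,
                 list(lorenz = lapply(bundle$lorenz_curves, function(cu)
                   as.data.frame(cu)[c("x", "y", "unit")])))
    f <- file.path(out_dir, "bundle.json")
    jsonlite::write_json(payload, f, dataframe = "columns", digits = NA,
                         pretty = TRUE)
    written <- c(written, f)
  }
  f <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(bundle$run_metadata, f, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, f)
  written
}

#' Re-read an exported JSON bundle
#'
#' Reads `bundle.json` written by [export_bundle()] back into a list of data
#' frames (tables plus Lorenz point sets), for round-trip checks and
#' downstream consumption.
#'
#' @param path path to a `bundle.json` file or to the directory holding it.
#' @return named list of data frames.
#' @export
import_bundle <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "bundle.json")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw[names(raw) != "lorenz"] <- lapply(raw[names(raw) != "lorenz"],
                                        as.data.frame)
  if (!is.null(raw$lorenz)) raw$lorenz <- lapply(raw$lorenz, as.data.frame)
  raw
}
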