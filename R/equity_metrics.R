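# Equity statistics: per-1,000 rates, agglomeration degrees, Lorenz curves,
# trapezoid Gini, pairwise Gini oracle, staff-structure proportions.

#' Resources per 1,000 persons
#'
#' @param count non-negative resource count.
#' @param population positive population denominator.
#' @return `1000 * count / population`, vectorised.
#' @export
rate_per_thousand <- function(count, population) {
  if (any(!is.finite(population) | population <= 0)) {
    stop("population must be positive")
  }
  if (any(!is.finite(count) | count < 0)) stop("count must be non-negative")
  1000 * count / population
}

#' Agglomeration degree of a resource over geographical area (HRAD)
#'
#' `HRAD_i = (HR_i / A_i) / (HR_n / A_n)`: a unit's resource density per unit
#' area relative to the whole territory's density. A value of 1 means the unit
#' holds resources exactly in proportion to its share of the land area.
#'
#' @param resource_i resource count of the unit.
#' @param area_i area of the unit (same units as `area_total`).
#' @param resource_total resource count over the whole territory.
#' @param area_total total area.
#' @return HRAD, vectorised over the unit arguments.
#' @export
hrad <- function(resource_i, area_i, resource_total, area_total) {
  if (any(area_i <= 0) || area_total <= 0) stop("areas must be positive")
  if (resource_total <= 0) stop("total resource count must be positive")
  if (any(resource_i < 0)) stop("resource counts must be non-negative")
  (resource_i / area_i) / (resource_total / area_total)
}

#' Agglomeration degree of the target population over geographical area (PAD)
#'
#' Same construction as [hrad()] with the target population (here persons aged
#' 65 and above) in place of the resource.
#'
#' @param pop_i population of the unit.
#' @param area_i area of the unit.
#' @param pop_total total population.
#' @param area_total total area.
#' @return PAD, vectorised over the unit arguments.
#' @export
pad <- function(pop_i, area_i, pop_total, area_total) {
  if (any(pop_i <= 0) || pop_total <= 0) stop("populations must be positive")
  hrad(pop_i, area_i, pop_total, area_total)
}

#' Population-dimension agglomeration degree (HRAD/PAD)
#'
#' `HRAD_i / PAD_i = (HR_i / P_i) / (HR_n / P_n)`: a unit's per-capita resource
#' rate relative to the territory-wide per-capita rate. Computed directly from
#' populations (the areas cancel algebraically) to avoid needless rounding.
#'
#' @param resource_i resource count of the unit.
#' @param pop_i population of the unit.
#' @param resource_total total resource count.
#' @param pop_total total population.
#' @return HRAD/PAD, vectorised over the unit arguments.
#' @export
hrad_over_pad <- function(resource_i, pop_i, resource_total, pop_total) {
  if (any(pop_i <= 0) || pop_total <= 0) stop("populations must be positive")
  if (resource_total <= 0) stop("total resource count must be positive")
  if (any(resource_i < 0)) stop("resource counts must be non-negative")
  (resource_i / pop_i) / (resource_total / pop_total)
}

#' Classify an agglomeration degree
#'
#' Values above 1 indicate relative over-allocation, below 1 relative
#' under-allocation, and exactly 1 (within `tol`) absolute equity. Exact
#' equality is measure-zero on real data, so a small tolerance stands in for
#' the textbook `= 1` criterion.
#'
#' @param value non-negative agglomeration degree (HRAD or HRAD/PAD).
#' @param tol half-width of the band treated as equal to 1.
#' @return character vector in `{"over_allocated", "absolute_equity",
#'   "under_allocated"}`.
#' @export
classify_agglomeration <- function(value, tol = 1e-9) {
  if (any(!is.finite(value) | value < 0)) {
    stop("agglomeration degree must be non-negative")
  }
  ifelse(abs(value - 1) <= tol, "absolute_equity",
         ifelse(value > 1, "over_allocated", "under_allocated"))
}

#' Per-unit agglomeration table
#'
#' Computes HRAD, PAD and HRAD/PAD for every unit and resource of a table,
#' with both allocation classifications.
#'
#' @param table a [province_table()].
#' @param resources resource columns to analyse (default: all).
#' @return data frame with columns `unit`, `resource`, `hrad`, `pad`,
#'   `hrad_over_pad`, `area_class`, `population_class`.
#' @export
#' @examples
#' agg <- agglomeration(builtin_china_2020())
#' subset(agg, unit == "Shanghai" & resource == "institutions")
agglomeration <- function(table, resources = NULL) {
  stopifnot(inherits(table, "province_table"))
  if (is.null(resources)) resources <- attr(table, "resources")
  tot <- province_totals(table)
  out <- lapply(resources, function(rc) {
    h <- hrad(table[[rc]], table$area, tot[[rc]], tot$area)
    p <- pad(table$population_65plus, table$area, tot$population_65plus,
             tot$area)
    hp <- hrad_over_pad(table[[rc]], table$population_65plus, tot[[rc]],
                        tot$population_65plus)
    data.frame(unit = table$name, resource = rc,
               hrad = h, pad = p, hrad_over_pad = hp,
               area_class = classify_agglomeration(h),
               population_class = classify_agglomeration(hp))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Lorenz curve of a resource over area or population
#'
#' Units are ranked ascending by resource density — count per unit area for
#' the area dimension, count per person for the population dimension — and the
#' cumulative share of the denominator (x) is plotted against the cumulative
#' share of the resource (y), starting from (0, 0). With this ordering the
#' curve lies on or below the equality diagonal. Density ties are broken by
#' unit name for determinism; tie order does not affect the Gini coefficient.
#'
#' @param table a [province_table()].
#' @param resource name of a resource column.
#' @param dimension `"area"` or `"population"`.
#' @return a `lorenz_curve`: data frame with columns `x`, `y`, `unit` (the
#'   unit whose step ends at that point; empty for the origin), with
#'   attributes `dimension` and `resource`.
#' @export
#' @examples
#' lc <- lorenz_curve(builtin_china_2020(), "beds", "population")
#' head(lc)
lorenz_curve <- function(table, resource, dimension = c("area", "population")) {
  stopifnot(inherits(table, "province_table"))
  dimension <- match.arg(dimension)
  if (!resource %in% attr(table, "resources")) {
    stop("unknown resource ", sQuote(resource), "; available: ",
         paste(attr(table, "resources"), collapse = ", "))
  }
  num <- table[[resource]]
  den <- if (dimension == "area") table$area else table$population_65plus
  if (sum(num) <= 0) stop("resource total must be positive")
  o <- order(num / den, table$name)
  x <- cumsum(den[o]) / sum(den)
  y <- cumsum(num[o]) / sum(num)
  # pin the endpoint exactly; cumulative rounding can leave 1 - eps
  x[length(x)] <- 1
  y[length(y)] <- 1
  structure(data.frame(x = c(0, x), y = c(0, y),
                       unit = c("", table$name[o])),
            dimension = dimension, resource = resource,
            class = c("lorenz_curve", "data.frame"))
}

.check_lorenz <- function(curve) {
  if (!is.data.frame(curve) || !all(c("x", "y") %in% names(curve))) {
    stop("not a Lorenz curve: need columns x and y")
  }
  x <- curve$x
  y <- curve$y
  n <- length(x)
  tol <- 1e-8
  if (abs(x[1]) > tol || abs(y[1]) > tol ||
      abs(x[n] - 1) > tol || abs(y[n] - 1) > tol) {
    stop("Lorenz curve must run from (0,0) to (1,1)")
  }
  if (any(diff(x) <= 0)) stop("Lorenz curve x must be strictly increasing")
  if (any(diff(y) < -tol)) stop("Lorenz curve y must be non-decreasing")
  invisible(curve)
}

#' Gini coefficient of a Lorenz curve by the trapezoid rule
#'
#' `G = 1 - sum_i (X_i - X_{i-1}) (Y_i + Y_{i-1})` over consecutive curve
#' points with `(X_0, Y_0) = (0, 0)`: one minus twice the trapezoid area under
#' the curve, i.e. twice the area between the curve and the equality diagonal.
#' The value is banded on the conventional five-level equity scale (see
#' [classify_gini()]).
#'
#' @param curve a [lorenz_curve()], or any data frame with monotone `x`, `y`
#'   columns from (0,0) to (1,1).
#' @return a `gini_result`: list with `gini`, `band`, `dimension`, `resource`
#'   and the `curve` it was computed from.
#' @export
#' @examples
#' g <- gini_trapezoid(lorenz_curve(builtin_china_2020(), "institutions", "area"))
#' g$gini  # 0.685
gini_trapezoid <- function(curve) {
  .check_lorenz(curve)
  x <- curve$x
  y <- curve$y
  n <- length(x)
  g <- 1 - sum((x[-1] - x[-n]) * (y[-1] + y[-n]))
  # float drift on exactly-equal allocations can leave a tiny negative
  if (g < 0 && g > -1e-9) g <- 0
  structure(list(gini = g,
                 band = classify_gini(g),
                 dimension = attr(curve, "dimension"),
                 resource = attr(curve, "resource"),
                 curve = curve),
            class = "gini_result")
}

#' @export
print.gini_result <- function(x, ...) {
  cat(sprintf("Gini %.3f (%s)%s%s\n", x$gini, x$band,
              if (is.null(x$resource)) "" else paste0(" — ", x$resource),
              if (is.null(x$dimension)) "" else paste0(" by ", x$dimension)))
  invisible(x)
}

#' Gini coefficient of a resource over area or population
#'
#' Convenience wrapper: builds the ascending-density [lorenz_curve()] and
#' applies [gini_trapezoid()].
#'
#' @inheritParams lorenz_curve
#' @return a `gini_result`, see [gini_trapezoid()].
#' @export
gini <- function(table, resource, dimension = c("area", "population")) {
  gini_trapezoid(lorenz_curve(table, resource, dimension))
}

#' Weighted Gini via pairwise mean absolute differences
#'
#' Independent formulation of the grouped weighted Gini coefficient:
#' `G = sum_ij w_i w_j |r_i - r_j| / (2 W^2 rbar)` with rates
#' `r_i = value_i / weight_i`, total weight `W` and weighted mean rate
#' `rbar = sum(values) / W`. Algebraically identical to the trapezoid rule on
#' the ascending-density Lorenz curve, but shares no code with it (no sorting,
#' no cumulative sums), so it serves as a cross-check oracle.
#'
#' @param values per-unit resource counts (numerators).
#' @param weights per-unit denominator weights (areas or populations),
#'   positive.
#' @return the Gini coefficient as a bare number.
#' @export
gini_pairwise_oracle <- function(values, weights) {
  if (length(values) != length(weights)) stop("lengths differ")
  if (any(weights <= 0)) stop("weights must be positive")
  if (any(values < 0)) stop("values must be non-negative")
  if (sum(values) <= 0) stop("Gini undefined: all values zero")
  r <- values / weights
  W <- sum(weights)
  rbar <- sum(values) / W
  sum(outer(weights, weights) * abs(outer(r, r, "-"))) / (2 * W^2 * rbar)
}

#' Classify a Gini coefficient on the five-band equity scale
#'
#' Below 0.2: absolute equity (very good state); 0.2–0.3: equity (good);
#' 0.3–0.4: basic equity (normal); 0.4–0.5: inequity (alert); 0.5 and above:
#' high inequity (dangerous state).
#'
#' @param g Gini coefficient in `[0, 1)`.
#' @return character vector in `{"absolute_equity", "equity", "basic_equity",
#'   "inequity", "high_inequity"}`.
#' @export
classify_gini <- function(g) {
  if (any(!is.finite(g) | g < 0 | g >= 1)) stop("Gini must lie in [0, 1)")
  cut(g, breaks = c(-Inf, 0.2, 0.3, 0.4, 0.5, Inf), right = FALSE,
      labels = c("absolute_equity", "equity", "basic_equity", "inequity",
                 "high_inequity")) |> as.character()
}

#' Staff age and education structure as percentages
#'
#' For each unit with staff-structure columns, expresses the four employee age
#' bins (at most 35; 36–45; 46–55; 56 and over) and the two education bins
#' (junior college; bachelor or above) as percentages of the employee total.
#' Units without staff columns, or with zero employees, get `NA` percentages
#' and `available = FALSE` rather than an error.
#'
#' @param table a [province_table()] (needs an `employees` resource column for
#'   the denominators).
#' @return data frame with columns `unit`, `available` and one percentage
#'   column per bin (full precision; round for display).
#' @export
#' @examples
#' sp <- staff_proportions(builtin_china_2020())
#' round(sp[sp$unit == "Tibet", "age_le35_pct"], 2)  # 68.13
staff_proportions <- function(table) {
  stopifnot(inherits(table, "province_table"))
  bins <- c(.age_cols, .edu_cols)
  have_cols <- bins[bins %in% names(table)]
  out <- data.frame(unit = table$name, available = FALSE)
  for (b in bins) out[[paste0(b, "_pct")]] <- NA_real_
  if (length(have_cols) == 0L || !"employees" %in% names(table)) return(out)
  ok <- table$employees > 0 &
    rowSums(is.na(as.data.frame(table)[, have_cols, drop = FALSE])) == 0
  out$available <- ok
  for (b in have_cols) {
    out[[paste0(b, "_pct")]][ok] <- 100 * table[[b]][ok] / table$employees[ok]
  }
  out
}

#' Write a Lorenz curve to CSV
#'
#' Columns `x,y,unit`; the first row is the origin with an empty unit field.
#'
#' @param curve a [lorenz_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lorenz <- function(curve, path) {
  .check_lorenz(curve)
  utils::write.csv(as.data.frame(curve)[c("x", "y", "unit")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Plot a Lorenz curve against the equality diagonal
#'
#' @param x a [lorenz_curve()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.lorenz_curve <- function(x, ...) {
  lab <- sprintf("%s by %s", attr(x, "resource"), attr(x, "dimension"))
  graphics::plot(x$x, x$y, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = sprintf("cumulative share of %s", attr(x, "dimension")),
                 ylab = "cumulative share of resource", main = lab, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::points(x$x, x$y, pch = 20, cex = 0.6)
  invisible(x)
}
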