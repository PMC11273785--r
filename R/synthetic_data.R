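# Synthetic region tables: log-normal areas and population densities,
# log-normal per-capita resource rates with a controllable inequality knob.

#' Configuration for the synthetic table generator
#'
#' Defaults mirror the structure of the bundled 31-unit table: 31 units whose
#' log-areas and log population densities are heterogeneous on roughly the
#' scale seen there, four resources whose expected per-1,000 rates equal the
#' national rates of the bundled data (institutions 0.20, employees 2.72,
#' professionals 1.99, beds 25.61), and a log-scale rate dispersion of 0.5,
#' about the spread of the observed per-capita institution rates.
#'
#' @param n_units number of units (at least 2).
#' @param seed integer seed; identical configurations generate identical
#'   tables (Mersenne–Twister, fixed internally).
#' @param area_dispersion standard deviation of log-areas.
#' @param pop_density_dispersion standard deviation of log population density
#'   (persons per 10,000 km^2).
#' @param area_median median area in units of 10,000 km^2.
#' @param pop_density_median median population density (persons per
#'   10,000 km^2).
#' @param resource_rate_mean named vector of expected resource counts per
#'   1,000 persons, one per resource.
#' @param resource_rate_sigma log-scale dispersion of per-capita rates across
#'   units — the inequality knob. 0 gives equal rates everywhere (population-
#'   dimension Gini at rounding noise); larger values give more inequality.
#' @param resource_names resource column names; defaults to
#'   `names(resource_rate_mean)`.
#' @param region_labels optional region labels to assign.
#' @param region_probs assignment probabilities, one per label, summing to 1.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_units = 31L,
                             seed = 1L,
                             area_dispersion = 1.3,
                             pop_density_dispersion = 1.5,
                             area_median = 17,
                             pop_density_median = 3e5,
                             resource_rate_mean = c(institutions = 0.20,
                                                    employees = 2.72,
                                                    professionals = 1.99,
                                                    beds = 25.61),
                             resource_rate_sigma = 0.5,
                             resource_names = names(resource_rate_mean),
                             region_labels = c("eastern", "middle", "western"),
                             region_probs = c(11, 8, 12) / 31) {
  if (n_units < 2L) stop("n_units must be at least 2")
  if (area_dispersion < 0 || pop_density_dispersion < 0 ||
      resource_rate_sigma < 0) {
    stop("dispersions must be non-negative")
  }
  if (area_median <= 0 || pop_density_median <= 0) {
    stop("medians must be positive")
  }
  if (any(resource_rate_mean <= 0)) stop("resource_rate_mean must be positive")
  if (is.null(resource_names)) stop("resource_names required")
  if (length(resource_rate_mean) == 1L && length(resource_names) > 1L) {
    resource_rate_mean <- rep(resource_rate_mean, length(resource_names))
  }
  if (length(resource_rate_mean) != length(resource_names)) {
    stop("resource_rate_mean and resource_names lengths differ")
  }
  names(resource_rate_mean) <- resource_names
  if (!is.null(region_labels)) {
    if (length(region_probs) != length(region_labels)) {
      stop("region_probs must match region_labels")
    }
    if (any(region_probs < 0) || abs(sum(region_probs) - 1) > 1e-9) {
      stop("region_probs must be non-negative and sum to 1")
    }
  }
  structure(list(n_units = as.integer(n_units), seed = as.integer(seed),
                 area_dispersion = area_dispersion,
                 pop_density_dispersion = pop_density_dispersion,
                 area_median = area_median,
                 pop_density_median = pop_density_median,
                 resource_rate_mean = resource_rate_mean,
                 resource_rate_sigma = resource_rate_sigma,
                 resource_names = resource_names,
                 region_labels = region_labels,
                 region_probs = region_probs),
            class = "synthetic_config")
}

# Run fn under a local RNG state so callers' streams are untouched.
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  fn()
}

#' Generate a synthetic province table
#'
#' Areas are drawn log-normally; populations are area times a log-normal
#' density, rounded to at least one person; each resource count is the
#' population times a log-normal per-capita rate (mean
#' `resource_rate_mean`, log-sd `resource_rate_sigma`), rounded to a
#' non-negative integer — so zero-count units occur naturally at high
#' dispersion. Deterministic given the configuration.
#'
#' @param config a [synthetic_config()].
#' @return a [province_table()] that passes [validate_provinces()] with zero
#'   errors.
#' @export
#' @examples
#' tab <- generate_provinces(synthetic_config(n_units = 10, seed = 42))
#' gini(tab, "beds", "population")$gini
generate_provinces <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, function() {
    n <- config$n_units
    area <- exp(stats::rnorm(n, log(config$area_median),
                             config$area_dispersion))
    dens <- exp(stats::rnorm(n, log(config$pop_density_median),
                             config$pop_density_dispersion))
    pop <- pmax(1, round(area * dens))
    df <- data.frame(
      name = sprintf("unit_%02d", seq_len(n)),
      region = if (is.null(config$region_labels)) "all" else
        sample(config$region_labels, n, replace = TRUE,
               prob = config$region_probs),
      area = area, population_65plus = pop)
    s <- config$resource_rate_sigma
    for (rc in config$resource_names) {
      # mean-preserving log-normal: E[rate] = resource_rate_mean[rc]
      rate <- config$resource_rate_mean[[rc]] *
        exp(stats::rnorm(n, -s^2 / 2, s))
      df[[rc]] <- pmax(0, round(pop * rate / 1000))
    }
    province_table(df, resources = config$resource_names)
  })
}

#' Two-unit table with a closed-form Gini coefficient
#'
#' Builds a table of two units whose Lorenz curve has a single kink at
#' `(p, q)`: the low-density unit holds a share `p` of the denominator (area
#' or population) but only a share `q <= p` of the resource. The trapezoid
#' Gini of this curve is exactly `p - q`, which makes the table a closed-form
#' test harness for the Gini implementation.
#'
#' `p` and `q` are realised exactly when they have at most 8 decimal digits
#' (integer populations and counts are constructed on a 1e8 grid).
#'
#' @param p denominator share of the low-density unit, in (0, 1).
#' @param q resource share of the low-density unit, in (0, 1), `q <= p`.
#' @param dimension `"area"` or `"population"` — which denominator carries the
#'   share `p`.
#' @return a [province_table()] with one resource column `resource`.
#' @export
#' @examples
#' gini(two_group_table(0.8, 0.5, "population"), "resource", "population")$gini
two_group_table <- function(p, q, dimension = c("area", "population")) {
  dimension <- match.arg(dimension)
  if (!(p > 0 && p < 1) || !(q > 0 && q < 1)) stop("p and q must lie in (0, 1)")
  if (q > p) stop("q must not exceed p (the Lorenz curve would cross the diagonal)")
  scale <- 1e8
  res <- c(round(q * scale), round((1 - q) * scale))
  if (dimension == "area") {
    area <- c(p, 1 - p)
    pop <- c(scale / 2, scale / 2)
  } else {
    area <- c(1, 1)
    pop <- c(round(p * scale), round((1 - p) * scale))
  }
  province_table(data.frame(
    name = c("low_density", "high_density"), region = "all",
    area = area, population_65plus = pop, resource = res))
}

#' Synthetic staff age and education counts
#'
#' Age counts are multinomial over the four bins with the given weights and
#' sum exactly to `employee_total`. Education counts are multinomial over
#' junior college, bachelor-or-above and an implicit "below junior college"
#' remainder (weights are normalised if they sum to more than 1), so they
#' never exceed the employee total.
#'
#' @param employee_total positive integer.
#' @param age_weights four non-negative weights, not all zero.
#' @param edu_weights two non-negative weights; interpreted as proportions of
#'   the total when their sum is at most 1.
#' @param seed integer seed.
#' @return list with named integer vectors `age_counts`
#'   (`age_le35`, `age_36_45`, `age_46_55`, `age_ge56`) and `edu_counts`
#'   (`edu_junior_college`, `edu_bachelor_plus`).
#' @export
staff_structure_synth <- function(employee_total,
                                  age_weights = c(1, 1, 1, 1),
                                  edu_weights = c(0.155, 0.083),
                                  seed = 1L) {
  if (employee_total < 0 || employee_total != round(employee_total)) {
    stop("employee_total must be a non-negative integer")
  }
  if (length(age_weights) != 4L || any(age_weights < 0) ||
      sum(age_weights) == 0) {
    stop("age_weights must be four non-negative weights, not all zero")
  }
  if (length(edu_weights) != 2L || any(edu_weights < 0)) {
    stop("edu_weights must be two non-negative weights")
  }
  .with_seed(seed, function() {
    age <- drop(stats::rmultinom(1, employee_total,
                                 age_weights / sum(age_weights)))
    names(age) <- c("age_le35", "age_36_45", "age_46_55", "age_ge56")
    ew <- edu_weights
    if (sum(ew) > 1) ew <- ew / sum(ew)
    edu3 <- drop(stats::rmultinom(1, employee_total,
                                  c(ew, 1 - sum(ew))))
    edu <- edu3[1:2]
    names(edu) <- c("edu_junior_college", "edu_bachelor_plus")
    list(age_counts = age, edu_counts = edu)
  })
}
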