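# Small in-code fixtures for unit and property tests.

# absolute-tolerance comparison against printed reference values (testthat's
# expect_equal tolerance is relative, which is wrong for 3-dp print rounding)
expect_within <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}

toy_table <- function() {
  province_table(data.frame(
    name = c("A", "B"),
    region = c("r1", "r2"),
    area = c(1.0, 1.0),
    population_65plus = c(100L, 100L),
    beds = c(5L, 5L)))
}

# uniform densities: every agglomeration degree 1, every Gini 0
uniform_table <- function(n = 4) {
  province_table(data.frame(
    name = paste0("u", seq_len(n)),
    region = "all",
    area = rep(2.5, n),
    population_65plus = rep(1000L, n),
    beds = rep(40L, n)))
}

# a random valid table: heterogeneous areas, populations and counts
random_table <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:25, 1)
  province_table(data.frame(
    name = sprintf("r%02d", seq_len(n)),
    region = "all",
    area = stats::runif(n, 0.5, 150),
    population_65plus = sample(1e4:1e7, n),
    beds = stats::rpois(n, lambda = stats::runif(n, 1, 5000))))
}
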