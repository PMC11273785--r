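Package: equigeo
Title: Equity Analysis of Regional Health and Aged-Care Resource Allocation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the equity of health and aged-care resource
    allocation across administrative regions along two dimensions, geographical
    area and target population. Implements resource and population agglomeration
    degrees (HRAD, PAD and their ratio) with allocation classifications, weighted
    Lorenz curves built from ascending resource densities, and the trapezoid Gini
    coefficient with the five-band equity interpretation used in health-resource
    studies. Ships a fully transcribed 31-province table of Chinese older-adult
    care resources for the year 2020 (institutions, employees, professional
    staff, beds, staff age and education structure), a synthetic table generator
    with a controllable inequality parameter for property testing, and a
    reporting pipeline that exports agglomeration, Gini and Lorenz tables as CSV
    and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
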