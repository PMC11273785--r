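# Published 3-dp reference values for the bundled 2020 dataset, in fixture row
# order (eastern, western, middle blocks), used by the reproduction tests.

fixture_order <- c(
  "Beijing", "Tianjin", "Hebei", "Liaoning", "Shanghai", "Jiangsu", "Zhejiang",
  "Fujian", "Shandong", "Guangdong", "Hainan", "Inner Mongolia", "Chongqing",
  "Guangxi", "Sichuan", "Guizhou", "Yunnan", "Tibet", "Shaanxi", "Gansu",
  "Qinghai", "Ningxia", "Xinjiang", "Shanxi", "Jilin", "Heilongjiang", "Anhui",
  "Jiangxi", "Henan", "Hubei", "Hunan")

resource_cols <- c("institutions", "employees", "professionals", "beds")

# HRAD per resource (columns: institutions, employees, professionals, beds)
printed_hrad <- matrix(c(
  8.988, 22.988, 26.546, 13.574,  8.393, 11.463, 12.487, 10.395,
  2.308, 2.908, 3.163, 2.424,     3.457, 2.407, 2.216, 2.363,
  26.803, 86.128, 90.986, 43.636, 5.816, 8.129, 8.873, 8.152,
  4.273, 4.778, 4.886, 6.398,     1.331, 1.341, 1.320, 1.370,
  3.501, 4.515, 4.932, 4.483,     2.656, 3.314, 3.523, 2.762,
  0.342, 0.596, 0.610, 0.502,     0.144, 0.129, 0.126, 0.129,
  2.840, 2.726, 2.716, 2.455,     0.602, 1.008, 1.089, 0.757,
  1.320, 0.811, 0.628, 1.208,     1.416, 0.710, 0.518, 0.945,
  0.564, 0.362, 0.380, 0.446,     0.005, 0.007, 0.007, 0.007,
  0.902, 1.110, 1.135, 1.008,     0.159, 0.144, 0.135, 0.135,
  0.022, 0.018, 0.017, 0.018,     0.426, 0.502, 0.515, 0.595,
  0.057, 0.064, 0.072, 0.059,     1.071, 1.045, 0.940, 0.910,
  2.018, 1.754, 1.566, 1.433,     0.912, 0.652, 0.668, 0.690,
  4.418, 3.206, 2.853, 5.082,     2.734, 1.835, 1.673, 1.971,
  4.903, 3.829, 3.647, 3.668,     2.500, 2.509, 2.111, 2.975,
  2.838, 1.982, 1.964, 2.096),
  ncol = 4, byrow = TRUE,
  dimnames = list(fixture_order, resource_cols))

printed_pad <- c(
  8.971, 8.613, 2.780, 2.522, 32.471, 6.469, 4.182, 1.919, 4.916, 3.040,
  1.501, 0.134, 3.356, 1.300, 1.473, 1.279, 0.650, 0.009, 1.294, 0.373,
  0.036, 0.527, 0.061, 1.452, 1.013, 0.531, 3.303, 1.626, 4.054, 2.290,
  2.348)
names(printed_pad) <- fixture_order

# HRAD/PAD per resource
printed_hrad_over_pad <- matrix(c(
  1.002, 2.562, 2.959, 1.513,  0.974, 1.331, 1.450, 1.207,
  0.830, 1.046, 1.138, 0.872,  1.371, 0.954, 0.879, 0.937,
  0.825, 2.652, 2.802, 1.344,  0.899, 1.257, 1.372, 1.260,
  1.022, 1.143, 1.169, 1.530,  0.694, 0.699, 0.688, 0.714,
  0.712, 0.919, 1.003, 0.912,  0.874, 1.090, 1.159, 0.909,
  0.228, 0.397, 0.407, 0.334,  1.078, 0.959, 0.942, 0.965,
  0.846, 0.812, 0.809, 0.732,  0.463, 0.775, 0.838, 0.582,
  0.896, 0.551, 0.426, 0.820,  1.108, 0.556, 0.406, 0.739,
  0.867, 0.556, 0.584, 0.686,  0.555, 0.770, 0.848, 0.785,
  0.697, 0.858, 0.877, 0.779,  0.425, 0.386, 0.360, 0.360,
  0.622, 0.502, 0.464, 0.511,  0.808, 0.952, 0.976, 1.129,
  0.932, 1.043, 1.174, 0.965,  0.738, 0.719, 0.647, 0.626,
  1.992, 1.732, 1.546, 1.414,  1.717, 1.227, 1.258, 1.300,
  1.337, 0.971, 0.864, 1.538,  1.682, 1.129, 1.029, 1.212,
  1.209, 0.944, 0.899, 0.905,  1.092, 1.096, 0.922, 1.300,
  1.209, 0.844, 0.837, 0.893),
  ncol = 4, byrow = TRUE,
  dimnames = list(fixture_order, resource_cols))

# national Gini per resource: area dimension then population dimension
printed_gini_national <- list(
  area = c(institutions = 0.685, employees = 0.727, professionals = 0.736,
           beds = 0.715),
  population = c(institutions = 0.170, employees = 0.186,
                 professionals = 0.215, beds = 0.159))

# regional Gini grid (rows: region; columns: resource), per dimension
printed_gini_regional <- list(
  area = matrix(c(0.281, 0.397, 0.414, 0.371,
                  0.699, 0.678, 0.670, 0.689,
                  0.313, 0.312, 0.302, 0.361),
                ncol = 4, byrow = TRUE,
                dimnames = list(c("eastern", "western", "middle"),
                                resource_cols)),
  population = matrix(c(0.111, 0.170, 0.184, 0.131,
                        0.134, 0.140, 0.200, 0.105,
                        0.121, 0.108, 0.102, 0.137),
                      ncol = 4, byrow = TRUE,
                      dimnames = list(c("eastern", "western", "middle"),
                                      resource_cols)))

printed_rates_national <- c(institutions = 0.20, employees = 2.72,
                            professionals = 1.99, beds = 25.61)

# staff-structure percentage grid: four age bins then two education bins
printed_staff_pct <- matrix(c(
  18.80, 19.83, 43.68, 17.68, 14.87, 9.00,
  18.16, 33.05, 33.08, 15.71, 12.97, 11.13,
  20.91, 29.96, 33.78, 15.34, 13.80, 6.19,
  18.37, 29.87, 35.62, 16.14, 13.86, 6.39,
  9.67, 20.99, 42.48, 26.85, 11.63, 6.87,
  25.08, 27.08, 32.43, 15.41, 18.16, 10.79,
  18.37, 28.06, 34.37, 19.19, 12.14, 6.75,
  20.87, 26.18, 32.30, 20.65, 15.18, 9.53,
  25.20, 31.25, 30.31, 13.23, 21.34, 12.37,
  20.30, 27.76, 37.93, 14.01, 14.41, 10.57,
  31.34, 27.73, 34.95, 5.99, 14.00, 8.27,
  18.84, 32.54, 36.15, 12.47, 17.75, 9.04,
  17.73, 22.74, 38.62, 20.91, 15.29, 6.67,
  29.14, 30.59, 28.42, 11.85, 25.46, 14.22,
  22.82, 32.51, 31.17, 13.50, 18.30, 7.15,
  30.17, 34.42, 27.14, 8.26, 23.06, 11.07,
  30.68, 35.06, 27.94, 6.33, 18.61, 12.44,
  68.13, 28.18, 3.23, 0.46, 9.01, 7.16,
  30.78, 30.72, 27.25, 11.25, 22.07, 10.83,
  30.69, 41.14, 23.11, 5.06, 23.72, 10.88,
  23.22, 47.15, 28.06, 1.57, 13.53, 10.11,
  26.51, 39.68, 26.95, 6.86, 18.86, 16.29,
  28.43, 35.02, 29.92, 6.63, 17.86, 8.10,
  25.41, 31.43, 30.03, 13.13, 16.53, 7.41,
  8.89, 23.61, 61.12, 6.38, 4.50, 2.80,
  20.59, 36.06, 32.67, 10.68, 12.30, 5.89,
  18.48, 30.40, 34.80, 16.32, 14.36, 5.96,
  15.16, 23.93, 35.48, 25.43, 12.32, 4.30,
  18.18, 27.94, 35.05, 18.84, 11.80, 5.79,
  16.45, 40.35, 29.53, 13.66, 13.32, 5.48,
  21.40, 33.13, 33.49, 11.98, 19.07, 10.35),
  ncol = 6, byrow = TRUE,
  dimnames = list(fixture_order,
                  c("age_le35_pct", "age_36_45_pct", "age_46_55_pct",
                    "age_ge56_pct", "edu_junior_college_pct",
                    "edu_bachelor_plus_pct")))

printed_staff_national_pct <- c(age_le35_pct = 20.47, age_36_45_pct = 29.30,
                                age_46_55_pct = 34.82, age_ge56_pct = 15.41,
                                edu_junior_college_pct = 15.45,
                                edu_bachelor_plus_pct = 8.25)
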