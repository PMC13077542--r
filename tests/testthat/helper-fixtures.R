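# Shared helpers: tiny in-code fixtures for the unit tests.

# a registry + noise-free calibration series with known slopes
make_exact_study <- function() {
  reg <- compound_registry(c("FHUEA", "A", "B"),
                           mw = c(358.1, 414.07, 500.13))
  slopes <- c(FHUEA = 800, A = 500, B = 1200)
  series <- lapply(names(slopes), function(id) {
    lv <- c(0.2, 0.5, 1, 2, 5, 10)
    calibration_series(id, lv, slopes[[id]] * lv)
  })
  list(registry = reg, series = series, slopes = slopes)
}

# write a small PaDEL-style descriptor CSV; returns the path
write_descriptor_fixture <- function(
    dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "desc.csv")
  writeLines(c(
    "Name,d1,d2,d3,d4",
    "cmpA,1.0,2.0,0.1,5",
    "cmpB,2.0,4.0,0.2,6",
    "cmpC,3.0,6.5,,7"), path)
  path
}

# independent OLS via the explicit normal equations (oracle for lm-based fit)
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  list(slope = slope, intercept = intercept)
}

small_sim_config <- function(seed = 7) {
  generator_config(n_compounds = 24, n_descriptors = 40, n_informative = 6,
                   nzv_fraction = 0.1, missing_fraction = 0.05,
                   area_noise_cv = 0, intercept_scale = 0, ie_noise_sd = 0,
                   seed = seed)
}
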