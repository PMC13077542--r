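test_that("an exact line is fitted exactly", {
  fit <- fit_calibration(calibration_series("X", c(1, 2, 5), c(2, 4, 10)))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r2, 1)
})

test_that("noisy calibration matches the normal-equation oracle", {
  lv <- c(0.2, 0.5, 1, 2, 5, 10)
  set.seed(101)
  areas <- 3.5 * lv + rnorm(length(lv), 0, 0.1)
  fit <- fit_calibration(calibration_series("X", lv, areas))
  oracle <- ols_oracle(lv, areas)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-12)
  expect_lt(abs(fit$slope - 3.5), 0.1)
})

test_that("degenerate or invalid series are rejected", {
  expect_error(fit_calibration(calibration_series("X", c(1, 1), c(2, 2.1))),
               "degenerate")
  expect_error(calibration_series("X", 1, NaN), "non-finite")
  expect_error(calibration_series("X", c(1, -2), c(1, 2)), "positive")
  expect_error(calibration_series("X", c(1, 2), 1), "length")
})

test_that("relative log IE follows the slope and molecular-weight ratios", {
  anchor <- list(id = "FHUEA", mw = 320)
  afit <- structure(list(compound_id = "FHUEA", slope = 800, intercept = 0,
                         r2 = 1), class = "calibration_fit")
  # anchor against itself
  self <- relative_log_ie(afit, anchor, afit, anchor)
  expect_identical(self$log_ie, 0)
  expect_identical(self$source, "experimental")
  # pure slope ratio at equal molecular weight
  f10 <- structure(list(compound_id = "A", slope = 8000), class = "calibration_fit")
  expect_equal(relative_log_ie(f10, list(id = "A", mw = 320),
                               afit, anchor)$log_ie, 1)
  # hand arithmetic: (500/800) * (320/400) = 0.5
  fB <- structure(list(compound_id = "B", slope = 500), class = "calibration_fit")
  rie <- relative_log_ie(fB, list(id = "B", mw = 400), afit, anchor)
  expect_equal(rie$log_ie, log10(0.625 * 0.8))
  expect_equal(round(rie$log_ie, 4), -0.3010)
})

test_that("non-positive slopes cannot form a log IE", {
  anchor <- list(id = "FHUEA", mw = 320)
  afit <- structure(list(compound_id = "FHUEA", slope = 800),
                    class = "calibration_fit")
  bad <- structure(list(compound_id = "NEG", slope = -3),
                   class = "calibration_fit")
  expect_error(relative_log_ie(bad, list(id = "NEG", mw = 400), afit, anchor),
               "NEG")
  expect_error(predict_concentration(10, list(log_ie = 0),
                                     list(id = "A", mw = 400),
                                     bad, anchor),
               "non-positive")
})

test_that("concentration inversion reproduces hand arithmetic", {
  anchor <- list(id = "FHUEA", mw = 320)
  afit <- structure(list(compound_id = "FHUEA", slope = 800),
                    class = "calibration_fit")
  # A = 1000, logIE = -log10(2), MW = 400: C = 1000*320/(0.5*800*400) = 2
  expect_equal(predict_concentration(1000, list(log_ie = log10(0.5)),
                                     list(id = "B", mw = 400), afit, anchor),
               2)
  # logIE 0 and equal molecular weights collapse to area / anchor slope
  expect_equal(predict_concentration(400, list(log_ie = 0),
                                     list(id = "C", mw = 320), afit, anchor),
               0.5)
})

test_that("inversion is the exact inverse of the IE definition", {
  st <- make_exact_study()
  fits <- lapply(st$series, fit_calibration)
  names(fits) <- vapply(fits, `[[`, "", "compound_id")
  anchor <- list(id = "FHUEA", mw = st$registry$mw[1])
  for (id in c("A", "B")) {
    cmp <- list(id = id, mw = st$registry$mw[st$registry$id == id])
    rie <- relative_log_ie(fits[[id]], cmp, fits$FHUEA, anchor)
    for (conc in c(0.01, 0.37, 1, 12, 250)) {
      area <- st$slopes[[id]] * conc
      expect_equal(predict_concentration(area, rie, cmp, fits$FHUEA, anchor),
                   conc, tolerance = 1e-12)
    }
  }
})

test_that("relative IEs are invariant to a common response rescaling", {
  st <- make_exact_study()
  anchor <- list(id = "FHUEA", mw = st$registry$mw[1])
  ie_of <- function(series_list) {
    fits <- lapply(series_list, fit_calibration)
    names(fits) <- vapply(fits, `[[`, "", "compound_id")
    vapply(c("A", "B"), function(id) {
      cmp <- list(id = id, mw = st$registry$mw[st$registry$id == id])
      relative_log_ie(fits[[id]], cmp, fits$FHUEA, anchor)$log_ie
    }, numeric(1))
  }
  scaled <- lapply(st$series, function(s) {
    calibration_series(s$compound_id, s$levels, s$areas * 37.5)
  })
  expect_equal(ie_of(st$series), ie_of(scaled), tolerance = 1e-12)
})

test_that("relative log IE is antisymmetric", {
  st <- make_exact_study()
  fits <- lapply(st$series, fit_calibration)
  names(fits) <- vapply(fits, `[[`, "", "compound_id")
  rows <- split(st$registry, st$registry$id)
  ab <- relative_log_ie(fits$A, rows$A, fits$B, rows$B)$log_ie
  ba <- relative_log_ie(fits$B, rows$B, fits$A, rows$A)$log_ie
  expect_equal(ab, -ba, tolerance = 1e-12)
})

test_that("calibrate_study returns a complete, anchored IE table", {
  st <- make_exact_study()
  fits <- calibrate_study(st$series, st$registry, anchor_id = "FHUEA")
  expect_setequal(fits$compound_id, st$registry$id)
  expect_equal(fits$exp_log_ie[fits$compound_id == "FHUEA"], 0)
  expect_error(calibrate_study(st$series, st$registry, anchor_id = "nope"),
               "anchor")
})

test_that("calibration and registry tables round-trip through files", {
  dir <- withr::local_tempdir()
  st <- make_exact_study()
  calib <- do.call(rbind, lapply(st$series, function(s) {
    data.frame(compound_id = s$compound_id, level_ng_per_mL = s$levels,
               area = s$areas)
  }))
  cp <- file.path(dir, "calib.csv")
  write.csv(calib, cp, row.names = FALSE)
  series2 <- read_calibration_table(cp)
  expect_length(series2, 3)
  expect_equal(series2[[1]]$areas, st$series[[1]]$areas)
  rp <- file.path(dir, "reg.csv")
  write.csv(st$registry, rp, row.names = FALSE)
  reg2 <- read_registry_table(rp)
  expect_equal(reg2$mw, st$registry$mw)
  expect_error(compound_registry(c("a", "a"), mw = c(1, 2)), "unique")
  expect_error(compound_registry("a", mw = -5), "positive")
})
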