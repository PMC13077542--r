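test_that("the PaDEL-style reader preserves names and missing cells", {
  path <- write_descriptor_fixture()
  m <- read_descriptor_table(path)
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(rownames(m), c("cmpA", "cmpB", "cmpC"))
  expect_equal(colnames(m), c("d1", "d2", "d3", "d4"))
  expect_true(is.na(m["cmpC", "d3"]))     # empty cell is missing, not zero
  expect_equal(m["cmpB", "d2"], 4)
})

test_that("the reader rejects malformed tables", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.csv")
  writeLines(c("Name,d1", "x,1", "x,2"), dup)
  expect_error(read_descriptor_table(dup), "duplicated")
  nocol <- file.path(dir, "nocol.csv")
  writeLines(c("Name", "x"), nocol)
  expect_error(read_descriptor_table(nocol), "zero descriptor")
})

test_that("columns with missing or non-finite values are deleted", {
  m <- cbind(ok = 1:6 / 2, with_na = c(1, NaN, 3, 4, 5, 6),
             with_inf = c(1, 2, Inf, 4, 5, 6))
  res <- drop_missing(m)
  expect_equal(colnames(res$matrix), "ok")
  expect_setequal(res$dropped, c("with_na", "with_inf"))
  clean <- cbind(a = rnorm(5), b = rnorm(5))
  expect_identical(drop_missing(clean)$matrix, clean)   # identity case
  expect_error(drop_missing(cbind(x = c(NA, 1))), "all descriptor")
})

test_that("near-zero-variance filtering applies both frequency criteria", {
  n <- 50
  m <- cbind(constant = rep(3, n),
             rich = seq_len(n) + 0,
             sparse = c(rep(0, 48), 1, 1),      # ratio 24 > 19, 4% < 10%
             binary_balanced = rep(c(0, 1), 25)) # ratio 1: kept
  res <- drop_near_zero_variance(m)
  expect_setequal(res$dropped, c("constant", "sparse"))
  expect_setequal(colnames(res$matrix), c("rich", "binary_balanced"))
})

test_that("correlation filtering removes one member per offending pair", {
  set.seed(42)
  x <- rnorm(40)
  m <- cbind(a = x, b = x, c = rnorm(40))
  res <- drop_correlated(m, threshold = 0.8)
  expect_length(res$dropped, 1)
  expect_true(res$dropped %in% c("a", "b"))

  # mutually independent columns survive untouched
  set.seed(7)
  ind <- matrix(rnorm(60 * 8), 60, dimnames = list(NULL, paste0("v", 1:8)))
  cm <- cor(ind); diag(cm) <- 0
  stopifnot(max(abs(cm)) < 0.8)  # precondition verified by full scan
  expect_length(drop_correlated(ind, 0.8)$dropped, 0)
})

test_that("a planted high-correlation block is broken up", {
  set.seed(11)
  n <- 60
  shared <- rnorm(n)
  block <- sapply(1:3, function(i) sqrt(0.95) * shared +
                    sqrt(0.05) * rnorm(n))
  colnames(block) <- paste0("blk", 1:3)
  m <- cbind(block, i1 = rnorm(n), i2 = rnorm(n))
  res <- drop_correlated(m, 0.8)
  expect_gte(sum(res$dropped %in% colnames(block)), 2)
  cm <- cor(res$matrix); diag(cm) <- 0
  expect_lt(max(abs(cm)), 0.8)  # exhaustive pairwise audit of the output
})

test_that("requesting all columns skips elimination", {
  m <- matrix(rnorm(40), 10, dimnames = list(NULL, paste0("v", 1:4)))
  rep <- rfe_select(m, rnorm(10), subset_sizes = 4, folds = 2, repeats = 1)
  expect_setequal(rep$selected, colnames(m))
})

test_that("RFE recovers planted linear drivers", {
  set.seed(5)
  n <- 60; p <- 50
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- X[, 1:5] %*% c(1, -1, 0.8, -0.9, 1.1) + rnorm(n, 0, 0.05)
  rep <- rfe_select(X, as.numeric(y), subset_sizes = c(5, 10, 20, 50),
                    folds = 5, repeats = 3, seed = 3)
  expect_gte(sum(sprintf("f%02d", 1:5) %in% rep$selected), 4)
  expect_equal(nrow(rep$cv_profile), 4)
  expect_error(rfe_select(X, as.numeric(y), folds = 100), "folds")
})

test_that("on pure noise the CV profile is flat and one-SE picks small", {
  set.seed(9)
  n <- 40; p <- 30
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, sprintf("n%02d", 1:p)))
  y <- rnorm(n)
  rep <- rfe_select(X, y, subset_sizes = c(5, 10, 20), folds = 5,
                    repeats = 3, seed = 2, tol_se = 1)
  # no size does materially better than predicting noise
  expect_lt(diff(range(rep$cv_profile$rmse_mean)), 0.5 * sd(y))
  expect_equal(rep$best_size, 5L)
})

test_that("the selection report is deterministic given a seed", {
  set.seed(13)
  X <- matrix(rnorm(40 * 12), 40, dimnames = list(NULL, paste0("v", 1:12)))
  y <- X[, 1] + rnorm(40, 0, 0.2)
  r1 <- rfe_select(X, y, subset_sizes = c(3, 6, 12), folds = 4,
                   repeats = 2, seed = 99)
  r2 <- rfe_select(X, y, subset_sizes = c(3, 6, 12), folds = 4,
                   repeats = 2, seed = 99)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$cv_profile, r2$cv_profile)
})

test_that("the cascade never adds columns and audits cleanly", {
  cfg <- small_sim_config()
  st <- simulate_ie_study(cfg)
  s1 <- drop_missing(st$descriptors)
  s2 <- drop_near_zero_variance(s1$matrix)
  s3 <- drop_correlated(s2$matrix)
  expect_true(ncol(st$descriptors) >= ncol(s1$matrix))
  expect_true(ncol(s1$matrix) >= ncol(s2$matrix))
  expect_true(ncol(s2$matrix) >= ncol(s3$matrix))
  cl <- clean_descriptors(st$descriptors)
  expect_identical(colnames(cl$matrix), colnames(s3$matrix))
  # the per-stage drop lists are disjoint
  all_drops <- c(cl$dropped_missing, cl$dropped_nzv, cl$dropped_correlated)
  expect_equal(anyDuplicated(all_drops), 0L)
})

test_that("selection reports are written with a machine-readable sidecar", {
  dir <- withr::local_tempdir()
  set.seed(3)
  X <- matrix(rnorm(30 * 8), 30, dimnames = list(NULL, paste0("v", 1:8)))
  y <- X[, 2] + rnorm(30, 0, 0.1)
  rep <- rfe_select(X, y, subset_sizes = c(2, 4, 8), folds = 3, repeats = 2)
  p <- file.path(dir, "report.txt")
  write_selection_report(rep, p)
  expect_true(file.exists(p))
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_identical(side$selected, rep$selected)
})
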