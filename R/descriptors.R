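# Descriptor-table handling and the feature-cleaning cascade.
#
# With ~1 400 PaDEL 2D descriptors against only a few dozen compounds, QSAR
# fitting needs aggressive feature reduction: drop columns with missing or
# non-finite values, drop near-zero-variance columns, break up highly
# correlated pairs, and finally run cross-validated recursive feature
# elimination (RFE).  Descriptor matrices are plain numeric matrices with
# compound ids as rownames.

#' Read a descriptor table (PaDEL export layout)
#'
#' First column holds compound names; all remaining columns are numeric
#' descriptors.  Empty cells, `NA`, `Inf` and `NaN` markers are kept as
#' missing values, never coerced to zero.
#'
#' @param path file path.
#' @param sep field separator (default comma, the PaDEL CSV dialect).
#'
#' @return A numeric matrix, rows = compounds (rownames = compound names),
#'   columns = descriptors.
#' @export
read_descriptor_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "", "NaN", "null", "Infinity"))
  if (ncol(df) < 2) stop("descriptor table has zero descriptor columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated compound names in descriptor table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicated descriptor names")
  m
}

#' Write a descriptor matrix in the same layout
#' @param m descriptor matrix (rownames = compound names).
#' @param path output path.
#' @param sep field separator.
#' @export
write_descriptor_table <- function(m, path, sep = ",") {
  df <- data.frame(Name = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Drop descriptor columns containing missing or non-finite values
#'
#' Column deletion, not imputation: any column with at least one `NA`,
#' `NaN` or infinite entry is removed.
#'
#' @param m descriptor matrix.
#' @return A list with `matrix` (the surviving columns) and `dropped`
#'   (character vector of removed column names).
#' @export
drop_missing <- function(m) {
  bad <- apply(m, 2, function(x) any(!is.finite(x)))
  keep <- m[, !bad, drop = FALSE]
  if (ncol(keep) == 0) stop("all descriptor columns contain missing values")
  list(matrix = keep, dropped = colnames(m)[bad])
}

#' Drop near-zero-variance descriptors
#'
#' A column is removed when the ratio of the most frequent value's count to
#' the second most frequent value's count exceeds `freq_ratio` AND the
#' percentage of distinct values is below `unique_pct`.  Constant columns
#' are always removed.  Defaults (19 = 95/5 and 10%) follow the caret
#' convention.
#'
#' @param m descriptor matrix, no missing values.
#' @param freq_ratio frequency-ratio cutoff.
#' @param unique_pct distinct-value percentage cutoff.
#' @return list with `matrix` and `dropped`, as [drop_missing()].
#' @export
drop_near_zero_variance <- function(m, freq_ratio = 19, unique_pct = 10) {
  stopifnot(all(is.finite(m)))
  idx <- caret::nearZeroVar(m, freqCut = freq_ratio, uniqueCut = unique_pct)
  dropped <- colnames(m)[idx]
  keep <- if (length(idx)) m[, -idx, drop = FALSE] else m
  if (ncol(keep) == 0) stop("all descriptor columns are near zero variance")
  list(matrix = keep, dropped = dropped)
}

#' Drop one member of every highly correlated descriptor pair
#'
#' Greedy caret-style elimination: while any pair of columns has absolute
#' Pearson correlation above `threshold`, the member of the worst pair with
#' the larger mean absolute correlation to everything else is removed.  The
#' result contains no pair with |r| above the threshold.
#'
#' @param m descriptor matrix, no missing values, at least two rows.
#' @param threshold absolute-correlation cutoff (default 0.8).
#' @return list with `matrix` and `dropped`.
#' @export
drop_correlated <- function(m, threshold = 0.8) {
  stopifnot(all(is.finite(m)), nrow(m) >= 2)
  cm <- suppressWarnings(stats::cor(m))
  cm[!is.finite(cm)] <- 0          # zero-variance guard; NZV runs first
  diag(cm) <- 1
  idx <- caret::findCorrelation(cm, cutoff = threshold, exact = TRUE)
  idx <- sort(idx)
  dropped <- colnames(m)[idx]
  keep <- if (length(idx)) m[, -idx, drop = FALSE] else m
  list(matrix = keep, dropped = dropped)
}

#' Run the full cleaning cascade
#'
#' missing -> near-zero variance -> pairwise correlation, recording what
#' each stage removed.
#'
#' @inheritParams drop_near_zero_variance
#' @inheritParams drop_correlated
#' @return list with `matrix` and the three per-stage drop lists
#'   (`dropped_missing`, `dropped_nzv`, `dropped_correlated`).
#' @export
clean_descriptors <- function(m, freq_ratio = 19, unique_pct = 10,
                              threshold = 0.8) {
  s1 <- drop_missing(m)
  s2 <- drop_near_zero_variance(s1$matrix, freq_ratio, unique_pct)
  s3 <- drop_correlated(s2$matrix, threshold)
  list(matrix = s3$matrix,
       dropped_missing = s1$dropped,
       dropped_nzv = s2$dropped,
       dropped_correlated = s3$dropped)
}

rf_rank_features <- function(X, y, seed, ntree = 500) {
  set.seed(seed)
  rf <- randomForest::randomForest(X, y, ntree = ntree, importance = TRUE)
  tab <- randomForest::importance(rf, type = 1, scale = FALSE)
  imp <- stats::setNames(tab[, 1], rownames(tab))
  imp[!is.finite(imp)] <- 0
  # descending importance, stable alphabetical tie-break
  names(sort(-imp[order(names(imp))], method = "radix"))
}

rf_cv_rmse <- function(X, y, fold_id, seed, ntree = 500) {
  preds <- numeric(length(y))
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    set.seed(seed + k)
    rf <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                     ntree = ntree)
    preds[!tr] <- stats::predict(rf, X[!tr, , drop = FALSE])
  }
  sqrt(mean((preds - y)^2))
}

#' Recursive feature elimination with cross-validation
#'
#' Backward selection guided by random-forest permutation importance.  For
#' every repeat x fold resample, features are ranked on the analysis part,
#' then for each candidate subset size the top-ranked subset is refit and
#' scored (RMSE) on the assessment part.  The selected size minimises mean
#' CV RMSE; with `tol_se > 0`, the smallest size whose mean RMSE is within
#' `tol_se` standard errors of the minimum is taken instead.  The final
#' selected set is the top of a ranking fit on all rows.
#'
#' @param m cleaned descriptor matrix (rows align with `y`).
#' @param y numeric response (relative log10 ionization efficiency).
#' @param subset_sizes candidate subset sizes, each <= ncol(m).
#' @param folds,repeats cross-validation design (default 5 x 5).
#' @param seed integer seed; the whole procedure is reproducible from it.
#' @param tol_se one-standard-error style tolerance; 0 = strict minimum
#'   (ties broken toward the smaller size).
#' @param ntree trees per random forest.
#'
#' @return An object of class `selection_report`: list with `selected`,
#'   `rfe_candidates`, `cv_profile` (data frame: size, rmse_mean, rmse_se),
#'   `best_size`, and empty slots for the cascade drop lists (filled by
#'   [select_features()]).
#' @export
rfe_select <- function(m, y, subset_sizes = c(5, 10, 18, 30, 60),
                       folds = 5, repeats = 5, seed = 1, tol_se = 0,
                       ntree = 500) {
  stopifnot(nrow(m) == length(y))
  if (folds > nrow(m)) stop("more CV folds than compounds")
  subset_sizes <- sort(unique(as.integer(subset_sizes)))
  subset_sizes <- subset_sizes[subset_sizes >= 1]
  if (any(subset_sizes > ncol(m))) {
    subset_sizes <- unique(pmin(subset_sizes, ncol(m)))
  }
  p <- ncol(m)

  if (identical(subset_sizes, p)) {
    # degenerate request: keep everything
    cv <- data.frame(size = p, rmse_mean = NA_real_, rmse_se = NA_real_)
    return(structure(list(selected = colnames(m), rfe_candidates = colnames(m),
                          cv_profile = cv, best_size = p,
                          dropped_missing = character(),
                          dropped_nzv = character(),
                          dropped_correlated = character()),
                     class = "selection_report"))
  }

  set.seed(seed)
  resample_seeds <- sample.int(.Machine$integer.max, repeats * (folds + 1))
  scores <- matrix(NA_real_, nrow = repeats * folds,
                   ncol = length(subset_sizes),
                   dimnames = list(NULL, as.character(subset_sizes)))
  r <- 0L
  for (rep in seq_len(repeats)) {
    set.seed(resample_seeds[(rep - 1L) * (folds + 1L) + 1L])
    fold_id <- sample(rep_len(seq_len(folds), nrow(m)))
    for (k in seq_len(folds)) {
      r <- r + 1L
      s <- resample_seeds[(rep - 1L) * (folds + 1L) + 1L + k]
      tr <- fold_id != k
      ranking <- rf_rank_features(m[tr, , drop = FALSE], y[tr], seed = s,
                                  ntree = ntree)
      for (j in seq_along(subset_sizes)) {
        feats <- ranking[seq_len(subset_sizes[j])]
        set.seed(s + j)
        rf <- randomForest::randomForest(m[tr, feats, drop = FALSE], y[tr],
                                         ntree = ntree)
        pr <- stats::predict(rf, m[!tr, feats, drop = FALSE])
        scores[r, j] <- sqrt(mean((pr - y[!tr])^2))
      }
    }
  }
  rmse_mean <- colMeans(scores)
  rmse_se <- apply(scores, 2, stats::sd) / sqrt(nrow(scores))
  best <- which.min(rmse_mean)  # which.min already prefers the smaller size
  if (tol_se > 0) {
    cut <- rmse_mean[best] + tol_se * rmse_se[best]
    best <- which(rmse_mean <= cut)[1]
  }
  best_size <- subset_sizes[best]

  final_ranking <- rf_rank_features(m, y, seed = seed, ntree = ntree)
  structure(
    list(selected = final_ranking[seq_len(best_size)],
         rfe_candidates = colnames(m),
         cv_profile = data.frame(size = subset_sizes, rmse_mean = rmse_mean,
                                 rmse_se = rmse_se, row.names = NULL),
         best_size = best_size,
         dropped_missing = character(),
         dropped_nzv = character(),
         dropped_correlated = character()),
    class = "selection_report"
  )
}

#' Clean a raw descriptor matrix and select features by RFE
#'
#' The full preprocessing path: cleaning cascade followed by [rfe_select()].
#'
#' @inheritParams rfe_select
#' @inheritParams clean_descriptors
#' @param m raw descriptor matrix (may contain missing values).
#' @return A `selection_report` whose cascade drop lists are filled in.
#' @export
select_features <- function(m, y, subset_sizes = c(5, 10, 18, 30, 60),
                            folds = 5, repeats = 5, seed = 1, tol_se = 0,
                            freq_ratio = 19, unique_pct = 10,
                            threshold = 0.8, ntree = 500) {
  cl <- clean_descriptors(m, freq_ratio, unique_pct, threshold)
  rep <- rfe_select(cl$matrix, y, subset_sizes, folds, repeats, seed,
                    tol_se, ntree)
  rep$dropped_missing <- cl$dropped_missing
  rep$dropped_nzv <- cl$dropped_nzv
  rep$dropped_correlated <- cl$dropped_correlated
  rep
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat("  dropped: ", length(x$dropped_missing), " missing, ",
      length(x$dropped_nzv), " near-zero-variance, ",
      length(x$dropped_correlated), " correlated\n", sep = "")
  cat("  RFE candidates:", length(x$rfe_candidates), "\n")
  cat("  selected size:", x$best_size, "\n")
  print(x$cv_profile, row.names = FALSE)
  invisible(x)
}

#' Write a selection report
#'
#' Human-readable stage lists plus a JSON sidecar for machines.
#'
#' @param report a `selection_report`.
#' @param path output path for the text report; the sidecar gets `.json`
#'   appended.
#' @export
write_selection_report <- function(report, path) {
  lines <- c(
    "# feature selection report",
    paste0("dropped_missing: ", paste(report$dropped_missing, collapse = " ")),
    paste0("dropped_nzv: ", paste(report$dropped_nzv, collapse = " ")),
    paste0("dropped_correlated: ",
           paste(report$dropped_correlated, collapse = " ")),
    paste0("rfe_candidates: ", length(report$rfe_candidates)),
    paste0("best_size: ", report$best_size),
    paste0("selected: ", paste(report$selected, collapse = " "))
  )
  writeLines(lines, path)
  jsonlite::write_json(unclass(report), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
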