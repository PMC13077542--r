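# Calibration curves and anchor-relative ionization efficiencies.
#
# In ESI-MS the slope of the peak-area vs concentration calibration line is
# an operational measure of a compound's ionization efficiency (IE).  All IE
# values are expressed relative to an anchor compound (by default FHUEA,
# 2H-perfluoro-2-octenoic acid); a molecular-weight ratio converts the
# mass-concentration slopes to a molar-response ratio.

#' Create a compound registry
#'
#' A compound registry holds the identity and molecular weight of every
#' analyte.  The molecular weight enters the relative-ionization-efficiency
#' formula as the mass-to-molar conversion term.
#'
#' @param id character vector of unique short identifiers.
#' @param name free-text compound names (defaults to `id`).
#' @param mw molecular weights in g/mol; must be positive.
#'
#' @return A data frame of class `compound_registry` with columns `id`,
#'   `name`, `mw`.
#' @export
#'
#' @examples
#' compound_registry(c("PFOA", "FHUEA"), mw = c(414.07, 358.09))
compound_registry <- function(id, name = id, mw) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("compound ids must be unique; duplicated: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  mw <- as.numeric(mw)
  if (length(mw) != length(id)) stop("`mw` must match `id` in length")
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    stop("molecular weights must be finite and positive")
  }
  structure(
    data.frame(id = id, name = as.character(name), mw = mw,
               stringsAsFactors = FALSE),
    class = c("compound_registry", "data.frame")
  )
}

registry_mw <- function(registry, id) {
  i <- match(id, registry$id)
  if (anyNA(i)) {
    stop("compound(s) not in registry: ",
         paste(id[is.na(i)], collapse = ", "))
  }
  registry$mw[i]
}

#' Create a calibration series
#'
#' A series of standard-solution concentrations (ng/mL) with the measured
#' full-scan peak areas for one compound.
#'
#' @param compound_id compound identifier.
#' @param levels mass concentrations in ng/mL, strictly positive.
#' @param areas peak areas (arbitrary counts), same length as `levels`.
#'
#' @return A list of class `calibration_series`.
#' @export
calibration_series <- function(compound_id, levels, areas) {
  levels <- as.numeric(levels)
  areas <- as.numeric(areas)
  if (length(levels) != length(areas)) {
    stop("`levels` and `areas` must have equal length")
  }
  if (any(!is.finite(levels)) || any(levels <= 0)) {
    stop("concentration levels must be finite and strictly positive")
  }
  if (any(!is.finite(areas))) {
    stop("non-finite peak area in series for ", compound_id)
  }
  structure(
    list(compound_id = as.character(compound_id), levels = levels,
         areas = areas),
    class = "calibration_series"
  )
}

#' Fit a calibration line for one compound
#'
#' Ordinary least squares of peak area on mass concentration, with a free
#' intercept.  The slope is the compound's (absolute) ionization efficiency;
#' the intercept is estimated and reported but never used when inverting
#' predicted efficiencies into concentrations.
#'
#' @param series a [calibration_series()].
#'
#' @return A list of class `calibration_fit` with elements `compound_id`,
#'   `slope` (area per ng/mL), `intercept` (area) and `r2` (squared
#'   correlation of fitted and observed areas).
#' @export
#'
#' @examples
#' fit_calibration(calibration_series("X", c(1, 2, 5), c(2, 4, 10)))
fit_calibration <- function(series) {
  stopifnot(inherits(series, "calibration_series"))
  if (length(unique(series$levels)) < 2) {
    stop("degenerate calibration series for ", series$compound_id,
         ": need at least 2 distinct concentration levels")
  }
  fit <- stats::lm(area ~ level,
                   data = data.frame(level = series$levels,
                                     area = series$areas))
  co <- stats::coef(fit)
  r2 <- if (stats::var(series$areas) == 0) {
    1  # flat areas reproduced exactly by a flat line
  } else {
    stats::cor(stats::fitted(fit), series$areas)^2
  }
  structure(
    list(compound_id = series$compound_id,
         slope = unname(co["level"]),
         intercept = unname(co["(Intercept)"]),
         r2 = r2),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> %s: slope %.6g, intercept %.6g, R2 %.4f\n",
              x$compound_id, x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Experimental relative log10 ionization efficiency
#'
#' Relates a compound's calibration slope to the anchor's:
#' \deqn{\mathrm{logIE} = \log_{10}\!\left(\frac{S}{S_\mathrm{anchor}}
#'   \cdot \frac{M_\mathrm{anchor}}{M}\right)}
#' where \eqn{S} are slopes in area per (ng/mL) and \eqn{M} molecular
#' weights in g/mol.  The molecular-weight ratio converts the mass-based
#' slopes into a molar response ratio.  The anchor's own value is exactly 0.
#'
#' @param fit,anchor_fit [fit_calibration()] results for the compound and
#'   the anchor.
#' @param compound,anchor single rows (or id/mw lists) from a
#'   [compound_registry()]; only `mw` is used, `id` for messages.
#'
#' @return A list of class `relative_ie` with `compound_id`, `log_ie`
#'   (dimensionless, log10 relative to anchor) and `source = "experimental"`.
#' @export
relative_log_ie <- function(fit, compound, anchor_fit, anchor) {
  for (f in list(fit, anchor_fit)) {
    if (!is.finite(f$slope) || f$slope <= 0) {
      stop("non-positive calibration slope for ", f$compound_id,
           "; cannot form a log ionization efficiency")
    }
  }
  log_ie <- log10((fit$slope / anchor_fit$slope) *
                    (anchor$mw / compound$mw))
  structure(
    list(compound_id = fit$compound_id, log_ie = log_ie,
         source = "experimental"),
    class = "relative_ie"
  )
}

#' Invert a predicted ionization efficiency into a concentration
#'
#' Given a measured peak area and a (predicted or experimental) relative
#' log10 ionization efficiency, the concentration is recovered through the
#' anchor's calibration slope:
#' \deqn{C_\mathrm{pred} = \frac{A \, M_\mathrm{anchor}}
#'   {10^{\mathrm{logIE}} \, S_\mathrm{anchor} \, M}}
#' This is a slope-only inversion: calibration intercepts are deliberately
#' ignored, which is why predictions at concentrations comparable to
#' intercept/slope carry extra bias.
#'
#' @param area measured peak area, non-negative.
#' @param pred a `relative_ie` (or any list with a `log_ie` element).
#' @param compound,anchor registry rows supplying molecular weights.
#' @param anchor_fit the anchor's `calibration_fit`.
#'
#' @return Predicted mass concentration in ng/mL.
#' @export
predict_concentration <- function(area, pred, compound, anchor_fit, anchor) {
  if (!is.finite(anchor_fit$slope) || anchor_fit$slope <= 0) {
    stop("anchor ", anchor_fit$compound_id, " has a non-positive slope")
  }
  if (any(area < 0)) stop("peak area must be non-negative")
  area * anchor$mw / (10^pred$log_ie * anchor_fit$slope * compound$mw)
}

#' Fit calibrations and compute experimental IEs for a whole study
#'
#' Convenience wrapper: fits every compound's calibration line and derives
#' the anchor-relative experimental log10 ionization efficiency.
#'
#' @param series_list list of [calibration_series()] objects.
#' @param registry a [compound_registry()].
#' @param anchor_id identifier of the anchor compound; must have a fitted
#'   series with a positive slope.
#'
#' @return A data frame with columns `compound_id`, `slope`, `intercept`,
#'   `r2`, `exp_log_ie`.
#' @export
calibrate_study <- function(series_list, registry, anchor_id = "FHUEA") {
  fits <- lapply(series_list, fit_calibration)
  ids <- vapply(fits, `[[`, character(1), "compound_id")
  names(fits) <- ids
  if (!anchor_id %in% ids) {
    stop("anchor compound '", anchor_id, "' has no calibration series")
  }
  anchor_fit <- fits[[anchor_id]]
  anchor_row <- list(id = anchor_id, mw = registry_mw(registry, anchor_id))
  out <- lapply(fits, function(f) {
    cmp <- list(id = f$compound_id,
                mw = registry_mw(registry, f$compound_id))
    rie <- relative_log_ie(f, cmp, anchor_fit, anchor_row)
    data.frame(compound_id = f$compound_id, slope = f$slope,
               intercept = f$intercept, r2 = f$r2,
               exp_log_ie = rie$log_ie, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a calibration table
#'
#' Expects delimited text with columns `compound_id`, `level_ng_per_mL`,
#' `area`, one calibration point per row.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return A list of [calibration_series()], one per compound, in first
#'   appearance order.
#' @export
read_calibration_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("compound_id", "level_ng_per_mL", "area")
  if (!all(need %in% names(df))) {
    stop("calibration table must have columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(df$compound_id)
  lapply(ids, function(id) {
    d <- df[df$compound_id == id, , drop = FALSE]
    calibration_series(id, d$level_ng_per_mL, d$area)
  })
}

#' Read a compound registry table
#'
#' Delimited text with columns `id`, `mw` and optionally `name`.
#'
#' @inheritParams read_calibration_table
#' @return A [compound_registry()].
#' @export
read_registry_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("id", "mw") %in% names(df))) {
    stop("registry table must have columns `id` and `mw`")
  }
  nm <- if ("name" %in% names(df)) df$name else df$id
  compound_registry(df$id, nm, df$mw)
}
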