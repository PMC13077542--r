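# Synthetic study generator.
#
# Emulates the three inputs of a relative-ionization-efficiency study so the
# whole pipeline is testable without a descriptor calculator or instrument
# data: (a) a compounds x descriptors matrix with correlated blocks and
# planted missing / near-constant columns, (b) a latent smooth nonlinear
# log10-IE function of a small informative descriptor subset, and (c) noisy
# linear calibration series whose slopes encode those IEs.
#
# All randomness flows from the single config seed: the seed initialises one
# RNG draw of per-stage sub-seeds, so each stage is independently
# reproducible.

#' Configuration for the synthetic study generator
#'
#' Defaults mirror a 50-compound PFAS calibration study: six standard
#' levels from 0.2 to 10 ng/mL, a descriptor table wide relative to the
#' number of compounds (200 columns for speed, standing in for a full
#' PaDEL export), 18 informative descriptors, and a few percent of
#' multiplicative area noise.
#'
#' @param n_compounds number of compounds (the first is the anchor FHUEA).
#' @param n_descriptors total descriptor columns.
#' @param n_informative number of descriptors that generate the latent IE.
#' @param informative_correlation pairwise correlation among informative
#'   descriptors within a latent-factor group; length 1 or 2 (primary,
#'   secondary factor).  Informative descriptors are noisy proxies of two
#'   latent molecular factors (think fluorinated chain length and
#'   head-group character), mirroring how many PaDEL descriptors track the
#'   same underlying structural property; the defaults sit below the 0.8
#'   cleaning cutoff so the generative signal survives the cascade.
#' @param ie_span total spread of the anchor-relative log10 IE values
#'   (log10 units); 2.0 corresponds to a 100-fold ionization-efficiency
#'   range across the compound set.
#' @param ie_mode `"nonlinear"` (saturating + interaction terms, the
#'   default), `"linear"` (for linear-model sanity checks) or `"step"`
#'   (threshold + interaction dominated, the regime where tree ensembles
#'   should clearly beat linear models).
#' @param block_correlation pairwise correlation inside planted descriptor
#'   blocks, in [0, 1).
#' @param block_size,block_fraction size of each correlated block and the
#'   fraction of non-informative, non-planted columns organised in blocks.
#' @param nzv_fraction fraction of columns made near-constant.
#' @param missing_fraction fraction of columns given missing cells.
#' @param ie_noise_sd Gaussian noise on the latent log10 IE (log10 units).
#' @param calib_levels calibration levels, ng/mL.
#' @param area_noise_cv multiplicative CV of peak-area noise.
#' @param intercept_scale calibration intercepts are drawn as
#'   |N(0, intercept_scale * slope)|; 0 forces lines through the origin.
#' @param anchor_slope absolute slope of the anchor compound (area per
#'   ng/mL); an arbitrary instrument-response scale.
#' @param seed integer master seed.
#'
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 50, n_descriptors = 200,
                             n_informative = 18,
                             informative_correlation = 0.6,
                             ie_mode = c("nonlinear", "linear", "step"),
                             ie_span = 2,
                             block_correlation = 0.9,
                             block_size = 4, block_fraction = 0.4,
                             nzv_fraction = 0.1, missing_fraction = 0.05,
                             ie_noise_sd = 0.03,
                             calib_levels = c(0.2, 0.5, 1, 2, 5, 10),
                             area_noise_cv = 0.02, intercept_scale = 0.05,
                             anchor_slope = 1e5, seed = 1) {
  cfg <- list(n_compounds = n_compounds, n_descriptors = n_descriptors,
              n_informative = n_informative,
              informative_correlation = rep_len(informative_correlation, 2),
              ie_mode = match.arg(ie_mode), ie_span = ie_span,
              block_correlation = block_correlation,
              block_size = block_size, block_fraction = block_fraction,
              nzv_fraction = nzv_fraction,
              missing_fraction = missing_fraction,
              ie_noise_sd = ie_noise_sd, calib_levels = calib_levels,
              area_noise_cv = area_noise_cv,
              intercept_scale = intercept_scale,
              anchor_slope = anchor_slope, seed = as.integer(seed))
  if (cfg$n_informative < 1 || cfg$n_informative > cfg$n_descriptors) {
    stop("n_informative must be between 1 and n_descriptors")
  }
  if (cfg$nzv_fraction + cfg$missing_fraction >= 1) {
    stop("nzv_fraction + missing_fraction must be < 1")
  }
  if (cfg$block_correlation < 0 || cfg$block_correlation >= 1) {
    stop("block_correlation must be in [0, 1)")
  }
  if (any(cfg$informative_correlation < 0) ||
      any(cfg$informative_correlation >= 1)) {
    stop("informative_correlation must be in [0, 1)")
  }
  if (cfg$ie_span <= 0) stop("ie_span must be positive")
  if (cfg$ie_noise_sd < 0 || cfg$area_noise_cv < 0 ||
      cfg$intercept_scale < 0) {
    stop("noise parameters must be non-negative")
  }
  structure(cfg, class = "generator_config")
}

stage_seeds <- function(cfg) {
  set.seed(cfg$seed)
  stats::setNames(sample.int(2^31 - 2, 6),
                  c("layout", "values", "ie_fun", "ie_noise",
                    "compounds", "calib"))
}

#' Generate a synthetic descriptor matrix
#'
#' Non-informative columns are organised partly into correlated Gaussian
#' blocks; `nzv_fraction` of columns are made near-constant and
#' `missing_fraction` are given missing cells.  Informative columns are
#' mutually independent and never planted with missing values, so the
#' cleaning cascade cannot remove the generative signal.
#'
#' @param cfg a [generator_config()].
#' @return list with `matrix` (the raw descriptor matrix, compounds in
#'   rows) and `truth`, a `synthetic_truth` list recording the informative
#'   feature names and values, the planted column sets, the generative
#'   coefficient spec and the stage seeds.
#' @export
generate_descriptors <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  seeds <- stage_seeds(cfg)
  n <- cfg$n_compounds
  p <- cfg$n_descriptors
  cols <- sprintf("D%04d", seq_len(p))
  ids <- c("FHUEA", sprintf("PFAS%02d", seq_len(n)[-1]))

  set.seed(seeds["layout"])
  n_nzv <- round(cfg$nzv_fraction * p)
  n_miss <- round(cfg$missing_fraction * p)
  pool <- sample(cols)                      # random column roles
  take <- function(x, k) if (k > 0) x[-seq_len(k)] else x
  informative <- sort(pool[seq_len(cfg$n_informative)])
  rest <- take(pool, cfg$n_informative)
  nzv_cols <- sort(rest[seq_len(n_nzv)])
  rest <- take(rest, n_nzv)
  miss_cols <- sort(rest[seq_len(n_miss)])
  rest <- take(rest, n_miss)
  n_block_cols <- floor(length(rest) * cfg$block_fraction /
                          cfg$block_size) * cfg$block_size
  block_cols <- rest[seq_len(n_block_cols)]
  blocks <- split(block_cols,
                  rep(seq_len(n_block_cols / cfg$block_size),
                      each = cfg$block_size))

  set.seed(seeds["values"])
  m <- matrix(stats::rnorm(n * p), nrow = n, dimnames = list(ids, cols))
  # informative descriptors: noisy proxies of two latent molecular
  # factors, the primary one carrying ~2/3 of the proxies
  k <- cfg$n_informative
  k1 <- if (k >= 2) ceiling(k / 2) else k
  informative_groups <- list(primary = informative[seq_len(k1)],
                             secondary = informative[-seq_len(k1)])
  for (gi in seq_along(informative_groups)) {
    g <- informative_groups[[gi]]
    if (length(g) == 0) next
    rho_i <- cfg$informative_correlation[gi]
    shared <- stats::rnorm(n)
    m[, g] <- sqrt(rho_i) * shared +
      sqrt(1 - rho_i) * matrix(stats::rnorm(n * length(g)), nrow = n)
  }
  # equicorrelated blocks: shared factor + independent remainder
  rho <- cfg$block_correlation
  for (b in blocks) {
    shared <- stats::rnorm(n)
    m[, b] <- sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(stats::rnorm(n * length(b)), nrow = n)
  }
  # near-constant columns: zeros with a handful of ones
  k_hot <- max(1L, round(0.04 * n))
  for (cc in nzv_cols) {
    x <- numeric(n)
    x[sample(n, k_hot)] <- 1
    m[, cc] <- x
  }
  # missing cells on designated columns (at least one per column)
  for (cc in miss_cols) {
    m[sample(n, max(1L, round(0.05 * n))), cc] <- NA_real_
  }

  truth <- structure(
    list(cfg = cfg, seeds = seeds, compound_ids = ids,
         informative_features = informative,
         informative_groups = informative_groups,
         informative_values = m[, informative, drop = FALSE],
         nzv_cols = nzv_cols, missing_cols = miss_cols, blocks = blocks),
    class = "synthetic_truth")
  list(matrix = m, truth = truth)
}

# Latent IE function: smooth function of the standardized group means of
# the observed informative proxies.  Deterministic given the descriptor
# values, so a model seeing all proxies faces no irreducible attenuation.
ie_function_spec <- function(cfg) {
  switch(cfg$ie_mode,
    nonlinear = list(mode = "nonlinear", w_sat = 0.3, rate = 1.5,
                     w2 = 0.85, w_int = 0.15),
    linear = list(mode = "linear", w_sat = 0, rate = 1.5, w2 = 0.85,
                  w_int = 0),
    step = list(mode = "step", w1 = 0.5, w_step1 = 1, thr1 = 0,
                w_step2 = 0.8, thr2 = -0.3, w_int = 0.5))
}

eval_ie_function <- function(spec, V, groups) {
  std_mean <- function(cols) {
    if (length(cols) == 0) return(numeric(nrow(V)))
    u <- rowMeans(V[, cols, drop = FALSE])
    s <- stats::sd(u)
    if (s == 0) u - mean(u) else (u - mean(u)) / s
  }
  u1 <- std_mean(groups$primary)
  u2 <- std_mean(groups$secondary)
  if (identical(spec$mode, "step")) {
    spec$w1 * u1 + spec$w_step1 * (u1 > spec$thr1) +
      spec$w_step2 * (u2 > spec$thr2) + spec$w_int * u1 * u2
  } else {
    u1 + spec$w_sat * tanh(spec$rate * u1) + spec$w2 * u2 +
      spec$w_int * u1 * u2
  }
}

#' Generate the latent relative log10 IE values
#'
#' The latent log10 IE is a smooth function of the two latent molecular
#' factors, evaluated through the standardized means of their observed
#' descriptor proxies: a dominant monotone term with a saturating
#' component in the primary factor, a weaker linear secondary term and a
#' mild interaction (`ie_mode = "linear"` drops the nonlinear pieces).
#' Values are rescaled so the anchor-relative log10 IEs span `ie_span`
#' (default 2, i.e. a 100-fold IE range, staying within the \[-1.5, 1.5\]
#' band typical of anchor-relative PFAS efficiencies), then Gaussian noise
#' of sd `ie_noise_sd` is added.  The anchor's (first compound's) value is
#' exactly 0 by construction.
#'
#' @param truth a `synthetic_truth` from [generate_descriptors()].
#' @param cfg the same [generator_config()].
#' @return the `truth` list extended with `ie_spec`, `true_log_ie`
#'   (anchor-relative, noisy) and `noiseless_log_ie`.
#' @export
generate_log_ie <- function(truth, cfg = truth$cfg) {
  spec <- ie_function_spec(cfg)
  f <- eval_ie_function(spec, truth$informative_values,
                        truth$informative_groups)
  rel <- f - f[1]                      # anchor-relative
  scale <- cfg$ie_span / diff(range(rel))
  rel <- rel * scale
  set.seed(truth$seeds["ie_noise"])
  noise <- stats::rnorm(length(rel), 0, cfg$ie_noise_sd)
  noise[1] <- 0                        # the anchor's self-IE is exactly 0
  truth$ie_spec <- spec
  truth$ie_scale <- scale
  truth$noiseless_log_ie <- stats::setNames(rel, truth$compound_ids)
  truth$true_log_ie <- stats::setNames(rel + noise, truth$compound_ids)
  truth
}

#' Generate compound registry, slopes and noisy calibration series
#'
#' Molecular weights are drawn uniformly in 250-700 g/mol (the anchor is
#' fixed at 358.1, the molecular weight of FHUEA).  True slopes follow from
#' the latent IEs by inverting the relative-IE definition, and areas are
#' `intercept + slope * level * (1 + eps)` with `eps ~ N(0, area_noise_cv)`.
#'
#' @inheritParams generate_log_ie
#' @return the `truth` list extended with `registry`, `true_slopes`,
#'   `true_intercepts` and `calibration` (a list of
#'   [calibration_series()]).
#' @export
generate_calibration <- function(truth, cfg = truth$cfg) {
  stopifnot(!is.null(truth$true_log_ie))
  n <- cfg$n_compounds
  set.seed(truth$seeds["compounds"])
  mw <- c(358.1, stats::runif(n - 1, 250, 700))
  registry <- compound_registry(truth$compound_ids, mw = mw)
  # invert logIE = log10((S/Sa) * (MWa/MW))  =>  S = Sa 10^logIE MW/MWa
  slopes <- cfg$anchor_slope * 10^truth$true_log_ie * mw / mw[1]
  intercepts <- abs(stats::rnorm(n, 0, cfg$intercept_scale * slopes))
  set.seed(truth$seeds["calib"])
  series <- lapply(seq_len(n), function(i) {
    eps <- stats::rnorm(length(cfg$calib_levels), 0, cfg$area_noise_cv)
    areas <- intercepts[i] + slopes[i] * cfg$calib_levels * (1 + eps)
    calibration_series(truth$compound_ids[i], cfg$calib_levels, areas)
  })
  truth$registry <- registry
  truth$true_slopes <- stats::setNames(slopes, truth$compound_ids)
  truth$true_intercepts <- stats::setNames(intercepts, truth$compound_ids)
  truth$calibration <- series
  truth
}

#' Generate a complete synthetic IE study
#'
#' Runs [generate_descriptors()], [generate_log_ie()] and
#' [generate_calibration()] in sequence.
#'
#' @param cfg a [generator_config()].
#' @return list with `descriptors` (raw matrix), `truth` (fully populated),
#'   `registry` and `calibration` for convenience.
#' @export
simulate_ie_study <- function(cfg = generator_config()) {
  g <- generate_descriptors(cfg)
  truth <- generate_log_ie(g$truth, cfg)
  truth <- generate_calibration(truth, cfg)
  list(descriptors = g$matrix, truth = truth,
       registry = truth$registry, calibration = truth$calibration)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits the descriptor table, calibration table and registry in the same
#' delimited layouts the readers consume, plus a JSON truth sidecar, so the
#' generator doubles as a fixture factory for the command-line workflow.
#'
#' @param study result of [simulate_ie_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_descriptor_table(study$descriptors,
                         file.path(dir, "descriptors.csv"))
  calib <- do.call(rbind, lapply(study$calibration, function(s) {
    data.frame(compound_id = s$compound_id, level_ng_per_mL = s$levels,
               area = s$areas)
  }))
  utils::write.table(calib, file.path(dir, "calibration.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(study$registry, file.path(dir, "registry.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  truth <- study$truth
  sidecar <- list(informative_features = truth$informative_features,
                  true_log_ie = as.list(truth$true_log_ie),
                  true_slopes = as.list(truth$true_slopes),
                  seed = truth$cfg$seed)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
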