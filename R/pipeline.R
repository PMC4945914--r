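#' Default binarizer parameter grids
#'
#' Threshold sweeps 0.05 to 0.95 in steps of 0.05 (clipped downstream to
#' the observed weight range); density sweeps 0.05 to 0.50 in steps of
#' 0.05. MST and MCC are parameter-free.
#'
#' @param binarizer binarizer name.
#' @return Numeric grid (or `NA` for mst/mcc).
#' @export
default_grid <- function(binarizer) {
  switch(match.arg(binarizer, binarizer_names()),
    threshold = seq(0.05, 0.95, by = 0.05),
    density = seq(0.05, 0.50, by = 0.05),
    mst = NA_real_,
    mcc = NA_real_
  )
}

#' Run the full comparison pipeline on a synthetic cohort
#'
#' Executes synth -> preprocess -> connectivity -> binarize -> metrics ->
#' group comparison for every requested estimator x binarizer x metric
#' combination and assembles the report. The configuration is a nested
#' list; unspecified entries fall back to the defaults below. Fully
#' deterministic for a fixed config.
#'
#' @param config list with optional entries: `cohort` (a [cohort_spec()];
#'   default [two_group_cohort_spec()]), `preproc` (list: `epoch_len_s`,
#'   `band_hz`, `abs_thresh_uV`, `trans_thresh_uV`, `fir_order`),
#'   `estimators` (character vector), `binarizers` (character vector),
#'   `metrics` (character vector), `grids` (named list binarizer -> grid),
#'   `alpha`, `p_adjust`, `sl` (an [sl_params()]), `seed`.
#' @param recordings optional pre-generated list of [recording()] objects
#'   (bypasses the synth stage; group labels must be present).
#' @return A list with `report` (the [assemble_report()] output), `sweeps`,
#'   `connectivity` (per estimator, per subject), and the fully resolved
#'   `config`.
#' @export
run_pipeline <- function(config = list(), recordings = NULL) {
  cfg <- resolve_config(config)
  recs <- recordings %||% generate_cohort(cfg$cohort)
  groups <- vapply(recs, function(r) r$group, character(1))
  if (any(groups == "unknown")) stop_fc("group labels required for group statistics")
  pp <- cfg$preproc
  ess <- lapply(recs, function(r) {
    preprocess(r, epoch_len_s = pp$epoch_len_s, band_hz = pp$band_hz,
               abs_thresh_uV = pp$abs_thresh_uV,
               trans_thresh_uV = pp$trans_thresh_uV, fir_order = pp$fir_order)
  })
  conn <- list()
  for (est in cfg$estimators) {
    conn[[est]] <- lapply(ess, subject_connectivity, estimator = est,
                          sl = cfg$sl, band_hz = pp$band_hz)
  }
  sweeps <- list()
  for (est in cfg$estimators) {
    for (bin in cfg$binarizers) {
      grid <- cfg$grids[[bin]] %||% default_grid(bin)
      for (met in cfg$metrics) {
        sweeps[[sprintf("%s_%s_%s", est, bin, met)]] <-
          sweep_metric(conn[[est]], groups, bin, grid, met)
      }
    }
  }
  report <- assemble_report(sweeps, alpha = cfg$alpha, p_adjust = cfg$p_adjust)
  list(report = report, sweeps = sweeps, connectivity = conn, config = cfg)
}

resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    cohort = NULL,
    preproc = list(epoch_len_s = 1, band_hz = c(7, 13), abs_thresh_uV = 100,
                   trans_thresh_uV = 50, fir_order = NULL),
    estimators = "correlation",
    binarizers = c("density", "threshold", "mst", "mcc"),
    metrics = "global_efficiency",
    grids = list(),
    alpha = 0.05,
    p_adjust = "none",
    sl = sl_params(),
    seed = 1L
  )
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$cohort)) cfg$cohort <- two_group_cohort_spec(seed = cfg$seed)
  cfg$estimators <- match.arg(cfg$estimators, estimator_names(), several.ok = TRUE)
  cfg$binarizers <- match.arg(cfg$binarizers, binarizer_names(), several.ok = TRUE)
  cfg$metrics <- match.arg(cfg$metrics, metric_names(), several.ok = TRUE)
  cfg
}
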