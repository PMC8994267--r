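# Worked example on a publicly archived wolf summer telemetry dataset
# (2-h GPS fixes with town-distance and trail-density covariates). The data
# are not bundled here; point `data_dir` at a local copy.

#' Refit the wolf summer movement and selection models
#'
#' Expects two CSV files extracted from the archived wolf summer dataset:
#'
#' * `wolf_summer_steps.csv`: one row per observed 2-h step with columns
#'   `animal_id`, `seg_id`, `l` (m), `theta` (rad, NA at segment starts),
#'   `hour`, `c_hour`, `d_town` (capped-linear distance, 5 km), and
#'   `trail_density` (km/km^2) at the step start;
#' * `wolf_summer_strata.csv`: candidate-level rows with `stratum`,
#'   `animal_id`, `used`, `p_fast`, `c_hour`, `trail_density`,
#'   `trail_density_sq`, plus any further selection covariates.
#'
#' Refits the two-state HMM (reporting the trail-road density transition
#' coefficients) and the conditional-logistic SSF (reporting the quadratic
#' trail-density selection coefficient).
#'
#' @param data_dir directory containing the two CSV files.
#' @param ... passed to [fit_hmm()].
#' @return list with `hmm_fit`, `ssf_fit`, `trail_density_slow_to_fast`,
#'   `trail_density_fast_to_slow`, `trail_density_sq_beta`.
#' @export
fit_wolf_summer_example <- function(data_dir, ...) {
  steps_csv <- file.path(data_dir, "wolf_summer_steps.csv")
  strata_csv <- file.path(data_dir, "wolf_summer_strata.csv")
  if (!file.exists(steps_csv) || !file.exists(strata_csv))
    stop("wolf summer data not found under '", data_dir,
         "'; obtain the archived wolf summer dataset and extract ",
         "wolf_summer_steps.csv / wolf_summer_strata.csv", call. = FALSE)
  steps <- readr::read_csv(steps_csv, show_col_types = FALSE, progress = FALSE)
  hmm_fit <- fit_hmm(steps, ...)
  strata <- readr::read_csv(strata_csv, show_col_types = FALSE, progress = FALSE)
  ssf_fit <- fit_conditional_logit(as_ssf_data(strata))
  list(hmm_fit = hmm_fit, ssf_fit = ssf_fit,
       trail_density_slow_to_fast = hmm_fit$params$beta["slow_to_fast", "trail_density"],
       trail_density_fast_to_slow = hmm_fit$params$beta["fast_to_slow", "trail_density"],
       trail_density_sq_beta = unname(ssf_fit$beta["trail_density_sq"]))
}
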