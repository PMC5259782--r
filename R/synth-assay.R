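#' Configuration for the Michaelis-Menten assay simulator
#'
#' Describes the statistical structure the kinetics analysis assumes:
#' Michaelis-Menten mean velocities per enzyme variant, multiplicative
#' effector action on `Vmax` and `Km`, and multiplicative Gaussian
#' replicate noise (a coefficient of variation, matching the roughly
#' proportional SDs seen in effector panels).
#'
#' @param variants tibble/data frame with columns `variant`, `vmax`
#'   (units; i.e. µmol min^-1 per assay) and `km_mM`.
#' @param substrate_mM substrate concentration grid (> 0).
#' @param effectors optional tibble with columns `effector`,
#'   `vmax_factor`, `km_factor`; the mock (factors 1) is always included.
#' @param cv coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param n_reps replicates per condition.
#' @param protein_pmol,protein_ug enzyme amount metadata carried into the
#'   output (defaults 4 pmol / 0.6 µg).
#' @param seed RNG seed (required).
#' @return a list of class `assay_sim_config`.
#' @export
assay_sim_config <- function(variants,
                             substrate_mM = c(0.125, 0.25, 0.5, 1, 2, 4),
                             effectors = NULL,
                             cv = 0, n_reps = 3L,
                             protein_pmol = 4, protein_ug = 0.6,
                             seed) {
  if (missing(seed)) abort("seed is required")
  need <- c("variant", "vmax", "km_mM")
  if (!all(need %in% names(variants))) {
    abort("variants needs columns variant, vmax, km_mM")
  }
  if (any(variants$vmax <= 0) || any(variants$km_mM <= 0)) {
    abort("kinetic parameters must be > 0")
  }
  if (any(substrate_mM <= 0)) abort("substrate concentrations must be > 0")
  if (cv < 0) abort("cv must be >= 0")
  if (n_reps < 1L) abort("n_reps must be >= 1")
  if (!is.null(effectors)) {
    if (!all(c("effector", "vmax_factor", "km_factor") %in%
             names(effectors))) {
      abort("effectors needs columns effector, vmax_factor, km_factor")
    }
    if (any(effectors$effector == "MOCK")) {
      abort("do not list MOCK among effectors; it is added automatically")
    }
  }
  structure(list(variants = tibble::as_tibble(variants),
                 substrate_mM = substrate_mM,
                 effectors = if (is.null(effectors)) NULL else
                   tibble::as_tibble(effectors),
                 cv = cv, n_reps = as.integer(n_reps),
                 protein_pmol = protein_pmol, protein_ug = protein_ug,
                 seed = as.integer(seed)),
            class = "assay_sim_config")
}

#' Simulate substrate-titration assay data
#'
#' Velocities are drawn as
#' \deqn{v = \frac{V_{max} f_V \, [S]}{K_m f_K + [S]} (1 + cv\,z)}
#' with `z` standard normal per replicate and `(f_V, f_K)` the effector's
#' multiplicative factors (1 for mock). Negative draws are truncated at 0.
#'
#' @param config an [assay_sim_config()].
#' @return a list with
#'   * `rates` — long tibble: `variant`, `effector`, `substrate_mM`,
#'     `replicate`, `velocity` (units), plus `protein_pmol`,
#'     `protein_ug`;
#'   * `truth` — tibble of the per-condition true parameters
#'     (`variant`, `effector`, `true_vmax`, `true_km_mM`).
#' @export
generate_assay_dataset <- function(config) {
  stopifnot(inherits(config, "assay_sim_config"))
  set.seed(config$seed)
  eff <- dplyr::bind_rows(
    tibble::tibble(effector = "MOCK", vmax_factor = 1, km_factor = 1),
    config$effectors)
  grid <- tidyr::expand_grid(config$variants, eff,
                             substrate_mM = config$substrate_mM,
                             replicate = seq_len(config$n_reps))
  mu <- with(grid, vmax * vmax_factor * substrate_mM /
                     (km_mM * km_factor + substrate_mM))
  noise <- if (config$cv > 0) 1 + config$cv * stats::rnorm(nrow(grid)) else 1
  grid$velocity <- pmax(0, mu * noise)
  rates <- dplyr::select(grid, "variant", "effector", "substrate_mM",
                         "replicate", "velocity")
  rates$protein_pmol <- config$protein_pmol
  rates$protein_ug <- config$protein_ug
  truth <- dplyr::distinct(
    dplyr::transmute(grid, .data$variant, .data$effector,
                     true_vmax = .data$vmax * .data$vmax_factor,
                     true_km_mM = .data$km_mM * .data$km_factor))
  list(rates = rates, truth = truth)
}

#' Simulate a fixed-substrate effector panel
#'
#' Emulates a relative-activity panel: replicate velocities at one
#' (typically half-saturating) substrate concentration for a mock
#' condition and each effector, the effector acting as a multiplicative
#' activity factor (optionally pH-dependent: supply one row per
#' effector/pH).
#'
#' @param mock_velocity true mock velocity (units).
#' @param factors tibble with columns `effector`, `activity_factor`
#'   (effector velocity = `mock_velocity * activity_factor`); optional
#'   `pH` column for pH-dependent panels.
#' @param n_reps replicates per condition.
#' @param cv coefficient of variation of multiplicative noise.
#' @param seed RNG seed (required).
#' @return long tibble `effector`, (`pH`,) `replicate`, `velocity`,
#'   including `MOCK` rows (per pH if applicable).
#' @export
generate_effector_assay <- function(mock_velocity, factors, n_reps = 3L,
                                    cv = 0, seed) {
  if (missing(seed)) abort("seed is required")
  if (mock_velocity <= 0) abort("mock_velocity must be > 0")
  if (!all(c("effector", "activity_factor") %in% names(factors))) {
    abort("factors needs columns effector, activity_factor")
  }
  set.seed(as.integer(seed))
  by_ph <- "pH" %in% names(factors)
  mock <- tibble::tibble(effector = "MOCK", activity_factor = 1)
  if (by_ph) {
    mock <- tidyr::expand_grid(mock, pH = unique(factors$pH))
  }
  all_cond <- dplyr::bind_rows(mock, tibble::as_tibble(factors))
  out <- tidyr::expand_grid(all_cond, replicate = seq_len(n_reps))
  mu <- mock_velocity * out$activity_factor
  noise <- if (cv > 0) 1 + cv * stats::rnorm(nrow(out)) else 1
  out$velocity <- pmax(0, mu * noise)
  dplyr::select(out, -"activity_factor")
}

#' Simulate a unimodal pH or temperature activity profile
#'
#' Gaussian-shaped mean activity
#' `a(g) = max_activity * exp(-(g - peak)^2 / (2 width^2))` with optional
#' multiplicative noise; emulates the bell-shaped pH and temperature
#' response of an enzyme around its optimum.
#'
#' @param peak location of the optimum (should lie within `grid`; a peak
#'   outside the grid triggers a warning).
#' @param width Gaussian standard deviation, same units as `grid`;
#'   `Inf` gives a flat profile.
#' @param grid strictly increasing measurement grid (>= 3 points).
#' @param noise coefficient of variation of multiplicative noise.
#' @param seed RNG seed (required when `noise > 0`).
#' @param max_activity activity at the peak.
#' @return tibble with columns `grid`, `activity`, ready for
#'   [find_optimum()].
#' @export
generate_activity_profile <- function(peak, width, grid, noise = 0,
                                      seed = NULL, max_activity = 1) {
  if (length(grid) < 3L || any(diff(grid) <= 0)) {
    abort("grid must be strictly increasing with >= 3 points")
  }
  if (peak < min(grid) || peak > max(grid)) {
    warn("peak lies outside the measurement grid")
  }
  a <- if (is.infinite(width)) rep(max_activity, length(grid)) else
    max_activity * exp(-(grid - peak)^2 / (2 * width^2))
  if (noise > 0) {
    if (is.null(seed)) abort("seed is required when noise > 0")
    set.seed(as.integer(seed))
    a <- pmax(0, a * (1 + noise * stats::rnorm(length(grid))))
  }
  tibble::tibble(grid = grid, activity = a)
}

#' Linear A340 traces consistent with given velocities
#'
#' Inverts the coupled-assay relation used by [initial_rate()]: for each
#' velocity `v` (units), the trace falls at `slope = -v * 6.22 / volume`
#' absorbance min^-1 from `a0`, sampled on a regular time grid, with
#' optional additive Gaussian absorbance noise.
#'
#' @param rates tibble with a `velocity` column; all other columns are
#'   carried through as metadata.
#' @param duration_s,n_points time grid (default 60 s, 13 points).
#' @param a0 starting absorbance (default 1.0).
#' @param volume_ml,path_cm assay geometry (defaults 1, 1).
#' @param noise_sd additive absorbance noise SD (default 0).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return long tibble: metadata columns, `time_s`, `A340`.
#' @export
assay_traces <- function(rates, duration_s = 60, n_points = 13L,
                         a0 = 1.0, volume_ml = 1, path_cm = 1,
                         noise_sd = 0, seed = NULL) {
  if (!"velocity" %in% names(rates)) abort("rates needs a velocity column")
  if (noise_sd > 0) {
    if (is.null(seed)) abort("seed is required when noise_sd > 0")
    set.seed(as.integer(seed))
  }
  tgrid <- seq(0, duration_s, length.out = n_points)
  out <- tidyr::expand_grid(rates, time_s = tgrid)
  slope_per_s <- -out$velocity * EPSILON_NADH_340 * path_cm /
    volume_ml / 60
  a <- a0 + slope_per_s * out$time_s
  if (noise_sd > 0) a <- a + stats::rnorm(length(a), sd = noise_sd)
  out$A340 <- pmin(3, pmax(0, a))
  out
}
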