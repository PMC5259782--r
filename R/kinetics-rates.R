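# Extinction coefficient of NADH at 340 nm, mM^-1 cm^-1; the standard
# constant for malate-dehydrogenase-coupled assays read as A340 decrease.
EPSILON_NADH_340 <- 6.22

#' Initial reaction velocity from an A340 trace
#'
#' PEPC activity is read through a malate-dehydrogenase coupled assay in
#' which each turnover consumes one NADH, so the A340 absorbance falls
#' linearly during the initial phase. The velocity in enzyme units
#' (µmol NADH min^-1) is
#' \deqn{v = |slope| / (\epsilon \cdot l) \times V}
#' with slope in absorbance min^-1, \eqn{\epsilon = 6.22} mM^-1 cm^-1,
#' path length `l` in cm and assay volume `V` in mL.
#'
#' The slope is an ordinary least-squares fit over the chosen window:
#' `"max-linear-segment"` (default) uses the longest prefix of the trace
#' whose linear fit has r^2 >= `r2_min` (at least `min_points` points);
#' `"first-k-points"` uses the first `k` points. An increasing trace means
#' no NADH consumption (no reaction, or a mis-oriented trace): the velocity
#' is reported as 0 with a warning.
#'
#' @param trace data frame with columns `time_s` (strictly increasing
#'   seconds) and `A340`; at least 4 points.
#' @param window `"max-linear-segment"` or `"first-k-points"`.
#' @param k window size for `"first-k-points"`.
#' @param volume_ml assay volume in mL (default 1).
#' @param path_cm cuvette path length in cm (default 1).
#' @param r2_min,min_points linearity criterion for
#'   `"max-linear-segment"` (defaults 0.99 and 4).
#' @return tibble with `velocity_units` (µmol min^-1), `slope_per_min`,
#'   `r_squared`, `n_points`.
#' @export
initial_rate <- function(trace, window = c("max-linear-segment",
                                           "first-k-points"),
                         k = 5L, volume_ml = 1, path_cm = 1,
                         r2_min = 0.99, min_points = 4L) {
  window <- match.arg(window)
  if (!all(c("time_s", "A340") %in% names(trace))) {
    abort("trace needs columns time_s and A340")
  }
  t_s <- trace$time_s
  a <- trace$A340
  if (length(t_s) < 4L) abort("trace must have >= 4 points")
  if (any(diff(t_s) <= 0)) abort("time_s must be strictly increasing")
  if (any(a < 0 | a > 3)) abort("A340 outside [0, 3]")

  fit_prefix <- function(n) {
    tt <- t_s[seq_len(n)] / 60
    aa <- a[seq_len(n)]
    if (sd(aa) == 0) return(list(slope = 0, r2 = 1))
    f <- lm(aa ~ tt)
    ss_tot <- sum((aa - mean(aa))^2)
    list(slope = unname(coef(f)[[2]]),
         r2 = 1 - sum(stats::residuals(f)^2) / ss_tot)
  }

  if (window == "first-k-points") {
    if (k < 3L) abort("window must span >= 3 points")
    if (k > length(t_s)) abort("window longer than trace")
    best <- fit_prefix(k)
    n_used <- k
  } else {
    if (min_points > length(t_s)) abort("window longer than trace")
    n_used <- min_points
    best <- fit_prefix(min_points)
    for (n in seq(min_points + 1L, length(t_s))) {
      cand <- fit_prefix(n)
      if (cand$r2 >= r2_min) {
        best <- cand
        n_used <- n
      } else break
    }
  }
  slope <- best$slope
  if (slope > 1e-12) {
    warn("A340 increases over the window: no NADH consumption detected; velocity set to 0")
    v <- 0
  } else {
    v <- abs(slope) / (EPSILON_NADH_340 * path_cm) * volume_ml
  }
  tibble::tibble(velocity_units = v, slope_per_min = slope,
                 r_squared = best$r2, n_points = n_used)
}

#' Specific activity and implied molecular mass
#'
#' Converts a raw velocity (enzyme units, µmol min^-1) to specific
#' activity per mg and per pmol of enzyme, and reports the subunit mass
#' implied by the stated pmol/µg pair — a useful consistency check on
#' assay metadata (e.g. 4 pmol = 0.6 µg implies a 150 kDa subunit).
#'
#' @param velocity_units velocity in enzyme units.
#' @param pmol,ug amount of enzyme in the assay (both > 0).
#' @return tibble with `units_per_mg`, `units_per_pmol`,
#'   `implied_mass_kda`.
#' @export
specific_activity <- function(velocity_units, pmol, ug) {
  if (any(pmol <= 0) || any(ug <= 0)) abort("protein amounts must be > 0")
  tibble::tibble(
    units_per_mg = velocity_units / (ug / 1000),
    units_per_pmol = velocity_units / pmol,
    implied_mass_kda = ug * 1e6 / pmol / 1000
  )
}
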