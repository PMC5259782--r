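#' Relative activity of an effector condition versus mock
#'
#' Expresses each effector replicate as a percentage of the mock mean
#' (mock set at 100%), and reports mean, sample SD, replicate count, and —
#' when replicate counts match — a paired two-tailed t-test of the raw
#' velocities against mock.
#'
#' @param effector_reps numeric vector of replicate velocities under the
#'   effector.
#' @param mock_reps numeric vector of replicate velocities without
#'   effector; the mock mean must be > 0.
#' @return tibble with `relative_activity` (mean %), `sd`, `n`,
#'   `t_statistic`, `df`, `p_value` (test columns `NA` when replicate
#'   counts differ or `n < 2`).
#' @examples
#' relative_activity(c(0.852, 0.852, 0.852), c(1, 1, 1))
#' @export
relative_activity <- function(effector_reps, mock_reps) {
  if (!length(effector_reps) || !length(mock_reps)) {
    abort("need >= 1 replicate in each group")
  }
  mock_mean <- mean(mock_reps)
  if (mock_mean <= 0) abort("mock mean must be > 0")
  rel <- effector_reps / mock_mean * 100
  n <- length(rel)
  tt <- if (n >= 2L && n == length(mock_reps) &&
            !isTRUE(all.equal(effector_reps, mock_reps)) &&
            sd(effector_reps - mock_reps) > 0) {
    paired_t_test(effector_reps, mock_reps)
  } else {
    tibble::tibble(t_statistic = NA_real_, df = NA_real_,
                   p_value = NA_real_)
  }
  tibble::tibble(relative_activity = mean(rel),
                 sd = if (n >= 2L) sd(rel) else NA_real_,
                 n = n,
                 t_statistic = tt$t_statistic, df = tt$df,
                 p_value = tt$p_value)
}

#' Effector panel table
#'
#' Builds a Table-1-style report from long-format replicate velocities:
#' one row per effector condition with relative activity (% of mock,
#' mean ± SD), replicate count and paired t-test versus mock. The mock
#' row itself is included (100% by construction, tested against itself is
#' meaningless, so its test columns are `NA`).
#'
#' @param data data frame with columns `effector`, `replicate`,
#'   `velocity`; optionally `effector_mM` (carried through).
#' @param mock_label value of `effector` identifying the mock condition
#'   (default `"MOCK"`).
#' @return tibble, one row per effector.
#' @export
effector_table <- function(data, mock_label = "MOCK") {
  need <- c("effector", "replicate", "velocity")
  if (!all(need %in% names(data))) {
    abort("data needs columns effector, replicate, velocity")
  }
  if (!mock_label %in% data$effector) {
    abort(paste0("no mock condition (effector == \"", mock_label,
                 "\") in data"))
  }
  mock <- dplyr::arrange(
    dplyr::filter(data, .data$effector == mock_label), .data$replicate)
  out <- dplyr::group_modify(
    dplyr::group_by(data, .data$effector,
                    dplyr::across(dplyr::any_of("effector_mM"))),
    function(df, key) {
      df <- dplyr::arrange(df, .data$replicate)
      res <- relative_activity(df$velocity, mock$velocity)
      if (key$effector == mock_label) {
        # mock vs itself: 100% by definition, no test
        res$t_statistic <- NA_real_
        res$df <- NA_real_
        res$p_value <- NA_real_
      }
      res
    })
  dplyr::ungroup(out)
}

#' Locate the optimum of a pH or temperature activity profile
#'
#' Returns the grid value with the highest mean activity (argmax over the
#' measured grid; no interpolation). Ties are resolved to the lower grid
#' value with a message; a maximum at either end of the grid triggers a
#' "boundary optimum" warning since the true peak may lie outside the
#' measured range.
#'
#' @param profile data frame with columns `grid` (strictly increasing pH
#'   or temperature values, >= 3 points) and `activity` (mean activity);
#'   an optional `sd` column is ignored here.
#' @return tibble with `optimum` and `activity`.
#' @export
find_optimum <- function(profile) {
  if (!all(c("grid", "activity") %in% names(profile))) {
    abort("profile needs columns grid and activity")
  }
  g <- profile$grid
  a <- profile$activity
  if (length(g) < 3L) abort("profile needs >= 3 grid points")
  if (any(diff(g) <= 0)) abort("grid must be strictly increasing")
  best <- which(a == max(a))
  if (length(best) > 1L) {
    message("tied maxima at ", paste(g[best], collapse = ", "),
            "; reporting the lowest grid value")
  }
  i <- best[[1L]]
  if (i == 1L || i == length(g)) {
    warn("boundary optimum: maximum activity at the edge of the measured grid")
  }
  tibble::tibble(optimum = g[[i]], activity = a[[i]])
}

#' Compare effector inhibition across pH
#'
#' For one effector at one concentration assayed at two or more pH
#' values, tabulates the relative activity per pH and tests whether
#' inhibition is enhanced at higher pH (lower relative activity at the
#' higher pH). Each pH above the lowest is compared against the lowest pH:
#' the difference in mean relative activity (percentage points) and, when
#' replicate counts match, a paired t-test of the per-replicate relative
#' activities.
#'
#' @param data data frame with columns `pH`, `replicate`,
#'   `relative_activity` (per-replicate % of that pH's mock), all rows one
#'   effector/concentration; a constant `effector` column is allowed and
#'   carried through.
#' @return tibble, one row per pH above the reference: `pH_ref`, `pH`,
#'   `relative_ref`, `relative`, `delta` (points; negative = stronger
#'   inhibition at higher pH), `t_statistic`, `df`, `p_value`,
#'   `enhanced_at_higher_pH`.
#' @export
inhibition_vs_ph <- function(data) {
  need <- c("pH", "replicate", "relative_activity")
  if (!all(need %in% names(data))) {
    abort("data needs columns pH, replicate, relative_activity")
  }
  if ("effector" %in% names(data) &&
      length(unique(data$effector)) > 1L) {
    abort("data mixes effectors; filter to one effector/concentration first")
  }
  phs <- sort(unique(data$pH))
  if (length(phs) < 2L) abort("need >= 2 pH values")
  ref <- dplyr::arrange(dplyr::filter(data, .data$pH == phs[[1L]]),
                        .data$replicate)
  rows <- lapply(phs[-1L], function(p) {
    cur <- dplyr::arrange(dplyr::filter(data, .data$pH == p),
                          .data$replicate)
    delta <- mean(cur$relative_activity) - mean(ref$relative_activity)
    tt <- if (nrow(cur) == nrow(ref) && nrow(cur) >= 2L &&
              sd(cur$relative_activity - ref$relative_activity) > 0) {
      paired_t_test(cur$relative_activity, ref$relative_activity)
    } else {
      tibble::tibble(t_statistic = NA_real_, df = NA_real_,
                     p_value = NA_real_)
    }
    tibble::tibble(pH_ref = phs[[1L]], pH = p,
                   relative_ref = mean(ref$relative_activity),
                   relative = mean(cur$relative_activity),
                   delta = delta,
                   t_statistic = tt$t_statistic, df = tt$df,
                   p_value = tt$p_value,
                   enhanced_at_higher_pH = delta < 0)
  })
  dplyr::bind_rows(rows)
}
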