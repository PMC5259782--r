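test_that("initial rate converts a linear A340 slope into enzyme units", {
  t_s <- seq(0, 60, by = 5)
  trace <- data.frame(time_s = t_s, A340 = 1 - 0.0622 * t_s / 60)
  r <- initial_rate(trace)
  expect_equal(r$velocity_units, 0.01, tolerance = 1e-9)
  expect_equal(r$slope_per_min, -0.0622, tolerance = 1e-9)

  flat <- data.frame(time_s = t_s, A340 = rep(1, length(t_s)))
  expect_equal(initial_rate(flat)$velocity_units, 0)
  rising <- data.frame(time_s = t_s, A340 = 1 + 0.01 * t_s / 60)
  expect_warning(r2 <- initial_rate(rising), "increases")
  expect_equal(r2$velocity_units, 0)
})

test_that("initial-rate windows and validation behave", {
  t_s <- seq(0, 120, by = 10)
  # linear for 60 s, then the trace flattens (substrate exhaustion)
  a <- ifelse(t_s <= 60, 1 - 0.3 * t_s / 60, 0.7)
  trace <- data.frame(time_s = t_s, A340 = a)
  full <- initial_rate(trace)                   # longest linear prefix
  expect_equal(full$slope_per_min, -0.3, tolerance = 1e-6)
  expect_lt(full$n_points, length(t_s))
  firstk <- initial_rate(trace, window = "first-k-points", k = 4)
  expect_equal(firstk$n_points, 4L)
  expect_error(initial_rate(trace[1:3, ]), ">= 4 points")
  expect_error(initial_rate(trace, window = "first-k-points", k = 2),
               ">= 3 points")
  expect_error(initial_rate(data.frame(time_s = c(0, 1, 1, 2),
                                       A340 = c(1, 1, 1, 1))),
               "strictly increasing")
})

test_that("specific activity scales correctly and implies the subunit mass", {
  sa <- specific_activity(1.044e-3, pmol = 4, ug = 0.6)
  expect_equal(sa$units_per_mg, 1.74, tolerance = 1e-9)
  expect_equal(sa$implied_mass_kda, 150)
  expect_equal(specific_activity(1, 4, 0.6)$units_per_mg / 2,
               specific_activity(1, 8, 1.2)$units_per_mg)
  expect_error(specific_activity(1, 0, 0.6), "> 0")
})

test_that("both fitting routes recover noiseless parameters to machine precision", {
  d <- mm_data(2, 0.5)
  for (m in c("LB", "NLS")) {
    f <- fit_michaelis_menten(d, method = m)
    expect_equal(f$vmax, 2, tolerance = 1e-8)
    expect_equal(f$km, 0.5, tolerance = 1e-8)
    expect_equal(f$r_squared, 1, tolerance = 1e-8)
  }
  td <- tidy(fit_michaelis_menten(d))
  expect_equal(td$term, c("Vmax", "Km"))
  expect_equal(td$estimate, c(2, 0.5), tolerance = 1e-8)
})

test_that("LB and NLS agree on noiseless data for random true parameters", {
  set.seed(23)
  for (rep in 1:20) {
    vmax <- runif(1, 0.1, 10)
    km <- runif(1, 0.05, 5)
    d <- mm_data(vmax, km, s = km * c(0.25, 0.5, 1, 2, 4, 8))
    lb <- fit_michaelis_menten(d, method = "LB")
    nl <- fit_michaelis_menten(d, method = "NLS")
    expect_equal(lb$vmax, nl$vmax, tolerance = 1e-6)
    expect_equal(lb$km, nl$km, tolerance = 1e-6)
    expect_equal(lb$km, km, tolerance = 1e-6)
  }
})

test_that("fits are scale-equivariant in velocity", {
  d <- mm_data(1.5, 0.8)
  f1 <- fit_michaelis_menten(d)
  d$velocity <- d$velocity * 37
  f2 <- fit_michaelis_menten(d)
  expect_equal(f2$vmax, 37 * f1$vmax, tolerance = 1e-9)
  expect_equal(f2$km, f1$km, tolerance = 1e-9)
})

test_that("fit guards: few concentrations, dropped points, no saturation", {
  expect_error(fit_michaelis_menten(mm_data(2, 0.5, s = c(1, 2))),
               ">= 3 distinct")
  d <- mm_data(2, 0.5)
  d$velocity[1] <- 0
  expect_warning(f <- fit_michaelis_menten(d), "dropped")
  expect_equal(f$n_points, 5L)
  # super-linear velocities have a negative 1/v intercept: no MM behaviour
  bad <- data.frame(substrate_mM = c(1, 2, 4), velocity = c(1, 4, 16))
  expect_error(fit_michaelis_menten(bad), "fit failure")
})

test_that("replicate averaging happens before the reciprocal transform", {
  d <- mm_data(2, 0.5, reps = 3)
  d$velocity <- d$velocity * rep(c(0.8, 1.0, 1.2), each = 6)
  f_avg <- fit_michaelis_menten(d)                       # default
  f_pool <- fit_michaelis_menten(d, average_replicates = FALSE)
  # averaged velocities are exactly on the curve again
  expect_equal(f_avg$vmax, 2, tolerance = 1e-8)
  expect_equal(f_avg$km, 0.5, tolerance = 1e-8)
  # pooling reciprocals weights the low replicate more: estimates differ
  expect_false(isTRUE(all.equal(f_pool$vmax, f_avg$vmax, tolerance = 1e-6)))
})

test_that("NLS is at least as accurate as LB under multiplicative noise", {
  err <- t(vapply(1:200, function(i) {
    d <- mm_data(2, 0.5, cv = 0.05, reps = 3, seed = i - 1)
    lb <- fit_michaelis_menten(d, method = "LB")
    nl <- fit_michaelis_menten(d, method = "NLS")
    c(lb = abs(lb$km - 0.5), nl = abs(nl$km - 0.5))
  }, c(lb = 0, nl = 0)))
  expect_lte(median(err[, "nl"]) / 0.5, 0.10)
  expect_lte(median(err[, "nl"]), median(err[, "lb"]))
  expect_lte(median(err[, "lb"]) / 0.5, 0.15)
})

test_that("relative activity reproduces hand-computed panels", {
  expect_equal(relative_activity(c(1, 2), c(1, 2))$relative_activity, 100)
  ra <- relative_activity(c(0.852, 0.852, 0.852), c(1, 1, 1))
  expect_equal(ra$relative_activity, 85.2, tolerance = 1e-9)
  expect_equal(ra$sd, 0)
  ra2 <- relative_activity(c(0.7, 0.8, 0.75), c(1.0, 1.1, 0.9))
  expect_equal(ra2$relative_activity, 75, tolerance = 1e-9)
  expect_equal(ra2$sd, 5, tolerance = 1e-9)
  expect_equal(ra2$df, 2)
  expect_error(relative_activity(c(1), c(0)), "mock mean")
})

test_that("effector_table builds a mock-anchored panel with t-tests", {
  panel <- generate_effector_assay(
    1, factors = tibble::tibble(effector = c("aspartate", "malate"),
                                activity_factor = c(0.852, 0.771)),
    n_reps = 3, cv = 0.03, seed = 8)
  tab <- effector_table(panel)
  expect_setequal(tab$effector, c("MOCK", "aspartate", "malate"))
  mock_row <- tab[tab$effector == "MOCK", ]
  expect_equal(mock_row$relative_activity, 100, tolerance = 1e-9)
  expect_true(is.na(mock_row$p_value))
  asp <- tab[tab$effector == "aspartate", ]
  expect_equal(asp$relative_activity, 85.2, tolerance = 0.1)
  expect_false(is.na(asp$p_value))
  expect_error(effector_table(panel[panel$effector != "MOCK", ]),
               "no mock")
})

test_that("inhibition-mode classification follows the rule table", {
  base <- fit_michaelis_menten(mm_data(1.74, 0.34))
  mal <- fit_michaelis_menten(mm_data(1.74 * 1.26, 0.34 * 2.4))
  expect_equal(classify_inhibition_mode(base, mal)$mode,
               "Km-and-Vmax-increase (malate/fumarate-type)")
  expect_equal(classify_inhibition_mode(base, base)$mode, "no-effect")
  comp <- fit_michaelis_menten(mm_data(1.74, 0.68))
  expect_equal(classify_inhibition_mode(base, comp)$mode,
               "competitive-like")
  noncomp <- fit_michaelis_menten(mm_data(1.0, 0.34))
  expect_equal(classify_inhibition_mode(base, noncomp)$mode,
               "noncompetitive-like")
  unc <- fit_michaelis_menten(mm_data(1.0, 0.17))
  expect_equal(classify_inhibition_mode(base, unc)$mode,
               "uncompetitive-like")
  mixed <- fit_michaelis_menten(mm_data(2.5, 0.17))
  expect_equal(classify_inhibition_mode(base, mixed)$mode, "mixed")
})

test_that("optimum detection is an argmax with tie and boundary handling", {
  prof <- data.frame(grid = c(7.0, 7.3, 8.0, 9.0),
                     activity = c(0.8, 1.0, 0.9, 0.6))
  expect_equal(find_optimum(prof)$optimum, 7.3)
  mono <- data.frame(grid = 1:4, activity = 1:4)
  expect_warning(opt <- find_optimum(mono), "boundary")
  expect_equal(opt$optimum, 4)
  flat <- data.frame(grid = 1:4, activity = rep(2, 4))
  expect_message(expect_warning(opt2 <- find_optimum(flat)), "tied")
  expect_equal(opt2$optimum, 1)
  expect_error(find_optimum(data.frame(grid = 1:2, activity = 1:2)),
               ">= 3")
})

test_that("synthetic unimodal profiles peak where planted", {
  prof <- generate_activity_profile(8.0, width = 0.6,
                                    grid = seq(6.5, 9.5, 0.5))
  expect_equal(find_optimum(prof)$optimum, 8.0)
  temp <- generate_activity_profile(35, width = 5, grid = seq(15, 50, 5))
  expect_equal(find_optimum(temp)$optimum, 35)
  expect_warning(generate_activity_profile(12, 1, seq(6, 9, 0.5)),
                 "outside")
})

test_that("pH comparison flags inhibition enhanced at alkaline pH", {
  mk <- function(ph, rel) tibble::tibble(pH = ph, replicate = 1:3,
                                         relative_activity = rel)
  d <- dplyr::bind_rows(mk(7.3, c(85, 86, 84)), mk(9.0, c(60, 62, 58)))
  cmp <- inhibition_vs_ph(d)
  expect_equal(cmp$delta, -25, tolerance = 1e-9)
  expect_true(cmp$enhanced_at_higher_pH)
  expect_false(is.na(cmp$p_value))

  same <- dplyr::bind_rows(mk(7.3, c(85, 86, 84)), mk(9.0, c(85, 86, 84)))
  expect_false(inhibition_vs_ph(same)$enhanced_at_higher_pH)
  expect_error(inhibition_vs_ph(mk(7.3, c(85, 86, 84))), ">= 2 pH")
})

test_that("pH-dependent effector simulation round-trips through the analysis", {
  panel <- generate_effector_assay(
    1, factors = tibble::tibble(effector = "malate",
                                pH = c(7.3, 9.0),
                                activity_factor = c(0.85, 0.60)),
    n_reps = 3, cv = 0, seed = 2)
  rel <- dplyr::bind_rows(lapply(split(panel, panel$pH), function(d) {
    mock <- d$velocity[d$effector == "MOCK"]
    eff <- d[d$effector == "malate", ]
    tibble::tibble(pH = eff$pH, replicate = eff$replicate,
                   relative_activity = eff$velocity / mean(mock) * 100)
  }))
  cmp <- inhibition_vs_ph(rel)
  expect_true(cmp$enhanced_at_higher_pH)
  expect_equal(cmp$delta, -25, tolerance = 1e-9)
})
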