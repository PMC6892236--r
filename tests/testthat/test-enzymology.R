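test_that("activity units implement the umol/min/mg definition", {
  expect_equal(activity_units(10, 10, 1), 1)
  expect_equal(activity_units(6100, 10, 1), 610)  # wild-type activity scale
  expect_equal(activity_units(10, 10, 2), activity_units(10, 10, 1) / 2)
  expect_error(activity_units(0, 10, 1), "positive")
})

test_that("both kinetics fits recover planted parameters exactly on noise-free data", {
  for (planted in list(c(0.75, 680), c(0.42, 1160))) {
    d <- make_kinetics(1, km = planted[1], vmax = planted[2],
                       s_grid = c(0.5, 1, 2, 4, 8, 10))$table
    for (method in c("lineweaver_burk", "nonlinear")) {
      fit <- fit_michaelis_menten(d, method)
      expect_equal(fit$Km, planted[1], tolerance = 1e-8)
      expect_equal(fit$Vmax, planted[2], tolerance = 1e-8)
      expect_gt(fit$r_squared, 0.999999)
    }
  }
})

test_that("LB and nonlinear fits agree on noise-free curves across parameter grids", {
  grid <- expand.grid(km = c(0.3, 0.75, 2), vmax = c(100, 680, 2200))
  for (i in seq_len(nrow(grid))) {
    d <- make_kinetics(i, grid$km[i], grid$vmax[i])$table
    f1 <- fit_michaelis_menten(d, "lineweaver_burk")
    f2 <- fit_michaelis_menten(d, "nonlinear")
    expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
  }
})

test_that("kinetics fit guards its preconditions and boundary cases", {
  d <- data.frame(substrate_mg_per_mL = c(1, 2, 4), rate = c(1, 2, 3))
  expect_error(fit_michaelis_menten(d), "at least 4")
  d <- data.frame(substrate_mg_per_mL = c(1, 2, 4, 8), rate = c(1, -2, 3, 4))
  expect_error(fit_michaelis_menten(d), "non-positive rate")
  # saturated rates: Km driven to the zero boundary
  d <- data.frame(substrate_mg_per_mL = c(1, 2, 4, 8), rate = rep(500, 4))
  expect_warning(fit_michaelis_menten(d, "nonlinear"), "saturation")
})

test_that("kcat and catalytic efficiency follow the closed-form conversions", {
  expect_equal(kcat_from_vmax(60, 1), 1)
  expect_equal(kcat_from_vmax(680, 37.9), 429.5333, tolerance = 1e-6)
  expect_equal(kcat_from_vmax(2200, 38.5), 1411.667, tolerance = 1e-6)
  expect_equal(catalytic_efficiency(430, 0.75), 573.3333, tolerance = 1e-6)
  expect_equal(catalytic_efficiency(740, 0.42), 1761.905, tolerance = 1e-6)
  expect_equal(catalytic_efficiency(0, 1), 0)
  expect_error(kcat_from_vmax(-1, 10), "positive")
  expect_error(catalytic_efficiency(10, 0), "positive")
  # linearity / inverse proportionality
  expect_equal(catalytic_efficiency(kcat_from_vmax(2 * 680, 37.9), 0.75),
               2 * catalytic_efficiency(kcat_from_vmax(680, 37.9), 0.75))
  expect_equal(catalytic_efficiency(kcat_from_vmax(680, 37.9), 1.5),
               catalytic_efficiency(kcat_from_vmax(680, 37.9), 0.75) / 2)
})

test_that("fold changes reproduce the reference-table headline ranges", {
  ref <- xyle_reference_tables()$kinetics
  eff <- stats::setNames(ref$kcat_over_km_ml_s_mg, ref$enzyme)
  hybrids <- eff[c("XylE", grep("^XylE-", names(eff), value = TRUE))]
  fc <- fold_changes(hybrids, "XylE")
  expect_equal(fc$max, 4.0)
  expect_equal(round(fc$min, 1), 2.4)
  expect_equal(fc$fold[["XylE"]], 1.0)
  sa <- stats::setNames(ref$specific_activity_u_mg, ref$enzyme)
  fs <- fold_changes(sa[c("XylE", grep("^XylE-", names(sa), value = TRUE))],
                     "XylE")
  expect_equal(round(fs$max, 1), 3.3)
  expect_equal(round(fs$min, 1), 1.2)
  expect_error(fold_changes(hybrids, "missing"), "not found")
})

test_that("published-table consistency audit flags the discordant row only", {
  ref <- xyle_reference_tables()$kinetics
  ref <- ref[!is.na(ref$km_mg_ml), ]
  audit <- kinetics_consistency(ref)
  expect_false(audit$consistent[audit$enzyme == "XylE-M3"])
  expect_equal(round(audit$recomputed[audit$enzyme == "XylE-M3"], 0), 1410)
  expect_true(all(audit$consistent[audit$enzyme != "XylE-M3"]))
})

test_that("T50 fits recover planted logistic midpoints exactly", {
  for (t50 in c(66.5, 71.2)) {
    d <- make_t50(1, t50 = t50, s = 2)$table
    fit <- fit_t50(d)
    expect_equal(fit$T50, t50, tolerance = 1e-6)
    expect_equal(fit$slope, 2, tolerance = 1e-6)
  }
  d1 <- make_t50(1, 66.5)$table
  d2 <- make_t50(1, 71.2)$table
  expect_equal(fit_t50(d2)$T50 - fit_t50(d1)$T50, 4.7, tolerance = 1e-6)
})

test_that("T50 handles symmetric three-point data and guards extrapolation", {
  d <- data.frame(temperature_C = c(60, 65, 70), residual_pct = c(100, 50, 0))
  expect_equal(fit_t50(d, method = "interpolation")$T50, 65)
  expect_equal(fit_t50(d, method = "logistic")$T50, 65, tolerance = 1e-3)
  d <- data.frame(temperature_C = seq(30, 50, 5), residual_pct = 100 - 0:4)
  expect_error(fit_t50(d), "never crosses 50%")
})

test_that("half-life fits invert first-order decay exactly", {
  d <- make_decay(1, t_half = 1)$table
  fit <- fit_half_life(d)
  expect_equal(fit$k, log(2), tolerance = 1e-10)
  expect_equal(fit$t_half, 1, tolerance = 1e-10)
  for (th in c(1.2, 2.3)) {
    fit <- fit_half_life(make_decay(2, t_half = th)$table)
    expect_equal(fit$t_half, th, tolerance = 1e-9)
  }
  expect_error(fit_half_life(
    data.frame(time_h = 0:3, residual_pct = c(100, 50, -1, 10))), "positive")
  expect_warning(
    f <- fit_half_life(data.frame(time_h = 0:3,
                                  residual_pct = c(90, 95, 100, 105))),
    "no decay")
  expect_equal(f$t_half, Inf)
})

test_that("degree of synergy: additivity, scale invariance, printed 15-h value", {
  t <- 1:10
  add <- data.frame(time_h = t, cellulase_only = t, xylanase_only = 0.1 * t,
                    both = 1.1 * t)
  expect_true(all(abs(degree_of_synergy(add)$ds$DS - 1) < 1e-12))

  sy <- make_synergy(4)$table
  ds1 <- degree_of_synergy(sy)
  sy2 <- sy
  for (cn in c("both", "cellulase_only", "xylanase_only", "control"))
    sy2[[cn]] <- sy2[[cn]] * 7.3
  expect_equal(degree_of_synergy(sy2)$ds$DS, ds1$ds$DS, tolerance = 1e-12)

  printed <- degree_of_synergy(data.frame(
    time_h = 15, both = 3.9, cellulase_only = 3.2, xylanase_only = 0.45))
  expect_equal(round(printed$max_ds, 3), 1.068)

  doubled <- degree_of_synergy(data.frame(
    time_h = 1, both = 2, cellulase_only = 1, xylanase_only = 0))
  expect_equal(doubled$max_ds, 2)

  expect_warning(z <- degree_of_synergy(data.frame(
    time_h = 1:2, both = c(1, 1), cellulase_only = c(0, 1),
    xylanase_only = c(0, 0.5))), "skipped")
  expect_true(is.na(z$ds$DS[1]))
})

test_that("DS control subtraction and first-crossing reporting work", {
  sy <- make_synergy(5, ds_profile = function(t) 0.8 + 0.04 * t)$table
  ds <- degree_of_synergy(sy)
  expect_equal(ds$t_first_gt1, 6)   # 0.8 + 0.04 t > 1 at t > 5
  with_ctl <- degree_of_synergy(sy, subtract_control = TRUE)
  expect_false(isTRUE(all.equal(with_ctl$ds$DS, ds$ds$DS)))
  expect_error(degree_of_synergy(sy[, -5], subtract_control = TRUE), "control")
})

test_that("percent change follows its closed form", {
  expect_equal(percent_change(2.85, 1), 185)
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(2.15, 1), 115)
  expect_error(percent_change(1, 0), "positive")
})

test_that("kinetics_summary assembles the full characterization row", {
  d <- make_kinetics(1, 0.75, 680)$table
  fit <- fit_michaelis_menten(d)
  row <- kinetics_summary(fit, mw_kda = 37.9, specific_activity = 610)
  expect_equal(row$kcat, 429.5333, tolerance = 1e-6)
  expect_equal(row$kcat_over_Km, row$kcat / row$Km)
  expect_message(kinetics_summary(fit, seq = random_aa(330, 3)), "computed from sequence")
  expect_error(kinetics_summary(fit), "mw_kda or a sequence")
  # mass helper sanity: a ~330-residue xylanase domain is in the ~37 kDa band
  expect_equal(protein_mw_kda(strrep("G", 10)), (10 * 57.0519 + 18.0153) / 1000)
})
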