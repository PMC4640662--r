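MM <- 18.016

test_that("staircase and restimulation protocols evaluate as quoted", {
  st <- protocol_staircase()
  expect_equal(protocol_value(st, 12), 150 / MM)      # third step
  expect_equal(protocol_value(st, 0), 50 / MM)
  expect_equal(protocol_value(st, 17), 200 / MM)
  rs <- protocol_restimulation()
  expect_equal(protocol_value(rs, 62), 0)             # stimulus removed
  expect_equal(protocol_value(rs, 30), 300 / MM)
  expect_equal(protocol_value(rs, 70), 300 / MM)
  lv <- protocol_constant_level(6)
  expect_equal(protocol_value(lv, 30), 500 / MM)      # highest constant level
  expect_length(make_grodsky_protocols(), 5)
})

test_that("sinusoidal infusion has the stated mean, amplitude and extrema", {
  p <- make_sinusoidal(6, 0.33, 120, duration = 720)
  kex <- 6 / 180.16
  expect_equal(protocol_value(p, 0), kex)                  # sin(0) = 0
  expect_equal(protocol_value(p, 30), kex * 1.33)          # crest
  expect_equal(min(protocol_value(p, seq(0, 240, 0.1))), kex * 0.67,
               tolerance = 1e-4)
  p0 <- make_sinusoidal(6, 0, 120, duration = 720)
  expect_equal(protocol_value(p0, c(7, 33, 101)), rep(kex, 3))
})

test_that("pulsed infusion is on for T_i of every T_ex", {
  p <- make_pulsed(6, T_ex = 10, T_i = 1, duration = 90)
  g <- 6 / 180.16
  expect_equal(protocol_value(p, 0.5), g)
  expect_equal(protocol_value(p, 5), 0)
  expect_equal(protocol_value(p, 30.99), g)
  tgrid <- seq(0, 90 - 0.1, by = 0.1)
  expect_equal(mean(protocol_value(p, tgrid) > 0), 1 / 10, tolerance = 0.01)
  expect_error(make_pulsed(6, T_ex = 10, T_i = 12), "T_i < T_ex")
})

test_that("IVGTT bolus rate and sampling schedule", {
  iv <- make_ivgtt(0.36, 3)
  expect_equal(protocol_value(iv$protocol, 1), 0.36 * 1000 / (3 * 180.16))
  expect_equal(protocol_value(iv$protocol, 1), 0.666, tolerance = 1e-3)
  expect_equal(protocol_value(iv$protocol, 5), 0)
  expect_length(iv$sampling_min, 23)
  expect_equal(range(iv$sampling_min), c(-30, 180))
  zero <- make_ivgtt(0, 3)
  expect_equal(protocol_value(zero$protocol, 1), 0)
  expect_error(make_ivgtt(0.36, 7))
})

test_that("caloric and pump-rate conversions", {
  expect_equal(kcal_to_enteral_rate(90, 60), 0.035, tolerance = 0.01)
  expect_equal(kcal_to_enteral_rate(0, 60), 0)
  expect_equal(kcal_to_enteral_rate(180, 60), 2 * kcal_to_enteral_rate(90, 60))
  expect_equal(rate_to_cc_per_hr(6, 70, 0.2), 126)
  expect_equal(rate_to_cc_per_hr(0, 70), 0)
  expect_equal(rate_to_cc_per_hr(3, 70, 0.2), 63)
})

test_that("protocols are nonnegative over their span", {
  protos <- c(make_grodsky_protocols(),
              list(make_sinusoidal(6, 0.33, 97, duration = 720),
                   make_pulsed(6, duration = 90),
                   make_enteral(duration = 720),
                   make_ivgtt()$protocol))
  for (p in protos) {
    tgrid <- seq(0, max(p$segments$t_end) - 1e-6, length.out = 500)
    expect_true(all(protocol_value(p, tgrid) >= 0))
  }
})

test_that("malformed protocols are rejected", {
  expect_error(glucose_protocol("imposed-concentration",
    tibble::tibble(t_start = c(0, 5), t_end = c(10, 15),
                   shape = "constant", value = 1)), "overlap")
  expect_error(glucose_protocol("imposed-concentration",
    tibble::tibble(t_start = 5, t_end = 5, shape = "constant", value = 1)))
})

test_that("phenotype scenarios apply the tabulated multipliers", {
  d <- load_defaults("human", n = 100)
  ngt <- apply_phenotype(d$meta, d$env, "NGT")
  expect_equal(ngt$params$k2, d$env$k2)
  expect_equal(ngt$meta$params, d$meta$params)

  igt <- apply_phenotype(d$meta, d$env, "IGT")
  expect_equal(igt$params$k2, d$env$k2 * 0.65)
  expect_equal(igt$params$k3_bar, d$env$k3_bar)
  expect_equal(igt$meta$params$mean[igt$meta$params$parameter == "rho"],
               6.5e-3 * 0.5)
  expect_equal(igt$meta$params$mean[igt$meta$params$parameter == "Dbar"], 3e-3)

  t2 <- apply_phenotype(d$meta, d$env, "T2DM", shift_thresholds = TRUE)
  expect_equal(t2$params$k2, d$env$k2 * 0.3)
  expect_equal(t2$params$k3_bar, d$env$k3_bar * 1.6)
  expect_equal(t2$meta$params$mean[t2$meta$params$parameter == "rho"],
               6.5e-3 * 0.05)
  expect_equal(t2$meta$params$mean[t2$meta$params$parameter == "Dbar"],
               3e-3 * 0.3)
  expect_equal(t2$meta$threshold$g_half, 4)
  t2a <- apply_phenotype(d$meta, d$env, "T2DM", shift_thresholds = FALSE)
  expect_equal(t2a$meta$threshold$g_half, 9.7697)

  expect_error(apply_phenotype(d$meta, d$env, "NGT", shift_thresholds = TRUE),
               "no shifted")
  expect_error(apply_phenotype(d$meta, d$env, "bogus"), "unknown phenotype")
})
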