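test_that("sampled thresholds follow the Hill CDF (KS distance < 0.01 at 1e5)", {
  d <- load_defaults("human", n = 1e5)
  u <- sample_population(d$meta, seed = 1)
  emp <- stats::ecdf(u$G_n)
  g <- seq(0.5, 40, by = 0.1)
  ks <- max(abs(emp(g) - threshold_cdf(g, d$meta$threshold)))
  expect_lt(ks, 0.01)
})

test_that("log-normal draws match the tabulated moments", {
  d <- load_defaults("human", n = 1e5)
  u <- sample_population(d$meta, seed = 2)
  # alpha_n: mean 0.3, sd 0.12 -> sample mean within 3 standard errors
  expect_lt(abs(mean(u$alpha_n) - 0.3), 3 * 0.12 / sqrt(1e5))
  expect_equal(sd(u$alpha_n), 0.12, tolerance = 0.05)
  # all parameters positive, refractory above resting threshold
  expect_true(all(as.matrix(u) > 0))
  expect_true(all(u$R_n > u$G_n))
})

test_that("zero-sd parameters collapse to their mean", {
  pm <- tibble::tibble(
    parameter = c("alpha", "R", "k", "Dbar", "rho", "Gamma", "gamma", "zeta"),
    mean = c(0.3, 1000, 0.1, 3e-3, 6.5e-3, 9, 10, 0.1),
    sd = 0)
  meta <- population_meta(100, pm, threshold_dist(2.5, 9.8), tau = 8)
  u <- sample_population(meta, seed = 1)
  expect_equal(u$alpha_n, rep(0.3, 100))
  expect_equal(u$zeta_n, rep(0.1, 100))
})

test_that("packet-size means scale as n_ref / n (total insulin invariant)", {
  d_ref <- load_defaults("human", n = 1e4)   # n_ref stays 1e5
  u <- sample_population(d_ref$meta, seed = 3)
  expect_equal(d_ref$meta$n_ref / d_ref$meta$n, 10)
  expect_equal(mean(u$Dbar_n), 3e-3 * 10, tolerance = 0.02)
  expect_equal(mean(u$rho_n), 6.5e-3 * 10, tolerance = 0.02)
  # total available basal insulin approx. n * mean(Dbar) is n-invariant
  d_full <- load_defaults("human", n = 1e5)
  v <- sample_population(d_full$meta, seed = 3)
  expect_equal(sum(u$Dbar_n) / sum(v$Dbar_n), 1, tolerance = 0.05)
})

test_that("reproducible for a fixed seed", {
  d <- load_defaults("rat", n = 200)
  expect_identical(sample_population(d$meta, seed = 5),
                   sample_population(d$meta, seed = 5))
})

test_that("asymptotic packet size obeys its limits and the tabulated example", {
  u <- one_unit()
  expect_equal(asymptotic_packet_size(u, 0), u$Dbar_n)
  expect_equal(asymptotic_packet_size(u, 1e6), u$rho_n / u$k_n + u$Dbar_n,
               tolerance = 1e-6)
  # means of the human table at basal glycemia 4.25 mM
  expect_equal(asymptotic_packet_size(u, 4.25), 3.04e-3, tolerance = 1e-2)
})

test_that("firing semantics: sub-threshold decay, single firing, refractoriness", {
  u <- one_unit(G_n = 4, R_n = 1000)
  st <- initial_state(u, 0)

  # sub-threshold: no release, B decays toward G_n
  out <- step_units(st, u, G_now = 2, G_delayed = 2, dt = 0.1)
  expect_equal(out$released, 0)
  expect_equal(out$firings, 0L, ignore_attr = TRUE)
  st2 <- tibble::tibble(B_n = 10, J_n = st$J_n, D_n = st$D_n)
  out2 <- step_units(st2, u, G_now = 2, G_delayed = 2, dt = 0.1)
  expect_lt(out2$state$B_n, 10)
  expect_gt(out2$state$B_n, u$G_n)

  # firing: releases the whole packet, threshold jumps to R_n, packet resets
  out3 <- step_units(st, u, G_now = 5, G_delayed = 5, dt = 0.1)
  expect_equal(out3$released, st$J_n)
  expect_equal(out3$firings, 1L, ignore_attr = TRUE)
  expect_equal(out3$state$B_n, u$R_n * (1 - 0.1 * u$alpha_n) + 0.1 * u$alpha_n * u$G_n)
  expect_lt(out3$state$J_n, 1e-4)

  # refractory: cannot re-fire on the next step at physiological glycemia
  out4 <- step_units(out3$state, u, G_now = 20, G_delayed = 20, dt = 0.1)
  expect_equal(out4$firings, 0L, ignore_attr = TRUE)

  expect_error(step_units(tibble::tibble(B_n = NaN, J_n = 0, D_n = 0), u,
                          5, 5, 0.1), "non-finite")
})

test_that("released mass equals the sum of packets at firing instants", {
  d <- load_defaults("rat", n = 300)
  u <- sample_population(d$meta, seed = 8)
  st <- initial_state(u, 0)
  total <- 0; J_at_fire <- 0
  G_seq <- c(rep(0, 10), rep(8, 30), rep(12, 30))
  for (g in G_seq) {
    fire <- g >= st$B_n
    J_at_fire <- J_at_fire + sum(st$J_n[fire])
    out <- step_units(st, u, g, g, dt = 0.5)
    total <- total + out$released
    st <- out$state
  }
  expect_equal(total, J_at_fire)
  expect_gt(total, 0)
})

test_that("potentiation level never falls below the basal packet size", {
  d <- load_defaults("rat", n = 200)
  u <- sample_population(d$meta, seed = 9)
  st <- initial_state(u, 0)
  ok <- TRUE
  for (g in c(rep(16, 60), rep(0, 120))) {
    st <- step_units(st, u, g, g, dt = 0.5)$state
    ok <- ok && all(st$D_n >= u$Dbar_n - 1e-12)
  }
  expect_true(ok)
})

test_that("trajectories converge as dt is halved on a sub-threshold protocol", {
  u <- one_unit(G_n = 10)
  run <- function(dt) {
    st <- tibble::tibble(B_n = 8, J_n = 2e-3, D_n = 2.5e-3)
    for (i in seq_len(round(20 / dt))) {
      st <- step_units(st, u, G_now = 5, G_delayed = 5, dt = dt)$state
    }
    unlist(st)
  }
  e1 <- max(abs(run(0.2) - run(0.025)))
  e2 <- max(abs(run(0.1) - run(0.025)))
  e3 <- max(abs(run(0.05) - run(0.025)))
  expect_lt(e2, e1)
  expect_lt(e3, e2)
  # error shrinks roughly linearly in dt (explicit Euler)
  expect_equal(e1 / e2, 2, tolerance = 0.6)
})

test_that("constant supra-basal glycemia gives periodic firing at the closed-form period", {
  u <- one_unit(G_n = 4, R_n = 1000, alpha_n = 0.3)
  dt <- 0.1; G <- 7
  st <- initial_state(u, 0)
  fires <- integer(0)
  for (i in 1:2500) {
    out <- step_units(st, u, G, G, dt)
    st <- out$state
    if (out$firings > 0) fires <- c(fires, i)
  }
  periods <- diff(fires) * dt
  expect_gt(length(periods), 5)
  expect_lt(diff(range(periods)), dt + 1e-9)    # strictly periodic
  # exact closed form of the discrete scheme: B_n decays geometrically
  n_steps <- ceiling(log((G - u$G_n) / (u$R_n - u$G_n)) / log(1 - u$alpha_n * dt))
  expect_lte(abs(periods[1] - n_steps * dt), dt + 1e-9)
  # converges to the continuous-time expression as dt shrinks
  t_cont <- log((u$R_n - u$G_n) / (G - u$G_n)) / u$alpha_n
  expect_equal(periods[1], t_cont, tolerance = 0.03)
})
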