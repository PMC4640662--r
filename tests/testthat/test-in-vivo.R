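test_that("OU step: deterministic decay, fixed point, stationary variance", {
  # b = 0: pure exponential decay within Euler error
  xi <- 1
  for (i in 1:100) xi <- ou_step(xi, a = 0.04, b = 0, dt = 0.1, noise = 0)
  expect_equal(xi, exp(-0.04 * 10), tolerance = 1e-3)
  expect_equal(ou_step(0, 0.04, 5.56e-4, 0.1, 0), 0)
})

test_that("saturate and urinary drive are the stated piecewise maps", {
  expect_equal(saturate(-1, 0, 2), 0)
  expect_equal(saturate(1.5, 0, 2), 1.5)
  expect_equal(saturate(3, 0, 2), 2)
  expect_equal(urinary_drive(4, 9), 0)
  expect_equal(urinary_drive(9, 9), 0)
  expect_equal(urinary_drive(12, 9), 3)
})

test_that("environment step: hepatic output raises glycemia at the tabulated rate", {
  p <- in_vivo_params()
  st <- list(G = 4, Q = 0, I = 0, A = 0, xi = 0)
  out <- step_environment(st, p, released = 0, dt = 0.1)
  # no insulin, below renal threshold: dG/dt = k3_bar / V_G = 0.05 mM/min
  expect_equal((out$G - st$G) / 0.1, p$k3_bar / p$V_G)
  expect_equal((out$G - st$G) / 0.1, 0.05)
})

test_that("liver compartment balance and hepatic branching fraction", {
  p <- in_vivo_params()
  # constant release r: Q converges to r / (h_d + h_x); the impulse-then-decay
  # scheme has fixed point r (1 - c) / c with c = (h_d + h_x) dt, which
  # approaches the continuous balance as dt -> 0
  st <- list(G = 4, Q = 0, I = 0, A = 0, xi = 0)
  r_step <- 0.05   # pmol/kgBW per 0.1-min step
  for (i in 1:20000) st <- step_environment(st, p, released = r_step, dt = 0.1)
  c01 <- (p$h_d + p$h_x) * 0.1
  expect_equal(st$Q, r_step * (1 - c01) / c01, tolerance = 1e-6)
  st <- list(G = 4, Q = 0, I = 0, A = 0, xi = 0)
  for (i in 1:20000) st <- step_environment(st, p, released = r_step / 10,
                                            dt = 0.01)
  expect_equal(st$Q, (r_step / 0.1) / (p$h_d + p$h_x), tolerance = 0.02)
  # fraction of released insulin reaching plasma = h_d / (h_d + h_x)
  st <- list(G = 4, Q = 0, I = 0, A = 0, xi = 0)
  to_plasma <- 0
  for (i in 1:30000) {
    q_pre <- st$Q + if (i > 10000) 0 else r_step
    st <- step_environment(st, p, released = if (i > 10000) 0 else r_step, dt = 0.1)
    to_plasma <- to_plasma + p$h_d * q_pre * 0.1
  }
  expect_equal(to_plasma / (10000 * r_step), p$h_d / (p$h_d + p$h_x),
               tolerance = 1e-3)
  expect_equal(p$h_d / (p$h_d + p$h_x), 0.643, tolerance = 1e-3)
})

test_that("in vivo insulin bookkeeping telescopes exactly", {
  p <- in_vivo_params()
  st <- list(G = 4.25, Q = 0, I = 0, A = 0, xi = 0)
  rel <- abs(sin(1:500)) * 0.1
  lost <- 0
  for (i in 1:500) {
    q_post <- st$Q + rel[i]
    i_pre <- st$I
    st <- step_environment(st, p, released = rel[i], dt = 0.1)
    lost <- lost + (p$h_x * q_post + p$k4 * i_pre * p$V_I) * 0.1
  }
  stored <- st$Q + st$I * p$V_I
  expect_equal(sum(rel), lost + stored, tolerance = 1e-10)
})

test_that("compiled simulator agrees with the pure-R reference loop", {
  d <- load_defaults("human", n = 40)
  u <- sample_population(d$meta, seed = 3)
  env <- d$env
  dt <- 0.1; nst <- 250; tau_steps <- as.integer(round(d$meta$tau / dt))
  set.seed(21); noise <- rnorm(nst)
  kex <- 0.02 * (1 + sin(seq_len(nst) / 15))

  st <- initial_state(u, env$G_b)
  state <- list(G = env$G_b, Q = rep(0, env$L), I = 0, A = 0, xi = 1e-3)
  gbuf <- rep(env$G_b, tau_steps); pos <- 1
  G_ref <- numeric(nst)
  for (s in seq_len(nst)) {
    G_ref[s] <- state$G
    Gd <- gbuf[pos]; gbuf[pos] <- state$G; pos <- pos %% tau_steps + 1
    outu <- step_units(st, u, state$G, Gd, dt)
    st <- outu$state
    state <- step_environment(state, env, outu$released, kex = kex[s],
                              dt = dt, noise = noise[s])
  }

  st0 <- initial_state(u, env$G_b)
  res <- isletsim:::cpp_simulate_in_vivo(
    u, unclass(env),
    list(B_n = st0$B_n, J_n = st0$J_n, D_n = st0$D_n,
         G = env$G_b, Q = rep(0, env$L), I = 0, A = 0, xi = 1e-3),
    kex, numeric(nst), noise, rep(env$G_b, tau_steps), dt, tau_steps)
  expect_equal(res$G, G_ref, tolerance = 1e-12)
})

test_that("hepatic glucose output stays inside its clipped band", {
  d <- load_defaults("human", n = 2000)
  u <- sample_population(d$meta, seed = 31)
  r <- simulate_in_vivo(u, d$meta, d$env, NULL, duration = 200, seed = 32,
                        burn_in = 50)
  k3 <- d$env$k3_bar + saturate(attr(r, "xi"), d$env$m, d$env$M_sat)
  expect_true(all(k3 >= d$env$k3_bar + d$env$m))
  expect_true(all(k3 <= d$env$k3_bar + d$env$M_sat))
})

test_that("glycemia stays positive and the fasting loop is stationary", {
  d <- load_defaults("human", n = 5000)
  for (s in 1:10) {
    u <- sample_population(d$meta, seed = 40 + s)
    r <- simulate_in_vivo(u, d$meta, d$env, NULL, duration = 60,
                          seed = 50 + s, burn_in = 120)
    expect_true(all(r$glycemia > 0))
  }
  # deterministic hepatic output: the closed loop settles to a stationary
  # fasting state in the physiological band
  env0 <- d$env; env0$b <- 0
  u <- sample_population(d$meta, seed = 61)
  r <- simulate_in_vivo(u, d$meta, env0, NULL, duration = 240, seed = 62)
  h1 <- mean(r$glycemia[r$time < 120])
  h2 <- mean(r$glycemia[r$time >= 120])
  expect_equal(h1, h2, tolerance = 0.02)
  expect_gt(mean(r$glycemia), 3.5)
  expect_lt(mean(r$glycemia), 6.5)
})

test_that("enteral feeding amplifies ultradian insulin oscillations", {
  d <- load_defaults("human", n = 2e4)
  u <- sample_population(d$meta, seed = 71)
  fast_sd <- function(prot) {
    r <- simulate_in_vivo(u, d$meta, d$env, prot, duration = 480, seed = 72)
    i1 <- r$insulin[r$time %% 1 < 1e-9]
    w <- 241
    tr <- as.numeric(stats::filter(i1, rep(1 / w, w), sides = 2))
    tr[is.na(tr)] <- mean(i1)
    sd(i1 - tr)
  }
  expect_gt(fast_sd(make_enteral(duration = 480)), 3 * fast_sd(NULL))
})

test_that("in vivo runs reject ill-posed inputs", {
  d <- load_defaults("human", n = 50)
  u <- sample_population(d$meta, seed = 1)
  expect_error(simulate_in_vivo(u, d$meta, d$env, protocol_staircase(),
                                duration = 30, seed = 1),
               "imposed-concentration")
  expect_error(simulate_in_vivo(u, d$meta, d$env, make_pulsed(6, duration = 90),
                                duration = 30, seed = 1),
               "beyond")
})
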