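#' In vivo environment parameters
#'
#' Parameters of the closed-loop glucose-insulin environment: an `L`-chain of
#' liver compartments filtering portal insulin, first-order plasma insulin
#' kinetics, and a single glycemia compartment with renal elimination above a
#' threshold, insulin-dependent tissue uptake, stochastic net hepatic glucose
#' output (an Ornstein-Uhlenbeck process clipped to a finite band around the
#' central value), splanchnic absorption and exogenous infusions.  Defaults
#' are the human parameter set (see [load_defaults()]).
#'
#' @param L Number of liver compartments.
#' @param h_d,h_x Liver transfer and clearance rates, 1/min.
#' @param k4 Plasma insulin clearance, 1/min.
#' @param V_I Insulin distribution volume, l/kgBW.
#' @param k1 Renal glucose elimination rate, 1/min.
#' @param G_u Renal glycemia threshold, mM.
#' @param k2 Insulin sensitivity, 1/(min pM).
#' @param k3_bar Central net hepatic glucose output, mmol/kgBW/min.
#' @param V_G Glucose distribution volume, l/kgBW.
#' @param G_b Basal glycemia, mM.
#' @param k_ga Splanchnic glucose absorption rate, 1/min.
#' @param a,b Ornstein-Uhlenbeck reversion rate (1/min) and volatility
#'   (mmol/kgBW/min^1.5) of the hepatic-output noise.
#' @param m,M_sat Lower/upper clip of the hepatic-output fluctuation,
#'   mmol/kgBW/min.
#' @return An object of class `"in_vivo_params"`.
#' @export
in_vivo_params <- function(L = 1, h_d = 0.9, h_x = 0.5, k4 = 0.08, V_I = 0.25,
                           k1 = 8.57e-3, G_u = 9, k2 = 1.4e-4, k3_bar = 0.01,
                           V_G = 0.2, G_b = 4.25, k_ga = 0.03, a = 0.04,
                           b = 5.56e-4, m = -5.56e-3, M_sat = 9.44e-2) {
  stopifnot(L >= 1, h_d > 0, h_x > 0, k4 > 0, V_I > 0, k1 > 0, G_u > 0,
            k2 > 0, k3_bar > 0, V_G > 0, G_b > 0, k_ga > 0, a > 0, b >= 0,
            m < M_sat)
  structure(as.list(environment()), class = "in_vivo_params")
}

#' Elementary environment operations
#'
#' `ou_step()` advances the hepatic-output noise one Euler-Maruyama step:
#' \eqn{\xi \leftarrow \xi - a\xi\,dt + b\sqrt{dt}\,z}.  `saturate()` clips
#' its argument to `[m, M_sat]` (identity on `[m, M_sat)`), bounding the
#' stochastic hepatic output.  `urinary_drive()` is the supra-threshold
#' glycemia `max(0, G - G_u)` driving renal glucose elimination.
#'
#' @param xi Current noise state, mmol/kgBW/min.
#' @param a,b OU reversion rate and volatility.
#' @param dt Step, min.
#' @param noise Standard normal variate(s).
#' @export
ou_step <- function(xi, a, b, dt, noise) {
  stopifnot(dt > 0)
  xi - a * xi * dt + b * sqrt(dt) * noise
}

#' @rdname ou_step
#' @param x Value(s) to clip.
#' @param m,M_sat Clip bounds, `m < M_sat`.
#' @export
saturate <- function(x, m, M_sat) {
  stopifnot(m < M_sat)
  pmin(pmax(x, m), M_sat)
}

#' @rdname ou_step
#' @param G Glycemia, mM.
#' @param G_u Renal threshold, mM.
#' @export
urinary_drive <- function(G, G_u) {
  if (any(G < 0)) stop("glycemia must be nonnegative", call. = FALSE)
  pmax(0, G - G_u)
}

#' Advance the in vivo environment one Euler step
#'
#' Reference (pure-R) semantics of the environment update used by
#' [simulate_in_vivo()]: the released insulin mass is added to the first
#' liver compartment as an impulse, then the liver chain, plasma insulin,
#' splanchnic mass, glycemia and hepatic-output noise advance one explicit
#' Euler step on start-of-step values, with
#' \deqn{\dot G = -k_1 \max(0, G-G_u) - k_2 I G + \left(k_3(t) + k_{ga} A +
#'       k_{ex}\right)/V_G, \quad k_3(t) = \bar k_3 + \tilde s(\xi),}
#' the mass fluxes (hepatic output, gut absorption, infusion) being converted
#' to concentration rates by the glucose distribution volume.
#'
#' @param state List with `G` (mM), `Q` (length-`L` numeric, pmol/kgBW),
#'   `I` (pM), `A` (mmol/kgBW), `xi` (mmol/kgBW/min).
#' @param params An [in_vivo_params()].
#' @param released Insulin mass released by the pancreas this step, pmol/kgBW.
#' @param kex Exogenous IV glucose rate, mmol/kgBW/min.
#' @param vent Enteral glucose rate, mmol/kgBW/min.
#' @param dt Step, min.
#' @param noise Standard normal variate for the OU update.
#' @return The updated state list.
#' @export
step_environment <- function(state, params, released, kex = 0, vent = 0,
                             dt = 0.1, noise = 0) {
  stopifnot(inherits(params, "in_vivo_params"), dt > 0, released >= 0)
  p <- params
  G <- state$G; Q <- state$Q; I <- state$I; A <- state$A; xi <- state$xi

  k3 <- p$k3_bar + saturate(xi, p$m, p$M_sat)
  dG <- -p$k1 * urinary_drive(G, p$G_u) - p$k2 * I * G +
    (k3 + p$k_ga * A + kex) / p$V_G

  Q[1] <- Q[1] + released
  Qold <- Q
  Q[1] <- Q[1] - dt * (p$h_d + p$h_x) * Qold[1]
  if (p$L > 1) {
    for (l in 2:p$L) {
      Q[l] <- Q[l] + dt * (p$h_d * Qold[l - 1] - (p$h_d + p$h_x) * Qold[l])
    }
  }
  I <- I + dt * (-p$k4 * I + p$h_d * Qold[p$L] / p$V_I)
  A <- A + dt * (-p$k_ga * A + vent)
  G <- G + dt * dG
  xi <- ou_step(xi, p$a, p$b, dt, noise)

  if (G <= 0 || !is.finite(G)) {
    stop("glycemia became non-positive: numerical failure (reduce dt)",
         call. = FALSE)
  }
  list(G = G, Q = Q, I = I, A = A, xi = xi)
}

#' Simulate the closed-loop in vivo glucose-insulin system
#'
#' Runs the full organ model: at every step the secretory-unit population
#' fires against current glycemia (with the potentiation drive sensing
#' glycemia `tau` minutes earlier), and the released insulin flows through
#' the liver chain into plasma, where it drives tissue glucose uptake,
#' closing the loop.  Before the protocol starts the closed loop is burned in
#' for `burn_in` minutes with no exogenous input, so that the system is at
#' its stochastic fasting steady state at `t = 0`.
#'
#' @param units Unit parameter tibble from [sample_population()].
#' @param meta The [population_meta()] the units were drawn from (provides
#'   `tau`).
#' @param params An [in_vivo_params()].
#' @param protocol A [glucose_protocol()] of kind `"iv-rate"` or
#'   `"enteral-rate"` (or `NULL` for no exogenous input).
#' @param duration Protocol duration, min.
#' @param dt Integration step, min (default 0.1).
#' @param seed Integer seed (population noise and OU process).
#' @param burn_in Burn-in length, min (default 600).
#' @param keep_burn_in If `TRUE`, the returned series includes the burn-in
#'   at negative times.
#' @return A tibble of class `"islet_sim"` with columns `time` (min),
#'   `glycemia` (mM), `insulin` (pM), `isr` (pmol/kgBW/min, instantaneous
#'   released mass / dt), `firings`.  Attributes: `dt`, `environment`
#'   (`"in_vivo"`), `params`, `final` (full final state).
#' @export
simulate_in_vivo <- function(units, meta, params = in_vivo_params(),
                             protocol = NULL, duration, dt = 0.1, seed = NULL,
                             burn_in = 600, keep_burn_in = FALSE) {
  stopifnot(inherits(meta, "population_meta"),
            inherits(params, "in_vivo_params"), duration > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "glucose_protocol"))
    if (protocol$kind == "imposed-concentration") {
      stop("imposed-concentration protocols are for simulate_in_vitro()",
           call. = FALSE)
    }
    if (max(protocol$segments$t_end) > duration + 1e-9) {
      stop("protocol extends beyond `duration`", call. = FALSE)
    }
  }

  tau_steps <- as.integer(round(meta$tau / dt))
  n_burn <- as.integer(round(burn_in / dt))
  n_main <- as.integer(round(duration / dt))

  st0 <- initial_state(units, params$G_b)
  xi0 <- if (params$b > 0) stats::rnorm(1, 0, params$b / sqrt(2 * params$a)) else 0
  state0 <- list(B_n = st0$B_n, J_n = st0$J_n, D_n = st0$D_n,
                 G = params$G_b, Q = rep(0, params$L), I = 0, A = 0, xi = xi0)

  run_chunk <- function(state0, kex, vent, gdel_init) {
    nsteps <- length(kex)
    noise <- if (params$b > 0) stats::rnorm(nsteps) else numeric(nsteps)
    cpp_simulate_in_vivo(units, unclass(params), state0, kex, vent, noise,
                         gdel_init, dt, tau_steps)
  }

  gdel0 <- rep(params$G_b, tau_steps)
  if (n_burn > 0) {
    burn <- run_chunk(state0, numeric(n_burn), numeric(n_burn), gdel0)
    fin <- burn$final
    if (tau_steps > 0) {
      idx <- ((fin$ring_pos + seq_len(tau_steps) - 1) %% tau_steps) + 1
      gdel0 <- fin$ring[idx]
    }
    state0 <- list(B_n = fin$B_n, J_n = fin$J_n, D_n = fin$D_n,
                   G = fin$G, Q = fin$Q, I = fin$I, A = fin$A, xi = fin$xi)
  }

  tmain <- (seq_len(n_main) - 1) * dt
  kex <- vent <- numeric(n_main)
  if (!is.null(protocol)) {
    v <- protocol_value(protocol, tmain)
    if (protocol$kind == "iv-rate") kex <- v else vent <- v
  }
  main <- run_chunk(state0, kex, vent, gdel0)

  res <- tibble::tibble(time = tmain,
                        glycemia = main$G,
                        insulin = main$I,
                        isr = main$released / dt,
                        firings = main$firings)
  if (keep_burn_in && n_burn > 0) {
    res <- dplyr::bind_rows(
      tibble::tibble(time = (seq_len(n_burn) - 1) * dt - burn_in,
                     glycemia = burn$G, insulin = burn$I,
                     isr = burn$released / dt, firings = burn$firings),
      res)
  }
  structure(res, class = c("islet_sim", class(res)),
            dt = dt, environment = "in_vivo", params = params,
            xi = main$xi, final = main$final)
}

#' Bin instantaneous secretion into average ISR per interval
#'
#' @param result An `"islet_sim"` tibble.
#' @param width Bin width, min (default 1).
#' @return A tibble with `time` (bin start) and `isr` (mean over the bin).
#' @export
bin_isr <- function(result, width = 1) {
  stopifnot(inherits(result, "islet_sim"))
  result |>
    dplyr::mutate(bin = floor(.data$time / width) * width) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(isr = mean(.data$isr), .groups = "drop") |>
    dplyr::rename(time = "bin")
}

#' @export
autoplot.islet_sim <- function(object, ...) {
  long <- object |>
    dplyr::select(dplyr::any_of(c("time", "glycemia", "insulin", "isr"))) |>
    tidyr::pivot_longer(-"time", names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~ .data$variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL)
}
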