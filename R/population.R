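#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib isletsim, .registration = TRUE
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

# mg/dl per mM of glucose
MGDL_PER_MM <- 18.016
# g/mol of glucose
GLUCOSE_MOLAR_MASS <- 180.16

# truncation bounds for sampled resting thresholds (mM); the Hill CDF has a
# heavy upper tail and a sample of 1e5 would otherwise occasionally place a
# threshold at physically meaningless glycemias
G_N_TRUNC <- c(0.1, 100)

#' Population meta-parameters of the secretory-unit ensemble
#'
#' A population of `n` independent firing units is described by a small set of
#' meta-parameters: every per-unit parameter is drawn from an independent
#' log-normal distribution whose arithmetic mean and standard deviation are
#' given here, except the resting threshold `G_n`, drawn from the Hill-shaped
#' [threshold_dist()].  `n_ref` is the reference population size at which the
#' packet-size means (`Dbar`, `rho`) are defined: when simulating with a
#' different `n` those means are rescaled by `n_ref / n` so that the total
#' insulin the organ can deliver is invariant in the numerical population
#' size.
#'
#' @param n Number of units to simulate.
#' @param params A data frame with columns `parameter`, `mean`, `sd` covering
#'   `alpha` (1/min), `R` (mM), `k` (1/min), `Dbar` (pmol/kgBW),
#'   `rho` (pmol/kgBW/min), `Gamma` (mM), `gamma` (-), `zeta` (1/min).
#' @param threshold A [threshold_dist()] for the resting thresholds.
#' @param tau Glucose-sensing delay of the potentiation drive, min.
#' @param n_ref Reference unit count for the packet-size means.
#' @return An object of class `"population_meta"`.
#' @seealso [load_defaults()] for the species parameter sets.
#' @export
population_meta <- function(n, params, threshold, tau, n_ref = n) {
  stopifnot(is.data.frame(params),
            all(c("parameter", "mean", "sd") %in% names(params)),
            inherits(threshold, "threshold_dist"))
  need <- c("alpha", "R", "k", "Dbar", "rho", "Gamma", "gamma", "zeta")
  if (!all(need %in% params$parameter)) {
    stop("params must cover: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (any(params$sd < 0) || any(params$mean <= 0)) {
    stop("parameter means must be positive and sds nonnegative", call. = FALSE)
  }
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  structure(list(n = as.integer(n), params = tibble::as_tibble(params),
                 threshold = threshold, tau = tau, n_ref = n_ref),
            class = "population_meta")
}

#' @export
print.population_meta <- function(x, ...) {
  cat(sprintf("<population_meta> n = %d (n_ref = %g), tau = %g min\n",
              x$n, x$n_ref, x$tau))
  print(x$threshold)
  print(x$params, n = Inf)
  invisible(x)
}

# arithmetic mean/sd -> log-scale (meanlog, sdlog), moment matched
lognormal_moments <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Sample a heterogeneous population of secretory units
#'
#' Draws the per-unit parameters of `meta$n` firing units: resting thresholds
#' `G_n` by inverse-CDF sampling of the Hill threshold distribution (truncated
#' to 0.1-100 mM), all other parameters as independent log-normals moment
#' matched to the arithmetic mean/sd in `meta$params`.  The packet-size means
#' (`Dbar`, `rho`) are scaled by `meta$n_ref / meta$n` so total available
#' insulin does not depend on the numerical population size.  The refractory
#' threshold is forced above the resting threshold (`R_n > G_n`).
#'
#' @param meta A [population_meta()].
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A tibble with one row per unit and columns `G_n`, `R_n`, `alpha_n`,
#'   `k_n`, `Dbar_n`, `rho_n`, `Gamma_n`, `gamma_n`, `zeta_n`.
#' @export
sample_population <- function(meta, seed = NULL) {
  stopifnot(inherits(meta, "population_meta"))
  if (!is.null(seed)) set.seed(seed)
  n <- meta$n
  scale_packet <- meta$n_ref / n

  draw <- function(name, scale = 1) {
    row <- meta$params[meta$params$parameter == name, ]
    m <- row$mean * scale
    s <- row$sd * scale
    if (s == 0) return(rep(m, n))
    lm <- lognormal_moments(m, s)
    stats::rlnorm(n, lm$meanlog, lm$sdlog)
  }

  # inverse-CDF draw of G_n restricted to the truncation window
  p_lo <- threshold_cdf(G_N_TRUNC[1], meta$threshold)
  p_hi <- threshold_cdf(G_N_TRUNC[2], meta$threshold)
  G_n <- threshold_quantile(stats::runif(n, p_lo, p_hi), meta$threshold)

  R_n <- draw("R")
  R_n <- pmax(R_n, G_n * 1.001)   # refractory level must exceed resting threshold

  tibble::tibble(
    G_n = G_n,
    R_n = R_n,
    alpha_n = draw("alpha"),
    k_n = draw("k"),
    Dbar_n = draw("Dbar", scale_packet),
    rho_n = draw("rho", scale_packet),
    Gamma_n = draw("Gamma"),
    gamma_n = draw("gamma"),
    zeta_n = draw("zeta"))
}

#' Asymptotic insulin packet size at constant glycemia
#'
#' Under constant glycemia `G_b` the potentiation level of a unit converges to
#' \eqn{\rho/k \cdot G_b^\gamma / (G_b^\gamma + \Gamma^\gamma) + \bar D}.  At
#' zero glucose this is the basal packet size `Dbar`; at saturating glucose it
#' is `rho/k + Dbar`.
#'
#' @param units A data frame of unit parameters as from [sample_population()].
#' @param G_b Constant glycemia, mM (>= 0).
#' @return Numeric vector of asymptotic packet sizes, pmol/kgBW.
#' @export
asymptotic_packet_size <- function(units, G_b) {
  stopifnot(is.data.frame(units), G_b >= 0)
  hill <- if (G_b == 0) 0 else
    G_b^units$gamma_n / (G_b^units$gamma_n + units$Gamma_n^units$gamma_n)
  units$rho_n / units$k_n * hill + units$Dbar_n
}

#' Initial unit states
#'
#' In vitro, units start from the zero-glucose basal state: threshold at its
#' resting value and packet at the basal size.  In vivo, packets start at
#' their asymptotic size for basal glycemia `G_b` (the closed loop is then
#' burned in before any protocol).
#'
#' @param units Unit parameter tibble.
#' @param G_b Basal glycemia, mM; 0 gives the in vitro basal state.
#' @return A tibble with columns `B_n`, `J_n`, `D_n`.
#' @export
initial_state <- function(units, G_b = 0) {
  D0 <- asymptotic_packet_size(units, G_b)
  tibble::tibble(B_n = units$G_n, J_n = D0, D_n = D0)
}

#' Advance the unit population by one Euler step
#'
#' Implements one step of the hybrid unit dynamics: the firing set
#' \eqn{S = \{n : G \ge B_n\}} is evaluated on the start-of-step state; firing
#' units release their whole packet (`released` accumulates their `J_n`),
#' their threshold jumps to the refractory level `R_n` and their packet resets
#' to zero.  All units then advance one explicit-Euler step of
#' \deqn{dB = -\alpha B + \alpha G_n,\quad dJ = \zeta (D - J),\quad
#'       dD = -k (D - \bar D) + \rho\, G_\tau^\gamma/(G_\tau^\gamma + \Gamma^\gamma),}
#' where \eqn{G_\tau} is the glycemia sensed `tau` minutes ago.
#'
#' This pure-R implementation is the reference semantics; the simulators use
#' an equivalent compiled loop.
#'
#' @param state Tibble with columns `B_n`, `J_n`, `D_n`.
#' @param units Unit parameter tibble.
#' @param G_now Sensed glycemia at the step start, mM.
#' @param G_delayed Glycemia at `t - tau`, mM.
#' @param dt Step, min (> 0).
#' @return A list with `state` (updated tibble), `released` (pmol/kgBW) and
#'   `firings` (count).
#' @export
step_units <- function(state, units, G_now, G_delayed, dt) {
  stopifnot(dt > 0, nrow(state) == nrow(units))
  if (!all(is.finite(state$B_n)) || !all(is.finite(state$J_n)) ||
      !all(is.finite(state$D_n))) {
    stop("non-finite unit state: numerical failure", call. = FALSE)
  }
  B <- state$B_n; J <- state$J_n; D <- state$D_n

  fire <- G_now >= B
  released <- sum(J[fire])
  firings <- sum(fire)
  B[fire] <- units$R_n[fire]
  J[fire] <- 0

  hill <- if (G_delayed <= 0) 0 else
    1 / (1 + exp(units$gamma_n * (log(units$Gamma_n) - log(G_delayed))))
  B <- B + dt * units$alpha_n * (units$G_n - B)
  J <- J + dt * units$zeta_n * (D - J)
  D <- D + dt * (-units$k_n * (D - units$Dbar_n) + units$rho_n * hill)

  list(state = tibble::tibble(B_n = B, J_n = J, D_n = D),
       released = released, firings = firings)
}
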