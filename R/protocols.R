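#' Glucose administration protocols
#'
#' A `glucose_protocol` is a piecewise description of the glucose input to a
#' simulation.  Three kinds exist:
#' * `"imposed-concentration"` — the perfusate glucose concentration imposed
#'   on an isolated pancreas, mM (in vitro);
#' * `"iv-rate"` — an intravenous glucose infusion rate, mmol/kgBW/min
#'   (in vivo, enters the glycemia equation);
#' * `"enteral-rate"` — an enteral glucose delivery rate, mmol/kgBW/min
#'   (in vivo, enters the splanchnic absorption compartment).
#'
#' Segments are half-open intervals `[t_start, t_end)` with shapes `constant`,
#' `ramp` (linear from `value` to `value_end`), `sinusoid`
#' (`value + amplitude * sin(2*pi*t/period)`, `t` relative to segment start)
#' or `pulse` (`value` during the first `width` minutes of every `period`).
#' Outside all segments the protocol evaluates to 0.
#'
#' @param kind Protocol kind (see above).
#' @param segments Tibble with columns `t_start`, `t_end`, `shape`, `value`,
#'   and optionally `value_end`, `amplitude`, `period`, `width`.
#' @return An object of class `"glucose_protocol"`.
#' @export
glucose_protocol <- function(kind, segments) {
  kind <- match.arg(kind, c("imposed-concentration", "iv-rate", "enteral-rate"))
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("t_start", "t_end", "shape", "value") %in% names(segments)))
  for (col in c("value_end", "amplitude", "period", "width")) {
    if (!col %in% names(segments)) segments[[col]] <- NA_real_
  }
  if (any(segments$t_start < 0) || any(segments$t_end <= segments$t_start)) {
    stop("segments must have 0 <= t_start < t_end", call. = FALSE)
  }
  o <- order(segments$t_start)
  segments <- segments[o, ]
  if (nrow(segments) > 1 &&
      any(segments$t_start[-1] < segments$t_end[-nrow(segments)] - 1e-9)) {
    stop("protocol segments must not overlap", call. = FALSE)
  }
  structure(list(kind = kind, segments = segments), class = "glucose_protocol")
}

#' @export
print.glucose_protocol <- function(x, ...) {
  cat(sprintf("<glucose_protocol> kind = %s, %d segment(s), span [%g, %g) min\n",
              x$kind, nrow(x$segments), min(x$segments$t_start),
              max(x$segments$t_end)))
  print(x$segments)
  invisible(x)
}

#' Evaluate a protocol at given times
#'
#' Protocols are left-continuous piecewise functions; simulators evaluate them
#' at step starts.
#'
#' @param protocol A [glucose_protocol()].
#' @param t Times, min (vectorised).
#' @return Numeric vector: concentration (mM) or rate (mmol/kgBW/min).
#' @export
protocol_value <- function(protocol, t) {
  stopifnot(inherits(protocol, "glucose_protocol"))
  out <- numeric(length(t))
  seg <- protocol$segments
  for (i in seq_len(nrow(seg))) {
    in_seg <- t >= seg$t_start[i] & t < seg$t_end[i]
    if (!any(in_seg)) next
    tt <- t[in_seg] - seg$t_start[i]
    out[in_seg] <- switch(
      seg$shape[i],
      constant = seg$value[i],
      ramp = seg$value[i] + (seg$value_end[i] - seg$value[i]) *
        tt / (seg$t_end[i] - seg$t_start[i]),
      sinusoid = seg$value[i] + seg$amplitude[i] * sin(2 * pi * tt / seg$period[i]),
      pulse = ifelse(tt %% seg$period[i] < seg$width[i], seg$value[i], 0),
      stop("unknown segment shape: ", seg$shape[i], call. = FALSE))
  }
  if (any(out < -1e-12)) stop("protocol evaluates to a negative value", call. = FALSE)
  pmax(out, 0)
}

seg_constant <- function(t_start, t_end, value) {
  tibble::tibble(t_start = t_start, t_end = t_end, shape = "constant", value = value)
}

#' Perfused-pancreas stimulation protocols
#'
#' Builders for the five classical perfusion experiments on the isolated rat
#' pancreas (imposed glucose concentration, supplied in mg/dl and converted
#' to mM internally):
#' 1. staircase: 50 mg/dl increments every 5 min, 50 to 200 mg/dl, final level
#'    held to `duration`;
#' 2. constant infusion at one of 50, 100, 150, 200, 300, 500 mg/dl for
#'    60 min (`level_index` selects the level, 1-based);
#' 3. 300 mg/dl for 60 min, stimulus removed for 5 min, 300 mg/dl again;
#' 4. ramp 0 to 300 mg/dl over 10 min, then hold;
#' 5. pure ramp 0 to 500 mg/dl over 60 min.
#'
#' The ramp slopes and durations of experiments 4-5 are configurable since the
#' original reports give only the qualitative shape.
#'
#' @param duration Total protocol length, min.
#' @param level_index Which constant level for experiment 2 (1-based).
#' @param ramp_to,ramp_minutes Ramp target (mg/dl) and rise time (min).
#' @return A [glucose_protocol()] of kind `"imposed-concentration"`, or for
#'   `make_grodsky_protocols()` a named list of the five defaults.
#' @name grodsky_protocols
NULL

#' @rdname grodsky_protocols
#' @export
protocol_staircase <- function(duration = 22) {
  steps <- seq(50, 200, by = 50) / MGDL_PER_MM
  seg <- seg_constant(t_start = (seq_along(steps) - 1) * 5,
                      t_end = c(seq_along(steps)[-length(steps)] * 5, duration),
                      value = steps)
  glucose_protocol("imposed-concentration", seg)
}

#' @rdname grodsky_protocols
#' @export
protocol_constant_level <- function(level_index = 1, duration = 60) {
  levels <- c(50, 100, 150, 200, 300, 500)
  stopifnot(level_index %in% seq_along(levels))
  glucose_protocol("imposed-concentration",
                   seg_constant(0, duration, levels[level_index] / MGDL_PER_MM))
}

#' @rdname grodsky_protocols
#' @export
protocol_restimulation <- function(duration = 95) {
  g <- 300 / MGDL_PER_MM
  glucose_protocol("imposed-concentration", dplyr::bind_rows(
    seg_constant(0, 60, g),
    seg_constant(60, 65, 0),
    seg_constant(65, duration, g)))
}

#' @rdname grodsky_protocols
#' @export
protocol_ramp_hold <- function(ramp_to = 300, ramp_minutes = 10, duration = 80) {
  glucose_protocol("imposed-concentration", dplyr::bind_rows(
    tibble::tibble(t_start = 0, t_end = ramp_minutes, shape = "ramp",
                   value = 0, value_end = ramp_to / MGDL_PER_MM),
    seg_constant(ramp_minutes, duration, ramp_to / MGDL_PER_MM)))
}

#' @rdname grodsky_protocols
#' @export
protocol_ramp <- function(ramp_to = 500, ramp_minutes = 60) {
  glucose_protocol("imposed-concentration",
                   tibble::tibble(t_start = 0, t_end = ramp_minutes, shape = "ramp",
                                  value = 0, value_end = ramp_to / MGDL_PER_MM))
}

#' @rdname grodsky_protocols
#' @export
make_grodsky_protocols <- function() {
  list(staircase = protocol_staircase(),
       constant = protocol_constant_level(5),
       restimulation = protocol_restimulation(),
       ramp_hold = protocol_ramp_hold(),
       ramp = protocol_ramp())
}

#' Sinusoidal intravenous glucose infusion
#'
#' Rate \eqn{k_{ex}(t) = \bar k_{ex} + \Delta_{ex} \sin(2\pi t/T_{ex})} with
#' \eqn{\Delta_{ex}} a fraction of the mean rate, used to entrain ultradian
#' insulin oscillations.
#'
#' @param kex_bar_mg Mean infusion rate, mg/kgBW/min.
#' @param delta_frac Relative amplitude in \[0, 1).
#' @param T_ex Forcing period, min.
#' @param duration Protocol length, min.
#' @return An `"iv-rate"` [glucose_protocol()] (internally mmol/kgBW/min).
#' @export
make_sinusoidal <- function(kex_bar_mg = 6, delta_frac = 0.33, T_ex = 120,
                            duration = 1440) {
  stopifnot(delta_frac >= 0, delta_frac < 1)
  kex <- kex_bar_mg / GLUCOSE_MOLAR_MASS  # mg/kg/min -> mmol/kg/min
  glucose_protocol("iv-rate", tibble::tibble(
    t_start = 0, t_end = duration, shape = "sinusoid",
    value = kex, amplitude = delta_frac * kex, period = T_ex))
}

#' Pulsed intravenous glucose infusion
#'
#' Rate `g_inf` during the first `T_i` minutes of every pulsing period `T_ex`,
#' 0 otherwise: a train of brief glucose boli used to entrain high-frequency
#' insulin pulsatility.
#'
#' @param g_inf_mg Pulse rate, mg/kgBW/min.
#' @param T_ex Pulsing period, min.
#' @param T_i Pulse width, min (0 < `T_i` < `T_ex`).
#' @param duration Protocol length, min.
#' @return An `"iv-rate"` [glucose_protocol()].
#' @export
make_pulsed <- function(g_inf_mg = 6, T_ex = 10, T_i = 1, duration = 90) {
  stopifnot(T_i > 0, T_i < T_ex)
  glucose_protocol("iv-rate", tibble::tibble(
    t_start = 0, t_end = duration, shape = "pulse",
    value = g_inf_mg / GLUCOSE_MOLAR_MASS, period = T_ex, width = T_i))
}

#' Constant enteral feeding protocol
#'
#' @param rate_mmol Enteral glucose delivery, mmol/kgBW/min (see
#'   [kcal_to_enteral_rate()]).
#' @param duration Protocol length, min.
#' @return An `"enteral-rate"` [glucose_protocol()].
#' @export
make_enteral <- function(rate_mmol = kcal_to_enteral_rate(90, 60),
                         duration = 1440) {
  glucose_protocol("enteral-rate", seg_constant(0, duration, rate_mmol))
}

#' Intravenous glucose tolerance test protocol
#'
#' A bolus of `dose_g_per_kg` grams of glucose per kg body weight delivered as
#' a constant intravenous rate over `infusion_minutes` (1-4 min), plus the
#' standard 23-point sampling schedule (-30' to 180').
#'
#' @param dose_g_per_kg Glucose dose, g/kgBW.
#' @param infusion_minutes Bolus delivery time, min (between 1 and 4).
#' @return A list with `protocol` (an `"iv-rate"` [glucose_protocol()]) and
#'   `sampling_min` (the 23 sampling times, min).
#' @export
make_ivgtt <- function(dose_g_per_kg = 0.36, infusion_minutes = 3) {
  stopifnot(infusion_minutes >= 1, infusion_minutes <= 4, dose_g_per_kg >= 0)
  rate <- dose_g_per_kg * 1000 / (infusion_minutes * GLUCOSE_MOLAR_MASS)
  protocol <- if (dose_g_per_kg == 0) {
    glucose_protocol("iv-rate", seg_constant(0, infusion_minutes, 0))
  } else {
    glucose_protocol("iv-rate", seg_constant(0, infusion_minutes, rate))
  }
  list(protocol = protocol,
       sampling_min = c(-30, -15, 0, 2, 4, 6, 8, 10, 12, 15, 20, 25, 30, 35,
                        40, 50, 60, 80, 100, 120, 140, 160, 180))
}

#' Unit conversions for glucose administration
#'
#' `kcal_to_enteral_rate()` converts a caloric enteral feeding rate into an
#' equivalent glucose delivery rate, treating all calories as glucose at
#' 4 kcal/g (molar mass 180.16 g/mol).  `rate_to_cc_per_hr()` converts a
#' weight-normalised infusion rate into pump units for a glucose solution of
#' given concentration (default 0.2 g/cc, i.e. a 20% solution).
#'
#' @param kcal_per_h Caloric rate, kcal/h.
#' @param body_weight_kg Body weight, kg.
#' @return `kcal_to_enteral_rate()`: mmol/kgBW/min.
#' @examples
#' kcal_to_enteral_rate(90, 60)   # ~0.035 mmol/kgBW/min
#' rate_to_cc_per_hr(6, 70)       # 126 cc/hr
#' @export
kcal_to_enteral_rate <- function(kcal_per_h, body_weight_kg) {
  stopifnot(kcal_per_h >= 0, body_weight_kg > 0)
  g_per_min <- kcal_per_h / 4 / 60
  g_per_min * 1000 / GLUCOSE_MOLAR_MASS / body_weight_kg
}

#' @rdname kcal_to_enteral_rate
#' @param mg_per_kg_min Infusion rate, mg/kgBW/min.
#' @param solution_g_per_cc Glucose solution concentration, g/cc.
#' @return `rate_to_cc_per_hr()`: pump rate in cc/hr.
#' @export
rate_to_cc_per_hr <- function(mg_per_kg_min, body_weight_kg,
                              solution_g_per_cc = 0.2) {
  stopifnot(mg_per_kg_min >= 0, body_weight_kg > 0, solution_g_per_cc > 0)
  mg_per_kg_min * body_weight_kg * 60 / 1000 / solution_g_per_cc
}

#' Glucose-tolerance phenotype scenarios
#'
#' Multiplicative modifications of the normal (NGT) in vivo parameter set that
#' reproduce impaired fasting glucose (IFG, raised hepatic glucose output),
#' impaired glucose tolerance (IGT, reduced peripheral insulin sensitivity),
#' the combined IFG+IGT state, and type 2 diabetes (T2DM, combined resistance
#' plus reduced secretory capacity).  For T2DM an optional left shift of the
#' firing-threshold distribution (`g_half` = 4 mM) models earlier, more
#' complete recruitment of the remaining secretory capacity.
#'
#' @return `phenotype_table()`: a tibble of the multipliers per scenario.
#' @export
phenotype_table <- function() {
  tibble::tibble(
    name = c("NGT", "IFG", "IGT", "IFG+IGT", "T2DM"),
    k2_mult = c(1, 1, 0.65, 0.65, 0.3),
    k3_mult = c(1, 1.6, 1, 1.6, 1.6),
    rho_mult = c(1, 0.5, 0.5, 0.25, 0.05),
    Dbar_mult = c(1, 1, 1, 1, 0.3),
    g_half_shifted = c(NA, NA, NA, NA, 4))
}

#' @rdname phenotype_table
#' @param meta A [population_meta()] (NGT baseline).
#' @param params An [in_vivo_params()] (NGT baseline).
#' @param name Scenario name: `"NGT"`, `"IFG"`, `"IGT"`, `"IFG+IGT"`, `"T2DM"`.
#' @param shift_thresholds For T2DM only: also shift `g_half` to 4 mM.
#' @return `apply_phenotype()`: a list with modified `meta` and `params`.
#' @export
apply_phenotype <- function(meta, params, name, shift_thresholds = FALSE) {
  stopifnot(inherits(meta, "population_meta"), inherits(params, "in_vivo_params"))
  tab <- phenotype_table()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1) {
    stop("unknown phenotype: ", name, " (one of ",
         paste(tab$name, collapse = ", "), ")", call. = FALSE)
  }
  params$k2 <- params$k2 * row$k2_mult
  params$k3_bar <- params$k3_bar * row$k3_mult
  pm <- meta$params
  pm$mean[pm$parameter == "rho"] <- pm$mean[pm$parameter == "rho"] * row$rho_mult
  pm$sd[pm$parameter == "rho"] <- pm$sd[pm$parameter == "rho"] * row$rho_mult
  pm$mean[pm$parameter == "Dbar"] <- pm$mean[pm$parameter == "Dbar"] * row$Dbar_mult
  pm$sd[pm$parameter == "Dbar"] <- pm$sd[pm$parameter == "Dbar"] * row$Dbar_mult
  meta$params <- pm
  if (shift_thresholds) {
    if (is.na(row$g_half_shifted)) {
      stop("phenotype ", name, " has no shifted-threshold variant", call. = FALSE)
    }
    meta$threshold <- threshold_dist(meta$threshold$nu, row$g_half_shifted)
  }
  list(meta = meta, params = params)
}
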