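#' Firing-threshold distribution of the secretory-unit population
#'
#' The resting glycemic thresholds \eqn{G_n} of the secretory units are
#' distributed according to a Hill-shaped cumulative distribution
#' \deqn{F(g) = g^\nu / (g_{1/2}^\nu + g^\nu),}
#' where \eqn{\nu > 0} is a dimensionless steepness exponent and
#' \eqn{g_{1/2} > 0} (mM) is the glycemia at which half of the population is
#' recruitable.  `threshold_dist()` constructs the distribution object;
#' `threshold_cdf()` and `threshold_pdf()` evaluate its CDF and density.
#'
#' @param nu Hill exponent (dimensionless, > 0).
#' @param g_half Half-activation glycemia in mM (> 0).
#' @return `threshold_dist()` returns an object of class `"threshold_dist"`.
#' @examples
#' d <- threshold_dist(2.5137, 9.7697)
#' threshold_cdf(c(0, 9.7697, 27.753), d)
#' @export
threshold_dist <- function(nu, g_half) {
  stopifnot(is.numeric(nu), is.numeric(g_half), length(nu) == 1, length(g_half) == 1)
  if (!is.finite(nu) || !is.finite(g_half) || nu <= 0 || g_half <= 0) {
    stop("`nu` and `g_half` must be finite and strictly positive", call. = FALSE)
  }
  structure(list(nu = nu, g_half = g_half), class = "threshold_dist")
}

#' @export
print.threshold_dist <- function(x, ...) {
  cat(sprintf("<threshold_dist> Hill CDF: nu = %.4f, g_half = %.4f mM\n",
              x$nu, x$g_half))
  invisible(x)
}

#' @rdname threshold_dist
#' @param g Glycemia in mM (vectorised, must be >= 0).
#' @param dist A `threshold_dist` object.
#' @return `threshold_cdf()` returns the recruitable fraction in \[0, 1\];
#'   `threshold_pdf()` the density in 1/mM.
#' @export
threshold_cdf <- function(g, dist) {
  stopifnot(inherits(dist, "threshold_dist"))
  if (any(g < 0, na.rm = TRUE)) stop("glycemia must be nonnegative", call. = FALSE)
  g^dist$nu / (dist$g_half^dist$nu + g^dist$nu)
}

#' @rdname threshold_dist
#' @export
threshold_pdf <- function(g, dist) {
  stopifnot(inherits(dist, "threshold_dist"))
  if (any(g < 0, na.rm = TRUE)) stop("glycemia must be nonnegative", call. = FALSE)
  nu <- dist$nu
  gh <- dist$g_half
  nu * gh^nu * g^(nu - 1) / (g^nu + gh^nu)^2
}

#' @rdname threshold_dist
#' @param p Probabilities in \[0, 1\] (vectorised).
#' @export
threshold_quantile <- function(p, dist) {
  stopifnot(inherits(dist, "threshold_dist"))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  dist$g_half * (p / (1 - p))^(1 / dist$nu)
}

#' Fit the firing-threshold distribution to percent-activation data
#'
#' Fits the Hill CDF \eqn{F(g) = g^\nu/(g_{1/2}^\nu + g^\nu)} to observed
#' percent-activation points by unweighted ordinary least squares on the
#' fraction scale.  Percent activation is the fraction of secretory units
#' recruited (firing at least once) at a given imposed glucose concentration,
#' as read off step-stimulation perfusion experiments; glycemias are supplied
#' in mg/dl and converted to mM by dividing by 18.016.
#'
#' @param points A data frame with columns `glycemia_mg_dl` and
#'   `percent_activation` (0-100).  At least 3 points with distinct glycemias.
#' @return An object of class `"threshold_fit"`, containing the fitted
#'   `threshold_dist`, the data, residuals and the residual sum of squares.
#'   Supports [tidy()], [glance()], [autoplot()][ggplot2::autoplot].
#' @examples
#' fit <- fit_threshold_cdf(grodsky_activation())
#' tidy(fit)
#' @export
fit_threshold_cdf <- function(points) {
  stopifnot(is.data.frame(points))
  if (!all(c("glycemia_mg_dl", "percent_activation") %in% names(points))) {
    stop("`points` needs columns glycemia_mg_dl and percent_activation", call. = FALSE)
  }
  g_mM <- points$glycemia_mg_dl / MGDL_PER_MM
  pa <- points$percent_activation / 100
  if (any(pa < 0 | pa > 1)) stop("percent_activation must lie in [0, 100]", call. = FALSE)
  if (length(unique(g_mM)) < 3) {
    stop("need at least 3 points with distinct glycemias to identify (nu, g_half)",
         call. = FALSE)
  }
  if (length(unique(pa)) < 2) {
    stop("all percent-activation values equal: fit is unidentifiable", call. = FALSE)
  }

  sse <- function(par) {
    f <- g_mM^par[1] / (par[2]^par[1] + g_mM^par[1])
    sum((f - pa)^2)
  }
  # crude grid start, then two rounds of Nelder-Mead polish
  grid <- expand.grid(nu = seq(0.5, 8, by = 0.5), gh = seq(1, 30, by = 1))
  start <- unlist(grid[which.min(apply(grid, 1, sse)), ])
  opt <- stats::optim(start, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt <- stats::optim(opt$par, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  dist <- threshold_dist(opt$par[[1]], opt$par[[2]])
  fitted <- threshold_cdf(g_mM, dist)
  structure(
    list(dist = dist,
         data = tibble::tibble(glycemia_mM = g_mM, activation = pa,
                               fitted = fitted, residual = pa - fitted),
         rss = opt$value,
         convergence = opt$convergence),
    class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf(
    "<threshold_fit> nu = %.4f, g_half = %.4f mM (RSS = %.3g, n = %d)\n",
    x$dist$nu, x$dist$g_half, x$rss, nrow(x$data)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.threshold_fit <- function(x, ...) {
  tibble::tibble(term = c("nu", "g_half"),
                 estimate = c(x$dist$nu, x$dist$g_half),
                 units = c("", "mM"))
}

#' @export
glance.threshold_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, nobs = nrow(x$data), converged = x$convergence == 0)
}

#' @export
autoplot.threshold_fit <- function(object, ...) {
  grid <- tibble::tibble(glycemia_mM = seq(0, max(object$data$glycemia_mM) * 1.1,
                                           length.out = 200))
  grid$fitted <- threshold_cdf(grid$glycemia_mM, object$dist)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$glycemia_mM, .data$activation)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "glycemia (mM)", y = "recruited fraction",
                  title = "Firing-threshold cumulative distribution")
}

#' Percent-activation table from classical perfused-pancreas step experiments
#'
#' Six (glycemia, percent-activation) points extracted from constant-level
#' perfusion experiments on the isolated rat pancreas: the initial secretion
#' peak at each imposed glucose level is attributed to the units whose resting
#' thresholds lie below that level, giving an empirical recruitment CDF.
#'
#' @return A tibble with columns `glycemia_mg_dl` and `percent_activation`.
#' @export
grodsky_activation <- function() {
  tibble::tibble(
    glycemia_mg_dl = c(50, 100, 150, 200, 300, 500),
    percent_activation = c(2, 18.75, 43.75, 56.25, 75, 100))
}
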