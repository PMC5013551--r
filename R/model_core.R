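#' Average trip speed predicted by the kick model
#'
#' In the layered kick model the maximal speed is reached mid-trip after a
#' Poisson number of upward jumps, and the trip-averaged speed follows the
#' triangle approximation \eqn{\bar v(t) = v_0 + p' \delta v' t}, clipped at
#' the speed cap. Average speed therefore grows linearly with trip duration,
#' in contrast with the \eqn{t^{1/2}} growth of the Brownian-velocity null
#' model.
#'
#' @param t Trip duration(s) in hours, non-negative.
#' @param params A [kick_params()] object.
#' @return Mean speed(s) in km/h, clipped to at most `params$v_max`.
#' @examples
#' p <- kick_params(17.9, 20.9, 1.06)
#' mean_speed(1, p) # 17.9 + 1.06 * 20.9
#' @export
mean_speed <- function(t, params) {
  stopifnot(inherits(params, "kick_params"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative")
  pmin(params$v0 + params$p_half * params$dv_half * t, params$v_max)
}

#' Gamma-continued Poisson weight
#'
#' The Poisson probability mass \eqn{e^{-\lambda}\lambda^k / k!} continued to
#' real non-negative \eqn{k} through \eqn{k! = \Gamma(1+k)}. Evaluated in
#' log-space so large \eqn{\lambda} and \eqn{k} do not overflow. At integer
#' `k` this equals the ordinary Poisson pmf.
#'
#' @param k Non-negative real jump count(s).
#' @param lam Non-negative Poisson mean(s).
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' poisson_weight(2, 2) # == dpois(2, 2)
#' poisson_weight(1.5, 2)
#' @export
poisson_weight <- function(k, lam) {
  stopifnot(is.numeric(k), is.numeric(lam))
  if (any(k < 0)) stop("'k' must be non-negative")
  if (any(lam < 0)) stop("'lam' must be non-negative")
  n <- max(length(k), length(lam))
  k <- rep_len(k, n); lam <- rep_len(lam, n)
  out <- numeric(n)
  z <- lam == 0
  out[z] <- as.numeric(k[z] == 0)
  k0 <- !z & k == 0
  out[k0] <- exp(-lam[k0])
  i <- !z & !k0
  out[i] <- exp(-lam[i] + k[i] * log(lam[i]) - lgamma(1 + k[i]))
  out
}

## upper integration bound in layer-index units: the weight is negligible
## beyond lam + 30 sqrt(lam) + 30
.k_upper <- function(lam, k_max) pmin(k_max, lam + 30 * sqrt(lam + 1) + 30)

## normalizer of the continuous speed density: integral of the weight over the
## speed support [v0, v_max], computed by exact change of variables to the
## layer index k = (v - v0)/dv_half (robust for arbitrarily small dv_half)
.cond_norm <- function(lam, params) {
  k_max <- (params$v_max - params$v0) / params$dv_half
  vapply(lam, function(l) {
    stats::integrate(function(k) poisson_weight(k, l), 0, .k_upper(l, k_max),
                     rel.tol = 1e-10, abs.tol = 1e-13,
                     subdivisions = 400L)$value * params$dv_half
  }, numeric(1))
}

#' Conditional density of mean trip speed given duration
#'
#' The continuous-speed form of the kick model's conditional law: writing the
#' jump count as \eqn{k = (\bar v - v_0)/\delta v'} with Poisson mean
#' \eqn{\lambda = p' t}, the density is proportional to the Gamma-continued
#' Poisson weight on the support \eqn{[v_0, v_{max}]} and zero outside.
#' The normalizing constant has no closed form and is computed by adaptive
#' quadrature over the continuous layer index (equivalent to integrating over
#' speed, but stable for arbitrarily small `dv_half`).
#'
#' @param vbar Mean speed(s) in km/h at which to evaluate the density.
#' @param t Trip duration in hours (scalar, positive).
#' @param params A [kick_params()] object.
#' @return Density value(s) per km/h; integrates to 1 over
#'   `[params$v0, params$v_max]`.
#' @examples
#' p <- kick_params(17.9, 20.9, 1.06)
#' conditional_speed_pdf(c(20, 40, 60), t = 1, p)
#' @export
conditional_speed_pdf <- function(vbar, t, params) {
  stopifnot(inherits(params, "kick_params"), is.numeric(vbar),
            is.numeric(t), length(t) == 1L)
  if (t <= 0) stop("'t' must be positive")
  lam <- params$p_half * t
  z <- .cond_norm(lam, params)
  k <- (vbar - params$v0) / params$dv_half
  d <- numeric(length(vbar))
  inside <- vbar >= params$v0 & vbar <= params$v_max
  d[inside] <- poisson_weight(k[inside], lam) / z
  d
}

#' Displacement density of the kick model
#'
#' The trip-length (displacement) distribution obtained by mixing the
#' conditional speed law over the exponential travel-time distribution under
#' the constraint \eqn{\Delta r = \bar v t}:
#' \deqn{P(\Delta r) = \int P(t)\, \frac{1}{t}\,
#'       P(\bar v = \Delta r / t \mid t)\, dt,}
#' with the integral supported on \eqn{t \in [\Delta r/v_{max},
#' \Delta r/v_0]}. The quadrature is performed in the continuous layer-index
#' variable (an exact reparameterisation of the same integral) with absolute
#' tolerance 1e-12, which keeps the integrand order-one-wide even in the
#' single-layer limit \eqn{\delta v' \to 0}, where the density collapses to
#' the closed form \eqn{e^{-\Delta r / (v_0 \bar t)} / (v_0 \bar t)}.
#'
#' @param dr Displacement(s) in km, positive.
#' @param params A [kick_params()] object (its `t_bar` sets the travel-time
#'   scale).
#' @param t_min Lower truncation of the travel-time law in hours. The default
#'   0 is the pure exponential law used for the headline displacement
#'   prediction; set to `5/60` to match populations simulated with the 5-min
#'   trip filter (the law is then shifted so its mean is still `t_bar`).
#' @param k_form `"discrete"` (default) resolves the jump count as the
#'   superposition of ordinary Poisson terms, the exact law of the reduced
#'   sampler (jumps beyond the cap collapse onto the `v_max` atom);
#'   `"continuous"` mixes the Gamma-continued conditional density instead,
#'   matching [conditional_speed_pdf()] under the integral. The two agree
#'   in the single-layer limit but differ at small jump numbers, where the
#'   continuous analytic continuation spreads mass between the layers.
#' @return Density value(s) per km.
#' @examples
#' p <- kick_params(17.9, 20.9, 1.06, t_bar = 0.30)
#' displacement_pdf(c(1, 5, 20, 100), p)
#' @export
displacement_pdf <- function(dr, params, t_min = 0,
                             k_form = c("discrete", "continuous")) {
  stopifnot(inherits(params, "kick_params"), is.numeric(dr),
            is.numeric(t_min), length(t_min) == 1L, t_min >= 0)
  k_form <- match.arg(k_form)
  if (any(dr <= 0)) stop("'dr' must be positive")
  if (t_min >= params$t_bar)
    stop("'t_min' must be smaller than the mean travel time")
  v0 <- params$v0; dvh <- params$dv_half; ph <- params$p_half
  tb <- params$t_bar
  k_max <- (params$v_max - v0) / dvh
  scale <- if (t_min > 0) tb - t_min else tb
  p_t <- function(tt) {
    d <- exp(-(tt - t_min) / scale) / scale
    d[tt < t_min] <- 0
    d
  }
  if (k_form == "discrete") {
    ## P(dr) = sum_k Pois(k; p' dr/v_k) P_T(dr/v_k) / v_k, with every k past
    ## the cap collapsing onto the v_max atom (one closed-form tail term);
    ## the sum is truncated where the Poisson mass is negligible for every dr
    k_cap <- ceiling(k_max - 1e-12)              # first k with v_k >= v_max
    k_lim <- .k_upper(ph * max(dr) / v0, k_cap)
    ks <- seq_len(max(min(k_cap, k_lim + 1), 1)) - 1  # 0 .. min(k_cap, klim)-ish
    vk <- v0 + ks * dvh
    out <- numeric(length(dr))
    for (j in seq_along(ks)) {
      tt <- dr / vk[j]
      out <- out + stats::dpois(ks[j], ph * tt) * p_t(tt) / vk[j]
    }
    tt <- dr / params$v_max
    out + stats::ppois(k_cap - 1L, ph * tt, lower.tail = FALSE) *
      p_t(tt) / params$v_max
  } else {
    vapply(dr, function(r) {
      lam_max <- ph * r / v0
      f <- function(kk) {
        vk <- v0 + kk * dvh
        tt <- r / vk
        lam <- ph * tt
        w <- poisson_weight(kk, lam) / .cond_norm(lam, params)
        p_t(tt) * w * dvh / vk
      }
      stats::integrate(f, 0, .k_upper(lam_max, k_max), rel.tol = 1e-8,
                       abs.tol = 1e-12, subdivisions = 400L)$value
    }, numeric(1))
  }
}

#' Displacement density of the Brownian-velocity null model
#'
#' Under the null model the displacement at fixed duration is Gaussian with
#' mean `v_drift * t` and variance `D t^3 / 3` (integrated Brownian
#' velocity). The displacement modulus density is the fold of that kernel
#' mixed over the exponential travel-time law, evaluated by adaptive
#' quadrature. This brute-force integral is the oracle against which the
#' saddle-point tail analysis is checked.
#'
#' @param dr Displacement modulus(es) in km, positive.
#' @param params A [null_params()] object.
#' @return Density value(s) per km, normalized over `(0, Inf)`.
#' @examples
#' np <- null_params(D = 500, t_bar = 0.30)
#' null_displacement_pdf(c(1, 5, 20), np)
#' @export
null_displacement_pdf <- function(dr, params) {
  stopifnot(inherits(params, "null_params"), is.numeric(dr))
  if (any(dr <= 0)) stop("'dr' must be positive")
  D <- params$D; vd <- params$v_drift; tb <- params$t_bar
  vapply(dr, function(r) {
    ## integrate in log-time: the kernel is sharply cut off below
    ## t ~ (dr^2/D)^(1/3) while the integrand grows like t^(-3/2) above it,
    ## which defeats a naive quadrature on (0, Inf) at small dr
    g <- function(s) {
      tt <- exp(s)
      sd <- sqrt(D * tt^3 / 3)
      (stats::dnorm(r, vd * tt, sd) + stats::dnorm(-r, vd * tt, sd)) *
        exp(-tt / tb) / tb * tt
    }
    s_lo <- log(max(1e-12, (1.5 * r^2 / (D * 745))^(1 / 3)))
    s_hi <- log(700 * tb)
    stats::integrate(g, s_lo, s_hi, rel.tol = 1e-9, abs.tol = 1e-13,
                     subdivisions = 600L)$value
  }, numeric(1))
}

#' Stretched-exponential tail form of the displacement distribution
#'
#' The large-displacement tail obtained from the saddle-point evaluation of
#' the null model's displacement integral:
#' \deqn{P(\Delta r) \approx A\, \Delta r^{-\gamma}\,
#'       \exp(-C\, \Delta r^{\delta}),}
#' with stretching exponent \eqn{\delta = 1/2} and power-law prefactor
#' exponent \eqn{\gamma = 3/4} for the integrated-Brownian kernel (variance
#' growing as \eqn{t^3}); `C` then carries units \eqn{km^{-1/2}}. Both
#' exponents are exposed so alternative kernels can be explored.
#'
#' @param dr Displacement(s) in km, positive.
#' @param C Decay constant in km^(-stretch), positive.
#' @param amplitude Overall amplitude A (per km), default 1.
#' @param stretch Stretching exponent \eqn{\delta}, default 0.5.
#' @param prefactor Power-law prefactor exponent \eqn{\gamma}, default 0.75.
#' @return Density value(s), un-normalized unless `amplitude` is chosen so.
#' @examples
#' stretched_tail_pdf(c(10, 50, 200), C = 0.49)
#' @export
stretched_tail_pdf <- function(dr, C, amplitude = 1, stretch = 0.5,
                               prefactor = 0.75) {
  stopifnot(is.numeric(dr), is.numeric(C), length(C) == 1L)
  if (any(dr <= 0)) stop("'dr' must be positive")
  if (C <= 0) stop("'C' must be positive")
  amplitude * dr^(-prefactor) * exp(-C * dr^stretch)
}

#' Tail exponents of the null model by numeric saddle point
#'
#' Locates, for each displacement in a large-`dr` ladder, the travel time
#' `t*` minimizing the exponent
#' \eqn{\phi(t) = t/\bar t + \Delta r^2 / (2 \sigma^2(t))} of the
#' displacement integral, where \eqn{\sigma^2(t)} is the Gaussian kernel
#' variance (default `D t^3 / 3`, the integrated-Brownian kernel). The
#' stretching exponent is the slope of \eqn{\log \phi(t^*)} against
#' \eqn{\log \Delta r}; the prefactor exponent is the slope of
#' \eqn{\log \sigma(t^*)}, i.e. the power of \eqn{\Delta r} divided out of
#' the density when the integrand is evaluated at the saddle without the
#' Gaussian-fluctuation factor. For variance \eqn{\propto t} the closed-form
#' stretch is 1 (simple exponential tail); for \eqn{\propto t^3} it is 1/2
#' with prefactor 3/4.
#'
#' @param params A [null_params()] object.
#' @param variance_fun Kernel variance as a function of duration (hours ->
#'   km^2). Default `function(t) params$D * t^3 / 3`.
#' @param dr Ladder of large displacements (km) over which to regress;
#'   default log-spaced 1e3 to 1e6 km (asymptotic regime).
#' @return A list with `stretch`, `prefactor`, the saddle times `t_star`,
#'   and the exponent values `phi_star`.
#' @examples
#' np <- null_params(D = 500, t_bar = 0.30)
#' saddle_tail_exponent(np)$stretch # ~0.5
#' @export
saddle_tail_exponent <- function(params, variance_fun = NULL, dr = NULL) {
  stopifnot(inherits(params, "null_params"))
  if (is.null(variance_fun)) variance_fun <- function(t) params$D * t^3 / 3
  if (is.null(dr)) dr <- exp(seq(log(1e3), log(1e6), length.out = 40))
  tb <- params$t_bar
  phi <- function(tt, r) tt / tb + r^2 / (2 * variance_fun(tt))
  t_star <- vapply(dr, function(r) {
    o <- stats::optimize(phi, interval = c(1e-8, 1e8), r = r, tol = 1e-10)
    if (!is.finite(o$objective))
      stop("saddle-point minimization failed at dr = ", r)
    o$minimum
  }, numeric(1))
  phi_star <- phi(t_star, dr)
  ldr <- log(dr)
  stretch <- unname(stats::coef(stats::lm(log(phi_star) ~ ldr))[2])
  pref <- unname(stats::coef(
    stats::lm(log(sqrt(variance_fun(t_star))) ~ ldr))[2])
  list(stretch = stretch, prefactor = pref, t_star = t_star,
       phi_star = phi_star, dr = dr)
}

#' Tabulated probability density curve
#'
#' A light container for a density sampled on an ordered grid, with a
#' trapezoid-rule normalization check.
#'
#' @param grid Strictly increasing abscissa values (km or km/h).
#' @param density Non-negative density values, per unit of abscissa.
#' @param x_unit,d_unit Unit labels written to CSV headers.
#' @return An object of class `distribution_curve` (a data.frame with
#'   attributes).
#' @examples
#' g <- seq(0.1, 50, length.out = 200)
#' distribution_curve(g, exp(-g / 5) / 5)
#' @export
distribution_curve <- function(grid, density, x_unit = "km",
                               d_unit = "per_km") {
  stopifnot(is.numeric(grid), is.numeric(density),
            length(grid) == length(density), length(grid) >= 2L)
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  if (any(density < 0)) stop("'density' must be non-negative")
  structure(data.frame(x = grid, density = density),
            x_unit = x_unit, d_unit = d_unit,
            class = c("distribution_curve", "data.frame"))
}

#' Trapezoid-rule integral of a tabulated curve
#'
#' @param curve A [distribution_curve()].
#' @return The integral over the tabulated support.
#' @export
curve_mass <- function(curve) {
  stopifnot(inherits(curve, "distribution_curve"))
  pracma::trapz(curve$x, curve$density)
}

#' Write / read a tabulated curve as two-column CSV
#'
#' The header names the units, e.g. `x_km,density_per_km`.
#'
#' @param curve A [distribution_curve()].
#' @param path Output CSV path.
#' @return `write_curve_csv` returns `path` invisibly; `read_curve_csv`
#'   returns a [distribution_curve()].
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "distribution_curve"))
  df <- data.frame(curve$x, curve$density)
  names(df) <- c(paste0("x_", attr(curve, "x_unit")),
                 paste0("density_", attr(curve, "d_unit")))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) != 2L) stop("curve CSV must have exactly two columns")
  xu <- sub("^x_", "", names(df)[1])
  du <- sub("^density_", "", names(df)[2])
  distribution_curve(df[[1]], df[[2]], x_unit = xu, d_unit = du)
}
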