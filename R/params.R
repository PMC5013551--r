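#' Parameters of the layered kick model
#'
#' Bundles the generative parameters of the randomly accelerated walker on a
#' hierarchy of transport layers. A traveller starts at the base speed `v0`
#' (urban streets) and, at Poisson-distributed random times, jumps to the next
#' faster layer, gaining `2 * dv_half` km/h per jump, up to the speed cap
#' `v_max`. The canonical parameters are the *primed* pair actually fitted to
#' trip tables: the half-rate `p_half` (jumps per hour) and the half-gap
#' `dv_half` (km/h); the full per-phase rate `p = 2 * p_half` and layer gap
#' `dv = 2 * dv_half` are derived views, stored to avoid silent factor-of-two
#' mistakes.
#'
#' @param v0 Base speed in km/h, must be positive.
#' @param dv_half Speed half-gap \eqn{\delta v' = \delta v / 2} in km/h.
#' @param p_half Kick half-rate \eqn{p' = p / 2} in jumps per hour.
#' @param v_max Speed cap in km/h (default 130, the motorway limit used to
#'   truncate the speed support).
#' @param t_bar Mean travel time of the trip population in hours.
#'
#' @return An object of class `kick_params`: a list with the supplied fields
#'   plus derived `p`, `dv`, `n_layers = floor((v_max - v0) / dv)` and the
#'   discrete layer cap `v_cap = v0 + n_layers * dv`.
#'
#' @examples
#' kick_params(v0 = 17.9, dv_half = 20.9, p_half = 1.06)
#' @seealso [null_params()], [mean_speed()], [sample_mean_speed()]
#' @export
kick_params <- function(v0, dv_half, p_half, v_max = 130, t_bar = 0.30) {
  stopifnot(is.numeric(v0), length(v0) == 1L, is.finite(v0),
            is.numeric(dv_half), length(dv_half) == 1L, is.finite(dv_half),
            is.numeric(p_half), length(p_half) == 1L, is.finite(p_half),
            is.numeric(v_max), length(v_max) == 1L, is.finite(v_max),
            is.numeric(t_bar), length(t_bar) == 1L, is.finite(t_bar))
  if (v0 <= 0) stop("'v0' must be positive")
  if (dv_half <= 0) stop("'dv_half' must be positive")
  if (p_half <= 0) stop("'p_half' must be positive")
  if (v_max <= v0) stop("'v_max' must exceed 'v0'")
  if (t_bar <= 0) stop("'t_bar' must be positive")
  dv <- 2 * dv_half
  ## n_layers = 0 is allowed: a cap tighter than one full gap pins the
  ## discrete profile to the base speed
  n_layers <- as.integer(floor((v_max - v0) / dv))
  structure(
    list(v0 = v0, dv_half = dv_half, p_half = p_half,
         v_max = v_max, t_bar = t_bar,
         p = 2 * p_half, dv = dv,
         n_layers = n_layers, v_cap = v0 + n_layers * dv),
    class = "kick_params")
}

#' @export
print.kick_params <- function(x, ...) {
  cat("Layered kick model parameters\n")
  cat(sprintf("  v0      = %.3f km/h (base speed)\n", x$v0))
  cat(sprintf("  dv'     = %.3f km/h (half-gap; full gap dv = %.3f)\n",
              x$dv_half, x$dv))
  cat(sprintf("  p'      = %.4f /h   (half-rate; per-phase rate p = %.4f)\n",
              x$p_half, x$p))
  cat(sprintf("  v_max   = %.1f km/h; %d full layers (discrete cap %.1f km/h)\n",
              x$v_max, x$n_layers, x$v_cap))
  cat(sprintf("  t_bar   = %.3f h (mean travel time)\n", x$t_bar))
  invisible(x)
}

#' Number of transport layers implied by the speed cap
#'
#' The cap `v_max` limits the number of upward jumps to roughly
#' `(v_max - v0) / dv`. The discrete construction uses the floor of that
#' ratio; the headline "about three layers" statement refers to rounding it
#' to the nearest integer.
#'
#' @param params A [kick_params()] object.
#' @param method `"round"` (nearest integer, default) or `"floor"` (the
#'   largest fully fitting layer, used for capping simulated profiles).
#' @return Integer layer count.
#' @examples
#' layer_count(kick_params(17.9, 20.9, 1.06)) # 3
#' @export
layer_count <- function(params, method = c("round", "floor")) {
  stopifnot(inherits(params, "kick_params"))
  method <- match.arg(method)
  ratio <- (params$v_max - params$v0) / params$dv
  if (method == "round") as.integer(round(ratio)) else as.integer(floor(ratio))
}

#' Parameters of the Brownian-velocity null model
#'
#' The null model lets the (signed) velocity evolve as a Brownian motion with
#' diffusion coefficient `D`, starting from `v_drift`; the trip displacement
#' is the time integral of the velocity and the trip duration is exponential
#' with mean `t_bar`. Under this model the mean speed modulus grows like
#' \eqn{t^{1/2}}, which the kick model replaces with linear growth.
#'
#' @param D Velocity diffusion coefficient in (km/h)^2 per hour.
#' @param v_drift Initial / mean velocity in km/h (may be 0).
#' @param t_bar Mean travel time in hours.
#' @return An object of class `null_params`.
#' @examples
#' null_params(D = 500, v_drift = 0, t_bar = 0.30)
#' @seealso [simulate_null_trip()], [null_displacement_pdf()]
#' @export
null_params <- function(D, v_drift = 0, t_bar = 0.30) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(v_drift), length(v_drift) == 1L, is.finite(v_drift),
            is.numeric(t_bar), length(t_bar) == 1L, is.finite(t_bar))
  if (D <= 0) stop("'D' must be positive")
  if (t_bar <= 0) stop("'t_bar' must be positive")
  structure(list(D = D, v_drift = v_drift, t_bar = t_bar),
            class = "null_params")
}

#' @export
print.null_params <- function(x, ...) {
  cat("Brownian-velocity null model parameters\n")
  cat(sprintf("  D       = %.3f (km/h)^2/h\n", x$D))
  cat(sprintf("  v_drift = %.3f km/h\n", x$v_drift))
  cat(sprintf("  t_bar   = %.3f h\n", x$t_bar))
  invisible(x)
}
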