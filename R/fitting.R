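#' Fit the exponential travel-time law
#'
#' Maximum-likelihood fit of the left-truncated exponential law to trip
#' durations surviving the short-trip filter. By memorylessness the excess
#' `t - t_min` is exponential; the reported `t_bar` is the mean of the
#' filtered sample (the quantity the displacement prediction uses), with a
#' normal-approximation confidence interval.
#'
#' @param durations Trip durations in hours, all exceeding `t_min`; at
#'   least 30 values.
#' @param t_min Truncation threshold in hours (default 5 min).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `travel_time_fit`: list with `t_bar`, `ci`,
#'   `rate` (of the excess), `t_min`, `n`.
#' @examples
#' set.seed(1)
#' fit_travel_time(5 / 60 + rexp(1000, 1 / 0.2167))
#' @export
fit_travel_time <- function(durations, t_min = 5 / 60, conf = 0.95) {
  stopifnot(is.numeric(durations))
  if (length(durations) < 30) stop("need at least 30 durations")
  if (any(durations <= t_min))
    stop("all durations must exceed the threshold t_min")
  n <- length(durations)
  t_bar <- mean(durations)
  s <- stats::sd(durations)
  if (s < 1e-12 * max(t_bar, 1))
    warning("degenerate fit: all durations are (nearly) equal")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(t_bar = t_bar,
                 ci = t_bar + c(-1, 1) * z * s / sqrt(n),
                 rate = 1 / (t_bar - t_min),
                 t_min = t_min, n = n),
            class = "travel_time_fit")
}

#' @export
print.travel_time_fit <- function(x, ...) {
  cat(sprintf(
    "Travel-time fit: t_bar = %.4f h (CI %.4f-%.4f), excess rate %.3f /h, n = %d\n",
    x$t_bar, x$ci[1], x$ci[2], x$rate, x$n))
  invisible(x)
}

#' Bin trips into the conditional speed surface
#'
#' Produces the binned relative frequencies of mean speed given duration
#' used by the kick-parameter fit. Speeds are binned at integer km/h
#' (symmetric half-open bins `[v - 0.5, v + 0.5)`) on `[ceiling(v0), 130]`;
#' durations at 5-min intervals with centres 5, 10, ..., 180 min (edges
#' `[c - 2.5, c + 2.5)` min). Frequencies are normalized within each
#' duration bin. Trips outside the speed or duration window are dropped.
#'
#' @param trips Trip data.frame with `duration_h` and `mean_speed_kmh`
#'   (pre-filtered: path length > 1 km, duration > 5 min).
#' @param v0 Base speed in km/h fixing the lower speed edge.
#' @param v_max Upper speed bound (default 130 km/h).
#' @return An object of class `speed_surface`: list with `freq` and
#'   `counts` matrices (duration bins by speed bins), `t_centers_min`,
#'   `v_centers`, `n_per_tbin`, `t_mean_h` (within-bin mean duration,
#'   falling back to the bin centre when empty) and `n_trips`.
#' @examples
#' tr <- simulate_population(1000, kick_params(17.9, 20.9, 1.06), seed = 1)
#' s <- bin_speed_surface(tr, v0 = 17.9)
#' @export
bin_speed_surface <- function(trips, v0, v_max = 130) {
  stopifnot(is.data.frame(trips),
            all(c("duration_h", "mean_speed_kmh") %in% names(trips)))
  t_centers <- 5 * (1:36)
  v_centers <- ceiling(v0):v_max
  tm <- trips$duration_h * 60
  tbin <- floor((tm - 2.5) / 5) + 1
  vbin <- floor(trips$mean_speed_kmh + 0.5)
  keep <- tbin >= 1 & tbin <= 36 & vbin >= v_centers[1] & vbin <= v_max &
    trips$mean_speed_kmh >= v0
  tb <- factor(tbin[keep], levels = 1:36)
  vb <- factor(vbin[keep], levels = v_centers)
  counts <- matrix(as.numeric(table(tb, vb)), nrow = 36,
                   dimnames = list(t_centers, v_centers))
  n_per <- rowSums(counts)
  freq <- counts / pmax(n_per, 1)
  t_mean <- as.numeric(tapply(trips$duration_h[keep], tb, mean))
  empty <- is.na(t_mean)
  t_mean[empty] <- t_centers[empty] / 60
  structure(list(freq = freq, counts = counts, t_centers_min = t_centers,
                 v_centers = v_centers, n_per_tbin = n_per,
                 t_mean_h = t_mean, v0 = v0, v_max = v_max,
                 n_trips = sum(counts)),
            class = "speed_surface")
}

#' @export
print.speed_surface <- function(x, ...) {
  cat(sprintf(
    "Speed surface: %d trips, %d populated duration bins (of 36), speeds %d-%d km/h\n",
    x$n_trips, sum(x$n_per_tbin > 0), min(x$v_centers), max(x$v_centers)))
  invisible(x)
}

#' Base speed and acceleration from the mean-speed curve
#'
#' Ordinary least squares of binned mean speed against bin-centre duration
#' restricted to durations in `[0, 2]` h, giving the intercept (base speed
#' `v0`) and slope (effective acceleration `a`, which the kick model
#' identifies with `p_half * dv_half`).
#'
#' @param x Either a trip data.frame (`duration_h`, `mean_speed_kmh`),
#'   binned internally at 5-min intervals, or a data.frame with columns
#'   `t_h` and `v_mean` (a pre-binned curve; may carry an `n` column of
#'   bin counts).
#' @param weights `"none"` (default: plain OLS over bins) or `"counts"`
#'   (bins weighted by their trip counts, which keeps sparse long-duration
#'   bins from dominating the estimator's variance).
#' @return List of class `v0_fit` with `v0` (km/h), `a` (km/h^2), the
#'   fitted `curve` data.frame, and `n_bins`.
#' @examples
#' tr <- simulate_population(5000, kick_params(17.9, 20.9, 1.06), seed = 1)
#' fit_v0_accel(tr)
#' @export
fit_v0_accel <- function(x, weights = c("none", "counts")) {
  stopifnot(is.data.frame(x))
  weights <- match.arg(weights)
  if (all(c("t_h", "v_mean") %in% names(x))) {
    curve <- x[x$t_h <= 2, , drop = FALSE]
    if (!"n" %in% names(curve)) curve$n <- 1
  } else if (all(c("duration_h", "mean_speed_kmh") %in% names(x))) {
    tbin <- floor((x$duration_h * 60 - 2.5) / 5) + 1
    keep <- tbin >= 1 & tbin <= 24   # centres 5..120 min, i.e. [0, 2] h
    f <- factor(tbin[keep], 1:24)
    v_mean <- tapply(x$mean_speed_kmh[keep], f, mean)
    curve <- data.frame(t_h = 5 * (1:24) / 60, v_mean = as.numeric(v_mean),
                        n = tabulate(f, 24L))
    curve <- curve[!is.na(curve$v_mean), ]
  } else {
    stop("'x' must be a trip table or a (t_h, v_mean) curve")
  }
  if (nrow(curve) < 2 || length(unique(curve$t_h)) < 2)
    stop("need at least 2 populated duration bins with distinct centres")
  w <- if (weights == "counts") curve$n else rep(1, nrow(curve))
  fit <- stats::lm(v_mean ~ t_h, data = curve, weights = w)
  structure(list(v0 = unname(stats::coef(fit)[1]),
                 a = unname(stats::coef(fit)[2]),
                 curve = curve, n_bins = nrow(curve), weights = weights),
            class = "v0_fit")
}

#' @export
print.v0_fit <- function(x, ...) {
  cat(sprintf("Linear mean-speed fit on [0, 2] h: v0 = %.3f km/h, a = %.3f km/h^2 (%d bins)\n",
              x$v0, x$a, x$n_bins))
  invisible(x)
}

## model bin masses for one duration bin, continuous density version:
## Gamma-continued Poisson weight integrated over each integer speed bin
## (5-point midpoint rule), then renormalized across the speed window
.model_row_pdf <- function(p_half, dv_half, lam, v_centers, v0, v_max,
                           bin_model) {
  sub <- if (bin_model == "integral") seq(-0.4, 0.4, by = 0.2) else 0
  vv <- outer(v_centers, sub, "+")
  kk <- (vv - v0) / dv_half
  w <- matrix(poisson_weight(pmax(c(kk), 0), lam), nrow = nrow(vv))
  w[vv < v0 | vv > v_max] <- 0
  m <- rowMeans(w)
  s <- sum(m)
  if (s > 0 && is.finite(s)) m / s else rep(0, length(v_centers))
}

## discrete-atom version: Poisson mass at the sampler's support points
## v0 + k dv_half (clipped at v_max), dropped into integer speed bins
.model_row_atoms <- function(p_half, dv_half, lam, v_centers, v0, v_max) {
  k_hi <- as.integer(ceiling(lam + 30 * sqrt(lam + 1) + 30))
  k <- 0:k_hi
  vk <- pmin(v0 + k * dv_half, v_max)
  idx <- match(floor(vk + 0.5), v_centers)
  pr <- stats::dpois(k, lam)
  out <- numeric(length(v_centers))
  ok <- !is.na(idx)
  if (any(ok)) {
    acc <- rowsum(pr[ok], group = idx[ok])
    out[as.integer(rownames(acc))] <- acc[, 1]
  }
  s <- sum(out)
  if (s > 0) out / s else out
}

#' Fit the kick parameters from a binned speed surface
#'
#' Estimates the kick half-rate `p_half` and half-gap `dv_half` by
#' minimizing the squared differences between the binned empirical
#' conditional speed frequencies and the model frequencies, summed over all
#' populated duration bins simultaneously, with the base speed `v0` held
#' fixed.
#'
#' Two model columns are available. `model = "binned_pdf"` (default)
#' integrates the continuous conditional speed density over each integer
#' speed bin -- the form appropriate for continuous empirical speeds.
#' `model = "atoms"` places the discrete Poisson masses at the reduced
#' sampler's support points `v0 + k * dv_half`; it is the exact likeness of
#' populations drawn with [sample_mean_speed()], whose speeds are atomic, and is
#' the model used by the parameter-recovery experiments. Poisson means use
#' the within-bin mean durations stored in the surface.
#'
#' With `weights = "counts"` each duration bin's squared error is weighted
#' by its trip count, which prevents nearly empty long-duration bins from
#' dominating the objective; `"none"` is the plain unweighted sum.
#'
#' Optimization is multi-start: `"binned_pdf"` uses Nelder--Mead from a
#' Latin-hypercube of starting points within the bounds; `"atoms"` scans a
#' 0.05 km/h grid in `dv_half` (the objective is piecewise-constant in the
#' atom positions) with a 1-D golden-section solve in `p_half` at each grid
#' value. Ties are broken toward smaller `p_half`.
#'
#' @param surface A [bin_speed_surface()] result with at least 5 populated
#'   duration bins.
#' @param v0 Base speed in km/h (held fixed; typically from
#'   [fit_v0_accel()]).
#' @param model `"binned_pdf"` or `"atoms"` (see Details).
#' @param weights `"none"` (default) or `"counts"`.
#' @param bin_model For `"binned_pdf"`: `"integral"` (default, bin-averaged
#'   density) or `"center"` (density at the bin centre).
#' @param bounds List with elements `p_half` and `dv_half`, each a length-2
#'   numeric range. Defaults `p_half` in (0, 10] /h, `dv_half` in (0, 60]
#'   km/h.
#' @param n_starts Number of Latin-hypercube starts (default 16).
#' @param seed Integer seed for the start design (default 1).
#' @return An object of class `kick_fit`: list with `p_half`, `dv_half`,
#'   `v0`, `sse`, `n_trips`, `model`, `weights`, `convergence` and `trace`
#'   (best objective after each completed start / grid node, non-increasing
#'   by construction).
#' @examples
#' pars <- kick_params(17.9, 20.9, 1.06)
#' tr <- simulate_population(20000, pars, seed = 2)
#' s <- bin_speed_surface(tr, v0 = 17.9)
#' fit_kick_params(s, v0 = 17.9, model = "atoms", weights = "counts")
#' @export
fit_kick_params <- function(surface, v0,
                            model = c("binned_pdf", "atoms"),
                            weights = c("none", "counts"),
                            bin_model = c("integral", "center"),
                            bounds = list(p_half = c(1e-3, 10),
                                          dv_half = c(0.5, 60)),
                            n_starts = 16L, seed = 1L) {
  stopifnot(inherits(surface, "speed_surface"))
  model <- match.arg(model)
  weights <- match.arg(weights)
  bin_model <- match.arg(bin_model)
  pop <- which(surface$n_per_tbin > 0)
  if (length(pop) < 5) stop("need at least 5 populated duration bins")
  freq <- surface$freq[pop, , drop = FALSE]
  lam_t <- surface$t_mean_h[pop]
  w_t <- if (weights == "counts") surface$n_per_tbin[pop] else rep(1, length(pop))
  vc <- surface$v_centers
  vmx <- surface$v_max
  row_fun <- if (model == "atoms") {
    function(p_, d_, i) .model_row_atoms(p_, d_, p_ * lam_t[i], vc, v0, vmx)
  } else {
    function(p_, d_, i) .model_row_pdf(p_, d_, p_ * lam_t[i], vc, v0, vmx,
                                       bin_model)
  }
  sse <- function(p_, d_) {
    tot <- 0
    for (i in seq_along(pop)) {
      m <- row_fun(p_, d_, i)
      tot <- tot + w_t[i] * sum((m - freq[i, ])^2)
    }
    if (is.finite(tot)) tot else 1e10
  }
  trace <- numeric(0)
  if (model == "atoms") {
    dv_grid <- seq(bounds$dv_half[1], bounds$dv_half[2], by = 0.05)
    best <- list(sse = Inf, p = NA_real_, d = NA_real_)
    for (d_ in dv_grid) {
      o <- stats::optimize(function(p_) sse(p_, d_),
                           interval = bounds$p_half, tol = 1e-6)
      if (o$objective < best$sse - 1e-12 ||
          (abs(o$objective - best$sse) <= 1e-12 && o$minimum < best$p)) {
        best <- list(sse = o$objective, p = o$minimum, d = d_)
      }
      trace <- c(trace, best$sse)
    }
    conv <- 0L
  } else {
    set.seed(seed)
    ## Latin hypercube over (p_half, dv_half): one draw per stratum per
    ## dimension, strata randomly paired
    u1 <- (sample(n_starts) - stats::runif(n_starts)) / n_starts
    u2 <- (sample(n_starts) - stats::runif(n_starts)) / n_starts
    starts <- cbind(bounds$p_half[1] + u1 * diff(bounds$p_half),
                    bounds$dv_half[1] + u2 * diff(bounds$dv_half))
    clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])
    best <- list(sse = Inf, p = NA_real_, d = NA_real_)
    conv <- 1L
    for (s in seq_len(n_starts)) {
      o <- try(stats::optim(starts[s, ], function(par) {
        sse(clamp(par[1], bounds$p_half), clamp(par[2], bounds$dv_half))
      }, method = "Nelder-Mead",
      control = list(maxit = 400, reltol = 1e-10)), silent = TRUE)
      if (inherits(o, "try-error")) next
      conv <- 0L
      p_ <- clamp(o$par[1], bounds$p_half)
      d_ <- clamp(o$par[2], bounds$dv_half)
      if (o$value < best$sse - 1e-12 ||
          (abs(o$value - best$sse) <= 1e-12 && p_ < best$p)) {
        best <- list(sse = o$value, p = p_, d = d_)
      }
      trace <- c(trace, best$sse)
    }
    if (conv == 1L) stop("optimizer failed to converge from every start")
  }
  structure(list(p_half = best$p, dv_half = best$d, v0 = v0,
                 sse = best$sse, n_trips = surface$n_trips,
                 model = model, weights = weights, trace = trace,
                 convergence = conv, seed = seed),
            class = "kick_fit")
}

#' @export
print.kick_fit <- function(x, ...) {
  cat(sprintf(
    "Kick-parameter fit (%s model, %s weights): p' = %.4f /h, dv' = %.3f km/h\n",
    x$model, x$weights, x$p_half, x$dv_half))
  cat(sprintf("  v0 fixed at %.2f km/h; SSE = %.6g over %d trips\n",
              x$v0, x$sse, x$n_trips))
  invisible(x)
}

#' Predict the displacement distribution from fitted parameters
#'
#' The forward workflow: model parameters in, displacement density out,
#' with no refitting -- the displacement curve is a prediction, not an a
#' posteriori fit. Evaluates [displacement_pdf()] on a log-spaced grid.
#'
#' @param params A [kick_params()] object (needs `t_bar`).
#' @param dr_grid Displacement grid in km; default log-spaced 0.003--600 km
#'   (wide enough that the tabulated curve carries essentially all mass
#'   under the pure exponential travel-time law).
#' @param t_min Travel-time truncation passed to [displacement_pdf()].
#' @param k_form Jump-count treatment passed to [displacement_pdf()].
#' @return A [distribution_curve()] over `dr_grid`.
#' @examples
#' curve <- predict_displacement_curve(kick_params(17.9, 20.9, 1.06))
#' curve_mass(curve)
#' @export
predict_displacement_curve <- function(params,
                                       dr_grid = exp(seq(log(0.003), log(600),
                                                         length.out = 220)),
                                       t_min = 0,
                                       k_form = c("discrete", "continuous")) {
  stopifnot(inherits(params, "kick_params"))
  distribution_curve(dr_grid,
                     displacement_pdf(dr_grid, params, t_min = t_min,
                                      k_form = match.arg(k_form)),
                     x_unit = "km", d_unit = "per_km")
}
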