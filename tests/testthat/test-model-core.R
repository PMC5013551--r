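test_that("mean speed grows linearly from the base speed and saturates at the cap", {
  p <- headline_params()
  expect_equal(mean_speed(0, p), 17.9)
  expect_equal(mean_speed(1, p), 17.9 + 1.06 * 20.9) # 40.054 km/h
  expect_equal(mean_speed(1e6, p), p$v_max)
  expect_error(mean_speed(-0.1, p), "non-negative")
})

test_that("the Gamma-continued Poisson weight extends the pmf to real counts", {
  expect_equal(poisson_weight(0, 0), 1)
  expect_equal(poisson_weight(2, 2), exp(-2) * 4 / 2, tolerance = 1e-12)
  # at integer counts it must coincide with the standard Poisson pmf
  for (lam in c(0.1, 1, 5, 20)) {
    k <- 0:60
    expect_equal(poisson_weight(k, lam), dpois(k, lam), tolerance = 1e-12)
  }
  # log-space evaluation survives values that overflow a naive lam^k
  expect_true(is.finite(poisson_weight(400, 400)))
  expect_gt(poisson_weight(400, 400), 0)
  expect_error(poisson_weight(-1, 2), "non-negative")
  expect_error(poisson_weight(2, -1), "non-negative")
})

test_that("conditional speed density is supported on [v0, v_max] and normalized", {
  p <- headline_params()
  expect_equal(conditional_speed_pdf(c(5, 17.89), 1, p), c(0, 0))
  expect_equal(conditional_speed_pdf(131, 1, p), 0)
  for (t in c(0.25, 1, 3)) {
    vg <- seq(p$v0, p$v_max, by = 0.01)
    expect_equal(pracma::trapz(vg, conditional_speed_pdf(vg, t, p)), 1,
                 tolerance = 1e-6)
  }
  expect_error(conditional_speed_pdf(40, 0, p), "positive")
})

test_that("conditional speed density peaks where the continued Poisson weight peaks", {
  p <- headline_params()
  t <- 1.4
  vg <- seq(p$v0, p$v_max, by = 0.005)
  d <- conditional_speed_pdf(vg, t, p)
  ## independent brute-force oracle: maximize the weight written out directly
  lam <- p$p_half * t
  k <- (vg - p$v0) / p$dv_half
  w <- exp(-lam + k * log(lam) - lgamma(1 + k))
  expect_equal(vg[which.max(d)], vg[which.max(w)], tolerance = 0.01)
})

test_that("conditional speed density is Poisson-proportional at the layer speeds", {
  p <- headline_params()
  t <- 0.8
  lam <- p$p_half * t
  k <- 0:5
  vk <- p$v0 + k * p$dv_half
  ratio <- conditional_speed_pdf(vk, t, p) / dpois(k, lam)
  expect_equal(ratio / ratio[1], rep(1, length(k)), tolerance = 1e-10)
})

test_that("the continuous-density mean approaches the model mean speed as jumps accumulate", {
  ## The analytic continuation spreads mass between layers, so at small
  ## Poisson means the continuous density's mean sits well above
  ## v0 + p' dv' t; the discrepancy shrinks monotonically with p' t and is
  ## under 2% by p' t = 2 (before the speed cap truncates the support).
  p <- headline_params()
  rel <- vapply(c(0.5, 1, 1.5, 2) / p$p_half, function(t) {
    vg <- seq(p$v0, p$v_max, by = 0.01)
    d <- conditional_speed_pdf(vg, t, p)
    abs(pracma::trapz(vg, vg * d) - mean_speed(t, p)) / mean_speed(t, p)
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[4], 0.02)
})

test_that("displacement density is positive, normalized, and exact in the single-layer limit", {
  p <- headline_params()
  g <- exp(seq(log(0.003), log(600), length.out = 220))
  d <- displacement_pdf(g, p)
  expect_true(all(d >= 0))
  expect_equal(pracma::trapz(g, d), 1, tolerance = 1e-3)
  ## continuous-k variant normalizes too
  expect_equal(pracma::trapz(g, displacement_pdf(g, p, k_form = "continuous")),
               1, tolerance = 1e-3)
  ## dv' -> 0: a single layer at v0 makes dr = v0 t exponential
  p0 <- kick_params(17.9, 1e-6, 1.06, t_bar = 0.30)
  x <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
  closed <- exp(-x / (17.9 * 0.30)) / (17.9 * 0.30)
  expect_lt(max(abs(displacement_pdf(x, p0) - closed)), 1e-4)
  expect_lt(max(abs(displacement_pdf(x, p0, k_form = "continuous") - closed)),
            1e-4)
  expect_error(displacement_pdf(-1, p), "positive")
  expect_error(displacement_pdf(1, p, t_min = 1), "t_min")
})

test_that("displacement density reproduces the reduced sampler's histogram", {
  p <- headline_params()
  set.seed(71)
  n <- 2e5
  tr <- simulate_population(n, p, mode = "reduced", t_min = 5 / 60)
  dr <- tr$path_length_km
  q <- unname(quantile(dr, seq(0, 1, 0.1)))
  support_lo <- p$v0 * 5 / 60
  mass <- vapply(1:10, function(i) {
    lo <- max(q[i], support_lo + 1e-9)
    hi <- if (i == 10) 2000 else q[i + 1]
    g <- exp(seq(log(lo), log(hi), length.out = 150))
    pracma::trapz(g, displacement_pdf(g, p, t_min = 5 / 60))
  }, numeric(1))
  z <- (0.1 - mass) / sqrt(mass * (1 - mass) / n)
  expect_true(all(abs(z) < 3))
})

test_that("null-model displacement density is normalized, unimodal-tailed, and matches simulation", {
  np <- null_params(D = 500, t_bar = 0.30)
  ## the folded density has an integrable dr^(-1/2)-type spike at the
  ## origin (vanishing travel times), so the grid must reach well below it
  g <- exp(seq(log(1e-7), log(400), length.out = 500))
  d <- null_displacement_pdf(g, np)
  expect_equal(pracma::trapz(g, d), 1, tolerance = 1e-3)
  ## monotone decreasing beyond the mode
  gi <- seq(1, 150, by = 0.5)
  di <- null_displacement_pdf(gi, np)
  m <- which.max(di)
  expect_true(all(diff(di[m:length(di)]) <= 1e-12))
  ## Monte-Carlo oracle: exponential durations, Euler velocity walk
  set.seed(5)
  n <- 1e4
  tt <- rexp(n, 1 / np$t_bar)
  x <- vapply(seq_len(n), function(i) {
    ns <- 200L
    dt <- tt[i] / ns
    v <- cumsum(c(0, rnorm(ns - 1L, 0, sqrt(np$D * dt))))
    abs(sum(v) * dt)
  }, numeric(1))
  q <- unname(quantile(x, seq(0, 1, 0.1)))
  mass <- vapply(1:10, function(i) {
    lo <- max(q[i], 1e-7)
    hi <- if (i == 10) max(x) * 3 else q[i + 1]
    g <- exp(seq(log(lo), log(hi), length.out = 120))
    pracma::trapz(g, null_displacement_pdf(g, np))
  }, numeric(1))
  z <- (0.1 - mass) / sqrt(mass * (1 - mass) / n)
  expect_true(all(abs(z) < 3))
  expect_error(null_displacement_pdf(0, np), "positive")
})

test_that("stretched tail form has the stated functional identities", {
  C <- 0.49
  x <- exp(seq(log(2), log(500), length.out = 60))
  lp <- log(stretched_tail_pdf(x, C))
  ## log pdf + C dr^(1/2) + (3/4) log dr is constant in dr
  expect_equal(diff(range(lp + C * x^0.5 + 0.75 * log(x))), 0,
               tolerance = 1e-12)
  ## scaling identity across a factor 16 in displacement
  r <- stretched_tail_pdf(16 * x, C) / stretched_tail_pdf(x, C)
  expect_equal(r, exp(-C * (16^0.5 - 1) * x^0.5) * 16^-0.75,
               tolerance = 1e-12)
  ## round-trip: regress out the prefactor, recover the stretching exponent
  y <- log(-log(stretched_tail_pdf(x, C) * x^0.75))
  fit <- lm(y ~ log(x))
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 1e-9)
  expect_error(stretched_tail_pdf(-1, C), "positive")
  expect_error(stretched_tail_pdf(1, -1), "positive")
})

test_that("saddle-point analysis recovers the known tail exponents", {
  np <- null_params(D = 400, t_bar = 0.30)
  ## integrated-Brownian kernel (variance ~ t^3): stretch 1/2, crude-saddle
  ## prefactor 3/4 -- the published exponent pair of the stretched tail
  s3 <- saddle_tail_exponent(np)
  expect_equal(s3$stretch, 0.5, tolerance = 0.02)
  expect_equal(s3$prefactor, 0.75, tolerance = 0.02)
  ## Laplace closed form for plain diffusion (variance ~ t): simple
  ## exponential tail
  s1 <- saddle_tail_exponent(np, variance_fun = function(t) np$D * t)
  expect_equal(s1$stretch, 1, tolerance = 0.02)
})

test_that("tabulated curves validate, integrate, and round-trip through CSV", {
  g <- seq(0.001, 80, length.out = 2000)
  cu <- distribution_curve(g, exp(-g / 5) / 5)
  expect_equal(curve_mass(cu), 1, tolerance = 1e-3)
  expect_error(distribution_curve(rev(g), exp(-g / 5) / 5), "increasing")
  expect_error(distribution_curve(g, -exp(-g / 5)), "non-negative")
  path <- tempfile(fileext = ".csv")
  write_curve_csv(cu, path)
  cu2 <- read_curve_csv(path)
  expect_equal(cu2$x, cu$x, tolerance = 1e-12)
  expect_equal(cu2$density, cu$density, tolerance = 1e-12)
  expect_identical(attr(cu2, "x_unit"), "km")
})
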