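---
title: "Randomly accelerated walkers: model, estimation and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomly accelerated walkers: model, estimation and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelwalk)
```

This vignette is the package's methods account: the two models it
implements, the estimation pipeline, the numerical choices behind the
analytic curves, what the synthetic-data generator does and does not
emulate, and the known limitations.

## The layered kick model

Vehicular trips are modelled as a walk on a hierarchy of transport
layers. A trip of duration $t$ starts on the base layer $L_0$ with speed
$v_0$ (units: km/h; urban streets). During the ascending half of the
trip, jumps to the next faster layer arrive as a Poisson process with
rate $p$ per hour; each jump adds a fixed speed gap $\delta v$, so layer
$L_k$ has speed $v_k = v_0 + k\,\delta v$. The descending half mirrors
the ascent, returning the trip to $v_0$ at its destination. Averaging
the symmetric profile gives the triangle approximation
$\bar v \approx (v_0 + v_m)/2$ with $v_m$ the mid-trip maximum, hence

$$\bar v(t) = v_0 + p'\,\delta v'\,t, \qquad p' = p/2,\;
  \delta v' = \delta v/2,$$

linear growth of mean speed with duration. The primed half-parameters
are the canonical ones throughout the package (they are what the data
identify); the full-rate views `p`, `dv` are derived fields of
`kick_params()`, stored once to keep factor-of-two errors out of user
code. The speed cap `v_max` (default 130 km/h, the motorway limit)
truncates everything; at the default parameters
$(130 - v_0)/\delta v \approx 2.7$, i.e. about three layers, matching
the 50 / 90 / 130 km/h progression of national speed limits.

Conditional on $t$, the jump count $k = (\bar v - v_0)/\delta v'$ is
Poisson with mean $\lambda = p' t$. Two readings of that law are
implemented and the distinction matters:

* **discrete atoms** — mean speeds sit exactly at $v_0 + k\,\delta v'$
  with ordinary Poisson masses. This is the generative law of the
  reduced sampler `sample_mean_speed()` and, via
  $P(\Delta r) = \sum_k \mathrm{Pois}(k;\, p'\Delta r/v_k)\,
  P_T(\Delta r/v_k)/v_k$, the default (`k_form = "discrete"`) of
  `displacement_pdf()`. Jumps beyond the cap collapse onto the
  $v_{max}$ atom (a single closed-form tail term).
* **continuous density** — `conditional_speed_pdf()` continues the
  Poisson weight to real $k$ through $\Gamma(1+k)$, giving a smooth
  density on $[v_0, v_{max}]$. This is the form fitted to *continuous*
  empirical speeds, and the `k_form = "continuous"` option of the
  displacement integral.

The continuation is not a reparameterisation: at small $\lambda$ the
continuous density spreads mass between the layers and its mean sits
well above $v_0 + \delta v' \lambda$ (29% relative at
$\lambda = 0.27$, still 1.2% at $\lambda = 2$; the property tests pin
this convergence down). Monte-Carlo identity tests therefore always pair
the discrete analytic form with the atomic sampler; mixing the two
families produces apparent disagreements that are approximation error,
not sampling noise.

Travel times are exponential with mean $\bar t$ (hours). Populations
simulated with the 5-minute trip filter draw durations from the
left-truncated law $t_{min} + \mathrm{Exp}(\bar t - t_{min})$, whose
mean is exactly the filtered-sample mean $\bar t$ that
`fit_travel_time()` reports. `displacement_pdf()` takes the matching
`t_min` argument; the headline forward prediction uses the pure
exponential (`t_min = 0`).

## The Brownian-velocity null model

The alternative the kick model displaces: velocity diffusing as a
Brownian motion with coefficient $D$ ((km/h)²/h), displacement the time
integral of velocity, hence Gaussian at fixed $t$ with variance
$D t^3/3$. Its signature is $\langle|\bar v|\rangle \propto t^{1/2}$ —
`simulate_null_trip()` and `simulate_null_population()` reproduce the
0.5 log–log slope, and the linear empirical speed law is what rejects
it. Mixing the folded Gaussian kernel over exponential travel times
(`null_displacement_pdf()`) and applying a saddle-point (Laplace)
analysis to the exponent $\phi(t) = t/\bar t + \Delta r^2/(2\sigma^2(t))$
gives the large-$\Delta r$ tail

$$P(\Delta r) \;\propto\; \Delta r^{-3/4}\,
  \exp\!\left(-C\,\Delta r^{1/2}\right),$$

a stretched exponential. On the exponent placement: with kernel variance
$\sigma^2(t) \propto t^3$, the minimiser scales as
$t^* \propto \Delta r^{1/2}$, so the stretch exponent is $1/2$ — which
is also what dimensional analysis of the decay constant ($C$ in
km$^{-1/2}$) requires — while $3/4$ is the power of $\Delta r$
accumulated by the integrand's prefactor $\sigma(t^*)^{-1}$ at the
saddle. `saddle_tail_exponent()` computes both numerically for any
user-supplied variance function and is validated against the Laplace
closed forms: variance $\propto t$ gives stretch 1 (plain exponential),
variance $\propto t^3$ gives stretch $1/2$. `stretched_tail_pdf()`
exposes both exponents as arguments with these defaults.

## The estimation pipeline

Fitting proceeds in the order the identifiability structure dictates:

1. **`fit_travel_time()`** — maximum likelihood for the left-truncated
   exponential; reports the filtered-sample mean (the quantity the
   displacement prediction consumes) with a normal-approximation CI.
   MLE rather than histogram regression: no binning arbitrariness.
2. **`fit_v0_accel()`** — the binned mean-speed line on $[0, 2]$ h
   (5-min bins, centres 5–120 min). The intercept estimates $v_0$, the
   slope the effective acceleration $a = p'\delta v'$. Plain OLS over
   bins is the default; `weights = "counts"` is provided because
   long-duration bins hold very few trips yet carry high leverage — at
   $10^6$ trips the unweighted intercept wanders by $\pm 2.4\%$ across
   seeds while the weighted one is stable to $\pm 0.1\%$ (with a $+0.8\%$
   residual from the exponential tilt of durations within each bin).
   Recovery experiments use the weighted form.
3. **`bin_speed_surface()`** — integer-km/h speed bins
   $[v-0.5, v+0.5)$ on $[\lceil v_0\rceil, 130]$, 5-min duration bins
   $[c-2.5, c+2.5)$ with centres 5–180 min, frequencies normalized
   within each duration bin; half-open edges make the binning exact and
   order-invariant. The surface stores within-bin mean durations, which
   the fit uses as Poisson means (bin centres would bias $p'$ by
   $\approx 2\%$).
4. **`fit_kick_params()`** — minimises the squared difference between
   empirical and model bin frequencies over all populated duration bins
   simultaneously, $v_0$ held fixed. The model column matches the data's
   nature: `"binned_pdf"` (continuous density integrated over each speed
   bin; `bin_model = "center"` evaluates at the centre instead,
   differing by under 0.5%) for continuous speeds, `"atoms"` for
   reduced-sampler populations — fitting the smooth density to atomic
   data biases $p'$ by $-11\%$, which is why both exist. Weighting the
   per-bin squared errors by trip counts (`weights = "counts"`) keeps
   nearly-empty bins from dominating the objective's noise (unweighted,
   the recovered $p'$ scatters $\pm 4\!-\!6\%$ across seeds; weighted,
   $\pm 0.5\%$). Optimisation is multi-start Nelder–Mead from a 16-point
   Latin hypercube within $p' \in (0, 10]$ /h, $\delta v' \in (0.5, 60]$
   km/h for the smooth model; the atom model's objective is
   piecewise-constant in the atom positions, so it is scanned on a
   0.05 km/h grid in $\delta v'$ (the reported half-gap's resolution)
   with a golden-section solve in $p'$ at each node. Ties break toward
   smaller $p'$; the incumbent trace is recorded and is non-increasing
   by construction.
5. **`predict_displacement_curve()`** — parameters in, $P(\Delta r)$
   out, no refitting.

Tail families for `fit_tail_model()` / `compare_tail_models()` are fit
by maximum likelihood above a cutoff (default 1 km, the trip filter):
exponential, pure power law (closed-form MLEs), stretched exponential
(Weibull-type, L-BFGS-B on $(\gamma, \log C)$), and the three-parameter
truncated power law $(\Delta r + \Delta r_0)^{-\beta} e^{-\Delta r/\kappa}$
with a numerically normalized likelihood — exponential data drive its
$\beta$ to 0, reproducing the convention that $\beta = 0$ rows mean
exponential behaviour. Comparison is by AIC with a Vuong-style standard
error on each log-likelihood difference (s.d. of pointwise contributions
times $\sqrt n$), so a ranking can be judged against its noise.

## Trip extraction rules

`segment_trips()` applies, per vehicle, to streams of engine events and
fixes:

* an engine-off gap of at least 5 min ends a trip (and is a rest);
* a gap under 30 s continues the trip *unless* the post-gap motion heads
  back toward the origin of the pre-gap segment — operationalised as
  displacement bearing within 30° of the origin direction *and* origin
  distance decreasing over the first three fixes, thresholds chosen to
  be robust at the 10–30 m position noise of insurance GPS devices;
* gaps between 30 s and 5 min continue the trip unconditionally, making
  the 5-min threshold the sole trip-end criterion.

Trip duration is wall-clock from first start to final stop (merged
micro-gaps count as driving time and are totalled per trip, so engine-on
time is conserved and auditable); path length sums fix-to-fix planar
distances, with the straight-line origin–destination distance also
emitted. `correct_signal_loss()` snaps a trip origin to the previous
stop when they disagree by more than 0.1 km (well above worst-case
noise), counting corrections. `filter_trips()` applies the strict
\>1 km, \>5 min filter. Free-flow speed is the 85th percentile of
per-road speeds under the linear-interpolation quantile convention
(type 7), validated against a sort-based oracle; `free_flow_profile()`
resamples per-trip free-flow series to relative trip time and exhibits
the mid-trip maximum that motivates the mirror construction.
`assign_residence()` takes the area holding the largest share of parking
time, ties broken to the earliest-observed area with a warning.
Coordinates are planar km internally; lon/lat files are projected at the
I/O boundary. Timestamps are ISO 8601 at second resolution.

## The synthetic fleet generator

`generate_fleet_log()` emulates the *structure* of insurance-device GPS
data: engine start/stop events; fixes at most 2 km apart, or 30 s on
roads at highway speeds (≥ 90 km/h); Gaussian position noise defaulting
to 20 m within the 10–30 m device band; rests of 5 min plus a lognormal
(meanlog $\log 0.75$, sdlog 0.6, in hours — a configurable plausibility
choice for trip/rest alternation, not an empirical claim); micro-stop
and signal-loss artifacts injected at configurable per-trip rates, every
injection recorded in the ground truth so extraction quality is scored
exactly. Trips run along a straight 1-D route with layer-labelled road
segments and square 10-km municipality tiles — a carrier for road ids,
positions and area labels, *not* a road network: no topology, no
origin–destination structure, no congestion, no 2-D geometry. Passing
extraction tests on these fleets therefore validates the segmentation
logic and bookkeeping, not robustness to map-matching error or urban
canyon noise.

## Numerical choices

* The Poisson weight is always evaluated in log space
  ($\lambda^k/\Gamma(1+k)$ overflows by $\lambda t \approx 30$).
* The continuous conditional density's normalizer and the
  continuous-form displacement integrand are computed by exact change of
  variables to the layer index $k = (v - v_0)/\delta v'$, integrated
  adaptively (absolute tolerance $10^{-12}$) with the upper limit
  $\min(K, \lambda + 30\sqrt{\lambda+1} + 30)$. A fixed speed-grid
  normalizer fails in the $\delta v' \to 0$ limit, where the weight
  becomes a sub-grid spike; in $k$-space the integrand stays order-one
  wide, and the single-layer closed form
  $e^{-\Delta r/(v_0\bar t)}/(v_0 \bar t)$ is reproduced to $10^{-9}$.
* `null_displacement_pdf()` integrates in log-time between the kernel's
  small-$t$ cutoff and $700\,\bar t$: the folded density has an
  integrable spike at $\Delta r \to 0$ (vanishing travel times) that
  defeats a naive quadrature on $(0,\infty)$.
* Degenerate inputs error early and loudly: non-positive durations or
  displacements, unsorted or non-alternating event streams (named by
  vehicle and timestamp), surfaces with fewer than five populated
  duration bins, tail fits with under 100 observations.

## Problem sizes in the tests

The test suite simulates at the sizes the claims are made at:
$10^6$-trip populations for parameter recovery (half-rate and half-gap
within 5%, base speed within 2%) and for decile-level Monte-Carlo
agreement of the analytic displacement curve (three binomial standard
errors per decile); $2\times 10^4$–$5\times 10^4$ replicates for
Poisson goodness-of-fit, integrated-Brownian variance and the
$t^{1/2}$ speed-scaling slope; $10^4$-trip fleets for the marginal-law
KS checks. Smaller sizes appear only where the property tested is exact
(binning, filtering, mirror symmetry, round-trips).

## Limitations

* The closed-form saturating $\bar v(t)$ under finitely many layers is
  not implemented; saturation is exercised by simulation only, and the
  discrete profile cap ($v_0 + \lfloor(v_{max}-v_0)/\delta v\rfloor\,
  \delta v$ = 101.5 km/h at the defaults) differs from the reduced
  sampler's 130 km/h clip, so the two simulation modes deliberately
  diverge for long trips.
* Parameters are constant: no congestion, no time-of-day or per-city
  variation of $v_0$, $p'$, $\delta v'$.
* Displacement means route length ($\Delta r = \bar v t$), not
  straight-line distance; both are emitted per extracted trip.
* The extraction module takes road ids as given annotations; there is no
  map matching.
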