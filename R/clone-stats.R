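#' Neutral-drift clone-size probability
#'
#' Probability that a mutant clone subject to neutral drift has size `n` at
#' time `t`:
#' \deqn{P_n(t) = \frac{1}{\ln(r\lambda t)} \frac{e^{-n/r\lambda t}}{n}}
#' where \eqn{r\lambda} is the stem-cell loss/replacement rate of the basal
#' layer (about 0.5 per week) and `t` is the elapsed time.
#'
#' @param n Clone size in cells (positive integer, vectorised).
#' @param r_lambda Loss/replacement rate, per cell per week.
#' @param t Elapsed time in weeks. `r_lambda * t` must exceed 1.
#' @return Probabilities, same length as `n`.
#' @export
neutral_pmf <- function(n, r_lambda, t) {
  a <- r_lambda * t
  if (a <= 1) abort("r_lambda * t must exceed 1 (log term undefined)")
  if (any(n < 1)) abort("clone size n must be >= 1")
  exp(-n / a) / (n * log(a))
}

#' Cumulative neutral-drift tail probability
#'
#' Probability under neutral drift of observing a clone of size `s` or larger
#' in a stem-cell population of `N` cells: the finite sum of [neutral_pmf()]
#' from `s` to `N`, evaluated stably in log space.
#'
#' @param s Minimum clone size (cells).
#' @param N Stem-cell population size.
#' @inheritParams neutral_pmf
#' @return A probability (0 when `s > N`).
#' @export
cumulative_tail <- function(s, N, r_lambda, t) {
  stopifnot(s >= 1)
  if (s > N) return(0)
  a <- r_lambda * t
  if (a <= 1) abort("r_lambda * t must exceed 1 (log term undefined)")
  n <- seq.int(s, N)
  lt <- -n / a - log(n) - log(log(a))
  m <- max(lt)
  exp(m + log(sum(exp(lt - m))))
}

#' Voter-model saturation time (Klein)
#'
#' Expected time for a lattice of `N` sites holding two cell types in neutral
#' competition (`r = 1/2`) to reach fixation of a single type:
#' \deqn{T = N(\ln N + 1/(2r))/\lambda.}
#' The result is in units of 1/`lam`; with `lam` per week, use
#' `weeks_to_years()` to convert.
#'
#' @param N Number of cells.
#' @param lam Loss/replacement rate (per week by convention).
#' @param r Time-step rate constant (1/2 for neutral competition).
#' @return Saturation time in the time unit of `lam`.
#' @export
klein_saturation_time <- function(N, lam, r = 0.5) {
  stopifnot(N >= 1, lam > 0)
  N * (log(N) + 1 / (2 * r)) / lam
}

#' Convert weeks to years
#'
#' Uses 365.25/7 = 52.18 weeks per year.
#' @param w Time in weeks.
#' @export
weeks_to_years <- function(w) w / (365.25 / 7)

#' Empirical first incomplete moment of a clone-size sample
#'
#' The normalised partial expectation
#' \deqn{\mu_1(n) = \frac{1}{\langle s \rangle} \sum_{m \ge n} m P_m}
#' estimated from a sample of clone sizes as the fraction of all cells (or
#' area, or VAF mass) residing in clones of size at least `n`. Equals 1 at the
#' minimum observed size and is non-increasing in `n`. Under neutral drift it
#' decays as \eqn{e^{-(n - n_0)/r\lambda t}}.
#'
#' @param sizes Positive clone sizes (cells, area or VAF).
#' @return A tibble with columns `n` (sorted unique sizes), `moment`, and
#'   `n_tail` (number of clones of size >= n).
#' @export
first_incomplete_moment <- function(sizes) {
  if (length(sizes) == 0) abort("empty clone-size sample")
  stopifnot(all(sizes > 0))
  r <- rle(sort(sizes))
  mass <- rev(cumsum(rev(r$values * r$lengths)))
  cnt <- rev(cumsum(rev(r$lengths)))
  tibble(n = r$values, moment = mass / sum(sizes), n_tail = cnt)
}

#' Fit the exponential incomplete-moment model of neutral drift
#'
#' Least-squares fit of the log empirical first incomplete moment against
#' clone size, returning the decay constant `r_lambda_t` (the mean size scale
#' of neutral clones, in the units of `sizes`) and the offset `n0` that
#' corrects for the detection size limit of sequencing:
#' \deqn{\mu_1(n) \approx e^{-(n - n_0)/r\lambda t}.}
#'
#' The fit uses the curve points with at least `min_tail` clones at or above
#' `n` (default 5), so the noisy extreme tail does not dominate the slope.
#'
#' @param sizes Positive clone sizes (at least 10, not all equal).
#' @param min_tail Minimum tail count for a curve point to enter the fit.
#' @return An object of class `icm_fit` with fields `r_lambda_t`, `n0`,
#'   `r_squared`, `fit_range`, `n_clones` and the fitted `curve`.
#' @export
fit_incomplete_moment <- function(sizes, min_tail = 5) {
  if (length(sizes) < 10) abort("need at least 10 clones to fit")
  if (length(unique(sizes)) < 3) abort("degenerate sample: clone sizes (nearly) all equal")
  curve <- first_incomplete_moment(sizes)
  pts <- curve[curve$n_tail >= min_tail & curve$moment > 0, ]
  if (nrow(pts) < 3) abort("too few distinct sizes above the tail-count floor")
  fit <- lm(log(moment) ~ n, data = pts)
  slope <- coef(fit)[["n"]]
  if (slope >= 0) abort("incomplete moment does not decay; exponential model inapplicable")
  a <- -1 / slope
  structure(list(r_lambda_t = a, n0 = a * coef(fit)[["(Intercept)"]],
                 r_squared = summary(fit)$r.squared,
                 fit_range = range(pts$n), n_clones = length(sizes),
                 curve = curve),
            class = "icm_fit")
}

#' @export
print.icm_fit <- function(x, ...) {
  cat(sprintf("Incomplete-moment fit: r*lambda*t = %.4g, n0 = %.4g (R^2 = %.4f, n = %d clones)\n",
              x$r_lambda_t, x$n0, x$r_squared, x$n_clones))
  invisible(x)
}

#' @method tidy icm_fit
#' @export
tidy.icm_fit <- function(x, ...) {
  tibble(term = c("r_lambda_t", "n0"), estimate = c(x$r_lambda_t, x$n0))
}

#' @method glance icm_fit
#' @export
glance.icm_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_clones = x$n_clones,
         fit_min = x$fit_range[1], fit_max = x$fit_range[2])
}

#' Boundary-nucleation clone-size density
#'
#' Geometric model of secondary (neutral) clones nucleating at the boundary of
#' an advantaged primary clone that expands radially at speed `alpha` to final
#' radius `R`. The number density of secondary clones of area `A` is
#' \deqn{M(A) = \frac{2\pi\gamma}{\sigma}\frac{1}{\alpha}
#'   \left(\sqrt{(A/\sigma)^2 + R^2} - A/\sigma\right)
#'   \left(\frac{A}{\sigma^2\sqrt{(A/\sigma)^2 + R^2}} - \frac{1}{\sigma}\right)}
#' The printed expression is negative because dr/dA < 0; the magnitude is
#' returned. For large `A` it approaches the inverse-cubic law
#' \eqn{(2\pi\gamma/\alpha)\,\sigma R^4/(4A^3)}.
#'
#' @param A Secondary clone area (same length unit squared as `sigma`, `R`).
#' @param sigma Cell diameter.
#' @param R Final primary-clone radius.
#' @param gamma Boundary nucleation constant (per boundary cell per time).
#' @param alpha Radial growth speed of the primary clone.
#' @return `|M(A)|`, vectorised over `A`.
#' @export
boundary_M <- function(A, sigma, R, gamma = 1, alpha = 1) {
  if (any(A <= 0)) abort("clone area A must be positive")
  stopifnot(R > sigma, sigma > 0, gamma > 0, alpha > 0)
  u <- A / sigma
  root <- sqrt(u^2 + R^2)
  # algebraically identical to the printed two-factor product
  # (root - u) * (A/(sigma^2 root) - 1/sigma), rewritten via
  # root - u = R^2/(root + u) to avoid cancellation at large A
  2 * pi * gamma * R^4 / (alpha * sigma^2 * (root + u)^2 * root)
}

#' Local log-log slope of the boundary-nucleation density
#'
#' Closed-form exponent
#' \deqn{\beta(A) = \frac{d\ln M(A)}{d\ln A}
#'   = -\frac{A(A + 2\sqrt{A^2 + \sigma^2 R^2})}{A^2 + \sigma^2 R^2}}
#' which tends to 0 as `A -> 0` and to -3 as `A -> Inf`: the distribution
#' approaches an inverse cubic power law once secondary clones are
#' non-negligible relative to the primary clone.
#'
#' @inheritParams boundary_M
#' @return `beta(A)`, vectorised.
#' @export
boundary_beta <- function(A, sigma, R) {
  stopifnot(all(A > 0))
  s2r2 <- sigma^2 * R^2
  -A * (A + 2 * sqrt(A^2 + s2r2)) / (A^2 + s2r2)
}

#' Exponential-growth clone-size density
#'
#' If primary and secondary clones expand exponentially at rate `b`, a clone
#' observed at time `T` that nucleated at time `t` has area
#' \eqn{A(t) = \pi(\sigma/2)^2 e^{b(T-t)}}, and the density of secondary clone
#' areas is
#' \deqn{M(A) = \frac{\gamma a \pi \sigma^2 e^{bT}}{4A}\frac{1}{bA}}
#' with `a` the initial clone area \eqn{\pi(\sigma/2)^2}: an exact inverse
#' square law, so the log-log slope is -2 for all `A` in the support
#' \eqn{(a, a e^{bT})}.
#'
#' @param A Clone area.
#' @param b Exponential growth rate (per time).
#' @param T_obs Observation time.
#' @param gamma Nucleation constant.
#' @param sigma Cell diameter.
#' @return `M(A)` (magnitude), vectorised.
#' @export
exponential_M <- function(A, b, T_obs, gamma = 1, sigma = 1) {
  stopifnot(b > 0, T_obs > 0, gamma > 0, sigma > 0)
  a <- pi * (sigma / 2)^2
  if (any(A < a | A > a * exp(b * T_obs)))
    abort("A outside the model support (a, a*exp(b*T))")
  gamma * a * pi * sigma^2 * exp(b * T_obs) / (4 * A) / (b * A)
}

#' Nucleation time of a clone of area A under exponential growth
#'
#' Inverts \eqn{A(t) = \pi(\sigma/2)^2 e^{b(T-t)}}:
#' \eqn{t(A) = T - (1/b)\ln(4A/(\pi\sigma^2))}.
#'
#' @inheritParams exponential_M
#' @export
exponential_nucleation_time <- function(A, b, T_obs, sigma = 1) {
  T_obs - log(4 * A / (pi * sigma^2)) / b
}

#' Fit a power law to clone sizes by log-log binned density
#'
#' Bins the sizes logarithmically (default 20 bins over `fit_range`), forms
#' the empirical density (count / bin width), and fits an unweighted least
#' squares line to log density vs log size over the non-empty bins. Residual
#' sums of squares against the fixed inverse-square (-2) and inverse-cubic
#' (-3) slopes are reported for model comparison.
#'
#' @param sizes Positive clone sizes (at least 20 within `fit_range`).
#' @param fit_range Numeric `c(min, max)`; defaults to the data range.
#' @param n_bins Number of logarithmic bins.
#' @return An object of class `powerlaw_fit` with `exponent`, `intercept`,
#'   `fit_range`, `rss`, `rss_slope2`, `rss_slope3`, `n_clones`, `bins`.
#' @export
fit_power_law <- function(sizes, fit_range = NULL, n_bins = 20) {
  stopifnot(all(sizes > 0))
  fit_range <- fit_range %||% range(sizes)
  x <- sizes[sizes >= fit_range[1] & sizes <= fit_range[2]]
  if (length(x) < 20) abort("need at least 20 clones within fit_range")
  if (diff(range(x)) == 0) abort("degenerate sample: all sizes equal")
  brk <- exp(seq(log(fit_range[1]), log(fit_range[2]), length.out = n_bins + 1))
  cnt <- graphics::hist(x, breaks = brk, plot = FALSE)$counts
  width <- diff(brk)
  mid <- sqrt(brk[-1] * brk[-length(brk)])
  keep <- cnt > 0
  bins <- tibble(mid = mid[keep], density = (cnt / width)[keep])
  fit <- lm(log(density) ~ log(mid), data = bins)
  lx <- log(bins$mid); ly <- log(bins$density)
  rss_fixed <- function(sl) sum((ly - sl * lx - mean(ly - sl * lx))^2)
  structure(list(exponent = coef(fit)[["log(mid)"]],
                 intercept = coef(fit)[["(Intercept)"]],
                 fit_range = fit_range, rss = sum(fit$residuals^2),
                 rss_slope2 = rss_fixed(-2), rss_slope3 = rss_fixed(-3),
                 n_clones = length(x), bins = bins),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: exponent = %.3f over [%.3g, %.3g] (n = %d clones)\n",
              x$exponent, x$fit_range[1], x$fit_range[2], x$n_clones))
  cat(sprintf("  RSS free slope %.3g | slope -2: %.3g | slope -3: %.3g\n",
              x$rss, x$rss_slope2, x$rss_slope3))
  invisible(x)
}

#' @method tidy powerlaw_fit
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("exponent", "intercept"),
         estimate = c(x$exponent, x$intercept))
}

#' @method glance powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(rss = x$rss, rss_slope2 = x$rss_slope2, rss_slope3 = x$rss_slope3,
         n_clones = x$n_clones)
}

#' Convert a variant allele fraction to cell counts and clone area
#'
#' Under the heterozygous diploid convention a clone occupying a cell fraction
#' f of the biopsy has VAF = f/2. With a linear progenitor density of
#' `linear_density` cells per mm, a biopsy of `area_mm2` holds
#' `linear_density^2 * area_mm2` basal cells; e.g. VAF 0.20 in a 16 mm^2
#' biopsy at 100 cells/mm is 40% of the population: 64,000 cells, 6.4 mm^2.
#'
#' @param vaf Variant allele fraction in (0, 0.5].
#' @param area_mm2 Biopsy surface area in mm^2.
#' @param linear_density Linear cell density, cells per mm.
#' @return A tibble with `vaf`, `cell_fraction`, `cells`, `area_mm2`.
#' @export
vaf_to_cells <- function(vaf, area_mm2, linear_density = 100) {
  if (any(vaf <= 0)) abort("vaf must be positive")
  if (any(vaf > 0.5)) abort("vaf exceeds the heterozygous diploid bound of 0.5")
  frac <- 2 * vaf
  tibble(vaf = vaf, cell_fraction = frac,
         cells = frac * linear_density^2 * area_mm2,
         area_mm2 = frac * area_mm2)
}
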