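#' Gamma model of among-site rate heterogeneity
#'
#' Relative site rates follow a gamma distribution with shape `alpha` and
#' mean fixed at 1 (scale chosen so the expectation is 1). Small `alpha`
#' means strong heterogeneity: a few fast sites carry most mutations.
#' `ncat` discrete equal-probability categories approximate the continuous
#' density for simulation; `ncat = Inf` denotes the continuous
#' distribution itself (the default used by the corrected estimators).
#'
#' @param alpha shape parameter (> 0). `Inf` is accepted and means uniform
#'   rates (no heterogeneity).
#' @param ncat number of discrete categories (>= 1), or `Inf`.
#' @return object of class `gamma_rate_model`.
#' @export
gamma_rate_model <- function(alpha, ncat = Inf) {
  if (!is.infinite(alpha) && alpha <= 0) stop("alpha must be positive")
  if (!is.infinite(ncat) && ncat < 1) stop("ncat must be >= 1")
  structure(list(alpha = alpha, ncat = ncat), class = "gamma_rate_model")
}

#' Discrete-gamma category rates
#'
#' Mean rates of `ncat` equal-probability slices of the gamma(alpha, alpha)
#' density (Yang's discretization by category means): category `i` gets the
#' conditional mean of the rate on its quantile slice, computable in closed
#' form from the incomplete-gamma identity
#' `E[r; r <= c] = P(G_{alpha+1} <= c alpha)` for `r ~ Gamma(alpha, alpha)`.
#' Rates are sorted ascending and average exactly 1.
#'
#' @param model a [gamma_rate_model] with finite `ncat`.
#' @return numeric vector of `ncat` rates with mean 1.
#' @export
discrete_gamma_rates <- function(model) {
  stopifnot(inherits(model, "gamma_rate_model"))
  k <- model$ncat
  if (is.infinite(k)) stop("ncat is Inf (continuous); no categories to report")
  if (is.infinite(model$alpha)) return(rep(1, k))
  a <- model$alpha
  cuts <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = a, rate = a)
  upper_mass <- stats::pgamma(cuts, shape = a + 1, rate = a)
  k * diff(upper_mass)
}

# expectation of f(r) under the rate model (continuous: adaptive quadrature
# on the gamma density; discrete: average over category mean rates)
rate_expectation <- function(f, model) {
  if (is.infinite(model$alpha)) return(f(1))
  if (is.finite(model$ncat)) return(mean(vapply(discrete_gamma_rates(model), f, 0)))
  a <- model$alpha
  # integrate over the essential support; keeps the quadrature honest for
  # very peaked (large alpha) and very skewed (small alpha) densities
  lo <- stats::qgamma(1e-14, shape = a, rate = a)
  hi <- stats::qgamma(1e-14, shape = a, rate = a, lower.tail = FALSE)
  stats::integrate(function(r) vapply(r, f, 0) * stats::dgamma(r, a, rate = a),
                   lo, hi, rel.tol = 1e-9, subdivisions = 2000L)$value
}

#' Expected per-site polymorphism under the finite-sites gamma model
#'
#' Exact single-site expectations of the three polymorphism statistics for
#' a neutral constant-size coalescent sample of `n` sequences mutating
#' under a Jukes-Cantor process at relative rate `r ~ gamma`, with mean
#' scaled mutation rate `theta` per site. Writing `x = theta * r`, a JC
#' mutation is equivalent to a redraw of the base uniformly from all four
#' at rate `4x/3` (per pair-coalescent time unit); the redraws partition
#' the sample into Ewens blocks with parameter `4x/3`, each block an
#' independent uniform base, which yields closed forms:
#' \itemize{
#' \item pairwise difference: `E[pi_site | r] = x / (1 + 4x/3)`
#' \item segregating: `E[S_site | r] = 1 - prod_{i=1}^{n-1} (i + x/3)/(i + 4x/3)`
#' \item minimum mutations: `E[eta_site | r] = 3 (1 - prod_{i=1}^{n-1} (i + x)/(i + 4x/3))`
#' }
#' All three reduce to `a1 * theta` (or `theta` for pi) as `theta -> 0`,
#' recovering the infinite-sites expectations.
#'
#' @param theta per-site scaled mutation rate (mean over sites).
#' @param model a [gamma_rate_model].
#' @param n sample size (needed for `S` and `eta`).
#' @return named vector `c(pi, S, eta)` of per-site expectations.
#' @export
expected_site_stats <- function(theta, model, n) {
  i <- seq_len(n - 1L)
  c(pi = rate_expectation(function(r) {
      x <- theta * r; x / (1 + 4 * x / 3)
    }, model),
    S = rate_expectation(function(r) {
      x <- theta * r; 1 - prod((i + x / 3) / (i + 4 * x / 3))
    }, model),
    eta = rate_expectation(function(r) {
      x <- theta * r; 3 * (1 - prod((i + x) / (i + 4 * x / 3)))
    }, model))
}

#' Finite-sites gamma-corrected estimators of the neutral parameter
#'
#' Method-of-moments estimators that invert the exact finite-sites
#' expectations of [expected_site_stats()]: given the observed statistic
#' (nucleotide diversity, segregating sites or the minimum number of
#' mutations), the estimate is the `theta` whose expectation matches the
#' observation under the gamma rate model. Corrections always increase the
#' uncorrected estimate (multiple hits hide mutations) and vanish in the
#' low-divergence limit; as `alpha -> Inf` they reduce to the uniform-rate
#' finite-sites estimators.
#'
#' @param input_kind `"pi"` (per-site nucleotide diversity), `"S"`
#'   (count of segregating sites) or `"Sstar"` (minimum number of
#'   mutations, eta).
#' @param value the observed statistic (a proportion for `"pi"`, a count
#'   otherwise).
#' @param n sample size (>= 2).
#' @param L included sites (used to convert counts to per-site scale).
#' @param model a [gamma_rate_model]; `ncat = Inf` (continuous) is the
#'   conventional choice for estimation.
#' @return object of class `corrected_theta` (list with `theta_hat` per
#'   site, `input_kind`, `value`, `n`, `L`, `alpha_used`, `ncat_used`,
#'   `theta_uncorrected`).
#' @export
corrected_theta <- function(input_kind = c("pi", "S", "Sstar"), value, n, L,
                            model) {
  input_kind <- match.arg(input_kind)
  stopifnot(inherits(model, "gamma_rate_model"), value >= 0, n >= 2, L >= 1)
  obs_per_site <- if (input_kind == "pi") value else value / L
  a1 <- tajima_coefficients(n)$a1
  uncor <- switch(input_kind, pi = value,
                  S = value / (a1 * L), Sstar = value / (a1 * L))
  if (value == 0) {
    th <- 0
  } else {
    key <- switch(input_kind, pi = "pi", S = "S", Sstar = "eta")
    # saturation ceilings of the expectations as theta -> Inf
    ceiling_ <- switch(input_kind, pi = 3 / 4,
                       S = 1 - (1 / 4)^(n - 1),
                       Sstar = 3 * (1 - (3 / 4)^(n - 1)))
    if (obs_per_site >= ceiling_)
      stop("observed ", input_kind, " (", signif(obs_per_site, 4),
           " per site) is at or above the finite-sites saturation ceiling ",
           signif(ceiling_, 4), "; the estimator is undefined")
    fn <- function(th) expected_site_stats(th, model, n)[[key]] - obs_per_site
    hi <- max(10 * uncor, 0.01)
    while (fn(hi) < 0 && hi < 1e6) hi <- hi * 4
    th <- stats::uniroot(fn, c(0, hi), tol = 1e-12)$root
  }
  structure(list(theta_hat = th, input_kind = input_kind, value = value,
                 n = n, L = L, alpha_used = model$alpha,
                 ncat_used = model$ncat, theta_uncorrected = uncor),
            class = "corrected_theta")
}

#' @export
print.corrected_theta <- function(x, ...) {
  cat(sprintf(
    "corrected theta (%s-based): %.4f per site  [uncorrected %.4f, alpha=%s]\n",
    x$input_kind, x$theta_hat, x$theta_uncorrected, format(x$alpha_used)))
  invisible(x)
}

#' Corrected D-type test statistic
#'
#' A finite-sites, rate-heterogeneity-aware analog of Tajima's D: the
#' contrast between the gamma-corrected pairwise-based and minimum-number-
#' of-mutations-based estimators of the neutral parameter, normalized by
#' Tajima's variance estimate evaluated at the observed minimum number of
#' mutations:
#' `D = L_eff (theta_pi_c - theta_Sstar_c) / sqrt(e1 eta + e2 eta (eta-1))`.
#' The statistic is 0 when the two corrected estimators coincide, carries
#' the sign of their difference, and reduces to an eta-based Tajima's D as
#' `alpha -> Inf` at low divergence. Compare to the beta interval or to a
#' simulated null ([build_null()]).
#'
#' @param a a [dna_alignment].
#' @param group optional group label.
#' @param model a [gamma_rate_model].
#' @return object of class `ds_star_plus`: list with `value`, `numerator`
#'   (per-locus estimator contrast), `denominator`, `theta_pi_hat`,
#'   `theta_Sstar_hat`, `eta`, `alpha_used`. `value` is `NA` when the
#'   group is monomorphic (`eta = 0`).
#' @export
ds_star_plus <- function(a, group = NULL, model) {
  sm <- summarize_polymorphism(a, group)
  if (sm$eta == 0L)
    return(structure(list(value = NA_real_, numerator = NA_real_,
                          denominator = NA_real_, theta_pi_hat = 0,
                          theta_Sstar_hat = 0, eta = 0L,
                          alpha_used = model$alpha),
                     class = "ds_star_plus"))
  tp <- corrected_theta("pi", sm$pi, sm$n, sm$L_eff, model)
  ts <- corrected_theta("Sstar", sm$eta, sm$n, sm$L_eff, model)
  co <- tajima_coefficients(sm$n)
  num <- sm$L_eff * (tp$theta_hat - ts$theta_hat)
  den <- sqrt(co$e1 * sm$eta + co$e2 * sm$eta * (sm$eta - 1))
  structure(list(value = num / den, numerator = num, denominator = den,
                 theta_pi_hat = tp$theta_hat, theta_Sstar_hat = ts$theta_hat,
                 eta = sm$eta, alpha_used = model$alpha),
            class = "ds_star_plus")
}

#' @export
print.ds_star_plus <- function(x, ...) {
  cat(sprintf("corrected D (Ds*+) = %.3f  [theta_pi=%.4f theta_S*=%.4f eta=%d alpha=%s]\n",
              x$value, x$theta_pi_hat, x$theta_Sstar_hat, x$eta,
              format(x$alpha_used)))
  invisible(x)
}
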