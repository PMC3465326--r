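#' Tajima's variance coefficients
#'
#' The dimensionless coefficients a1, a2, b1, b2, c1, c2, e1, e2 entering
#' Tajima's D and the variance of Watterson's estimator; all are functions
#' of the sample size only.
#'
#' @param n sample size (>= 2).
#' @return named list with components `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_coefficients <- function(n) {
  if (n < 2L) stop("need n >= 2")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Watterson's estimator of the neutral parameter (per site)
#'
#' `theta_W = S / (a1 * L)` with `a1` the harmonic number of `n - 1`.
#'
#' @param S number of segregating sites.
#' @param n sample size (>= 2).
#' @param L number of included sites.
#' @return per-site estimate.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2L) stop("need n >= 2")
  stopifnot(S >= 0, L >= 1)
  S / (tajima_coefficients(n)$a1 * L)
}

# Tajima's (1989) nearly-unbiased sampling variance of theta_W per locus
watterson_theta_var <- function(S, n) {
  co <- tajima_coefficients(n)
  S / co$a1^2 + co$a2 * S * (S - 1) / (co$a1^2 * (co$a1^2 + co$a2))
}

#' Mean pairwise differences within a group
#'
#' @param a a [dna_alignment].
#' @param group optional group label.
#' @param per_site divide by the number of included columns?
#' @return mean number (or proportion) of differing included sites over all
#'   unordered pairs.
#' @export
mean_pairwise_diff <- function(a, group = NULL, per_site = FALSE) {
  rows <- if (is.null(group)) seq_len(n_seq(a)) else group_rows(a, group)
  if (length(rows) < 2L) stop("need at least 2 sequences")
  inc <- included_columns(a, rows)
  m <- a$mat[rows, inc, drop = FALSE]
  n <- nrow(m)
  # per-column allele counts give the pairwise-difference total directly
  tot <- 0
  for (j in seq_len(ncol(m))) {
    cnt <- table(m[, j])
    tot <- tot + (n * (n - 1) / 2 - sum(cnt * (cnt - 1) / 2))
  }
  pit <- tot / (n * (n - 1) / 2)
  if (per_site) pit / sum(inc) else pit
}

#' Polymorphism summary for one group
#'
#' The standard single-locus summary row: sample size, included sites,
#' haplotype count and diversity, segregating sites, minimum number of
#' mutations, indel polymorphisms, nucleotide diversity and Watterson's
#' estimator, each with its sampling standard deviation where defined.
#' Haplotype diversity is `h = n/(n-1) (1 - sum p_i^2)` with Nei's variance;
#' the standard deviations of `pi` and `theta_W` use the no-recombination
#' (total) variances of Tajima (see the package vignette for the formulas).
#'
#' @param a a [dna_alignment].
#' @param group optional group label (default: all sequences).
#' @param missing_policy passed to [classify_sites()].
#' @return object of class `polymorphism_summary` (a list).
#' @export
summarize_polymorphism <- function(a, group = NULL,
                                   missing_policy = "complete") {
  rows <- if (is.null(group)) seq_len(n_seq(a)) else group_rows(a, group)
  n <- length(rows)
  if (n < 2L) stop("need at least 2 sequences in group")
  sub <- dna_alignment(apply(a$mat[rows, , drop = FALSE], 1L, paste, collapse = ""),
                       ids = rownames(a$mat)[rows],
                       groups = a$groups[rows])
  sc <- classify_sites(sub, missing_policy = missing_policy)
  inc <- included_columns(sub, missing_policy = missing_policy)
  L_eff <- sum(inc)
  S <- sum(sc$class == "segregating")
  eta <- sum(sc$eta_site)
  I <- attr(sc, "n_indel_events")
  hap <- collapse_haplotypes(sub)
  k <- nrow(hap)
  p <- hap$count / n
  h <- n / (n - 1) * (1 - sum(p^2))
  # Nei's (1987) sampling variance of haplotype diversity
  s2 <- sum(p^2)
  h_var <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  pit <- mean_pairwise_diff(sub)
  pi_site <- pit / L_eff
  co <- tajima_coefficients(n)
  pi_var_locus <- co$b1 * pit + co$b2 * pit^2   # no-recombination total variance
  thW <- watterson_theta(S, n, L_eff)
  thW_sd <- sqrt(watterson_theta_var(S, n)) / L_eff
  structure(list(
    group = if (is.null(group)) "all" else group,
    n = n, L = sub$L, L_eff = L_eff, k = k,
    h = h, h_sd = sqrt(max(h_var, 0)),
    S = S, eta = eta, I = I,
    pi = pi_site, pi_sd = sqrt(pi_var_locus) / L_eff,
    pi_total = pit,
    theta_W = thW, theta_W_sd = thW_sd,
    missing_policy = missing_policy
  ), class = "polymorphism_summary")
}

#' @export
print.polymorphism_summary <- function(x, ...) {
  cat(sprintf(
    "group %s: n=%d L=%d (L_eff=%d) k=%d h=%.3f (%.3f) S=%d eta=%d I=%d\n",
    x$group, x$n, x$L, x$L_eff, x$k, x$h, x$h_sd, x$S, x$eta, x$I))
  cat(sprintf("  pi=%.4f (%.4f)  theta_W=%.4f (%.4f)   [%s deletion]\n",
              x$pi, x$pi_sd, x$theta_W, x$theta_W_sd, x$missing_policy))
  invisible(x)
}

#' Tajima's D
#'
#' `D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S-1))`. Undefined when
#' `S = 0`; an explicit `NA` is returned (never silently 0).
#'
#' @param pi_total mean pairwise differences per locus.
#' @param S number of segregating sites.
#' @param n sample size.
#' @return the statistic, or `NA_real_` when `S = 0`.
#' @export
tajima_D <- function(pi_total, S, n) {
  if (S == 0L) return(NA_real_)
  co <- tajima_coefficients(n)
  (pi_total - S / co$a1) / sqrt(co$e1 * S + co$e2 * S * (S - 1))
}

#' Beta-distribution null interval for Tajima's D
#'
#' Tajima's scaled-beta approximation of the null distribution of D under
#' the infinite-sites model: D is assumed to range over `(Dmin, Dmax)` (the
#' extremes attainable as S grows large) and to follow the beta density on
#' that support whose mean is 0 and variance 1.
#'
#' @param n sample size (>= 4).
#' @param coverage two-sided coverage, default 0.95.
#' @return list with `lower`, `upper`, `Dmin`, `Dmax`, shape parameters
#'   `shape_upper` (weight toward `Dmax`) and `shape_lower`, and `density`,
#'   a vectorized density function.
#' @export
tajima_beta_interval <- function(n, coverage = 0.95) {
  if (n < 4L) stop("beta approximation needs n >= 4")
  co <- tajima_coefficients(n)
  Dmin <- (2 / n - 1 / co$a1) / sqrt(co$e2)
  pmax_ <- if (n %% 2L == 0L) n / (2 * (n - 1)) else (n + 1) / (2 * n)
  Dmax <- (pmax_ - 1 / co$a1) / sqrt(co$e2)
  a <- Dmin; b <- Dmax
  s <- -a * b - 1                      # alpha + beta from variance constraint
  sh_up <- -a * s / (b - a)            # mean-zero constraint
  sh_lo <- s - sh_up
  q <- stats::qbeta(c((1 - coverage) / 2, 1 - (1 - coverage) / 2),
                    sh_up, sh_lo)
  lims <- a + (b - a) * q
  dens <- function(x) ifelse(x <= a | x >= b, 0,
    stats::dbeta((x - a) / (b - a), sh_up, sh_lo) / (b - a))
  list(lower = lims[1L], upper = lims[2L], Dmin = Dmin, Dmax = Dmax,
       shape_upper = sh_up, shape_lower = sh_lo, density = dens,
       coverage = coverage)
}

# log unsigned Stirling numbers of the first kind, |s(n, k)| for k = 1..n,
# via the recursion |s(m,k)| = |s(m-1,k-1)| + (m-1)|s(m-1,k)| in log space
log_stirling_first <- function(n) {
  lse2 <- function(x, y) {
    m <- pmax(x, y)
    ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(pmin(x, y) - m)))
  }
  S <- matrix(-Inf, n + 1L, n + 1L)
  S[1L, 1L] <- 0
  for (m in seq_len(n)) for (k in seq_len(m)) {
    up <- S[m, k]
    right <- if (m >= 2L) S[m, k + 1L] + log(m - 1) else -Inf
    S[m + 1L, k + 1L] <- lse2(up, right)
  }
  S[n + 1L, seq_len(n) + 1L]
}

#' Ewens distribution of the number of alleles
#'
#' `P(K = k | theta, n)` under the Ewens sampling formula, computed from
#' unsigned Stirling numbers of the first kind in log space.
#'
#' @param n sample size.
#' @param theta scaled mutation rate conditioning the distribution
#'   (Fu's test plugs in the mean pairwise difference).
#' @return numeric vector of length `n`, `P(K = k)` for `k = 1..n`.
#' @export
ewens_k_pmf <- function(n, theta) {
  stopifnot(theta > 0, n >= 1)
  ls <- log_stirling_first(n)
  k <- seq_len(n)
  exp(ls + k * log(theta) - sum(log(theta + 0:(n - 1))))
}

#' Fu's Fs statistic
#'
#' `Fs = ln(S' / (1 - S'))` where `S' = P(K >= k_obs)` under the Ewens
#' distribution conditioned on the pairwise estimate of the scaled
#' mutation rate (`theta_hat` = mean pairwise differences per locus, per
#' Fu 1997). Strongly negative values indicate an excess of haplotypes, as
#' after demographic expansion or a selective sweep.
#'
#' @param a a [dna_alignment], or `NULL` when `theta_hat`/`k_obs`/`n` are
#'   given directly.
#' @param group optional group label.
#' @param theta_hat,k_obs,n direct inputs bypassing the alignment.
#' @return object of class `fu_fs` (list with `Fs`, `S_prime`, `theta_hat`,
#'   `k_obs`, `n`). `Fs` is `NA` (undefined) when `theta_hat = 0`;
#'   `S_prime` is clamped away from 0/1 with a warning if it underflows.
#' @export
fu_fs <- function(a = NULL, group = NULL, theta_hat = NULL, k_obs = NULL,
                  n = NULL) {
  if (!is.null(a)) {
    rows <- if (is.null(group)) seq_len(n_seq(a)) else group_rows(a, group)
    n <- length(rows)
    theta_hat <- mean_pairwise_diff(a, group)
    k_obs <- nrow(collapse_haplotypes(a, group))
  }
  stopifnot(!is.null(theta_hat), !is.null(k_obs), !is.null(n))
  if (theta_hat <= 0) {
    return(structure(list(Fs = NA_real_, S_prime = NA_real_,
                          theta_hat = theta_hat, k_obs = k_obs, n = n),
                     class = "fu_fs"))
  }
  pk <- ewens_k_pmf(n, theta_hat)
  Sp <- sum(pk[seq_len(n) >= k_obs])
  if (Sp <= 0 || Sp >= 1) {
    warning("S' at numerical bound; Fs clamped")
    Sp <- min(max(Sp, 1e-300), 1 - 1e-15)
  }
  structure(list(Fs = log(Sp / (1 - Sp)), S_prime = Sp,
                 theta_hat = theta_hat, k_obs = k_obs, n = n),
            class = "fu_fs")
}

#' @export
print.fu_fs <- function(x, ...) {
  cat(sprintf("Fu's Fs = %.3f  (k_obs=%d, theta_hat=%.3f, S'=%.4g, n=%d)\n",
              x$Fs, x$k_obs, x$theta_hat, x$S_prime, x$n))
  invisible(x)
}

#' Mean uncorrected divergence between two groups
#'
#' @param a a [dna_alignment].
#' @param group1,group2 group labels.
#' @return mean proportion of differing included sites over all
#'   cross-group pairs (complete-deletion columns over the joint sample).
#' @export
between_group_divergence <- function(a, group1, group2) {
  r1 <- group_rows(a, group1); r2 <- group_rows(a, group2)
  inc <- included_columns(a, c(r1, r2))
  m1 <- a$mat[r1, inc, drop = FALSE]
  m2 <- a$mat[r2, inc, drop = FALSE]
  tot <- 0
  for (i in seq_along(r1)) for (j in seq_along(r2))
    tot <- tot + sum(m1[i, ] != m2[j, ])
  tot / (length(r1) * length(r2)) / sum(inc)
}

#' Effective female population size from nucleotide diversity
#'
#' For a maternally inherited haploid locus the neutral expectation is
#' `pi = 2 N_ef mu`, so `N_ef = pi / (2 mu)`.
#'
#' @param pi nucleotide diversity (per site, or per genome if `mu` is per
#'   genome).
#' @param mu mutation rate per lineage per generation on the same scale as
#'   `pi`.
#' @return point estimate of `N_ef`.
#' @export
effective_size_from_pi <- function(pi, mu) {
  if (mu <= 0) stop("mu must be positive")
  stopifnot(pi >= 0)
  pi / (2 * mu)
}

#' Per-generation mutation rate from a pairwise divergence rate
#'
#' Converts a pairwise divergence rate (e.g. the avian mitochondrial
#' standard of 2% per million years between haplotype pairs) and a
#' generation time into a per-lineage per-generation rate:
#' `mu = T * rate / 2`.
#'
#' @param pairwise_rate_per_year divergence accumulated per haplotype pair
#'   per year (e.g. `0.02e-6`).
#' @param generation_time_years years per generation.
#' @return mutations per lineage per generation.
#' @export
mutation_rate_per_generation <- function(pairwise_rate_per_year,
                                         generation_time_years) {
  generation_time_years * pairwise_rate_per_year / 2
}
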