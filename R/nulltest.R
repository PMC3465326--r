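# fast per-alignment statistic block (complete-deletion, gap-free fast path)
alignment_stat_block <- function(a) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(match(a$mat, bases), nrow = nrow(a$mat))
  n <- nrow(m)
  cnt <- vapply(1:4, function(b) colSums(m == b, na.rm = TRUE),
                numeric(ncol(m)))
  if (ncol(m) == 1L) cnt <- matrix(cnt, nrow = 1L)
  keep <- rowSums(cnt) == n           # complete deletion of gap/ambiguous cols
  cnt <- cnt[keep, , drop = FALSE]
  L_eff <- sum(keep)
  distinct <- rowSums(cnt > 0)
  S <- sum(distinct >= 2L)
  eta <- sum(pmax(distinct - 1L, 0L))
  npair <- n * (n - 1) / 2
  pi_total <- sum(npair - rowSums(cnt * (cnt - 1) / 2)) / npair
  keycols <- which(keep)
  k <- if (length(keycols)) sum(!duplicated(a$mat[, keycols, drop = FALSE]))
       else 1L
  list(n = n, L_eff = L_eff, S = S, eta = eta, pi_total = pi_total, k = k)
}

# statistic block from an infinite-sites 0/1 matrix
is_stat_block <- function(M) {
  n <- nrow(M)
  if (ncol(M) == 0L)
    return(list(n = n, S = 0L, eta = 0L, pi_total = 0, k = 1L))
  cnt <- colSums(M)
  seg <- cnt > 0L & cnt < n
  npair <- n * (n - 1) / 2
  list(n = n, S = sum(seg), eta = sum(seg),
       pi_total = sum(cnt * (n - cnt)) / npair,
       k = sum(!duplicated(M)))
}

compute_statistic <- function(statistic, blk, aln = NULL, rates = NULL) {
  switch(statistic,
    D = tajima_D(blk$pi_total, blk$S, blk$n),
    Fs = if (blk$pi_total <= 0) NA_real_ else
      fu_fs(theta_hat = blk$pi_total, k_obs = blk$k, n = blk$n)$Fs,
    Ds_star_plus = {
      if (is.null(aln)) stop("Ds_star_plus needs an alignment")
      ds_star_plus(aln, model = rates)$value
    })
}

#' Monte-Carlo null distribution of a neutrality statistic
#'
#' Simulates `n_reps` neutral coalescent samples under the infinite-sites
#' (`"IS"`) or finite-sites (`"FS"`) mutation model and computes the
#' chosen statistic for each replicate. Replicates on which the statistic
#' is undefined (e.g. no polymorphism) are dropped and counted; a warning
#' is attached when more than 10% are dropped, since this shifts
#' percentiles at small theta.
#'
#' @param statistic `"D"`, `"Fs"` or `"Ds_star_plus"`.
#' @param model `"IS"` or `"FS"`.
#' @param params a [coalescent_params].
#' @param n_reps number of replicates (>= 1; >= 1000 for reported
#'   intervals).
#' @param seed master seed; replicate `i` uses an independent substream.
#' @param L locus length (required for FS).
#' @param subst a [substitution_model] (required for FS).
#' @param rates a [gamma_rate_model]: site-rate model for FS simulation
#'   and the correction model for `Ds_star_plus` (required for either).
#' @return object of class `null_distribution`: sorted `values`, counts,
#'   parameters. Use [quantile.null_distribution()] and [evaluate()].
#' @export
build_null <- function(statistic = c("D", "Fs", "Ds_star_plus"),
                       model = c("IS", "FS"), params, n_reps, seed,
                       L = NULL, subst = NULL, rates = NULL) {
  statistic <- match.arg(statistic)
  model <- match.arg(model)
  stopifnot(inherits(params, "coalescent_params"), n_reps >= 1)
  if (model == "FS" && (is.null(L) || is.null(subst) || is.null(rates)))
    stop("FS null needs L, subst and rates")
  if (statistic == "Ds_star_plus" && is.null(rates))
    stop("Ds_star_plus needs a gamma_rate_model in `rates`")
  vals <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    si <- derive_seed(seed, i)
    gen <- simulate_genealogy(params, seed = si)
    if (model == "IS") {
      M <- mutate_infinite_sites(gen, params$theta_locus)
      blk <- is_stat_block(M)
      aln <- NULL
      if (statistic == "Ds_star_plus" && blk$S > 0) {
        aln <- dna_alignment(apply(M, 1L, function(z)
          paste(c("A", "G")[z + 1L], collapse = "")))
      }
    } else {
      aln <- mutate_finite_sites(gen, params$theta_locus, L, subst, rates)
      blk <- alignment_stat_block(aln)
    }
    vals[i] <- if (blk$S == 0L) NA_real_ else
      compute_statistic(statistic, blk, aln, rates)
  }
  dropped <- sum(is.na(vals))
  vals <- sort(vals[!is.na(vals)])
  out <- structure(list(statistic = statistic, model = model,
                        values = vals, n_reps = n_reps,
                        n_dropped = dropped, params = params,
                        L = L, seed = seed),
                   class = "null_distribution")
  if (dropped > 0.1 * n_reps)
    attr(out, "warning") <- sprintf(
      "%d of %d replicates undefined (dropped)", dropped, n_reps)
  out
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("%s null of %s: %d replicates (%d dropped), theta=%.3f n=%d\n",
              x$model, x$statistic, x$n_reps, x$n_dropped,
              x$params$theta_locus, x$params$n))
  if (!is.null(attr(x, "warning"))) cat("warning:", attr(x, "warning"), "\n")
  q <- quantile(x, c(0.025, 0.05, 0.5, 0.95, 0.975))
  cat("quantiles 2.5/5/50/95/97.5%:", paste(sprintf("%.3f", q), collapse = " "),
      "\n")
  invisible(x)
}

#' Empirical quantiles of a simulated null
#'
#' Inverse-rank order statistic without interpolation: quantile `q` is the
#' `ceiling(q m)`-th smallest of the `m` retained draws (the smallest draw
#' for `q = 0`).
#'
#' @param x a `null_distribution`.
#' @param probs quantile levels.
#' @param ... unused.
#' @export
quantile.null_distribution <- function(x, probs = c(0.025, 0.975), ...) {
  m <- length(x$values)
  if (m == 0L) stop("empty null distribution")
  x$values[pmax(1L, ceiling(probs * m))]
}

#' Critical value(s) of a simulated null at a significance level
#'
#' Two-tailed statistics get the `(level/2, 1 - level/2)` empirical
#' quantiles. For the one-tailed (lower) Fu's Fs convention the critical
#' value at level `alpha` is the `alpha/2` quantile: the atypical null
#' distribution of Fs puts well under half its mass below zero, so the
#' nominal 5%-level cutoff sits near its 2nd percentile (Fu 1997); the
#' lower endpoint of the two-sided 95% machinery is the conventional
#' operational choice.
#'
#' @param null a `null_distribution`.
#' @param level significance level (default 0.05).
#' @param tail `"two"` or `"lower"`.
#' @return one (lower tail) or two (two-tailed) critical values.
#' @export
critical_values <- function(null, level = 0.05, tail = c("two", "lower")) {
  tail <- match.arg(tail)
  if (tail == "two")
    quantile(null, c(level / 2, 1 - level / 2))
  else
    quantile(null, level / 2)
}

#' Evaluate an observed statistic against a null
#'
#' Empirical p-values use the `(r + 1)/(m + 1)` convention, where `r` is
#' the number of null draws at least as extreme as the observation. For
#' the lower-tailed Fs test, significance follows the Fu calibration of
#' [critical_values()] (`p_lower < level/2`); for two-tailed statistics,
#' significance at `level` means falling outside the central
#' `1 - level` interval.
#'
#' @param value observed statistic (may be `NA` = undefined).
#' @param null a `null_distribution`, or the list returned by
#'   [tajima_beta_interval()] for the beta null of D.
#' @param tail `"two"` or `"lower"`.
#' @param level significance level.
#' @return object of class `neutrality_verdict`: list with `value`,
#'   `null_source`, `interval` or `threshold`, `p` (empirical nulls only),
#'   `significant` (`NA` when the statistic is undefined), `tail`.
#' @export
evaluate <- function(value, null, tail = c("two", "lower"), level = 0.05) {
  tail <- match.arg(tail)
  if (is.na(value)) {
    return(structure(list(value = NA_real_, null_source = "none",
                          significant = NA, tail = tail, level = level,
                          note = "statistic undefined; not evaluable"),
                     class = "neutrality_verdict"))
  }
  if (!inherits(null, "null_distribution")) {
    # beta null of Tajima's D
    sig <- value < null$lower || value > null$upper
    return(structure(list(value = value, null_source = "beta",
                          interval = c(null$lower, null$upper),
                          significant = sig, tail = "two", level = level),
                     class = "neutrality_verdict"))
  }
  m <- length(null$values)
  p_lower <- (sum(null$values <= value) + 1) / (m + 1)
  p_upper <- (sum(null$values >= value) + 1) / (m + 1)
  if (tail == "two") {
    iv <- critical_values(null, level, "two")
    sig <- value < iv[1L] || value > iv[2L]
    structure(list(value = value, null_source = null$model, interval = iv,
                   p = 2 * min(p_lower, p_upper), significant = sig,
                   tail = tail, level = level),
              class = "neutrality_verdict")
  } else {
    thr <- critical_values(null, level, "lower")
    structure(list(value = value, null_source = null$model, threshold = thr,
                   p = p_lower, significant = p_lower < level / 2,
                   tail = tail, level = level),
              class = "neutrality_verdict")
  }
}

#' @export
print.neutrality_verdict <- function(x, ...) {
  if (is.na(x$significant)) {
    cat("verdict: not evaluable (undefined statistic)\n")
    return(invisible(x))
  }
  lim <- if (!is.null(x$interval))
    sprintf("interval (%.3f, %.3f)", x$interval[1], x$interval[2])
  else sprintf("threshold %.3f", x$threshold)
  cat(sprintf("value %.3f vs %s null %s: %s%s\n", x$value, x$null_source,
              lim, if (x$significant) "SIGNIFICANT" else "not significant",
              if (!is.null(x$p)) sprintf(" (p ~ %.4f)", x$p) else ""))
  invisible(x)
}

#' Neutrality test battery for one group
#'
#' Computes Tajima's D (against its beta interval and, optionally, a
#' simulated null), the corrected D-type statistic and Fu's Fs, echoing
#' the layout of a standard neutrality-test table.
#'
#' @param a a [dna_alignment].
#' @param group optional group label.
#' @param rates a [gamma_rate_model] for the corrected statistic.
#' @param nulls optional named list of `null_distribution` objects
#'   (`D`, `Fs`, `Ds_star_plus`) to evaluate against.
#' @param level significance level.
#' @return a list of statistics and verdicts.
#' @export
neutrality_tests <- function(a, group = NULL, rates, nulls = list(),
                             level = 0.05) {
  sm <- summarize_polymorphism(a, group)
  D <- tajima_D(sm$pi_total, sm$S, sm$n)
  beta <- tajima_beta_interval(sm$n, 1 - level)
  ds <- ds_star_plus(a, group, rates)
  fs <- fu_fs(a, group)
  out <- list(
    summary = sm, D = D,
    D_beta = evaluate(D, beta),
    Ds_star_plus = ds$value,
    Ds_beta = evaluate(ds$value, beta),
    Fs = fs$Fs)
  if (!is.null(nulls$D)) out$D_null <- evaluate(D, nulls$D, "two", level)
  if (!is.null(nulls$Ds_star_plus))
    out$Ds_null <- evaluate(ds$value, nulls$Ds_star_plus, "two", level)
  if (!is.null(nulls$Fs)) out$Fs_null <- evaluate(fs$Fs, nulls$Fs, "lower",
                                                  level)
  out
}
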