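test_that("genealogies are reproducible, ultrametric, with exact node count", {
  p <- coalescent_params(12, 5)
  g1 <- simulate_genealogy(p, seed = 11)
  g2 <- simulate_genealogy(p, seed = 11)
  expect_identical(g1, g2)
  g3 <- simulate_genealogy(p, seed = 12)
  expect_false(identical(g1$tmrca, g3$tmrca))

  expect_length(g1$parent, 2 * 12 - 1)
  expect_true(all(g1$blen >= 0))
  ph <- ape::as.phylo(g1)
  expect_true(ape::is.ultrametric(ph, tol = 1e-8))
  expect_equal(ape::Ntip(ph), 12L)
})

test_that("coalescent times match closed-form expectations", {
  set.seed(301)
  # E[TMRCA] = 2(1 - 1/n); E[tree length] = 2 a1(n)
  p2 <- coalescent_params(2, 1)
  t2 <- replicate(4000, simulate_genealogy(p2)$tmrca)
  expect_equal(mean(t2), 1, tolerance = 3 * sd(t2) / sqrt(4000) + 1e-9)

  p10 <- coalescent_params(10, 1)
  reps <- replicate(4000, {
    g <- simulate_genealogy(p10); c(g$tmrca, g$tree_length)
  })
  expect_equal(mean(reps[1, ]), 2 * (1 - 1 / 10),
               tolerance = 3 * sd(reps[1, ]) / sqrt(4000))
  expect_equal(mean(reps[2, ]), 2 * sum(1 / seq_len(9)),
               tolerance = 3 * sd(reps[2, ]) / sqrt(4000))
})

test_that("growth pushes genealogies toward star shape", {
  set.seed(302)
  ext_share <- function(g) {
    n <- g$n
    sum(g$blen[seq_len(n)]) / g$tree_length
  }
  shares <- vapply(c(0, 5, 50), function(gr) {
    mean(replicate(400, ext_share(
      simulate_genealogy(coalescent_params(10, 1, growth = gr)))))
  }, 0)
  expect_true(all(diff(shares) > 0))
})

test_that("infinite-sites mutation obeys Watterson's expectation", {
  set.seed(303)
  n <- 10; theta <- 2
  p <- coalescent_params(n, theta)
  S <- replicate(4000, ncol(mutate_infinite_sites(simulate_genealogy(p),
                                                  theta)))
  a1 <- sum(1 / seq_len(n - 1))
  expect_equal(mean(S), theta * a1, tolerance = 3 * sd(S) / sqrt(4000))
  # theta -> 0: essentially never a mutation
  tiny <- replicate(200, ncol(mutate_infinite_sites(
    simulate_genealogy(coalescent_params(5, 1e-4)), 1e-4)))
  expect_lte(sum(tiny), 1)
  # neutral equilibrium: mean D near zero (slightly negative bias)
  set.seed(304)
  D <- replicate(2000, {
    M <- mutate_infinite_sites(simulate_genealogy(p), theta)
    blk <- finitesites:::is_stat_block(M)
    if (blk$S == 0) NA_real_ else tajima_D(blk$pi_total, blk$S, blk$n)
  })
  expect_lt(abs(mean(D, na.rm = TRUE)), 0.12)
})

test_that("finite-sites engine: degenerate tree, stationarity, rate effects", {
  jc <- substitution_model("HKY85", kappa = 1)
  unif <- gamma_rate_model(Inf, 1)
  # near-zero tree length: all sequences identical to each other
  g <- simulate_genealogy(coalescent_params(5, 1), seed = 1)
  g$blen <- g$blen * 1e-12
  a <- mutate_finite_sites(g, 1, 100, jc, unif, seed = 2)
  expect_equal(nrow(collapse_haplotypes(a)), 1L)

  # long branches: base composition converges to stationary frequencies
  skew <- substitution_model("HKY85", kappa = 4,
                             base_freqs = c(0.4, 0.3, 0.2, 0.1))
  g2 <- simulate_genealogy(coalescent_params(2, 1), seed = 3)
  g2$blen <- c(60, 60, 0)   # ~ many expected substitutions per site
  a2 <- mutate_finite_sites(g2, 2 * 100, 8000, skew, unif, seed = 4)
  freqs <- table(factor(a2$mat, c("A", "C", "G", "T"))) / length(a2$mat)
  expect_true(all(abs(as.numeric(freqs) - c(0.4, 0.3, 0.2, 0.1)) < 0.015))

  # invalid model rejected
  expect_error(substitution_model("GTR", rates = c(1, 1, 1)), "6")
  expect_error(substitution_model("HKY85", kappa = 1,
                                  base_freqs = c(0.5, 0.5, 0.2, -0.2)))

  # stronger heterogeneity concentrates hits: eta - S gap grows as alpha
  # shrinks, at matched theta
  set.seed(305)
  gap <- function(alpha, nrep = 60) {
    mean(replicate(nrep, {
      gg <- simulate_genealogy(coalescent_params(12, 8))
      aa <- mutate_finite_sites(gg, 8, 400, jc, gamma_rate_model(alpha, 8))
      blk <- finitesites:::alignment_stat_block(aa)
      blk$eta - blk$S
    }))
  }
  expect_gt(gap(0.05), gap(10))
})

test_that("IS and FS engines agree in the infinite-sites limit", {
  # large L, uniform rates, JC: the per-replicate S distributions of the
  # two engines should be statistically indistinguishable
  set.seed(306)
  n <- 12; theta <- 6; L <- 2000
  jc <- substitution_model("HKY85", kappa = 1)
  unif <- gamma_rate_model(Inf, 1)
  S_is <- replicate(250, ncol(mutate_infinite_sites(
    simulate_genealogy(coalescent_params(n, theta)), theta)))
  S_fs <- replicate(250, {
    g <- simulate_genealogy(coalescent_params(n, theta))
    a <- mutate_finite_sites(g, theta, L, jc, unif)
    finitesites:::alignment_stat_block(a)$S
  })
  expect_gt(suppressWarnings(ks.test(S_is, S_fs))$p.value, 0.01)
})

test_that("study profiles give study-shaped, seed-stable alignments", {
  a1 <- synth_study_like("CR", seed = 41)
  a2 <- synth_study_like("CR", seed = 41)
  expect_identical(a1$mat, a2$mat)
  expect_equal(dim(a1$mat), c(31L, 1208L))
  expect_equal(unname(unique(a1$groups)), "sim")

  nd <- synth_study_like("ND2", seed = 42)
  expect_equal(dim(nd$mat), c(31L, 1041L))
  expect_false(any(nd$mat == "-"))
})
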