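# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (enumeration, brute force, quadrature) kept free of any
# package internals it is used to check.

# mean pairwise difference by explicit double loop over pairs of strings
brute_pi_total <- function(seqs) {
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(chars[[i]] != chars[[j]])
  tot / (n * (n - 1) / 2)
}

# Tajima's D transcribed directly from the published coefficient
# definitions, independently of the package's tajima_coefficients()
brute_tajima_D <- function(pi_total, S, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# all integer partitions of n (as sorted part vectors)
integer_partitions <- function(n, maxpart = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(n, maxpart))) {
    for (rest in integer_partitions(n - p, p))
      out[[length(out) + 1L]] <- c(p, rest)
  }
  out
}

# Ewens P(K = k) by exhaustive enumeration over allele configurations:
# P(partition) = n! / (prod_j j^{a_j} a_j!) * theta^k / theta^{(n)}
enum_ewens_k_pmf <- function(n, theta) {
  rising <- prod(theta + 0:(n - 1))
  pk <- numeric(n)
  for (part in integer_partitions(n)) {
    k <- length(part)
    a <- table(part)
    w <- factorial(n) /
      prod(as.numeric(names(a))^as.integer(a) * factorial(as.integer(a)))
    pk[k] <- pk[k] + w * theta^k / rising
  }
  pk
}

# minimum changes for one column by exhaustive enumeration of ancestral
# states over all internal nodes of a (rooted, binary) phylo tree
brute_fitch_column <- function(tree, tipstates) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  known <- match(tipstates, c("A", "C", "G", "T"))
  grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- c(known, grid[g, ])
    ch <- sum(st[edge[, 1]] != st[edge[, 2]], na.rm = TRUE)
    best <- min(best, ch)
  }
  best
}

# conditional mean rate on each equal-probability gamma slice by
# adaptive quadrature (oracle for the closed-form discretization)
quad_gamma_means <- function(alpha, k) {
  cuts <- qgamma(seq(0, 1, length.out = k + 1), alpha, rate = alpha)
  vapply(seq_len(k), function(i) {
    integrate(function(r) r * dgamma(r, alpha, rate = alpha),
              cuts[i], cuts[i + 1], rel.tol = 1e-10)$value * k
  }, 0)
}

# small random alignment factory (no gaps)
random_alignment <- function(n, L, groups = "all", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), L, TRUE),
                             collapse = ""))
  dna_alignment(seqs, ids = paste0("s", seq_len(n)), groups = groups)
}
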