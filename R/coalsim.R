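#' Coalescent simulation parameters
#'
#' Time is measured in coalescent units of `N0` generations for a haploid
#' (maternally inherited) locus, so a specific pair of lineages coalesces
#' after an Exp(1) time in a constant-size population and the expected
#' number of mutations separating a random pair at a site is the per-site
#' `theta`. Exponential growth is parameterized backward in time as
#' `N(t) = N0 exp(-g t)` with `g` per coalescent unit; LAMARC-style growth
#' rates in units of 1/generations correspond to `g * N0`.
#'
#' @param n sample size (>= 2).
#' @param theta_locus per-locus scaled mutation rate (per-site theta times
#'   locus length).
#' @param growth exponential growth rate `g` (0 = constant size).
#' @return object of class `coalescent_params`.
#' @export
coalescent_params <- function(n, theta_locus, growth = 0) {
  stopifnot(n >= 2, theta_locus > 0, is.finite(growth))
  structure(list(n = as.integer(n), theta_locus = theta_locus,
                 growth = growth), class = "coalescent_params")
}

# deterministic per-replicate substream seed below 2^31
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + as.numeric(i) * 1000003) %%
               2147483647)
}

#' Simulate a neutral coalescent genealogy
#'
#' Standard n-coalescent: with `j` lineages the waiting time is
#' exponential with rate `j(j-1)/2` (constant size); under growth the
#' coalescence intensity at backward time `t` is multiplied by
#' `exp(g t)`, so waiting times are obtained by inverting the cumulative
#' intensity in closed form.
#'
#' @param params a [coalescent_params].
#' @param seed optional integer seed (reproducible genealogy).
#' @return object of class `genealogy`: list with `n`, `parent` (length
#'   `2n-1`, 0 for the root), `blen` (branch length to parent), `order`
#'   (internal nodes in increasing node age, i.e. coalescence order),
#'   `tmrca`, `tree_length`, `tip_labels`.
#' @export
simulate_genealogy <- function(params, seed = NULL) {
  stopifnot(inherits(params, "coalescent_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n; g <- params$growth
  nodes <- 2L * n - 1L
  parent <- integer(nodes)
  node_time <- numeric(nodes)
  alive <- seq_len(n)
  tcur <- 0
  nxt <- n + 1L
  for (j in n:2) {
    e <- stats::rexp(1, j * (j - 1) / 2)
    tcur <- if (g == 0) tcur + e else log(exp(g * tcur) + g * e) / g
    pick <- sample.int(length(alive), 2L)
    c1 <- alive[pick[1L]]; c2 <- alive[pick[2L]]
    parent[c1] <- nxt; parent[c2] <- nxt
    node_time[nxt] <- tcur
    alive <- c(alive[-pick], nxt)
    nxt <- nxt + 1L
  }
  blen <- numeric(nodes)
  nz <- which(parent > 0L)
  blen[nz] <- node_time[parent[nz]] - node_time[nz]
  structure(list(n = n, parent = parent, blen = blen,
                 node_time = node_time,
                 order = (n + 1L):nodes,
                 tmrca = tcur, tree_length = sum(blen),
                 tip_labels = paste0("t", seq_len(n))),
            class = "genealogy")
}

#' Convert a genealogy to an ape phylo tree
#'
#' @param x a `genealogy`.
#' @param ... unused.
#' @return an `ape::phylo` object (ultrametric, coalescent time units).
#' @exportS3Method ape::as.phylo
as.phylo.genealogy <- function(x, ...) {
  n <- x$n
  nodes <- 2L * n - 1L
  # ape convention: tips 1..n, root n+1, internals n+1..2n-1; our root is
  # node 2n-1 (oldest) so remap internals in reverse age order
  internal_old <- rev(x$order)           # oldest (root) first
  map <- integer(nodes)
  map[seq_len(n)] <- seq_len(n)
  map[internal_old] <- n + seq_len(n - 1L)
  edge <- cbind(map[x$parent[-nodes]], map[seq_len(nodes)][-nodes])
  structure(list(edge = edge, edge.length = x$blen[-nodes],
                 tip.label = x$tip_labels, Nnode = n - 1L),
            class = "phylo")
}

#' Infinite-sites mutation on a genealogy
#'
#' Each branch receives Poisson(`theta_locus/2` x branch length) mutations,
#' each at a fresh site; the result is the binary haplotype matrix of
#' segregating sites.
#'
#' @param gen a `genealogy`.
#' @param theta_locus per-locus scaled mutation rate.
#' @param seed optional integer seed.
#' @return 0/1 integer matrix, `n` rows (tips, rownames = tip labels) by
#'   `S` columns; `S = 0` gives a zero-column matrix.
#' @export
mutate_infinite_sites <- function(gen, theta_locus, seed = NULL) {
  stopifnot(inherits(gen, "genealogy"), theta_locus > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- gen$n
  nodes <- 2L * n - 1L
  S_total <- stats::rpois(1L, theta_locus / 2 * gen$tree_length)
  M <- matrix(0L, n, S_total, dimnames = list(gen$tip_labels, NULL))
  if (S_total == 0L) return(M)
  br <- sample.int(nodes - 1L, S_total, replace = TRUE,
                   prob = gen$blen[-nodes])
  desc <- tip_descendants(gen)
  for (s in seq_len(S_total)) M[desc[[br[s]]], s] <- 1L
  M
}

# list of tip index vectors below each node
tip_descendants <- function(gen) {
  n <- gen$n
  nodes <- 2L * n - 1L
  desc <- vector("list", nodes)
  for (i in seq_len(n)) desc[[i]] <- i
  kids <- split(seq_len(nodes - 1L), gen$parent[-nodes])
  for (nd in gen$order) {
    desc[[nd]] <- unlist(desc[kids[[as.character(nd)]]], use.names = FALSE)
  }
  desc
}

#' Nucleotide substitution model
#'
#' HKY85 (transition/transversion ratio `kappa`) or GTR (six
#' exchangeabilities in the order AC, AG, AT, CG, CT, GT) with arbitrary
#' base frequencies and an optional invariant-site fraction. The rate
#' matrix is scaled so the expected number of substitutions per site per
#' unit branch length is 1 at stationarity (before site-rate scaling).
#'
#' @param kind `"HKY85"` or `"GTR"`.
#' @param kappa transition/transversion rate ratio (HKY85).
#' @param rates six exchangeabilities `r_AC, r_AG, r_AT, r_CG, r_CT, r_GT`
#'   (GTR); zeros are tolerated for degenerate fits.
#' @param base_freqs equilibrium frequencies `pi_A, pi_C, pi_G, pi_T`
#'   (must sum to 1).
#' @param p_inv invariant-site fraction in `[0, 1)`.
#' @return object of class `substitution_model` with the scaled rate
#'   matrix `Q` and its eigendecomposition.
#' @export
substitution_model <- function(kind = c("HKY85", "GTR"), kappa = NULL,
                               rates = NULL,
                               base_freqs = rep(0.25, 4), p_inv = 0) {
  kind <- match.arg(kind)
  stopifnot(abs(sum(base_freqs) - 1) < 1e-8, all(base_freqs > 0),
            p_inv >= 0, p_inv < 1)
  bases <- c("A", "C", "G", "T")
  r <- if (kind == "HKY85") {
    if (is.null(kappa) || kappa <= 0) stop("HKY85 needs kappa > 0")
    # order AC, AG, AT, CG, CT, GT; AG and CT are transitions
    c(1, kappa, 1, 1, kappa, 1)
  } else {
    if (is.null(rates) || length(rates) != 6L || any(rates < 0))
      stop("GTR needs 6 non-negative exchangeabilities")
    rates
  }
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  pair <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pair[k, 1]; j <- pair[k, 2]
    Q[i, j] <- r[k] * base_freqs[j]
    Q[j, i] <- r[k] * base_freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix")
  Q <- Q / mu
  # reversible: symmetrize with pi^(1/2) for a stable eigendecomposition
  sp <- sqrt(base_freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(kind = kind, kappa = kappa, rates = rates,
                 base_freqs = base_freqs, p_inv = p_inv, Q = Q,
                 eig_values = eig$values,
                 eig_left = diag(1 / sp) %*% eig$vectors,
                 eig_right = t(eig$vectors) %*% diag(sp)),
            class = "substitution_model")
}

# transition probability matrix P(t) for a substitution_model
transition_prob <- function(model, t) {
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Finite-sites mutation on a genealogy
#'
#' Evolves `L` sites down the genealogy under a reversible substitution
#' model with discrete-gamma site rates and optional invariant sites. The
#' branch scale is chosen so that the locus-wide expected number of
#' substitutions per site per coalescent unit is `theta_locus / (2 L)`:
#' invariant sites never mutate and variable-site category rates are
#' renormalized by `1/(1 - p_inv)` so the locus-wide mean rate is 1.
#'
#' @param gen a `genealogy`.
#' @param theta_locus per-locus scaled mutation rate.
#' @param L number of sites.
#' @param model a [substitution_model].
#' @param rates a [gamma_rate_model] with finite `ncat` (use
#'   `gamma_rate_model(Inf, 1)` for uniform rates).
#' @param seed optional integer seed.
#' @param group group label for the returned alignment.
#' @return a [dna_alignment] of the `n` tip sequences.
#' @export
mutate_finite_sites <- function(gen, theta_locus, L, model, rates,
                                seed = NULL, group = "sim") {
  stopifnot(inherits(gen, "genealogy"), inherits(model, "substitution_model"),
            inherits(rates, "gamma_rate_model"), L >= 1, theta_locus > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- gen$n
  nodes <- 2L * n - 1L
  ncat <- if (is.finite(rates$ncat)) rates$ncat else 12L
  cat_rates <- discrete_gamma_rates(gamma_rate_model(rates$alpha, ncat))
  site_cat <- sample.int(ncat, L, replace = TRUE)
  if (model$p_inv > 0) {
    inv <- stats::runif(L) < model$p_inv
    site_cat[inv] <- 0L                       # category 0 = invariant
    cat_rates <- cat_rates / (1 - model$p_inv)
  }
  scale <- theta_locus / (2 * L)
  states <- matrix(0L, nodes, L)
  states[nodes, ] <- sample.int(4L, L, replace = TRUE,
                                prob = model$base_freqs)
  site_by_cat <- split(seq_len(L), site_cat)
  # preorder: root children first (descending node age), tips last
  preorder <- c(rev(gen$order)[-1L], seq_len(n))
  for (nd in preorder) {
    pstates <- states[gen$parent[nd], ]
    out <- pstates
    bl <- gen$blen[nd]
    if (bl > 0) {
      for (cn in names(site_by_cat)) {
        if (cn == "0") next
        P <- transition_prob(model, scale * cat_rates[as.integer(cn)] * bl)
        idx <- site_by_cat[[cn]]
        for (st in 1:4) {
          ii <- idx[pstates[idx] == st]
          if (length(ii))
            out[ii] <- sample.int(4L, length(ii), replace = TRUE,
                                  prob = P[st, ])
        }
      }
    }
    states[nd, ] <- out
  }
  bases <- c("A", "C", "G", "T")
  seqs <- apply(states[seq_len(n), , drop = FALSE], 1L,
                function(z) paste(bases[z], collapse = ""))
  dna_alignment(seqs, ids = gen$tip_labels, groups = group)
}

#' Study-profile synthetic alignments
#'
#' One-call generator of study-scale synthetic data sets under the two
#' fitted mitochondrial regimes: `"CR"` (control-region-like: n = 31,
#' L = 1208, HKY85 with kappa = 16.702, base frequencies
#' (0.312, 0.285, 0.134, 0.269), discrete-gamma alpha = 0.102 with 12
#' categories, per-site theta 0.0135) and `"ND2"` (protein-coding-like:
#' n = 31, L = 1041, GTR with exchangeabilities (5.122, 118.9, 3.560,
#' 8.226e-4, 47.54, 1), base frequencies (0.310, 0.355, 0.098, 0.237),
#' invariant fraction 0.723, per-site theta 0.0132).
#'
#' @param profile `"CR"` or `"ND2"`.
#' @param seed optional integer seed (same seed, same alignment).
#' @param n,growth optional overrides of the sample size and growth rate.
#' @return a [dna_alignment] with group `"sim"`.
#' @export
synth_study_like <- function(profile = c("CR", "ND2"), seed = NULL,
                             n = 31L, growth = 0) {
  profile <- match.arg(profile)
  cfg <- study_profile(profile)
  gen <- simulate_genealogy(coalescent_params(n, cfg$theta_site * cfg$L,
                                              growth), seed = seed)
  mutate_finite_sites(gen, cfg$theta_site * cfg$L, cfg$L, cfg$model,
                      cfg$rates, seed = NULL)
}

#' Fitted parameter bundles for the two study loci
#'
#' @param profile `"CR"` or `"ND2"`.
#' @return list with `L`, `theta_site`, `model` ([substitution_model]) and
#'   `rates` ([gamma_rate_model]).
#' @export
study_profile <- function(profile = c("CR", "ND2")) {
  profile <- match.arg(profile)
  if (profile == "CR") {
    list(L = 1208L, theta_site = 0.0135,
         model = substitution_model("HKY85", kappa = 16.702,
                                    base_freqs = c(0.312, 0.285, 0.134, 0.269)),
         rates = gamma_rate_model(0.102, 12L))
  } else {
    list(L = 1041L, theta_site = 0.0132,
         model = substitution_model("GTR",
                                    rates = c(5.122, 118.9, 3.560,
                                              8.226e-4, 47.54, 1),
                                    base_freqs = c(0.310, 0.355, 0.098, 0.237),
                                    p_inv = 0.723),
         rates = gamma_rate_model(Inf, 1L))
  }
}
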