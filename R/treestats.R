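#' Per-site minimum change counts on a genealogy (Fitch parsimony)
#'
#' For every alignment column, the minimum number of state changes on the
#' supplied tree (Fitch parsimony after arbitrary rooting; polytomies are
#' resolved with zero-length branches, which does not change minimum
#' counts). Tips with a gap or ambiguity at a column contribute the full
#' state set (equivalently, they are excluded at that column). These
#' counts are lower bounds on the true number of mutations and always at
#' least the alignment's per-site `eta`.
#'
#' @param a a [dna_alignment].
#' @param tree an `ape::phylo` tree (or path to a newick file) whose tip
#'   labels are a subset-matching of the alignment ids.
#' @return object of class `site_change_profile`: `data.frame` with
#'   `index` and `fitch_changes`; attribute `total_changes`.
#' @export
fitch_site_changes <- function(a, tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  missing_tips <- setdiff(tree$tip.label, rownames(a$mat))
  if (length(missing_tips))
    stop("tree tips absent from alignment: ",
         paste(missing_tips, collapse = ", "))
  tree <- ape::multi2di(tree)
  if (!ape::is.rooted(tree)) tree <- ape::root(tree, tree$tip.label[1L],
                                               resolve.root = TRUE)
  m <- a$mat[tree$tip.label, , drop = FALSE]
  ntip <- nrow(m)
  nnode <- tree$Nnode
  # postorder edges: children before parents
  reord <- stats::reorder(tree, "postorder")
  edge <- reord$edge
  # bitmask per residue: A=1 C=2 G=4 T=8; ambiguity = union; gap = all
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
           W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L, V = 7L,
           N = 15L, "-" = 15L, "?" = 15L)
  tipbits <- matrix(bit[m], nrow = ntip)
  L <- ncol(m)
  changes <- integer(L)
  sets <- matrix(0L, ntip + nnode, L)
  sets[seq_len(ntip), ] <- tipbits
  counts <- integer(L)
  done <- logical(ntip + nnode)
  done[seq_len(ntip)] <- TRUE
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; child <- edge[e, 2L]
    if (!done[par]) {
      sets[par, ] <- sets[child, ]
      done[par] <- TRUE
    } else {
      inter <- bitwAnd(sets[par, ], sets[child, ])
      empty <- inter == 0L
      counts <- counts + empty
      sets[par, ] <- ifelse(empty, bitwOr(sets[par, ], sets[child, ]), inter)
    }
  }
  out <- data.frame(index = seq_len(L), fitch_changes = counts)
  attr(out, "total_changes") <- sum(counts)
  class(out) <- c("site_change_profile", "data.frame")
  out
}

#' Identify candidate mutational hotspots
#'
#' Two criteria, separately or combined: (i) shared polymorphism -- a site
#' segregating within two or more reciprocally divergent groups; (ii) top
#' percentile of per-site change counts among variable sites (ties kept).
#' Every flagged site records which criterion fired, so parsimony-count
#' hotspots are never conflated with shared-polymorphism hotspots.
#'
#' @param profile a `site_change_profile` from [fitch_site_changes()]
#'   (needed for the percentile rule; may be `NULL` for the
#'   shared-polymorphism rule alone).
#' @param sites a site classification from [classify_sites()] of the same
#'   alignment.
#' @param rule `"shared"`, `"percentile"` or `"either"`.
#' @param percentile cut for the change-count rule (default 0.95: top 5%).
#' @param min_groups minimum number of groups for the shared rule.
#' @return `data.frame` with `index` and `criterion`
#'   (`"shared"`, `"percentile"` or `"shared+percentile"`), sorted by
#'   index; zero rows when nothing qualifies.
#' @export
find_hotspots <- function(profile = NULL, sites,
                          rule = c("shared", "percentile", "either"),
                          percentile = 0.95, min_groups = 2L) {
  rule <- match.arg(rule)
  shared_idx <- integer(0)
  if (rule %in% c("shared", "either")) {
    ng <- vapply(strsplit(sites$groups_polymorphic, ","), function(z)
      sum(nzchar(z)), 0L)
    shared_idx <- sites$index[ng >= min_groups]
  }
  pct_idx <- integer(0)
  if (rule %in% c("percentile", "either")) {
    if (is.null(profile)) stop("percentile rule needs a site change profile")
    varsites <- profile$fitch_changes > 0L
    if (any(varsites)) {
      cut <- stats::quantile(profile$fitch_changes[varsites], percentile,
                             type = 1)
      pct_idx <- profile$index[varsites & profile$fitch_changes >= cut]
      if (all(profile$fitch_changes[varsites] ==
                profile$fitch_changes[varsites][1L]))
        pct_idx <- integer(0)      # uniform counts: no site stands out
    }
  }
  idx <- sort(union(shared_idx, pct_idx))
  crit <- vapply(idx, function(i) {
    paste(c(if (i %in% shared_idx) "shared",
            if (i %in% pct_idx) "percentile"), collapse = "+")
  }, "")
  data.frame(index = idx, criterion = crit, stringsAsFactors = FALSE)
}
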