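#' Sliding-window polymorphism statistics
#'
#' Per-window segregating-site counts and nucleotide diversity, using the
#' same complete-deletion policy as the full-locus summaries, applied
#' within each window. Windows never wrap; the reported center is the
#' floor midpoint `start + floor((w - 1)/2)`.
#'
#' @param a a [dna_alignment].
#' @param group optional group label.
#' @param w window width in columns.
#' @param s step size (>= 1).
#' @param mask optional logical or integer vector of columns to exclude
#'   before windowing (e.g. a poly-pyrimidine run).
#' @return object of class `window_track`: a `data.frame` with `center`,
#'   `start`, `end` (1-based inclusive), `S`, `pi` (per included site),
#'   `L_eff`; attributes `w`, `s`, `group`.
#' @export
sliding_windows <- function(a, group = NULL, w, s = 1L, mask = NULL) {
  rows <- if (is.null(group)) seq_len(n_seq(a)) else group_rows(a, group)
  stopifnot(w >= 1L, s >= 1L)
  m <- a$mat[rows, , drop = FALSE]
  n <- length(rows)
  L <- ncol(m)
  excluded <- rep(FALSE, L)
  if (!is.null(mask)) {
    if (is.logical(mask)) excluded <- mask else excluded[mask] <- TRUE
  }
  if (w > L) {
    warning("window wider than locus; using a single full-locus window")
    w <- L
  }
  # per-column counts once; windows aggregate
  cnt <- vapply(c("A", "C", "G", "T"), function(b) colSums(m == b),
                numeric(L))
  if (L == 1L) cnt <- matrix(cnt, nrow = 1L)
  inc <- rowSums(cnt) == n & !excluded
  distinct <- rowSums(cnt > 0)
  seg <- inc & distinct >= 2L
  npair <- n * (n - 1) / 2
  pdiff <- ifelse(inc, npair - rowSums(cnt * (cnt - 1) / 2), 0) / npair
  starts <- seq.int(1L, L - w + 1L, by = s)
  Sw <- vapply(starts, function(st) sum(seg[st:(st + w - 1L)]), 0)
  Le <- vapply(starts, function(st) sum(inc[st:(st + w - 1L)]), 0)
  piw <- vapply(starts, function(st) sum(pdiff[st:(st + w - 1L)]), 0) /
    pmax(Le, 1L)
  out <- data.frame(center = starts + (w - 1L) %/% 2L, start = starts,
                    end = starts + w - 1L, S = as.integer(Sw), pi = piw,
                    L_eff = as.integer(Le))
  structure(out, w = w, s = s, group = if (is.null(group)) "all" else group,
            class = c("window_track", "data.frame"))
}

#' Compare two window tracks
#'
#' The locus-comparison report: maximum per-window segregating sites, how
#' many windows attain it, and maximum per-window diversity, for each
#' track. No significance is claimed.
#'
#' @param track1,track2 `window_track` objects built with equal `w`.
#' @return list with one entry per track (`max_S`, `n_windows_at_max`,
#'   `max_pi`) and the shared width `w`.
#' @export
compare_fragments <- function(track1, track2) {
  stopifnot(inherits(track1, "window_track"), inherits(track2, "window_track"))
  if (!identical(attr(track1, "w"), attr(track2, "w")))
    stop("tracks built with different window widths")
  one <- function(tr) list(max_S = max(tr$S),
                           n_windows_at_max = sum(tr$S == max(tr$S)),
                           max_pi = max(tr$pi))
  list(track1 = one(track1), track2 = one(track2), w = attr(track1, "w"))
}
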