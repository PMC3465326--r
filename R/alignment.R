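IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")
UNAMBIGUOUS <- c("A", "C", "G", "T")

#' Construct a multiple-sequence alignment
#'
#' The universal input container of the package: `n` aligned haploid
#' sequences over the DNA alphabet (IUPAC ambiguity codes and `-` gaps
#' allowed), each carrying a group label (typically a species or
#' population).
#'
#' @param seqs character vector of aligned sequences, all the same length.
#' @param ids unique sequence identifiers; defaults to `names(seqs)` or
#'   `seq1..seqn`.
#' @param groups group label per sequence (recycled if length 1).
#'   Defaults to `"all"`.
#' @return An object of class `dna_alignment`: a list with `mat` (an
#'   `n x L` uppercase character matrix with `ids` as rownames), `groups`
#'   (named character vector) and `L`.
#' @examples
#' aln <- dna_alignment(c(a = "ACGT-", b = "ACGTA", c = "AGGTA"))
#' aln
#' @export
dna_alignment <- function(seqs, ids = NULL, groups = "all") {
  if (length(seqs) == 0L) stop("alignment is empty")
  if (is.null(ids)) ids <- names(seqs)
  seqs <- chartr("U", "T", toupper(as.character(seqs)))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(ids)) stop("duplicate sequence IDs: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  L <- lens[1L]
  if (L < 1L) stop("alignment has zero columns")
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), ncol = L, byrow = TRUE,
                dimnames = list(ids, NULL))
  bad <- setdiff(unique(as.vector(mat)), IUPAC_CODES)
  if (length(bad)) stop("non-IUPAC characters in alignment: ",
                        paste(bad, collapse = " "))
  groups <- rep_len(as.character(groups), length(seqs))
  names(groups) <- ids
  structure(list(mat = mat, groups = groups, L = L),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("dna_alignment: %d sequences x %d columns\n", nrow(x$mat), x$L))
  tg <- table(x$groups)
  cat("groups:", paste(sprintf("%s (%d)", names(tg), tg), collapse = ", "), "\n")
  invisible(x)
}

n_seq <- function(a) nrow(a$mat)

#' Read an alignment from a FASTA file
#'
#' @param path FASTA file of aligned sequences.
#' @param group_map optional two-column table (or path to a headerless
#'   two-column TSV) mapping sequence id to group label. IDs absent from the
#'   map keep the default group `"all"`.
#' @return a [dna_alignment].
#' @export
read_alignment <- function(path, group_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = FALSE)
  if (length(d) == 0L) stop("empty FASTA file: ", path)
  seqs <- vapply(d, paste, "", collapse = "")
  groups <- rep("all", length(seqs))
  names(groups) <- names(seqs)
  if (!is.null(group_map)) {
    if (is.character(group_map) && length(group_map) == 1L)
      group_map <- utils::read.table(group_map, header = FALSE, sep = "\t",
                                     col.names = c("id", "group"),
                                     colClasses = "character")
    gm <- stats::setNames(as.character(group_map[[2L]]),
                          as.character(group_map[[1L]]))
    hit <- names(groups) %in% names(gm)
    groups[hit] <- gm[names(groups)[hit]]
  }
  dna_alignment(seqs, ids = names(seqs), groups = groups)
}

#' Write an alignment to FASTA
#'
#' @param a a [dna_alignment].
#' @param path output file.
#' @export
write_alignment <- function(a, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_seq(a)))
    writeLines(c(paste0(">", rownames(a$mat)[i]),
                 paste(a$mat[i, ], collapse = "")), con)
  invisible(path)
}

group_rows <- function(a, group) {
  if (is.null(group) || identical(group, "all") && !"all" %in% a$groups &&
      length(unique(a$groups)) > 1L)
    return(seq_len(n_seq(a)))
  idx <- which(a$groups == group)
  if (!length(idx)) stop("unknown group label: ", group)
  idx
}

#' Columns included under the missing-data policy
#'
#' Under complete deletion (the default throughout the package) any column
#' containing a gap or an ambiguity code is excluded from nucleotide
#' statistics; under pairwise deletion all columns are retained and
#' ambiguous residues are treated as missing row-wise.
#'
#' @param a a [dna_alignment].
#' @param rows row indices to consider (default all).
#' @param missing_policy `"complete"` or `"pairwise"`.
#' @return logical vector over columns, `TRUE` = included.
#' @export
included_columns <- function(a, rows = seq_len(n_seq(a)),
                             missing_policy = c("complete", "pairwise")) {
  missing_policy <- match.arg(missing_policy)
  m <- a$mat[rows, , drop = FALSE]
  if (missing_policy == "pairwise") return(rep(TRUE, a$L))
  apply(m, 2L, function(col) all(col %in% UNAMBIGUOUS))
}

#' Classify alignment columns
#'
#' Classifies every column as monomorphic, segregating, indel-segregating
#' or excluded, and records the per-column minimum number of mutations
#' (`eta_site` = number of distinct unambiguous bases minus one) and the
#' groups within which the column is polymorphic. Runs of adjacent gap
#' columns with an identical gap presence/absence pattern are collapsed
#' into a single indel event.
#'
#' @param a a [dna_alignment].
#' @param missing_policy `"complete"` (default; columns containing gaps or
#'   ambiguity codes are excluded from nucleotide classes) or `"pairwise"`.
#' @return a `data.frame` with one row per column: `index` (1-based),
#'   `class`, `distinct_bases`, `eta_site`, `groups_polymorphic`
#'   (comma-separated labels). Attributes: `n_indel_events` (count of
#'   collapsed indel events, the I statistic), `missing_policy`.
#' @export
classify_sites <- function(a, missing_policy = c("complete", "pairwise")) {
  missing_policy <- match.arg(missing_policy)
  m <- a$mat
  L <- a$L
  has_gap <- apply(m, 2L, function(col) any(col == "-"))
  has_amb <- apply(m, 2L, function(col) any(!col %in% c(UNAMBIGUOUS, "-")))
  cls <- character(L)
  distinct <- integer(L)
  gp <- character(L)
  glabs <- unique(a$groups)
  for (j in seq_len(L)) {
    col <- m[, j]
    if (missing_policy == "complete" && (has_gap[j] || has_amb[j])) {
      cls[j] <- if (has_gap[j]) "indel-segregating" else "excluded"
      distinct[j] <- 0L
      next
    }
    obs <- col[col %in% UNAMBIGUOUS]
    u <- unique(obs)
    distinct[j] <- length(u)
    cls[j] <- if (length(u) >= 2L) "segregating" else "monomorphic"
    if (length(u) >= 2L) {
      poly <- vapply(glabs, function(g) {
        og <- col[a$groups == g]
        length(unique(og[og %in% UNAMBIGUOUS])) >= 2L
      }, TRUE)
      gp[j] <- paste(glabs[poly], collapse = ",")
    }
  }
  eta_site <- pmax(distinct - 1L, 0L)
  # indel events: collapse adjacent all-gap-pattern-identical columns
  n_indel <- 0L
  gapcols <- which(has_gap)
  if (length(gapcols)) {
    pat <- apply(m[, gapcols, drop = FALSE] == "-", 2L, paste, collapse = "")
    prev <- -2L; prevpat <- ""
    for (k in seq_along(gapcols)) {
      if (!(gapcols[k] == prev + 1L && pat[k] == prevpat))
        n_indel <- n_indel + 1L
      prev <- gapcols[k]; prevpat <- pat[k]
    }
  }
  out <- data.frame(index = seq_len(L), class = cls,
                    distinct_bases = distinct, eta_site = eta_site,
                    groups_polymorphic = gp, stringsAsFactors = FALSE)
  attr(out, "n_indel_events") <- n_indel
  attr(out, "missing_policy") <- missing_policy
  out
}

#' Collapse an alignment into haplotypes
#'
#' Partitions the sequences into identity classes over included columns
#' (complete-deletion policy; ambiguity never matches a base, so two
#' sequences differing only at excluded columns are the same haplotype).
#' Output order is by first occurrence, so the partition is invariant to
#' record order up to relabelling.
#'
#' @param a a [dna_alignment].
#' @param group optional group label restricting the sample (default: all
#'   sequences).
#' @return a `data.frame` with columns `haplotype` (sequence over included
#'   columns), `count`, `members` (comma-separated ids).
#' @export
collapse_haplotypes <- function(a, group = NULL) {
  rows <- if (is.null(group)) seq_len(n_seq(a)) else group_rows(a, group)
  inc <- included_columns(a, rows)
  key <- apply(a$mat[rows, inc, drop = FALSE], 1L, paste, collapse = "")
  first <- !duplicated(key)
  ord <- key[first]
  data.frame(
    haplotype = ord,
    count = as.integer(table(factor(key, levels = ord))),
    members = vapply(ord, function(k)
      paste(rownames(a$mat)[rows][key == k], collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Fixed differences between two groups
#'
#' A column is a fixed nucleotide difference when every included member of
#' one group carries one base, every member of the other group another,
#' and the two differ. Fixed length differences are collapsed indel events
#' whose gap pattern separates the groups exactly.
#'
#' @param a a [dna_alignment].
#' @param group1,group2 group labels.
#' @return list with `fixed_nucleotide` and `fixed_length` counts and
#'   `sites` (1-based column indices of fixed nucleotide differences).
#' @export
fixed_differences <- function(a, group1, group2) {
  r1 <- group_rows(a, group1); r2 <- group_rows(a, group2)
  m <- a$mat
  fixed <- logical(a$L)
  for (j in seq_len(a$L)) {
    c1 <- m[r1, j]; c2 <- m[r2, j]
    u1 <- unique(c1[c1 %in% UNAMBIGUOUS])
    u2 <- unique(c2[c2 %in% UNAMBIGUOUS])
    fixed[j] <- length(u1) == 1L && length(u2) == 1L && u1 != u2 &&
      all(c1 %in% UNAMBIGUOUS) && all(c2 %in% UNAMBIGUOUS)
  }
  # fixed length differences: indel events with group-partitioning pattern
  rows <- c(r1, r2)
  has_gap <- apply(m[rows, , drop = FALSE], 2L, function(col) any(col == "-"))
  n_len <- 0L
  gapcols <- which(has_gap)
  if (length(gapcols)) {
    pat <- apply(m[rows, gapcols, drop = FALSE] == "-", 2L, paste, collapse = "")
    is1 <- seq_along(rows) <= length(r1)
    prev <- -2L; prevpat <- ""
    for (k in seq_along(gapcols)) {
      new_event <- !(gapcols[k] == prev + 1L && pat[k] == prevpat)
      if (new_event) {
        g <- m[rows, gapcols[k]] == "-"
        if ((all(g[is1]) && !any(g[!is1])) || (!any(g[is1]) && all(g[!is1])))
          n_len <- n_len + 1L
      }
      prev <- gapcols[k]; prevpat <- pat[k]
    }
  }
  list(fixed_nucleotide = sum(fixed), fixed_length = n_len,
       sites = which(fixed))
}

#' Sites polymorphic in every listed group
#'
#' Shared (correlated) polymorphism across groups that are otherwise
#' reciprocally divergent is a classical mutational hotspot signature. A
#' site qualifies whether or not the segregating states coincide across
#' groups.
#'
#' @param a a [dna_alignment].
#' @param groups two or more group labels.
#' @return sorted 1-based column indices.
#' @export
shared_polymorphic_sites <- function(a, groups) {
  stopifnot(length(groups) >= 2L)
  polys <- lapply(groups, function(g) {
    rows <- group_rows(a, g)
    m <- a$mat[rows, , drop = FALSE]
    which(apply(m, 2L, function(col) {
      length(unique(col[col %in% UNAMBIGUOUS])) >= 2L
    }))
  })
  sort(Reduce(intersect, polys))
}
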