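test_that("alignment construction validates shape and alphabet", {
  a <- dna_alignment(c(x = "ACGT-", y = "ACGTA", z = "AGGTA"))
  expect_s3_class(a, "dna_alignment")
  expect_equal(dim(a$mat), c(3L, 5L))
  expect_equal(rownames(a$mat), c("x", "y", "z"))

  expect_error(dna_alignment(c("ACGTA", "ACGT")), "ragged")
  expect_error(dna_alignment(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(dna_alignment(character(0)), "empty")
  expect_error(dna_alignment("AXGT"), "non-IUPAC")
  # U maps to T, case folded
  expect_equal(dna_alignment("acgu")$mat[1, ], c("A", "C", "G", "T"))
})

test_that("FASTA round-trip preserves residues and ids", {
  a <- random_alignment(5, 40, seed = 101)
  f <- tempfile(fileext = ".fasta")
  write_alignment(a, f)
  b <- read_alignment(f)
  expect_identical(a$mat, b$mat)
  expect_error(read_alignment(tempfile()), "no such file")
  # group map assignment
  gm <- data.frame(id = c("s1", "s2"), group = c("g1", "g1"))
  b2 <- read_alignment(f, gm)
  expect_equal(unname(b2$groups[c("s1", "s3")]), c("g1", "all"))
})

test_that("site classification counts S, eta and indel events", {
  a <- dna_alignment(c("AAGAC", "AAGAC", "AGTAC", "ATTAC"))
  sc <- classify_sites(a)
  expect_equal(sc$class, c("monomorphic", "segregating", "segregating",
                           "monomorphic", "monomorphic"))
  expect_equal(sc$eta_site, c(0L, 2L, 1L, 0L, 0L))

  # gap columns route to indel detection; adjacent identical gap patterns
  # collapse to one event
  b <- dna_alignment(c("A--CT", "A--CT", "AGGCT", "AGGC-"))
  scb <- classify_sites(b)
  expect_equal(attr(scb, "n_indel_events"), 2L)
  expect_equal(scb$class[2:3], rep("indel-segregating", 2))

  # ambiguity excluded under complete deletion, kept under pairwise
  d <- dna_alignment(c("ART", "AAT", "AGT"))
  expect_equal(classify_sites(d)$class[2], "excluded")
  expect_equal(classify_sites(d, "pairwise")$class[2], "segregating")
})

test_that("S <= eta <= 3S over random alignments", {
  for (seed in 1:10) {
    a <- random_alignment(8, 30, seed = seed)
    sc <- classify_sites(a)
    S <- sum(sc$class == "segregating")
    eta <- sum(sc$eta_site)
    expect_gte(eta, S)
    expect_lte(eta, 3L * S)
  }
})

test_that("haplotype collapse partitions the sample deterministically", {
  a <- dna_alignment(c(p = "ACGT", q = "ACGT", r = "ACGA"))
  h <- collapse_haplotypes(a)
  expect_equal(h$count, c(2L, 1L))
  expect_equal(h$members, c("p,q", "r"))
  expect_equal(sum(h$count), 3L)

  one <- collapse_haplotypes(dna_alignment(c("AC", "AC", "AC")))
  expect_equal(nrow(one), 1L)

  # invariant to record order up to relabeling; idempotent over members
  perm <- dna_alignment(c(r = "ACGA", q = "ACGT", p = "ACGT"))
  h2 <- collapse_haplotypes(perm)
  expect_setequal(h2$count, h$count)

  # identity over included columns only: sequences differing at an
  # excluded (gapped) column are one haplotype
  g <- dna_alignment(c("AC-T", "ACAT"))
  expect_equal(nrow(collapse_haplotypes(g)), 1L)
})

test_that("fixed differences require within-group monomorphism", {
  a <- dna_alignment(c(a1 = "AAAA", a2 = "AAAA", b1 = "GGGG", b2 = "GGGG"),
                     groups = c("g1", "g1", "g2", "g2"))
  fd <- fixed_differences(a, "g1", "g2")
  expect_equal(fd$fixed_nucleotide, 4L)
  expect_equal(fd$fixed_length, 0L)

  # a within-group polymorphism voids the column
  b <- dna_alignment(c(a1 = "AA", a2 = "AG", b1 = "GG", b2 = "GG"),
                     groups = c("g1", "g1", "g2", "g2"))
  expect_equal(fixed_differences(b, "g1", "g2")$fixed_nucleotide, 1L)

  # fixed length difference: gap run present in exactly one group
  d <- dna_alignment(c(a1 = "A--T", a2 = "A--T", b1 = "ACCT", b2 = "ACCT"),
                     groups = c("g1", "g1", "g2", "g2"))
  expect_equal(fixed_differences(d, "g1", "g2")$fixed_length, 1L)
  expect_error(fixed_differences(a, "g1", "nope"), "unknown group")
})

test_that("shared polymorphic sites intersect per-group polymorphism", {
  a <- dna_alignment(
    c(a1 = "AAGT", a2 = "ACGT", b1 = "AAGA", b2 = "ACGC"),
    groups = c("g1", "g1", "g2", "g2"))
  # column 2 polymorphic in both (states need not coincide);
  # column 4 only in g2
  expect_equal(shared_polymorphic_sites(a, c("g1", "g2")), 2L)

  mono <- dna_alignment(c(a1 = "AT", a2 = "AT", b1 = "AT", b2 = "AA"),
                        groups = c("g1", "g1", "g2", "g2"))
  expect_length(shared_polymorphic_sites(mono, c("g1", "g2")), 0L)
})
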