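test_that("protein alignment matches the brute-force DP oracle", {
  B <- blosum62_matrix()
  # classic textbook pair: co-optimal paths exist, so scores must agree
  a <- seq_record("a", "HEAGAWGHEE", "protein")
  b <- seq_record("b", "PAWHEAE", "protein")
  res <- align_protein_pair(a, b)
  o <- sw_oracle("HEAGAWGHEE", "PAWHEAE", B, 11, 1)
  expect_equal(res$score, o$score)
  expect_equal(res$score, 17)

  # random pairs: score always equal, identity equal when optimum unique
  set.seed(42)
  aa <- rownames(B)[1:20]
  for (k in 1:5) {
    x <- paste(sample(aa, 40, TRUE), collapse = "")
    y <- paste(sample(aa, 35, TRUE), collapse = "")
    res <- align_protein_pair(seq_record("x", x, "protein"),
                              seq_record("y", y, "protein"))
    o <- sw_oracle(x, y, B, 11, 1)
    expect_equal(res$score, o$score)
    expect_equal(res$identity, o$identity, tolerance = 1e-9)
  }
})

test_that("identical proteins align at 100/100/100", {
  a <- seq_record("a", "ACDEFGH", "protein")
  res <- align_protein_pair(a, seq_record("b", "ACDEFGH", "protein"))
  expect_equal(res$identity, 100)
  expect_equal(res$query_coverage, 100)
  expect_equal(res$subject_coverage, 100)
})

test_that("disjoint-alphabet pair yields the no-alignment sentinel", {
  res <- align_protein_pair(seq_record("w", "WWWWW", "protein"),
                            seq_record("p", "PPPPP", "protein"))
  expect_true(res$no_alignment)
  expect_equal(res$score, 0)
})

test_that("alignment score is symmetric", {
  set.seed(9)
  for (k in 1:4) {
    x <- seq_record("x", random_protein(60), "protein")
    y <- seq_record("y", random_protein(55), "protein")
    expect_equal(align_protein_pair(x, y)$score,
                 align_protein_pair(y, x)$score)
  }
})

test_that("nucleotide alignment recovers planted identity and strand", {
  set.seed(5)
  s <- random_dna(1020)
  a <- seq_record("a", s, "nucleotide")
  expect_equal(align_nucleotide_pair(a, seq_record("b", s, "nucleotide"),
                                     both_strands = FALSE)$identity, 100)

  # plant exactly 51 substitutions -> ~95% identity
  bases <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(bases), 51)
  for (i in pos) bases[i] <- setdiff(c("A", "C", "G", "T"), bases[i])[1]
  mut <- seq_record("m", paste(bases, collapse = ""), "nucleotide")
  res <- align_nucleotide_pair(a, mut)
  expect_true(abs(res$identity - 95.0) < 0.5)

  # short pair against the DP oracle, exact score equality
  x <- random_dna(150, seed = 6)
  yb <- strsplit(x, "")[[1]]
  for (i in sample(150, 8)) yb[i] <- setdiff(c("A", "C", "G", "T"), yb[i])[1]
  y <- paste(yb, collapse = "")
  mat <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = FALSE)
  o <- sw_oracle(x, y, mat, 5, 2)
  res <- align_nucleotide_pair(seq_record("x", x, "nucleotide"),
                               seq_record("y", y, "nucleotide"),
                               both_strands = FALSE)
  expect_equal(res$score, o$score)

  # reverse complement found when strand search enabled
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  res <- align_nucleotide_pair(seq_record("r", rc, "nucleotide"), a)
  expect_equal(res$strand, "-")
  expect_equal(res$identity, 100)
})

test_that("best_hits picks the highest score with deterministic ties", {
  a <- toy_proteome("A", c(q1 = "MKVLWAALLVTFLAGCQA"))
  # p1/p2 identical sequences: equal score and identity, p1 wins the tie
  b <- toy_proteome("B", c(p2 = "MKVLWAALLVTFLAGCQA",
                           p1 = "MKVLWAALLVTFLAGCQA"))
  bh <- best_hits(a, b)
  expect_equal(bh$hits$subject_id, "p1")

  # identical proteomes map every protein to its twin
  set.seed(14)
  seqs <- vapply(1:4, function(i) random_protein(50), character(1))
  names(seqs) <- paste0("p", 1:4)
  p <- toy_proteome("P", seqs)
  q <- toy_proteome("Q", seqs)
  bh <- best_hits(p, q)
  expect_equal(sort(bh$hits$query_id), sort(names(seqs)))
  expect_equal(bh$hits$subject_id, bh$hits$query_id)

  # hand-enumerated best hits on a constructed 2-protein case
  x1 <- random_protein(60, seed = 21)
  x2 <- random_protein(60, seed = 22)
  pa <- toy_proteome("X", c(a1 = x1, a2 = x2))
  pb <- toy_proteome("Y", c(b1 = x1, b2 = x2))
  bh <- best_hits(pa, pb)
  expect_equal(bh$hits$subject_id[bh$hits$query_id == "a1"], "b1")
  expect_equal(bh$hits$subject_id[bh$hits$query_id == "a2"], "b2")
})

test_that("best_hits is invariant under input order shuffling", {
  set.seed(31)
  seqs <- vapply(1:6, function(i) random_protein(45), character(1))
  names(seqs) <- paste0("p", 1:6)
  mut <- vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    v[1:5] <- "A"
    paste(v, collapse = "")
  }, character(1))
  names(mut) <- paste0("m", 1:6)
  a <- toy_proteome("A", seqs)
  b1 <- toy_proteome("B", mut)
  b2 <- toy_proteome("B", mut[sample(6)])
  h1 <- best_hits(a, b1)$hits
  h2 <- best_hits(a, b2)$hits
  o1 <- h1[order(h1$query_id), ]
  o2 <- h2[order(h2$query_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("reciprocal_pairs returns a matching of mutual best hits", {
  set.seed(51)
  seqs <- vapply(1:5, function(i) random_protein(50), character(1))
  names(seqs) <- paste0("g", 1:5)
  a <- toy_proteome("A", seqs)
  b <- toy_proteome("B", seqs)
  rp <- reciprocal_pairs(best_hits(a, b), best_hits(b, a))
  expect_equal(nrow(rp), 5)       # n self-pairs for identical proteomes
  expect_equal(rp$protein_a, rp$protein_b)
  expect_false(anyDuplicated(rp$protein_a) > 0)
  expect_false(anyDuplicated(rp$protein_b) > 0)

  # mismatched strain pair is rejected
  c3 <- toy_proteome("C", seqs)
  expect_error(reciprocal_pairs(best_hits(a, b), best_hits(c3, a)),
               "directions")
})

test_that("non-reciprocal chains produce no pairs", {
  # x's best hit is y, but y's best hit is z != x
  ab <- structure(list(query_strain = "A", subject_strain = "B",
                       hits = data.frame(query_id = "x", subject_id = "y",
                                         identity = 90, query_coverage = 100,
                                         subject_coverage = 100, score = 50,
                                         aln_length = 10)),
                  class = "best_hit_map")
  ba <- structure(list(query_strain = "B", subject_strain = "A",
                       hits = data.frame(query_id = "y", subject_id = "z",
                                         identity = 95, query_coverage = 100,
                                         subject_coverage = 100, score = 60,
                                         aln_length = 10)),
                  class = "best_hit_map")
  expect_equal(nrow(reciprocal_pairs(ab, ba)), 0)
})

test_that("reciprocal pair recall on simulated orthologs is >= 0.95", {
  cl <- sim_pair(0.30, n_genes = 60, seed = 77)
  rp <- reciprocal_pairs(best_hits(cl$proteomes$A, cl$proteomes$B),
                         best_hits(cl$proteomes$B, cl$proteomes$A))
  planted <- names(cl$truth$groups)
  recovered <- rp$protein_a[rp$protein_a == rp$protein_b]
  expect_gte(length(intersect(recovered, planted)) / length(planted), 0.95)
})

test_that("fragment_genome cuts contigs with flagged terminal remainder", {
  g <- genome("g", c(c1 = random_dna(3060, seed = 61)))
  fr <- fragment_genome(g, 1020)
  expect_length(fr, 3)
  expect_true(all(nchar(vapply(fr, `[[`, character(1), "seq")) == 1020))
  expect_equal(vapply(fr, `[[`, character(1), "id"),
               c("c1:1", "c1:1021", "c1:2041"))

  g2 <- genome("g2", c(c1 = random_dna(2500, seed = 62)))
  fr2 <- fragment_genome(g2, 1020)
  expect_equal(nchar(vapply(fr2, `[[`, character(1), "seq")),
               c(1020, 1020, 460))
  expect_equal(vapply(fr2, `[[`, character(1), "desc"),
               c("", "", "partial"))

  expect_error(fragment_genome(g, 50), ">= 100")
})
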