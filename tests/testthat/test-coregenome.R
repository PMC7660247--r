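# Helpers to construct pairsets and proteomes with planted orthology.
make_pairset <- function(a, b, pairs) {
  data.frame(strain_a = a, strain_b = b,
             protein_a = vapply(pairs, `[[`, character(1), 1),
             protein_b = vapply(pairs, `[[`, character(1), 2),
             stringsAsFactors = FALSE)
}

# three strains, three planted ortholog triples (g1..g3 in each strain)
triple_fixture <- function() {
  set.seed(141)
  genes <- vapply(1:3, function(i) random_protein(45), character(1))
  seqs <- stats::setNames(genes, paste0("g", 1:3))
  ps <- lapply(c("A", "B", "C"), function(s) toy_proteome(s, seqs))
  pairs <- lapply(paste0("g", 1:3), function(g) c(g, g))
  pairsets <- list(
    `A|B` = make_pairset("A", "B", pairs),
    `A|C` = make_pairset("A", "C", pairs),
    `B|C` = make_pairset("B", "C", pairs))
  list(proteomes = ps, pairsets = pairsets)
}

test_that("planted ortholog triples become single-copy groups", {
  fx <- triple_fixture()
  groups <- build_ortholog_groups(fx$pairsets, fx$proteomes)
  expect_length(groups, 3)
  for (g in groups) {
    expect_setequal(names(g$members), c("A", "B", "C"))
    expect_equal(length(unique(g$members)), 1)  # same gene everywhere
  }
})

test_that("components violating single-copy or completeness are dropped", {
  fx <- triple_fixture()
  # connect g1 of A to both g1 and g2 of B: component has 2 B proteins
  bad <- fx$pairsets
  bad$`A|B` <- rbind(bad$`A|B`,
                     make_pairset("A", "B", list(c("g1", "g2"))))
  groups <- build_ortholog_groups(bad, fx$proteomes)
  expect_length(groups, 1)   # only g3 survives (g1+g2 merged, multi-copy)

  # remove strain C edges for g2: component misses a strain
  miss <- fx$pairsets
  miss$`A|C` <- miss$`A|C`[miss$`A|C`$protein_a != "g2", ]
  miss$`B|C` <- miss$`B|C`[miss$`B|C`$protein_a != "g2", ]
  groups2 <- build_ortholog_groups(miss, fx$proteomes)
  expect_length(groups2, 2)

  # a missing pairset is an error naming the pair
  expect_error(build_ortholog_groups(fx$pairsets[c("A|B", "A|C")],
                                     fx$proteomes), "B / C")
})

test_that("length filter keeps >= 90% of the maximum, boundary inclusive", {
  mk_group <- function(lens) {
    seqs <- vapply(lens, function(l) strrep("A", l), character(1))
    structure(list(group_id = "g", members = c(A = "p", B = "p", C = "p")[
      seq_along(lens)],
      protein_seqs = stats::setNames(seqs, c("A", "B", "C")[seq_along(lens)]),
      cds_seqs = NULL), class = "ortholog_group")
  }
  expect_length(filter_by_length(list(mk_group(c(100, 95, 89)))), 0)
  expect_length(filter_by_length(list(mk_group(c(100, 90)))), 1)
  expect_length(filter_by_length(list(mk_group(c(80, 80, 80)))), 1)
})

test_that("filters are idempotent", {
  fx <- triple_fixture()
  groups <- build_ortholog_groups(fx$pairsets, fx$proteomes)
  once <- filter_by_length(groups)
  expect_identical(filter_by_length(once), once)
  al <- list(l1 = locus_aln("l1", c(A = "ATGATG", B = "ATGTTG")))
  once_d <- filter_by_divergence(al)
  expect_identical(filter_by_divergence(once_d), once_d)
})

test_that("identical members align without gaps at 3x protein length", {
  prot <- "MKVLW"
  cds <- "ATGAAAGTATTATGGTAA"   # with terminal stop
  grp <- structure(list(group_id = "OG1",
                        members = c(A = "p", B = "p"),
                        protein_seqs = c(A = prot, B = prot),
                        cds_seqs = c(A = cds, B = cds)),
                   class = "ortholog_group")
  al <- align_locus(grp)
  expect_equal(al$length, 15)  # stop codon stripped
  expect_false(any(grepl("-", al$rows)))
  expect_equal(unname(al$rows["A"]), "ATGAAAGTATTATGG")
})

test_that("an internal codon deletion yields one 3-column gap", {
  set.seed(143)
  gcd <- Biostrings::GENETIC_CODE
  sense <- names(gcd[gcd != "*"])
  codons <- sample(sense, 30, replace = TRUE)
  cds_full <- paste(codons, collapse = "")
  cds_del <- paste(codons[-15], collapse = "")
  prot_full <- paste(unname(gcd[codons]), collapse = "")
  prot_del <- paste(unname(gcd[codons[-15]]), collapse = "")
  grp <- structure(list(group_id = "OG1",
                        members = c(A = "p", B = "p"),
                        protein_seqs = c(A = prot_full, B = prot_del),
                        cds_seqs = c(A = cds_full, B = cds_del)),
                   class = "ortholog_group")
  al <- align_locus(grp)
  expect_equal(al$length, 90)
  expect_equal(sum(strsplit(al$rows[["B"]], "")[[1]] == "-"), 3)
  expect_false(grepl("-", al$rows[["A"]]))
})

test_that("groups without cds are rejected with a named reason", {
  grp <- structure(list(group_id = "OG9",
                        members = c(A = "p", B = "p"),
                        protein_seqs = c(A = "MKV", B = "MKV"),
                        cds_seqs = c(A = "ATGAAAGTA", B = NA)),
                   class = "ortholog_group")
  expect_error(align_locus(grp), "missing cds")
  res <- align_loci(list(grp))
  expect_length(res$alignments, 0)
  expect_match(res$rejected[["OG9"]], "missing cds")
})

test_that("divergence filter drops strictly below 25% identity", {
  rows_20 <- c(A = strrep("A", 20),
               B = paste0(strrep("A", 4), strrep("C", 16)))   # 20%
  rows_25 <- c(A = strrep("A", 20),
               B = paste0(strrep("A", 5), strrep("C", 15)))   # exactly 25%
  rows_id <- c(A = "ATGATG", B = "ATGATG")                    # 100%
  al <- list(a = locus_aln("a", rows_20), b = locus_aln("b", rows_25),
             c = locus_aln("c", rows_id))
  kept <- filter_by_divergence(al)
  expect_setequal(names(kept), c("b", "c"))
})

test_that("divergence statistic uses the worst pair by default", {
  rows <- c(A = strrep("A", 20), B = strrep("A", 20),
            C = paste0(strrep("A", 4), strrep("C", 16)))  # min pair 20%
  al <- list(x = locus_aln("x", rows))
  expect_length(filter_by_divergence(al, stat = "min"), 0)
  expect_length(filter_by_divergence(al, stat = "mean"), 1)
})

test_that("concatenation masks gap and invariant columns exactly", {
  # two loci, 20 columns total: 3 gap-containing + 4 invariant among them
  l1 <- locus_aln("l1", c(A = "ATGATGATG", B = "ATG-TGTTG",
                          C = "ATGATGCTG"))
  # l1: col4 gap; cols 1,2,3,5,6,9 invariant-ish; variable: 7,8
  l2 <- locus_aln("l2", c(A = "GGCCAAATCGT", B = "GGCCAAGTC-T",
                          C = "GGTCAAATC-T"))
  sm <- concatenate_and_mask(list(l1, l2))
  rows <- c(A = paste0("ATGATGATG", "GGCCAAATCGT"),
            B = paste0("ATG-TGTTG", "GGCCAAGTC-T"),
            C = paste0("ATGATGCTG", "GGTCAAATC-T"))
  expect_equal(sm$n_variable_sites, brute_force_columns(rows))
  expect_equal(sm$partitions$l1, c(start = 1L, end = 9L))
  expect_equal(sm$partitions$l2, c(start = 10L, end = 20L))
  # every surviving column: >= 2 states, no gaps
  expect_true(all(apply(sm$columns, 2, function(col)
    length(unique(col)) >= 2 && all(col %in% c("A", "C", "G", "T")))))
})

test_that("columns like {A, A, -} are removed and all-identical rows warn", {
  l <- locus_aln("l", c(A = "AAT", B = "AAT", C = "-AT"))
  expect_warning(sm <- concatenate_and_mask(list(l)), "empty")
  expect_equal(sm$n_variable_sites, 0)
})

test_that("supermatrix column classification matches brute force randomly", {
  set.seed(144)
  for (rep in 1:5) {
    n <- 4
    len <- 30
    rows <- vapply(1:n, function(i) {
      chars <- sample(c("A", "C", "G", "T", "-"), len, replace = TRUE,
                      prob = c(0.3, 0.3, 0.15, 0.15, 0.1))
      paste(chars, collapse = "")
    }, character(1))
    names(rows) <- paste0("s", 1:n)
    sm <- suppressWarnings(
      concatenate_and_mask(list(locus_aln("x", rows))))
    expect_equal(sm$n_variable_sites, brute_force_columns(rows))
  }
})

test_that("Jukes-Cantor distances match the closed form", {
  expect_equal(jc_distance(0.05), -0.75 * log(1 - 0.2 / 3),
               tolerance = 1e-12)
  expect_equal(round(jc_distance(0.05), 5), 0.05174)
  expect_equal(jc_distance(0), 0)
  for (p in c(0.01, 0.1, 0.3, 0.6))
    expect_equal(jc_distance(p), -0.75 * log(1 - 4 * p / 3),
                 tolerance = 1e-9)
  expect_error(jc_distance(0.8), "0.75")
})

test_that("distance matrix: zeros on identity, cap on saturation", {
  cols <- rbind(A = c("A", "C", "G", "T"), B = c("A", "C", "G", "T"),
                C = c("T", "G", "C", "A"))
  sm <- structure(list(ids = c("A", "B", "C"), columns = cols,
                       n_variable_sites = 4, partitions = list()),
                  class = "supermatrix")
  expect_warning(d <- jc_distance_matrix(sm), "capped")
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 5.0)  # p = 1 saturates
  expect_equal(d, t(d))
})

test_that("NJ handles 2- and 3-taxon cases in closed form", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  t2 <- nj_tree(d2)
  expect_setequal(t2$tip.label, c("a", "b"))
  expect_equal(sum(t2$edge.length), 0.4)

  # 3 taxa: star with branch lengths x = (dab + dac - dbc)/2 etc.
  dab <- 0.2; dac <- 0.3; dbc <- 0.4
  d3 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d3["a", "b"] <- d3["b", "a"] <- dab
  d3["a", "c"] <- d3["c", "a"] <- dac
  d3["b", "c"] <- d3["c", "b"] <- dbc
  t3 <- nj_tree(d3)
  la <- t3$edge.length[t3$edge[, 2] == which(t3$tip.label == "a")]
  expect_equal(la, (dab + dac - dbc) / 2, tolerance = 1e-9)
})

test_that("NJ recovers additive trees exactly (RF = 0)", {
  set.seed(145)
  for (rep in 1:4) {
    tr <- ape::rtree(8, br = function(n) runif(n, 0.05, 0.5))
    tr <- ape::unroot(tr)
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d)
    expect_equal(rf_distance(rec, tr), 0)
  }
})

test_that("RF distance counts bipartition symmetric differences", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(rf_distance(t1, t1), 0)
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t2), 2)
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_equal(rf_distance(t1, star), 1)
  t3 <- ape::read.tree(text = "((a,b),(c,e));")
  expect_error(rf_distance(t1, t3), "leaf sets")
})

test_that("trim_to_reference removes flanks and flags short queries", {
  core <- random_dna(300, seed = 146)
  ref <- seq_record("ref", core, "nucleotide")
  expect_equal(trim_to_reference(ref, ref)$seq, core)

  flanked <- seq_record("q", paste0(random_dna(50, seed = 147), core,
                                    random_dna(50, seed = 148)),
                        "nucleotide")
  trimmed <- trim_to_reference(flanked, ref)
  expect_equal(trimmed$seq, core)

  half <- seq_record("h", substr(core, 1, 120), "nucleotide")
  flagged <- trim_to_reference(half, ref)
  expect_true(isTRUE(attr(flagged, "low_coverage")))
})

test_that("16S species demarcation is strict greater-than 98.65", {
  expect_equal(demarcate_species(99.3), "same_species_candidate")
  expect_equal(demarcate_species(98.0), "distinct")
  expect_equal(demarcate_species(98.65), "distinct")
  expect_error(demarcate_species(101), "outside")
})

test_that("marker extraction finds the reference-like protein and cds", {
  cl <- clade4()
  p <- cl$proteomes$A
  target_id <- names(p$proteins)[3]
  ref <- seq_record("ref_marker", p$proteins[[target_id]]$seq, "protein")
  hit <- extract_marker(cl$proteomes$B, ref)
  expect_equal(hit$protein$id, target_id)  # same gene ids across strains
  expect_false(is.null(hit$cds))
})

test_that("the pipeline keeps all planted loci on a benign clade", {
  cl <- clade4()
  res <- cached("clade4_pipeline", core_genome_pipeline(cl$proteomes))
  # no duplication/loss, mild divergence: every planted group survives
  expect_equal(unname(res$stages["single_copy_groups"]),
               length(cl$truth$groups))
  expect_equal(unname(res$stages["after_divergence_filter"]),
               unname(res$stages["after_length_filter"]))
  expect_gt(res$supermatrix$n_variable_sites, 0)
  expect_setequal(res$supermatrix$ids, names(cl$proteomes))

  # distances feed NJ; the recovered topology matches the true tree
  d <- jc_distance_matrix(res$supermatrix)
  expect_equal(rf_distance(nj_tree(d), cl$truth$tree), 0)
})

test_that("supermatrix writers emit valid PHYLIP and FASTA", {
  cl <- clade4()
  res <- cached("clade4_pipeline", core_genome_pipeline(cl$proteomes))
  fp <- withr::local_tempfile()
  write_supermatrix_phylip(res$supermatrix, fp)
  lines <- readLines(fp)
  expect_match(lines[1], sprintf("^%d %d$", length(res$supermatrix$ids),
                                 res$supermatrix$n_variable_sites))
  ff <- withr::local_tempfile()
  write_supermatrix_fasta(res$supermatrix, ff)
  back <- read_fasta(ff, "nucleotide")
  expect_length(back, length(res$supermatrix$ids))
})
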