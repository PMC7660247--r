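# Shared fixture builders. Heavier simulated objects are cached so several
# test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A pair of proteomes at a planted amino-acid divergence.
sim_pair <- function(divergence, n_genes, seed, gene_length_mean = 100) {
  simulate_clade(sim_config(two_leaf_tree(divergence), n_genes = n_genes,
                            gene_length_mean = gene_length_mean,
                            gene_length_sd = 10, seed = seed))
}

# 4-strain clade with CDS, reused by metrics and coregenome tests.
clade4 <- function() cached("clade4", {
  simulate_clade(sim_config("((A:0.04,B:0.04):0.03,(C:0.04,D:0.04):0.03);",
                            n_genes = 30, gene_length_mean = 80,
                            gene_length_sd = 8, seed = 401))
})

# Hand-buildable locus alignment.
locus_aln <- function(group_id, rows) {
  structure(list(group_id = group_id, rows = rows,
                 length = nchar(rows[[1]])), class = "locus_alignment")
}

# Direct, loop-based classification of supermatrix columns (independent of
# concatenate_and_mask's vectorised path).
brute_force_columns <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gapfree <- all(col %in% c("A", "C", "G", "T"))
    variable <- length(unique(col)) >= 2
    keep[j] <- gapfree && variable
  }
  sum(keep)
}

toy_proteome <- function(strain, seqs) proteome(strain, seqs)
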