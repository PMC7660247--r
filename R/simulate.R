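# Synthetic clades with known ortholog truth, planted AAI matrices and
# assembly degradation utilities. Everything is deterministic given the
# mandatory seed.

.genetic_code <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      sense <- gc[gc != "*"]
      cache <<- list(code = gc, sense_codons = names(sense),
                     by_aa = split(names(sense), unname(sense)))
    }
    cache
  }
})

#' Simulation configuration for a synthetic clade
#'
#' @param tree Newick string with branch lengths interpreted as per-site
#'   amino-acid substitution probabilities along each branch.
#' @param n_genes Number of ancestral genes.
#' @param gene_length_mean,gene_length_sd Gene length distribution in
#'   codons (normal, truncated at 30 codons).
#' @param indel_rate Per-codon probability of an indel event per branch
#'   (indels act in whole codons, so CDS stay translatable).
#' @param duplication_rate,loss_rate Per-gene per-branch event
#'   probabilities.
#' @param seed Mandatory integer seed.
#' @return A `sim_config`.
#' @export
sim_config <- function(tree, n_genes = 100, gene_length_mean = 120,
                       gene_length_sd = 20, indel_rate = 0,
                       duplication_rate = 0, loss_rate = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (indel_rate < 0 || duplication_rate < 0 || loss_rate < 0)
    stop("rates must be >= 0")
  structure(list(tree = tree, n_genes = n_genes,
                 gene_length_mean = gene_length_mean,
                 gene_length_sd = gene_length_sd, indel_rate = indel_rate,
                 duplication_rate = duplication_rate, loss_rate = loss_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Two-leaf tree planting a target amino-acid divergence
#'
#' Each of the two branches gets per-site substitution probability
#' `p = 1 - sqrt(1 - divergence)`, so the probability that a site differs
#' between the leaves is approximately `divergence` (substitutions always
#' change the amino acid, and independent hits on both branches rarely
#' coincide).
#'
#' @param divergence Target pairwise amino-acid divergence in [0, 1)
#'   (e.g. 0.15 for ~85% identity).
#' @param labels Leaf labels.
#' @return Newick string.
#' @export
two_leaf_tree <- function(divergence, labels = c("A", "B")) {
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0,1)")
  p <- 1 - sqrt(1 - divergence)
  sprintf("(%s:%.10f,%s:%.10f);", labels[1], p, labels[2], p)
}

.random_gene <- function(len_codons) {
  gcd <- .genetic_code()
  sample(gcd$sense_codons, len_codons, replace = TRUE)
}

# Substitute codons with per-site probability b; each substitution picks a
# different amino acid uniformly, then one of its codons uniformly.
.evolve_gene <- function(codons, b, indel_rate) {
  gcd <- .genetic_code()
  if (b > 0) {
    hit <- which(stats::runif(length(codons)) < b)
    for (i in hit) {
      aa <- gcd$code[[codons[i]]]
      new_aa <- sample(setdiff(names(gcd$by_aa), aa), 1)
      codons[i] <- sample(gcd$by_aa[[new_aa]], 1)
    }
  }
  if (indel_rate > 0 && length(codons) > 31) {
    ev <- which(stats::runif(length(codons)) < indel_rate)
    for (i in rev(ev)) {          # right-to-left keeps indices valid
      if (stats::runif(1) < 0.5 && length(codons) > 31) {
        codons <- codons[-i]      # delete one codon
      } else {
        codons <- append(codons, sample(gcd$sense_codons, 1), after = i)
      }
    }
  }
  codons
}

#' Simulate a clade of genomes/proteomes with ortholog truth
#'
#' Draws an ancestral set of CDS and evolves it along the configured tree:
#' codon substitutions calibrated so a branch of length b changes each
#' amino-acid site with probability b, optional whole-codon indels, and
#' optional per-gene duplication/loss. Each leaf yields a `proteome` (with
#' CDS incl. terminal stop codons) and a `genome` (CDS concatenated with
#' random spacers). The truth component records the single-copy ortholog
#' groups, the expected pairwise amino-acid identity implied by the tree,
#' and the tree itself.
#'
#' @param config A [sim_config()].
#' @return A `sim_clade`: list with `proteomes`, `genomes`, `truth`
#'   (`groups`, `expected_identity` matrix in percent, `tree`).
#' @export
simulate_clade <- function(config) {
  set.seed(config$seed)
  tr <- tryCatch(ape::read.tree(text = config$tree),
                 error = function(e) NULL)
  if (is.null(tr) || is.null(tr$edge.length))
    stop("unparseable tree (need newick with branch lengths): ",
         config$tree)
  if (any(tr$edge.length < 0 | tr$edge.length >= 1))
    stop("branch lengths must be substitution probabilities in [0, 1)")
  lens <- pmax(30L, round(stats::rnorm(config$n_genes,
                                       config$gene_length_mean,
                                       config$gene_length_sd)))
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  root_genes <- stats::setNames(lapply(lens, .random_gene), gene_ids)

  ntips <- length(tr$tip.label)
  root <- ntips + 1L
  node_genes <- vector("list", ntips + tr$Nnode)
  node_genes[[root]] <- root_genes
  # preorder traversal: parents before children
  ord <- ape::reorder.phylo(tr, "cladewise")
  leaf_sets <- vector("list", ntips)
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    b <- ord$edge.length[k]
    genes <- node_genes[[parent]]
    if (config$loss_rate > 0) {
      lost <- stats::runif(length(genes)) < config$loss_rate
      genes <- genes[!lost]
    }
    genes <- lapply(genes, .evolve_gene, b = b,
                    indel_rate = config$indel_rate)
    if (config$duplication_rate > 0) {
      dup <- which(stats::runif(length(genes)) < config$duplication_rate)
      for (i in dup) {
        nm <- paste0(names(genes)[i], ".d", child)
        genes[[nm]] <- genes[[i]]
      }
    }
    node_genes[[child]] <- genes
    if (child <= ntips) leaf_sets[[child]] <- genes
  }

  spacer <- function() paste(sample(c("A", "C", "G", "T"), 50,
                                    replace = TRUE), collapse = "")
  gcd <- .genetic_code()
  proteomes <- list(); genomes <- list()
  for (i in seq_len(ntips)) {
    strain <- tr$tip.label[i]
    genes <- leaf_sets[[i]]
    cds <- vapply(genes, function(g) paste(c(g, "TAA"), collapse = ""),
                  character(1))
    prots <- vapply(genes, function(g)
      paste(unname(gcd$code[g]), collapse = ""), character(1))
    proteomes[[strain]] <- proteome(strain, prots, cds)
    contig <- paste(vapply(seq_along(cds), function(k)
      paste0(cds[k], spacer()), character(1)), collapse = "")
    genomes[[strain]] <- genome(strain,
                                stats::setNames(contig,
                                                paste0(strain, "_c1")))
  }

  # truth: gene families (duplicates share the ancestral prefix) present
  # exactly once in every leaf
  fams <- lapply(leaf_sets, function(g) sub("\\..*$", "", names(g)))
  single_copy <- Filter(function(g) {
    all(vapply(fams, function(p) sum(p == g) == 1L, logical(1)))
  }, gene_ids)
  groups <- lapply(single_copy, function(g)
    stats::setNames(rep(g, ntips), tr$tip.label))
  names(groups) <- single_copy

  tr2 <- tr
  tr2$edge.length <- -log(1 - tr$edge.length)
  D <- ape::cophenetic.phylo(tr2)[tr$tip.label, tr$tip.label]
  expected <- 100 * exp(-D)
  diag(expected) <- 100

  structure(list(proteomes = proteomes, genomes = genomes,
                 truth = list(groups = groups,
                              expected_identity = expected,
                              tree = tr),
                 config = config),
            class = "sim_clade")
}

#' @export
print.sim_clade <- function(x, ...) {
  cat(sprintf("<sim_clade: %d leaves, %d genes, seed %d>\n",
              length(x$proteomes), x$config$n_genes, x$config$seed))
  invisible(x)
}

#' Configuration for a planted bimodal AAI matrix
#'
#' Intra-genus values are drawn from N(`intra_mean`, `intra_sd`), between
#' genera from N(`inter_mean`, `inter_sd`), and every draw falling inside
#' the `forbidden_band` is rejected and redrawn, so the band is empty by
#' construction. The plantable-gap invariant
#' `inter_mean + 3*inter_sd < band low < band high < intra_mean -
#' 3*intra_sd` keeps the two modes well clear of the band.
#'
#' @param genus_sizes Integer vector of strains per planted genus.
#' @param intra_mean,intra_sd,inter_mean,inter_sd Percent parameters.
#' @param forbidden_band A [gap_band()].
#' @param seed Mandatory integer seed.
#' @return A `planted_matrix_config`.
#' @export
planted_matrix_config <- function(genus_sizes, intra_mean = 82,
                                  intra_sd = 1.5, inter_mean = 70,
                                  inter_sd = 1.0,
                                  forbidden_band = gap_band(74, 76),
                                  seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (any(genus_sizes < 1)) stop("genus sizes must be >= 1")
  ok <- inter_mean + 3 * inter_sd < forbidden_band$low &&
    forbidden_band$high < intra_mean - 3 * intra_sd
  if (!ok)
    stop("plantable-gap invariant violated: need inter_mean + 3*inter_sd ",
         "< band low < band high < intra_mean - 3*intra_sd")
  structure(list(genus_sizes = as.integer(genus_sizes),
                 intra_mean = intra_mean, intra_sd = intra_sd,
                 inter_mean = inter_mean, inter_sd = inter_sd,
                 forbidden_band = forbidden_band, seed = as.integer(seed)),
            class = "planted_matrix_config")
}

#' Generate a planted AAI matrix with truth labels
#'
#' @param config A [planted_matrix_config()].
#' @return List with `matrix` (a `pairwise_matrix`) and `truth`
#'   (data.frame `strain_id, genus`).
#' @export
planted_aai_matrix <- function(config) {
  set.seed(config$seed)
  n <- sum(config$genus_sizes)
  ids <- sprintf("s%02d", seq_len(n))
  genus <- rep(sprintf("G%d", seq_along(config$genus_sizes)),
               config$genus_sizes)
  band <- config$forbidden_band
  draw <- function(mean, sd) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (!(v > band$low && v < band$high) && v < 100 && v > 0) return(v)
    }
  }
  v <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      same <- genus[i] == genus[j]
      val <- if (same) draw(config$intra_mean, config$intra_sd)
             else draw(config$inter_mean, config$inter_sd)
      v[i, j] <- v[j, i] <- val
    }
  list(matrix = pairwise_matrix(ids, v, "aai"),
       truth = data.frame(strain_id = ids, genus = genus,
                          stringsAsFactors = FALSE))
}

#' Break a genome into more contigs without changing its content
#'
#' Splits the genome at `n_breaks` uniformly random internal positions —
#' a model of draft (fragmented) versus complete assemblies of the same
#' strain; base content is exactly conserved.
#'
#' @param g A `genome`.
#' @param n_breaks Number of breakpoints (< total length).
#' @param seed Integer seed.
#' @return A `genome` with `n_breaks` more contigs.
#' @export
degrade_assembly <- function(g, n_breaks, seed) {
  set.seed(seed)
  total <- genome_length(g)
  if (n_breaks >= total) stop("n_breaks must be below the genome length")
  if (n_breaks == 0) return(g)
  lens <- vapply(g$contigs, function(r) nchar(r$seq), numeric(1))
  offsets <- cumsum(c(0, lens[-length(lens)]))
  # global internal positions, excluding existing contig boundaries
  internal <- setdiff(seq_len(total - 1), cumsum(lens))
  breaks <- sort(sample(internal, min(n_breaks, length(internal))))
  out <- list()
  for (ci in seq_along(g$contigs)) {
    seqs <- g$contigs[[ci]]$seq
    local_breaks <- breaks[breaks > offsets[ci] &
                             breaks < offsets[ci] + lens[ci]] - offsets[ci]
    starts <- c(1, local_breaks + 1)
    ends <- c(local_breaks, lens[ci])
    for (k in seq_along(starts))
      out[[length(out) + 1]] <- seq_record(
        paste0(g$contigs[[ci]]$id, ".", k),
        substr(seqs, starts[k], ends[k]), "nucleotide")
  }
  genome(g$strain_id, out)
}

#' Apply uniform point substitutions to a nucleotide record
#'
#' Each base is replaced, with probability `rate`, by a different base
#' chosen uniformly — the construction used to plant a known nucleotide
#' divergence between two genomes.
#'
#' @param record A nucleotide `seq_record`.
#' @param rate Per-site substitution probability.
#' @param seed Integer seed.
#' @return The mutated `seq_record`.
#' @export
mutate_sequence <- function(record, rate, seed) {
  set.seed(seed)
  bases <- strsplit(record$seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate &
                 bases %in% c("A", "C", "G", "T"))
  for (i in hit)
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  seq_record(record$id, paste(bases, collapse = ""), "nucleotide",
             desc = record$desc)
}
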