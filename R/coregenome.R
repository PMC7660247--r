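# Single-copy core-genome construction: ortholog groups from reciprocal
# pairs, the length / divergence filter cascade, codon-aware alignment,
# gap+invariant masking into a variable-site supermatrix, and
# distance/tree/marker utilities.

.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Qualifying reciprocal pairs for every proteome pair
#'
#' Runs the reciprocal best-hit search for each unordered pair of
#' proteomes and keeps the pairs passing the AAI inclusion thresholds —
#' the same gene pairings that feed [compute_aai()].
#'
#' @param proteomes List of `proteome`s with unique strain ids.
#' @param thresholds An [aai_thresholds()].
#' @param coverage_mode,max_targets As in [compute_aai()].
#' @return Named list keyed `"A|B"` (sorted strain ids) of data.frames
#'   with columns `strain_a, strain_b, protein_a, protein_b`.
#' @export
core_pairsets <- function(proteomes, thresholds = aai_thresholds(),
                          coverage_mode = "both", max_targets = 8L) {
  ids <- vapply(proteomes, `[[`, character(1), "strain_id")
  if (anyDuplicated(ids)) stop("duplicate strain ids")
  names(proteomes) <- ids
  out <- list()
  n <- length(ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- proteomes[[i]]; b <- proteomes[[j]]
    res <- compute_aai(a, b, thresholds, coverage_mode, max_targets)
    rp <- res$pairs
    out[[.pair_key(a$strain_id, b$strain_id)]] <- data.frame(
      strain_a = rep(a$strain_id, nrow(rp)),
      strain_b = rep(b$strain_id, nrow(rp)),
      protein_a = rp$protein_a, protein_b = rp$protein_b,
      stringsAsFactors = FALSE)
  }
  out
}

#' Build single-copy ortholog groups from reciprocal pairs
#'
#' Proteins are graph nodes and qualifying reciprocal pairs are edges; a
#' connected component is kept if and only if it contains exactly one
#' protein from every strain — the "present in a single copy in all
#' strains" criterion. `clique = TRUE` additionally requires every member
#' pair to be directly connected.
#'
#' @param pairsets Named list from [core_pairsets()]; must cover all
#'   unordered strain pairs.
#' @param proteomes List of `proteome`s (sequence source; defines the
#'   strain set).
#' @param clique Require complete pairwise connectivity within a group.
#' @return List of `ortholog_group`s: `group_id`, `members`
#'   (strain -> protein id), `protein_seqs`, `cds_seqs` (strain-named
#'   character vectors; cds `NA` when absent).
#' @export
build_ortholog_groups <- function(pairsets, proteomes, clique = FALSE) {
  ids <- vapply(proteomes, `[[`, character(1), "strain_id")
  names(proteomes) <- ids
  n <- length(ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    key <- .pair_key(ids[i], ids[j])
    if (is.null(pairsets[[key]]))
      stop("missing pairset for strain pair ", ids[i], " / ", ids[j])
  }
  edges <- do.call(rbind, lapply(pairsets, function(ps) {
    if (!nrow(ps)) return(NULL)
    cbind(paste(ps$strain_a, ps$protein_a, sep = "\t"),
          paste(ps$strain_b, ps$protein_b, sep = "\t"))
  }))
  if (is.null(edges)) return(list())
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  verts <- igraph::V(g)$name
  groups <- split(verts, comp$membership)
  out <- list()
  for (grp in groups) {
    parts <- strsplit(grp, "\t", fixed = TRUE)
    strains <- vapply(parts, `[[`, character(1), 1)
    prots <- vapply(parts, `[[`, character(1), 2)
    if (length(grp) != n || anyDuplicated(strains) ||
        !setequal(strains, ids))
      next
    if (clique) {
      sg <- igraph::induced_subgraph(g, grp)
      if (igraph::ecount(sg) < n * (n - 1) / 2) next
    }
    o <- order(match(strains, ids))
    strains <- strains[o]; prots <- prots[o]
    pseqs <- vapply(seq_along(strains), function(k)
      proteomes[[strains[k]]]$proteins[[prots[k]]]$seq, character(1))
    cseqs <- vapply(seq_along(strains), function(k) {
      cds <- proteomes[[strains[k]]]$cds
      if (is.null(cds) || is.null(cds[[prots[k]]])) NA_character_
      else cds[[prots[k]]]$seq
    }, character(1))
    out[[length(out) + 1]] <- structure(
      list(group_id = NA_character_,
           members = stats::setNames(prots, strains),
           protein_seqs = stats::setNames(pseqs, strains),
           cds_seqs = stats::setNames(cseqs, strains)),
      class = "ortholog_group")
  }
  # deterministic ids: order by the first strain's protein id
  if (length(out)) {
    key <- vapply(out, function(g) g$members[[1]], character(1))
    out <- out[order(key)]
    for (i in seq_along(out))
      out[[i]]$group_id <- sprintf("OG%04d", i)
  }
  out
}

#' Length-uniformity filter on ortholog groups
#'
#' Keeps a group iff every member protein is at least `length_fraction`
#' (default 0.90, boundary inclusive) of the group's maximum member
#' length.
#'
#' @param groups List of `ortholog_group`s.
#' @param length_fraction Fraction in (0, 1].
#' @return Filtered list.
#' @export
filter_by_length <- function(groups, length_fraction = 0.90) {
  keep <- vapply(groups, function(g) {
    lens <- nchar(g$protein_seqs)
    all(lens >= length_fraction * max(lens))
  }, logical(1))
  groups[keep]
}

# Strip a terminal stop codon from a CDS (and a trailing '*' from the
# protein) so that codon counts match protein lengths exactly.
.strip_stop <- function(prot, cds) {
  if (endsWith(prot, "*")) prot <- substr(prot, 1, nchar(prot) - 1L)
  if (nchar(cds) == 3L * nchar(prot) + 3L)
    cds <- substr(cds, 1, nchar(cds) - 3L)
  list(prot = prot, cds = cds)
}

#' Codon-aware alignment of one ortholog group
#'
#' Aligns the member proteins with mafft and back-translates the protein
#' alignment to codons using each member's CDS: each aligned residue is
#' replaced by its codon and each protein gap by `---`. Terminal stop
#' codons are stripped before alignment, so columns are codon-complete.
#'
#' @param group An `ortholog_group` with a CDS for every member.
#' @return A `locus_alignment`: `group_id`, `rows` (strain-named aligned
#'   nucleotide strings of equal length, a multiple of 3).
#' @export
align_locus <- function(group) {
  if (any(is.na(group$cds_seqs)))
    stop("group ", group$group_id, " rejected: missing cds for strain ",
         names(group$cds_seqs)[is.na(group$cds_seqs)][1])
  strains <- names(group$protein_seqs)
  prot <- group$protein_seqs
  cds <- group$cds_seqs
  for (s in strains) {
    st <- .strip_stop(prot[[s]], cds[[s]])
    prot[[s]] <- st$prot; cds[[s]] <- st$cds
    if (nchar(cds[[s]]) != 3L * nchar(prot[[s]]))
      stop("group ", group$group_id, " rejected: cds/protein length ",
           "mismatch for strain ", s)
  }
  if (length(unique(prot)) == 1L) {
    aligned <- prot                       # identical members: trivial MSA
  } else {
    aligned <- .run_mafft(prot)
    aligned <- aligned[strains]
  }
  rows <- vapply(strains, function(s) {
    ap <- strsplit(aligned[[s]], "")[[1]]
    codons <- substring(cds[[s]], seq(1, nchar(cds[[s]]), 3),
                        seq(3, nchar(cds[[s]]), 3))
    out <- character(length(ap))
    k <- 0
    for (i in seq_along(ap)) {
      if (ap[i] == "-") out[i] <- "---"
      else { k <- k + 1; out[i] <- codons[k] }
    }
    paste(out, collapse = "")
  }, character(1))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1)
    stop("group ", group$group_id, ": inconsistent aligned lengths")
  structure(list(group_id = group$group_id, rows = rows,
                 length = unname(lens[1])),
            class = "locus_alignment")
}

# Multiple protein alignment through mafft (on PATH).
.run_mafft <- function(seqs) {
  mafft <- Sys.which("mafft")
  if (!nzchar(mafft)) stop("mafft not found on PATH")
  fin <- tempfile(fileext = ".faa")
  on.exit(unlink(fin), add = TRUE)
  writeLines(paste0(">", names(seqs), "\n", unlist(seqs)), fin)
  out <- suppressWarnings(
    system2(mafft, c("--auto", "--quiet", "--amino", shQuote(fin)),
            stdout = TRUE, stderr = FALSE))
  if (!length(out) || !startsWith(out[1], ">"))
    stop("mafft failed")
  hdr <- grepl("^>", out)
  ids <- sub("^>", "", sub("\\s.*$", "", out[hdr]))
  idx <- cumsum(hdr)
  body <- tapply(out[!hdr], idx[!hdr], paste, collapse = "")
  stats::setNames(toupper(unname(body)), ids)
}

#' Align many groups, collecting rejections
#' @param groups List of `ortholog_group`s.
#' @return List with `alignments` and `rejected` (named reasons).
#' @export
align_loci <- function(groups) {
  alignments <- list()
  rejected <- character(0)
  for (g in groups) {
    res <- tryCatch(align_locus(g), error = function(e) e)
    if (inherits(res, "error")) rejected[g$group_id] <- conditionMessage(res)
    else alignments[[g$group_id]] <- res
  }
  list(alignments = alignments, rejected = rejected)
}

# Pairwise ungapped nucleotide identity between two aligned rows.
.ungapped_identity <- function(x, y) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  ok <- a != "-" & b != "-"
  if (!any(ok)) return(0)
  100 * sum(a[ok] == b[ok]) / sum(ok)
}

#' Divergence filter on locus alignments
#'
#' Drops unusually divergent loci: a locus is removed iff its pairwise
#' ungapped nucleotide identity statistic falls strictly below
#' `min_identity` percent (default 25). The statistic is the minimum over
#' all row pairs by default (`stat = "min"`); `"mean"` is available.
#'
#' @param alignments List of `locus_alignment`s.
#' @param min_identity Percent threshold (strict less-than drops).
#' @param stat `"min"` or `"mean"` pairwise identity.
#' @return Filtered list.
#' @export
filter_by_divergence <- function(alignments, min_identity = 25,
                                 stat = c("min", "mean")) {
  stat <- match.arg(stat)
  keep <- vapply(alignments, function(al) {
    rows <- al$rows
    n <- length(rows)
    vals <- numeric(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      vals <- c(vals, .ungapped_identity(rows[[i]], rows[[j]]))
    s <- if (stat == "min") min(vals) else mean(vals)
    !(s < min_identity)
  }, logical(1))
  alignments[keep]
}

#' Concatenate locus alignments and mask to variable sites
#'
#' Concatenates the loci in `group_id` order, then deletes every column
#' containing a gap or ambiguity code and every invariant column. What
#' remains are the core variable nucleotide sites. Pre-masking partition
#' ranges are recorded for provenance.
#'
#' @param alignments List of `locus_alignment`s over one common strain set.
#' @return A `supermatrix`: `ids`, `columns` (character matrix, strains x
#'   sites), `n_variable_sites`, `partitions` (group_id -> c(start, end),
#'   pre-masking coordinates).
#' @export
concatenate_and_mask <- function(alignments) {
  if (!length(alignments)) stop("no alignments to concatenate")
  alignments <- alignments[order(vapply(alignments, `[[`, character(1),
                                        "group_id"))]
  ids <- sort(names(alignments[[1]]$rows))
  for (al in alignments)
    if (!setequal(names(al$rows), ids))
      stop("inconsistent strain sets across loci (", al$group_id, ")")
  mats <- list()
  partitions <- list()
  pos <- 0L
  for (al in alignments) {
    m <- do.call(rbind, strsplit(unlist(al$rows[ids]), ""))
    rownames(m) <- ids
    mats[[al$group_id]] <- m
    partitions[[al$group_id]] <- c(start = pos + 1L, end = pos + ncol(m))
    pos <- pos + ncol(m)
  }
  full <- do.call(cbind, mats)
  unambiguous <- apply(full, 2, function(col) all(col %in%
                                                    c("A", "C", "G", "T")))
  variable <- apply(full, 2, function(col) length(unique(col)) >= 2)
  keep <- unambiguous & variable
  cols <- full[, keep, drop = FALSE]
  if (!ncol(cols))
    warning("supermatrix is empty: no variable gap-free columns")
  structure(list(ids = ids, columns = cols,
                 n_variable_sites = ncol(cols), partitions = partitions),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix: %d strains x %d core variable sites (%d loci)>\n",
              length(x$ids), x$n_variable_sites, length(x$partitions)))
  invisible(x)
}

#' Jukes-Cantor distance matrix from a supermatrix
#'
#' Per pair, p is the proportion of mismatching columns and
#' `d = -(3/4) ln(1 - 4p/3)` substitutions/site. Saturated pairs
#' (p >= 0.75) are capped at 5.0 with a warning.
#'
#' @param sm A `supermatrix` with >= 2 rows and >= 1 column.
#' @param cap Distance assigned to saturated pairs.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
jc_distance_matrix <- function(sm, cap = 5.0) {
  if (length(sm$ids) < 2 || !ncol(sm$columns))
    stop("supermatrix must have >= 2 rows and >= 1 column")
  n <- length(sm$ids)
  d <- matrix(0, n, n, dimnames = list(sm$ids, sm$ids))
  capped <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- mean(sm$columns[i, ] != sm$columns[j, ])
    if (p >= 0.75) { d[i, j] <- d[j, i] <- cap; capped <- TRUE }
    else d[i, j] <- d[j, i] <- jc_distance(p)
  }
  if (capped) warning("saturated pair(s) (p >= 0.75) capped at ", cap)
  d
}

#' Jukes-Cantor distance for a mismatch proportion
#' @param p Mismatch proportion in [0, 0.75).
#' @return `-(3/4) ln(1 - 4p/3)`.
#' @export
jc_distance <- function(p) {
  if (any(p < 0 | p >= 0.75)) stop("p must be in [0, 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ (via ape), with negative branch lengths clamped to zero.
#'
#' @param d Symmetric numeric distance matrix with ids as dimnames.
#' @return An `ape::phylo` tree (unrooted for >= 3 taxa).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix is not symmetric")
  if (nrow(d) < 2) stop("need >= 2 taxa")
  if (nrow(d) == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                        rownames(d)[1], d[1, 2] / 2,
                                        rownames(d)[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Count of non-trivial bipartitions present in exactly one of the two
#' unrooted trees.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Integer symmetric-difference count.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Trim a sequence to the span of a reference
#'
#' Globally aligns the reference within the query (ends-free on the query)
#' and truncates the query to the columns spanned by the reference's first
#' and last residues — the way 16S sequences are trimmed to a common
#' near-full-length reference before identity comparison. If the aligned
#' query span covers less than half the reference the result is flagged
#' (attribute `low_coverage`).
#'
#' @param query,reference Nucleotide `seq_record`s.
#' @return The trimmed query `seq_record` (attribute `low_coverage` set
#'   when applicable).
#' @export
trim_to_reference <- function(query, reference) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reference$seq),
    Biostrings::DNAString(query$seq),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  sr <- Biostrings::subject(al)
  s_start <- BiocGenerics::start(sr)[1]
  s_end <- BiocGenerics::end(sr)[1]
  trimmed <- seq_record(query$id, substr(query$seq, s_start, s_end),
                        "nucleotide", desc = query$desc)
  span <- s_end - s_start + 1L
  if (span < 0.5 * nchar(reference$seq))
    attr(trimmed, "low_coverage") <- TRUE
  trimmed
}

#' 16S rRNA species demarcation flag
#'
#' Pairs with 16S identity strictly greater than 98.65% are flagged as
#' potentially the same species; the flag is a screen, not a verdict —
#' strains above it can still prove to be distinct species on
#' whole-genome evidence.
#'
#' @param identity Percent identity in [0, 100].
#' @return `"same_species_candidate"` or `"distinct"`.
#' @export
demarcate_species <- function(identity) {
  if (any(identity < 0 | identity > 100)) stop("identity outside [0,100]")
  ifelse(identity > 98.65, "same_species_candidate", "distinct")
}

#' Extract a marker gene from a proteome by reference similarity
#'
#' Finds the proteome member with the best protein-level alignment to a
#' reference marker protein (e.g. RpoB) and returns it with its CDS —
#' marker extraction from whole-genome data.
#'
#' @param p A `proteome`.
#' @param reference_protein A protein `seq_record`.
#' @return List with `protein` (seq_record), `cds` (seq_record or NULL)
#'   and `alignment` (the winning `alignment_result`), or NULL if nothing
#'   aligns.
#' @export
extract_marker <- function(p, reference_protein) {
  best <- NULL
  for (pr in p$proteins) {
    al <- align_protein_pair(pr, reference_protein)
    if (al$no_alignment) next
    if (is.null(best) || al$score > best$score) best <- al
  }
  if (is.null(best)) return(NULL)
  list(protein = p$proteins[[best$query_id]],
       cds = if (!is.null(p$cds)) p$cds[[best$query_id]] else NULL,
       alignment = best)
}

#' Write a supermatrix as relaxed PHYLIP
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_supermatrix_phylip <- function(sm, path) {
  rows <- apply(sm$columns, 1, paste, collapse = "")
  lines <- c(sprintf("%d %d", length(sm$ids), sm$n_variable_sites),
             sprintf("%s  %s", sm$ids, rows))
  writeLines(lines, path)
  invisible(path)
}

#' Write a supermatrix as FASTA
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_supermatrix_fasta <- function(sm, path) {
  rows <- apply(sm$columns, 1, paste, collapse = "")
  recs <- Map(function(i, s) seq_record(i, s, "nucleotide"), sm$ids, rows)
  write_fasta(unname(recs), path)
}

#' Run the full core-genome pipeline on a set of proteomes
#'
#' Reciprocal qualifying pairs -> single-copy ortholog groups ->
#' length-uniformity filter -> codon-aware alignment -> divergence filter
#' -> concatenation and masking. Per-stage counts are recorded.
#'
#' @param proteomes List of `proteome`s with CDS.
#' @param thresholds An [aai_thresholds()].
#' @param length_fraction,min_locus_nt_identity Filter parameters.
#' @param max_targets Passed to the search.
#' @return List with `supermatrix`, `stages` (named counts) and
#'   `rejected` (alignment rejection reasons).
#' @export
core_genome_pipeline <- function(proteomes, thresholds = aai_thresholds(),
                                 length_fraction = 0.90,
                                 min_locus_nt_identity = 25,
                                 max_targets = 8L) {
  ps <- core_pairsets(proteomes, thresholds, max_targets = max_targets)
  groups <- build_ortholog_groups(ps, proteomes)
  kept_len <- filter_by_length(groups, length_fraction)
  aligned <- align_loci(kept_len)
  kept_div <- filter_by_divergence(aligned$alignments,
                                   min_locus_nt_identity)
  sm <- concatenate_and_mask(kept_div)
  list(supermatrix = sm,
       stages = c(single_copy_groups = length(groups),
                  after_length_filter = length(kept_len),
                  aligned = length(aligned$alignments),
                  after_divergence_filter = length(kept_div),
                  variable_sites = sm$n_variable_sites),
       rejected = aligned$rejected)
}
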