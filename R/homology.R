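# Pairwise alignment, per-proteome best hits, reciprocal pairs and genome
# fragmentation. All DP alignments are delegated to
# Biostrings::pairwiseAlignment; identity follows the blast pident
# convention (matches / alignment columns, gap columns included) and
# coverage is per direction against the query's full length.

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.aln_no_hit <- function(qid, sid) {
  structure(list(query_id = qid, subject_id = sid, identity = 0,
                 query_coverage = 0, subject_coverage = 0, score = 0,
                 aln_length = 0L, no_alignment = TRUE, strand = "+"),
            class = "alignment_result")
}

.aln_result <- function(qid, sid, identity, qcov, scov, score, aln_length,
                        strand = "+") {
  structure(list(query_id = qid, subject_id = sid, identity = identity,
                 query_coverage = qcov, subject_coverage = scov,
                 score = score, aln_length = as.integer(aln_length),
                 no_alignment = FALSE, strand = strand),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  if (x$no_alignment)
    cat(sprintf("<alignment %s ~ %s: no positive-scoring alignment>\n",
                x$query_id, x$subject_id))
  else
    cat(sprintf(
      "<alignment %s ~ %s: id %.1f%%, cov %.1f/%.1f%%, score %g>\n",
      x$query_id, x$subject_id, x$identity, x$query_coverage,
      x$subject_coverage, x$score))
  invisible(x)
}

# Summarise a PairwiseAlignmentsSingleSubject (pattern = queries, subject =
# single target) into per-query identity / coverage / score vectors.
# Coverage of the *pattern* side uses each pattern's full length.
.aln_stats <- function(al, pattern_lens, subject_len) {
  sc <- Biostrings::score(al)
  cols <- Biostrings::nchar(al)                  # alignment columns
  matches <- Biostrings::nmatch(al)
  pr <- Biostrings::pattern(al)
  sr <- Biostrings::subject(al)
  p_res <- BiocGenerics::end(pr) - BiocGenerics::start(pr) + 1L
  s_res <- BiocGenerics::end(sr) - BiocGenerics::start(sr) + 1L
  list(score = sc,
       identity = ifelse(cols > 0, 100 * matches / cols, 0),
       cols = cols,
       p_cov = 100 * p_res / pattern_lens,
       s_cov = 100 * s_res / subject_len,
       p_start = BiocGenerics::start(pr), p_end = BiocGenerics::end(pr),
       s_start = BiocGenerics::start(sr), s_end = BiocGenerics::end(sr))
}

#' Align two protein sequences
#'
#' Optimal Smith-Waterman local alignment under BLOSUM62 with affine gap
#' penalties (open 11, extend 1 by default). Identity is
#' matches / alignment columns (gap columns included); each coverage is the
#' aligned residues of that sequence over its full length.
#'
#' @param a,b Protein `seq_record`s.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param substitution_matrix Matrix name or matrix; default BLOSUM62.
#' @return An `alignment_result`; when no positive-scoring alignment exists
#'   the result has `no_alignment = TRUE` and score 0.
#' @export
align_protein_pair <- function(a, b, gap_open = 11, gap_extend = 1,
                               substitution_matrix = NULL) {
  for (r in list(a, b))
    if (!inherits(r, "seq_record") || r$alphabet != "protein" ||
        !nzchar(r$seq))
      stop("align_protein_pair needs two non-empty protein seq_records")
  mat <- substitution_matrix
  if (is.null(mat)) mat <- .blosum62()
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(a$seq), Biostrings::AAString(b$seq),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  st <- .aln_stats(al, nchar(a$seq), nchar(b$seq))
  if (st$score[1] <= 0 || st$cols[1] == 0)
    return(.aln_no_hit(a$id, b$id))
  .aln_result(a$id, b$id, st$identity[1], st$p_cov[1], st$s_cov[1],
              st$score[1], st$cols[1])
}

#' Align two nucleotide sequences
#'
#' Local alignment with match/mismatch scoring (+2/-3) and affine gaps
#' (open 5, extend 2), blastn-style. Both strands of the query are searched
#' when `both_strands = TRUE`; the reported strand is that of the better
#' alignment.
#'
#' @param a,b Nucleotide `seq_record`s (query, subject).
#' @param match,mismatch Match reward / mismatch penalty.
#' @param gap_open,gap_extend Affine gap penalties.
#' @param both_strands Also try the reverse complement of `a`.
#' @return An `alignment_result` (strand in `$strand`).
#' @export
align_nucleotide_pair <- function(a, b, match = 2, mismatch = -3,
                                  gap_open = 5, gap_extend = 2,
                                  both_strands = TRUE) {
  for (r in list(a, b))
    if (!inherits(r, "seq_record") || r$alphabet != "nucleotide" ||
        !nzchar(r$seq))
      stop("align_nucleotide_pair needs two non-empty nucleotide seq_records")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  run <- function(qseq) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(qseq), Biostrings::DNAString(b$seq),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
  }
  al <- run(a$seq)
  strand <- "+"
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(a$seq)))
    al2 <- run(rc)
    if (Biostrings::score(al2)[1] > Biostrings::score(al)[1]) {
      al <- al2
      strand <- "-"
    }
  }
  st <- .aln_stats(al, nchar(a$seq), nchar(b$seq))
  if (st$score[1] <= 0 || st$cols[1] == 0)
    return(.aln_no_hit(a$id, b$id))
  .aln_result(a$id, b$id, st$identity[1], st$p_cov[1], st$s_cov[1],
              st$score[1], st$cols[1], strand)
}

# 3-mer inverted index over a protein set; returns, for each query index,
# candidate subject indices ranked by shared-kmer count.
.kmer_candidates <- function(qseqs, sseqs, k = 3L, top = 8L) {
  skmers <- lapply(sseqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  idx <- split(rep(seq_along(skmers), lengths(skmers)),
               unlist(skmers, use.names = FALSE))
  lapply(qseqs, function(q) {
    n <- nchar(q)
    if (n < k) return(seq_along(sseqs))
    qk <- unique(substring(q, 1:(n - k + 1L), k:n))
    hits <- unlist(idx[qk], use.names = FALSE)
    if (!length(hits)) return(integer(0))
    counts <- tabulate(hits, nbins = length(sseqs))
    cand <- which(counts > 0)
    cand[order(-counts[cand])][seq_len(min(top, length(cand)))]
  })
}

# All candidate protein alignments of proteome a (queries) against proteome
# b (subjects). Exhaustive when the problem is small or max_targets = 0;
# otherwise a shared-3-mer prescreen keeps the top `max_targets` subjects
# per query before exact DP. Returns a data.frame.
.proteome_hits <- function(a, b, gap_open = 11, gap_extend = 1,
                           max_targets = 8L, exhaustive_limit = 2500L) {
  qids <- names(a$proteins)
  sids <- names(b$proteins)
  qseqs <- vapply(a$proteins, `[[`, character(1), "seq")
  sseqs <- vapply(b$proteins, `[[`, character(1), "seq")
  nq <- length(qseqs); ns <- length(sseqs)
  if (max_targets <= 0L || nq * ns <= exhaustive_limit)
    cand <- rep(list(seq_len(ns)), nq)
  else
    cand <- .kmer_candidates(qseqs, sseqs, top = max_targets)
  sset <- Biostrings::AAStringSet(sseqs)
  mat <- .blosum62()
  slens <- nchar(sseqs)
  out <- vector("list", nq)
  for (i in seq_len(nq)) {
    ci <- cand[[i]]
    if (!length(ci)) next
    al <- Biostrings::pairwiseAlignment(
      sset[ci], Biostrings::AAString(qseqs[i]), type = "local",
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend)
    st <- .aln_stats(al, slens[ci], nchar(qseqs[i]))
    keep <- st$score > 0 & st$cols > 0
    if (!any(keep)) next
    out[[i]] <- data.frame(
      query_id = qids[i], subject_id = sids[ci][keep],
      identity = st$identity[keep],
      query_coverage = st$s_cov[keep],     # query was the DP 'subject'
      subject_coverage = st$p_cov[keep],
      score = st$score[keep], aln_length = st$cols[keep],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity = numeric(0), query_coverage = numeric(0),
                      subject_coverage = numeric(0), score = numeric(0),
                      aln_length = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Best hit of every query protein in a subject proteome
#'
#' For each protein of `query`, the single highest-scoring alignment
#' against `subject`. Ties are broken by higher identity, then by
#' lexicographically smaller subject id, so the result is independent of
#' input order. Queries with no positive-scoring alignment are absent.
#'
#' @param query,subject `proteome` objects.
#' @param max_targets Candidate subjects retained per query by the shared
#'   3-mer prescreen before exact DP; `0` forces an exhaustive all-vs-all
#'   search (always used when |query| x |subject| <= 2500).
#' @param hits Optional precomputed hit `data.frame` (e.g. from
#'   [read_hit_table()], columns as `.proteome_hits`) replacing the
#'   internal aligner.
#' @return A `best_hit_map`: list with `query_strain`, `subject_strain` and
#'   `hits` (data.frame, one row per query).
#' @export
best_hits <- function(query, subject, max_targets = 8L, hits = NULL) {
  if (!inherits(query, "proteome") || !inherits(subject, "proteome"))
    stop("best_hits needs two proteome objects")
  if (!length(query$proteins) || !length(subject$proteins))
    stop("empty proteome")
  if (is.null(hits))
    hits <- .proteome_hits(query, subject, max_targets = max_targets)
  if (nrow(hits)) {
    o <- order(hits$query_id, -hits$score, -hits$identity, hits$subject_id,
               method = "radix")
    hits <- hits[o, , drop = FALSE]
    hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
    rownames(hits) <- NULL
  }
  structure(list(query_strain = query$strain_id,
                 subject_strain = subject$strain_id, hits = hits),
            class = "best_hit_map")
}

#' @export
print.best_hit_map <- function(x, ...) {
  cat(sprintf("<best_hit_map %s -> %s: %d queries with hits>\n",
              x$query_strain, x$subject_strain, nrow(x$hits)))
  invisible(x)
}

#' Reciprocally consistent protein pairs between two proteomes
#'
#' Pairs (x, y) such that y is x's best hit in the A->B direction and x is
#' y's best hit in B->A. Each protein occurs in at most one pair.
#'
#' @param ab,ba `best_hit_map`s for the two directions of one proteome
#'   pair.
#' @return data.frame with `protein_a, protein_b, identity_ab, identity_ba,
#'   coverage_ab, coverage_ba` (coverages are query-side per direction).
#' @export
reciprocal_pairs <- function(ab, ba) {
  if (!inherits(ab, "best_hit_map") || !inherits(ba, "best_hit_map"))
    stop("reciprocal_pairs needs two best_hit_maps")
  if (ab$query_strain != ba$subject_strain ||
      ab$subject_strain != ba$query_strain)
    stop("best_hit_maps are not the two directions of one proteome pair (",
         ab$query_strain, "->", ab$subject_strain, " vs ",
         ba$query_strain, "->", ba$subject_strain, ")")
  empty <- data.frame(protein_a = character(0), protein_b = character(0),
                      identity_ab = numeric(0), identity_ba = numeric(0),
                      coverage_ab = numeric(0), coverage_ba = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(ab$hits) || !nrow(ba$hits)) return(empty)
  back <- stats::setNames(ba$hits$subject_id, ba$hits$query_id)
  sel <- !is.na(back[ab$hits$subject_id]) &
    back[ab$hits$subject_id] == ab$hits$query_id
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) return(empty)
  fwd <- ab$hits[sel, , drop = FALSE]
  rev_rows <- ba$hits[match(fwd$subject_id, ba$hits$query_id), ,
                      drop = FALSE]
  data.frame(protein_a = fwd$query_id, protein_b = fwd$subject_id,
             identity_ab = fwd$identity, identity_ba = rev_rows$identity,
             coverage_ab = fwd$query_coverage,
             coverage_ba = rev_rows$query_coverage,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cut a genome into consecutive fragments
#'
#' Splits every contig 5'->3' into consecutive non-overlapping fragments of
#' `fragment_length` bp (the JSpecies ANIb convention of ~1020 bp); a
#' shorter terminal fragment is retained and flagged `partial` in its
#' description. Fragment ids are `<contig>:<1-based start>`.
#'
#' @param g A [genome()].
#' @param fragment_length Fragment size in bp (>= 100).
#' @return List of nucleotide `seq_record`s.
#' @export
fragment_genome <- function(g, fragment_length = 1020) {
  if (!inherits(g, "genome")) stop("fragment_genome needs a genome")
  if (fragment_length < 100) stop("fragment_length must be >= 100")
  out <- list()
  for (ct in g$contigs) {
    n <- nchar(ct$seq)
    starts <- seq.int(1L, n, by = fragment_length)
    ends <- pmin(starts + fragment_length - 1L, n)
    for (j in seq_along(starts)) {
      partial <- (ends[j] - starts[j] + 1L) < fragment_length
      out[[length(out) + 1L]] <- seq_record(
        paste0(ct$id, ":", starts[j]),
        substr(ct$seq, starts[j], ends[j]), "nucleotide",
        desc = if (partial) "partial" else "")
    }
  }
  out
}
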