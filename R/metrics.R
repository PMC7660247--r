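# AAI, POCP and ANIb between strain pairs, plus all-vs-all matrices.

#' AAI inclusion thresholds
#'
#' The protein-pair inclusion criteria used for AAI and POCP: pairs must
#' exceed `min_identity` percent amino-acid identity over at least
#' `min_coverage` percent coverage length. AAI values are parameter
#' dependent, so genus-delineation cut-offs only transfer between studies
#' computed at the same thresholds (40/50 by default).
#'
#' @param min_identity Minimum percent identity (default 40).
#' @param min_coverage Minimum percent coverage (default 50).
#' @return A list of class `aai_thresholds`.
#' @export
aai_thresholds <- function(min_identity = 40, min_coverage = 50) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 100)
  structure(list(min_identity = min_identity, min_coverage = min_coverage),
            class = "aai_thresholds")
}

.coverage_ok <- function(cov_ab, cov_ba, min_coverage,
                         mode = c("both", "either", "shorter")) {
  mode <- match.arg(mode)
  switch(mode,
         both = cov_ab >= min_coverage & cov_ba >= min_coverage,
         either = cov_ab >= min_coverage | cov_ba >= min_coverage,
         # coverage relative to the shorter sequence is the larger of the
         # two per-direction coverages
         shorter = pmax(cov_ab, cov_ba) >= min_coverage)
}

#' Average amino acid identity between two proteomes
#'
#' Builds reciprocal best-hit pairs in both search directions, keeps pairs
#' whose identity is at least `min_identity` percent in both directions and
#' whose coverage passes `coverage_mode` at `min_coverage` percent, and
#' averages the per-pair identities (each the mean of the two directional
#' identities, which makes AAI exactly symmetric).
#'
#' @param a,b `proteome` objects.
#' @param thresholds An [aai_thresholds()].
#' @param coverage_mode `"both"` (default, each direction's query coverage
#'   must pass), `"either"`, or `"shorter"`.
#' @param max_targets Passed to [best_hits()].
#' @param hits_ab,hits_ba Optional precomputed hit data.frames (external
#'   search adapter), per direction.
#' @return An `aai_result` with fields `strain_a, strain_b, aai, n_pairs,
#'   sd`. When no pair qualifies, `aai` is `NA` and `n_pairs` 0 — an
#'   explicit "no qualifying pairs" result, never a silent zero.
#' @export
compute_aai <- function(a, b, thresholds = aai_thresholds(),
                        coverage_mode = "both", max_targets = 8L,
                        hits_ab = NULL, hits_ba = NULL) {
  ab <- best_hits(a, b, max_targets = max_targets, hits = hits_ab)
  ba <- best_hits(b, a, max_targets = max_targets, hits = hits_ba)
  rp <- reciprocal_pairs(ab, ba)
  keep <- rp$identity_ab >= thresholds$min_identity &
    rp$identity_ba >= thresholds$min_identity &
    .coverage_ok(rp$coverage_ab, rp$coverage_ba,
                 thresholds$min_coverage, coverage_mode)
  rp <- rp[keep, , drop = FALSE]
  per_pair <- (rp$identity_ab + rp$identity_ba) / 2
  structure(list(strain_a = a$strain_id, strain_b = b$strain_id,
                 aai = if (nrow(rp)) mean(per_pair) else NA_real_,
                 n_pairs = nrow(rp),
                 sd = if (nrow(rp) > 1) stats::sd(per_pair) else NA_real_,
                 pairs = rp),
            class = "aai_result")
}

#' @export
print.aai_result <- function(x, ...) {
  if (is.na(x$aai))
    cat(sprintf("<AAI %s ~ %s: no qualifying pairs>\n", x$strain_a,
                x$strain_b))
  else
    cat(sprintf("<AAI %s ~ %s: %.2f%% over %d pairs (sd %.2f)>\n",
                x$strain_a, x$strain_b, x$aai, x$n_pairs,
                if (is.na(x$sd)) 0 else x$sd))
  invisible(x)
}

#' Percentage of conserved proteins between two proteomes
#'
#' A protein is conserved if it has at least one positive-scoring alignment
#' in the other proteome with identity >= `min_identity` percent over
#' >= `min_coverage` percent of its own (query) length. POCP is
#' `100 * (C_a + C_b) / (T_a + T_b)`. When hits come from an external
#' 12-column table (via [hits_from_table()]) an e-value ceiling has already
#' been applied there; the internal aligner has no e-value statistic.
#'
#' @inheritParams compute_aai
#' @return A `pocp_result` with `pocp`, `conserved_a/b`, `total_a/b`.
#' @export
compute_pocp <- function(a, b, thresholds = aai_thresholds(),
                         max_targets = 8L, hits_ab = NULL, hits_ba = NULL) {
  if (!length(a$proteins) || !length(b$proteins)) stop("empty proteome")
  if (is.null(hits_ab)) hits_ab <- .proteome_hits(a, b,
                                                  max_targets = max_targets)
  if (is.null(hits_ba)) hits_ba <- .proteome_hits(b, a,
                                                  max_targets = max_targets)
  conserved <- function(h) {
    length(unique(h$query_id[h$identity >= thresholds$min_identity &
                               h$query_coverage >= thresholds$min_coverage]))
  }
  ca <- conserved(hits_ab)
  cb <- conserved(hits_ba)
  ta <- length(a$proteins)
  tb <- length(b$proteins)
  structure(list(strain_a = a$strain_id, strain_b = b$strain_id,
                 pocp = 100 * (ca + cb) / (ta + tb),
                 conserved_a = ca, conserved_b = cb,
                 total_a = ta, total_b = tb),
            class = "pocp_result")
}

#' Convert a 12-column hit table to internal hit format
#'
#' Adapter for external search tools: rows of a [read_hit_table()]
#' data.frame become internal hits with coverages computed from the
#' supplied proteomes' sequence lengths. Hits above `max_evalue` are
#' dropped (the published POCP criterion).
#'
#' @param tbl data.frame from [read_hit_table()].
#' @param query,subject The `proteome`s the table refers to.
#' @param max_evalue E-value ceiling (default 1e-5).
#' @return data.frame in the internal hit format accepted by
#'   [best_hits()] and [compute_pocp()].
#' @export
hits_from_table <- function(tbl, query, subject, max_evalue = 1e-5) {
  tbl <- tbl[tbl$evalue <= max_evalue, , drop = FALSE]
  bad <- setdiff(tbl$query_id, names(query$proteins))
  if (length(bad)) stop("hit query id not in proteome: ", bad[1])
  bad <- setdiff(tbl$subject_id, names(subject$proteins))
  if (length(bad)) stop("hit subject id not in proteome: ", bad[1])
  qlen <- nchar(vapply(query$proteins, `[[`, character(1), "seq"))
  slen <- nchar(vapply(subject$proteins, `[[`, character(1), "seq"))
  data.frame(query_id = tbl$query_id, subject_id = tbl$subject_id,
             identity = tbl$pct_identity,
             query_coverage = 100 * (tbl$q_end - tbl$q_start + 1) /
               qlen[tbl$query_id],
             subject_coverage = 100 * (abs(tbl$s_end - tbl$s_start) + 1) /
               slen[tbl$subject_id],
             score = tbl$score, aln_length = tbl$aln_length,
             stringsAsFactors = FALSE, row.names = NULL)
}

# One ANIb direction: fragment `qg`, align each fragment against every
# contig of `sg` on both strands, keep each fragment's best alignment,
# retain fragments passing the identity/coverage criteria.
.anib_direction <- function(qg, sg, fragment_length, min_identity,
                            min_coverage) {
  frags <- fragment_genome(qg, fragment_length)
  fseqs <- vapply(frags, `[[`, character(1), "seq")
  flens <- nchar(fseqs)
  nf <- length(fseqs)
  best_score <- rep(-Inf, nf)
  best_id <- numeric(nf)
  best_cov <- numeric(nf)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = FALSE)
  sets <- list(
    "+" = Biostrings::DNAStringSet(fseqs),
    "-" = Biostrings::reverseComplement(Biostrings::DNAStringSet(fseqs)))
  for (ct in sg$contigs) {
    subj <- Biostrings::DNAString(ct$seq)
    for (set in sets) {
      al <- Biostrings::pairwiseAlignment(
        set, subj, type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      st <- .aln_stats(al, flens, nchar(ct$seq))
      upd <- st$score > best_score
      best_score[upd] <- st$score[upd]
      best_id[upd] <- st$identity[upd]
      best_cov[upd] <- st$p_cov[upd]
    }
  }
  keep <- is.finite(best_score) & best_score > 0 &
    best_id >= min_identity & best_cov >= min_coverage
  list(ani = if (any(keep)) mean(best_id[keep]) else NA_real_,
       aligned_fraction = 100 * sum(flens[keep]) / genome_length(qg),
       n_fragments = nf, n_retained = sum(keep))
}

#' Average nucleotide identity by fragmentation (ANIb)
#'
#' Cuts each genome into ~1020-bp fragments, locally aligns every fragment
#' against the other genome (both strands, +2/-3 with affine gaps 5/2) and
#' averages the identities of fragments whose best alignment reaches
#' `min_identity` percent identity over `min_coverage` percent of the
#' fragment length (30/70, the JSpecies defaults). Both directions are
#' computed and reported with their mean.
#'
#' @param a,b `genome` objects.
#' @param fragment_length Fragment size in bp.
#' @param min_identity,min_coverage Fragment retention criteria (%).
#' @return An `anib_result` with `ani_ab`, `ani_ba`, `ani_mean`,
#'   `aligned_fraction_ab/ba` and retained-fragment counts. If no fragment
#'   is retained in a direction its ANI is `NA`.
#' @export
compute_anib <- function(a, b, fragment_length = 1020, min_identity = 30,
                         min_coverage = 70) {
  if (!inherits(a, "genome") || !inherits(b, "genome"))
    stop("compute_anib needs two genome objects")
  d1 <- .anib_direction(a, b, fragment_length, min_identity, min_coverage)
  d2 <- .anib_direction(b, a, fragment_length, min_identity, min_coverage)
  anis <- c(d1$ani, d2$ani)
  structure(list(strain_a = a$strain_id, strain_b = b$strain_id,
                 ani_ab = d1$ani, ani_ba = d2$ani,
                 ani_mean = if (all(is.na(anis))) NA_real_
                            else mean(anis, na.rm = TRUE),
                 aligned_fraction_ab = d1$aligned_fraction,
                 aligned_fraction_ba = d2$aligned_fraction,
                 n_retained_ab = d1$n_retained,
                 n_retained_ba = d2$n_retained),
            class = "anib_result")
}

#' @export
print.anib_result <- function(x, ...) {
  if (is.na(x$ani_mean))
    cat(sprintf("<ANIb %s ~ %s: no alignment>\n", x$strain_a, x$strain_b))
  else
    cat(sprintf("<ANIb %s ~ %s: %.2f%% (%.2f / %.2f)>\n", x$strain_a,
                x$strain_b, x$ani_mean, x$ani_ab, x$ani_ba))
  invisible(x)
}

#' All-vs-all pairwise identity matrix
#'
#' Computes every unordered strain pair once (n(n-1)/2 comparisons) with
#' [compute_aai()], [compute_anib()] or [compute_pocp()] and assembles a
#' symmetric matrix with a diagonal fixed at 100 by definition.
#'
#' @param strains List of `proteome`s (AAI/POCP) or `genome`s (ANIb) with
#'   unique strain ids.
#' @param metric `"aai"`, `"anib"` or `"pocp"`.
#' @param ... Passed to the per-pair function.
#' @return A `pairwise_matrix`: list with `ids`, symmetric `values` matrix
#'   (percent) and `metric`.
#' @export
build_matrix <- function(strains, metric = c("aai", "anib", "pocp"), ...) {
  metric <- match.arg(metric)
  if (length(strains) < 2) stop("need at least 2 strains")
  ids <- vapply(strains, `[[`, character(1), "strain_id")
  if (anyDuplicated(ids))
    stop("duplicate strain id: ", ids[duplicated(ids)][1])
  n <- length(ids)
  v <- matrix(100, n, n, dimnames = list(ids, ids))
  fun <- switch(metric,
                aai = function(x, y) compute_aai(x, y, ...)$aai,
                anib = function(x, y) compute_anib(x, y, ...)$ani_mean,
                pocp = function(x, y) compute_pocp(x, y, ...)$pocp)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    val <- fun(strains[[i]], strains[[j]])
    v[i, j] <- v[j, i] <- val
  }
  pairwise_matrix(ids, v, metric)
}

#' Construct a pairwise identity matrix object
#' @param ids Strain tokens (unique).
#' @param values Symmetric numeric matrix, diagonal 100.
#' @param metric Metric label (`"aai"`, `"anib"`, `"pocp"`).
#' @return A `pairwise_matrix`.
#' @export
pairwise_matrix <- function(ids, values, metric = "aai") {
  if (anyDuplicated(ids)) stop("duplicate strain ids")
  values <- as.matrix(values)
  if (nrow(values) != length(ids) || ncol(values) != length(ids))
    stop("matrix dimensions do not match ids")
  dimnames(values) <- list(ids, ids)
  if (any(abs(values - t(values)) > 1e-8, na.rm = TRUE))
    stop("matrix is not symmetric")
  structure(list(ids = ids, values = values, metric = metric),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<%s matrix: %d strains, %d pairwise comparisons>\n",
              toupper(x$metric), length(x$ids),
              length(x$ids) * (length(x$ids) - 1) / 2))
  invisible(x)
}

#' Off-diagonal values of a pairwise matrix
#' @param m A `pairwise_matrix`.
#' @return Numeric vector of the n(n-1)/2 unordered pair values.
#' @export
matrix_values <- function(m) {
  m$values[upper.tri(m$values)]
}

#' Write / read a symmetric identity matrix as TSV
#'
#' The format is a header row and column of strain ids around a symmetric
#' body printed at two decimals.
#'
#' @param m A `pairwise_matrix`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  body <- format(round(m$values, 2), nsmall = 2, trim = TRUE)
  df <- cbind(strain = m$ids, as.data.frame(body, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param metric Metric label to attach on read.
#' @export
read_matrix_tsv <- function(path, metric = "aai") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df[[1]]
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  pairwise_matrix(ids, v, metric)
}
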